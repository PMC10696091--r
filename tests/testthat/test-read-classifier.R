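test_that("segment_reference enumerates full-length stride windows", {
  s75 <- strrep("A", 75)
  expect_identical(segment_reference(s75, 76, 1), character(0))
  s76 <- paste(rep(c("A", "C", "G", "T"), 19), collapse = "")
  expect_identical(segment_reference(s76, 76, 5), s76)
  s300 <- strrep("ACGT", 75)
  # starts 1, 27, 53, ... while start + 75 <= 300
  expected_n <- length(seq(1, 300 - 76 + 1, by = 26))
  expect_length(segment_reference(s300, 76, 26), expected_n)
  expect_equal(expected_n, 9L)
  # N-containing segments are dropped
  sN <- paste0(strrep("A", 80), "N", strrep("C", 80))
  segs <- segment_reference(sN, 76, 10)
  expect_false(any(grepl("N", segs, fixed = TRUE)))
  expect_error(segment_reference(s300, 0, 1), "positive")
})

test_that("build_dataset splits before segmenting with no leakage", {
  models <- default_origin_models()
  refs <- dplyr::bind_rows(
    make_references(models["human"], 6, c(400, 600), 1),
    make_references(models["viral"], 6, c(400, 600), 2),
    make_references(models["bacterial"], 6, c(400, 600), 3))
  cfg <- segmentation_config(stride_by_class = c(human = 10L, viral = 10L,
                                                 bacterial = 10L))
  ds <- build_dataset(refs, cfg, rng_seed = 4)
  # each reference contributes to exactly one split
  for (acc in refs$accession) {
    in_split <- vapply(ds, function(d) acc %in% d$accession, logical(1))
    expect_lte(sum(in_split), 1L)
  }
  # no validation/test segment appears among training segments
  expect_length(intersect(ds$train$segment,
                          c(ds$val$segment, ds$test$segment)), 0L)
  expect_identical(ds, build_dataset(refs, cfg, rng_seed = 4))
  expect_error(build_dataset(refs[refs$label != "viral", ], cfg, 1),
               "no references")
})

test_that("stride ratios balance per-class segment counts", {
  # total lengths in 13 : 1 : 65 proportion against strides 26 : 2 : 130
  models <- default_origin_models()
  refs <- dplyr::bind_rows(
    make_references(models["human"], 3, c(26000, 26000), 5),
    make_references(models["viral"], 3, c(2000, 2000), 6),
    make_references(models["bacterial"], 3, c(130000, 130000), 7))
  ds <- build_dataset(refs, segmentation_config(
    split_fractions = c(train = 1, val = 0, test = 0)), rng_seed = 8)
  counts <- table(ds$train$label)
  # oracle: per class, sum over refs of floor((len - 76) / stride) + 1
  oracle <- c(bacterial = 3 * ((130000 - 76) %/% 130 + 1),
              human = 3 * ((26000 - 76) %/% 26 + 1),
              viral = 3 * ((2000 - 76) %/% 2 + 1))
  expect_equal(as.vector(counts[names(oracle)]), unname(oracle))
  expect_lt((max(counts) - min(counts)) / max(counts), 0.05)
})

test_that("normalize_reads applies the N and padding rules", {
  clean76 <- strrep("ACGT", 19)
  clean75 <- substr(clean76, 1, 75)
  one_n <- paste0("N", substr(clean76, 2, 76))
  two_n <- paste0("NN", substr(clean76, 3, 76))
  out <- withr::with_seed(1, normalize_reads(c(clean76, clean75, one_n,
                                               two_n)))
  expect_identical(out$sequence,
                   c(clean76, clean75, one_n, two_n))  # stored reads untouched
  expect_identical(out$scoring_sequence[1], clean76)
  expect_equal(nchar(out$scoring_sequence[2]), 76L)
  expect_identical(substr(out$scoring_sequence[2], 1, 75), clean75)
  expect_false(grepl("N", out$scoring_sequence[3], fixed = TRUE))
  expect_identical(substr(out$scoring_sequence[3], 1, 1), out$n_fill[3])
  expect_true(out$excluded[4])
  expect_true(is.na(out$scoring_sequence[4]))
  expect_error(normalize_reads(strrep("A", 77)), "longer")
})

test_that("CNN gradients match numerical differentiation", {
  cfg <- classifier_config(filters = c(5L, 4L), widths = c(3L, 3L),
                           dense_units = 6L, input_length = 20L,
                           rng_seed = 2)
  set.seed(3)
  seqs <- vapply(1:6, function(i) {
    paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  }, character(1))
  X <- microseek:::encode_onehot(seqs, 20L)
  Y <- microseek:::onehot_labels(sample(cfg$classes, 6, TRUE), cfg$classes)
  w <- withr::with_seed(2, microseek:::cnn_init(cfg))
  fw <- microseek:::cnn_forward(w, X, cfg, keep_cache = TRUE)
  g <- microseek:::cnn_backward(w, cfg, fw, Y)
  eps <- 1e-5
  for (nm in names(w)) {
    for (rep in 1:2) {
      i <- sample(length(w[[nm]]), 1)
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (microseek:::cnn_loss(microseek:::cnn_forward(wp, X, cfg)$probs, Y) -
              microseek:::cnn_loss(microseek:::cnn_forward(wm, X, cfg)$probs, Y)) /
        (2 * eps)
      expect_equal(unname(g[[nm]][i]), num, tolerance = 1e-4)
    }
  }
})

test_that("zero-epoch training returns an evaluable initialization", {
  models <- default_origin_models()
  refs <- dplyr::bind_rows(
    make_references(models["human"], 3, c(300, 400), 1),
    make_references(models["viral"], 3, c(300, 400), 2),
    make_references(models["bacterial"], 3, c(300, 400), 3))
  # deterministic split: one reference per class into each split
  mk_split <- function(idx) {
    dplyr::bind_rows(lapply(idx, function(i) tibble::tibble(
      segment = segment_reference(refs$sequence[i], 76, 20),
      label = refs$label[i], accession = refs$accession[i])))
  }
  ds <- list(train = mk_split(c(1, 4, 7)), val = mk_split(c(2, 5, 8)),
             test = mk_split(c(3, 6, 9)))
  m0 <- train_classifier(ds, classifier_config(epochs = 0L, rng_seed = 6))
  ev <- evaluate_classifier(m0, ds$test)
  expect_true(all(ev$metrics$auprc >= 0 & ev$metrics$auprc <= 1, na.rm = TRUE))
  probs <- predict_origin(m0, ds$test$segment)
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
})

test_that("AUROC matches brute-force pairwise computation", {
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.2), c(TRUE, FALSE, TRUE, FALSE)),
               0.75)
  set.seed(10)
  for (i in 1:10) {
    n <- 60
    scores <- sample(seq(0, 1, by = 0.1), n, TRUE)  # forced ties
    labels <- sample(c(TRUE, FALSE), n, TRUE)
    expect_equal(auroc(scores, labels), brute_auroc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUPRC endpoints behave like the published baselines", {
  labels <- rep(c(TRUE, FALSE), c(30, 60))
  perfect <- ifelse(labels, 1, 0)
  expect_equal(auprc(perfect, labels), 1.0, tolerance = 1e-12)
  expect_equal(auroc(perfect, labels), 1.0, tolerance = 1e-12)
  set.seed(11)
  lab3 <- rep(c("a", "b", "c"), each = 1000)
  rnd <- matrix(runif(9000), 3000, 3, dimnames = list(NULL, c("a", "b", "c")))
  m_auprc <- mean(vapply(colnames(rnd),
                         function(k) auprc(rnd[, k], lab3 == k), numeric(1)))
  m_auroc <- mean(vapply(colnames(rnd),
                         function(k) auroc(rnd[, k], lab3 == k), numeric(1)))
  expect_lt(abs(m_auprc - 1 / 3), 0.02)
  expect_lt(abs(m_auroc - 0.5), 0.02)
  # class absent from test labels -> NA metrics
  expect_true(is.na(auprc(runif(5), rep(FALSE, 5))))
})

test_that("scoring is deterministic and respects the exclusion mask", {
  model <- fixture_classifier()
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    sequence = c(strrep("ACGT", 19),
                 paste0("NN", strrep("GT", 37)),
                 substr(strrep("TGCA", 19), 1, 75)))
  s1 <- score_reads(model, reads, rng_seed = 3)
  s2 <- score_reads(model, reads, rng_seed = 3)
  expect_identical(s1, s2)
  expect_true(s1$excluded[2])
  expect_true(all(is.na(s1[2, c("p_human", "p_viral", "p_bacterial")])))
  sums <- rowSums(as.matrix(s1[c(1, 3), c("p_human", "p_viral",
                                          "p_bacterial")]))
  expect_equal(sums, c(1, 1), tolerance = 1e-6)
  expect_equal(nrow(score_reads(model, reads[0, ])), 0L)
})

test_that("the trained model separates bacterial from human reads", {
  model <- fixture_classifier()
  models <- default_origin_models()
  refs <- dplyr::bind_rows(
    make_references(models["human"], 2, c(500, 600), 31),
    make_references(models["bacterial"], 2, c(500, 600), 32))
  mk <- function(acc) {
    sp <- sample_spec("S", "P", "case", planted = stats::setNames(5, acc),
                      read_length = 76L, rng_seed = 33)
    make_reads(sp, refs)
  }
  hum <- score_reads(model, mk("HUM_0001"), 34)
  bac <- score_reads(model, mk("BAC_0001"), 35)
  expect_gt(mean(bac$p_bacterial, na.rm = TRUE),
            mean(hum$p_bacterial, na.rm = TRUE))
})

test_that("single-nucleotide substitution rarely flips the predicted class", {
  model <- fixture_classifier()
  ds <- fixture_dataset()
  set.seed(40)
  test_segs <- ds$test$segment[sample.int(nrow(ds$test), 150)]
  orig <- predict_origin(model, test_segs)
  mutated <- vapply(test_segs, function(s) {
    p <- sample.int(76, 1)
    b <- sample(setdiff(c("A", "C", "G", "T"), substr(s, p, p)), 1)
    `substr<-`(s, p, p, value = b)
  }, character(1))
  mut <- predict_origin(model, unname(mutated))
  flipped <- max.col(orig) != max.col(mut)
  expect_lt(mean(flipped), 0.10)
})
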