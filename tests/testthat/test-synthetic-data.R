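test_that("origin models validate their transition matrices", {
  bad <- matrix(1, 16, 4)  # rows sum to 4
  expect_error(origin_model("human", bad, 0.5), "sum to 1")
  models <- default_origin_models()
  for (m in models) {
    expect_equal(unname(rowSums(m$transition)), rep(1, 16), tolerance = 1e-9)
  }
  expect_setequal(vapply(models, `[[`, "", "label"),
                  c("human", "viral", "bacterial"))
})

test_that("reference generation is deterministic and respects boundaries", {
  models <- default_origin_models()
  expect_equal(nrow(make_references(models, 0, c(300, 400), 1)), 0L)
  r1 <- make_references(models, 3, c(300, 400), rng_seed = 7)
  r2 <- make_references(models, 3, c(300, 400), rng_seed = 7)
  expect_identical(r1, r2)
  r3 <- make_references(models, 3, c(300, 400), rng_seed = 8)
  expect_false(identical(r1$sequence, r3$sequence))
  expect_true(all(nchar(r1$sequence) >= 300 & nchar(r1$sequence) <= 400))
})

test_that("realized GC tracks the model's gc_target", {
  models <- default_origin_models()
  seqs <- withr::with_seed(5, {
    microseek:::markov_sequences(models$bacterial, rep(1000L, 10L))
  })
  gc <- mean(strsplit(paste(seqs, collapse = ""), "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - models$bacterial$gc_target), 0.03)
})

test_that("read simulation follows the shotgun model", {
  models <- default_origin_models()
  refs <- make_references(models["bacterial"], 1, c(760, 760), rng_seed = 2)
  # zero coverage, zero host reads: empty read set
  sp0 <- sample_spec("S0", "P1", "case",
                     planted = c(BAC_0001 = 0), read_length = 76L,
                     rng_seed = 1)
  expect_equal(nrow(make_reads(sp0, refs)), 0L)
  # n_rate 0: no N anywhere
  sp1 <- sample_spec("S1", "P1", "case", planted = c(BAC_0001 = 5),
                     read_length = 76L, n_rate = 0, rng_seed = 3)
  rd1 <- make_reads(sp1, refs)
  expect_false(any(grepl("N", rd1$sequence, fixed = TRUE)))
  # expected count = coverage * L / read_length with Poisson spread
  counts <- vapply(1:20, function(s) {
    sp <- sample_spec("S", "P1", "case", planted = c(BAC_0001 = 10),
                      read_length = 76L, rng_seed = s)
    nrow(make_reads(sp, refs))
  }, numeric(1))
  expect_true(all(counts >= 70 & counts <= 130))  # 100 +/- 30
  expect_lt(abs(mean(counts) - 100), 10)
  # unknown planted accession errors
  expect_error(make_reads(sample_spec("S", "P1", "case",
                                      planted = c(NOPE = 1), rng_seed = 1),
                          refs),
               "not found")
})

test_that("reads tile a planted transcript at high coverage", {
  # under uniform read starts the terminal few bases are structurally
  # under-covered (a position x < read_length is reachable only by the x
  # leftmost starts), so full-transcript tiling is checked over the
  # interior, where coverage >= 1 holds essentially surely at 20x
  models <- default_origin_models()
  refs <- make_references(models["bacterial"], 1, c(600, 600), rng_seed = 4)
  interior <- 75:526
  covered_all <- vapply(1:20, function(s) {
    sp <- sample_spec("S", "P1", "case", planted = c(BAC_0001 = 20),
                      read_length = 75L, rng_seed = s)
    rd <- make_reads(sp, refs)
    cov <- integer(600)
    for (i in seq_len(nrow(rd))) {
      ix <- rd$source_start[i]:(rd$source_start[i] + 74L)
      cov[ix] <- cov[ix] + 1L
    }
    all(cov[interior] >= 1L)
  }, logical(1))
  expect_gte(mean(covered_all), 0.9)  # true per-draw rate exceeds 0.99
})

test_that("null cohort covariates are exchangeable across arms", {
  cs <- cohort_spec(250, 250, covariate_effects = numeric(0), rng_seed = 21)
  cv <- make_cohort(cs)$covariates
  for (col in c("age", "weight", "seq_depth")) {
    ks <- stats::ks.test(cv[[col]][cv$cohort == "case"],
                         cv[[col]][cv$cohort == "control"])
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("nonzero covariate effects create learnable confounding", {
  cs <- cohort_spec(250, 250,
                    covariate_effects = c(age = 0.8, weight = 0.8,
                                          smoking = 0.8),
                    rng_seed = 22)
  cv <- make_cohort(cs)$covariates
  fp <- fit_propensity(cv[, c("race", "age", "sex", "weight", "smoking",
                              "seq_depth")],
                       cv$cohort, rng_seed = 23)
  expect_gt(fp$auc, 0.7)
})

test_that("survival generation responds to feature hazards", {
  pm <- matrix(rep(c(TRUE, FALSE), each = 200), ncol = 1,
               dimnames = list(sprintf("P%04d", 1:400), "F"))
  # null hazard: log-rank rejects near nominal rate
  rej <- vapply(1:120, function(s) {
    cs <- cohort_spec(200, 200, feature_hazard = c(F = 0),
                      censoring_rate = 0.2, rng_seed = s)
    sv <- make_cohort(cs, pm)$survival
    sv <- sv[sv$endpoint == "overall", ]
    logrank_test(sv$time, sv$event, pm[sv$patient_id, 1])$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
  # strong hazard: high power
  rej3 <- vapply(1:60, function(s) {
    cs <- cohort_spec(200, 200, feature_hazard = c(F = log(3)),
                      censoring_rate = 0.2, rng_seed = 4000 + s)
    sv <- make_cohort(cs, pm)$survival
    sv <- sv[sv$endpoint == "overall", ]
    logrank_test(sv$time, sv$event, pm[sv$patient_id, 1])$p < 0.05
  }, logical(1))
  expect_gt(mean(rej3), 0.9)
  # unknown hazard feature is a configuration error
  cs_bad <- cohort_spec(5, 5, feature_hazard = c(G = 1), rng_seed = 1)
  expect_error(make_cohort(cs_bad, pm), "not in presence matrix")
})

test_that("generators are pure functions of their seed", {
  models <- default_origin_models()
  refs <- make_references(models, 2, c(300, 400), rng_seed = 6)
  sp <- sample_spec("S", "P1", "case", planted = c(BAC_0001 = 5),
                    read_length = 75L, n_rate = 0.01,
                    host_read_count = 20, rng_seed = 5)
  expect_identical(make_reads(sp, refs), make_reads(sp, refs))
  cs <- cohort_spec(10, 10, covariate_effects = c(age = 1), rng_seed = 9)
  expect_identical(make_cohort(cs), make_cohort(cs))
})
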