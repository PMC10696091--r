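test_that("log-rank matches a step-by-step observed-minus-expected oracle", {
  # 12-patient hand fixture: times, events, groups
  tm <- c(5, 8, 12, 13, 18, 23, 26, 27, 30, 33, 42, 45)
  ev <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0, 1, 1)
  gr <- c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1)
  # tabular oracle: walk event times, accumulate O, E, V directly
  O1 <- 0; E1 <- 0; V <- 0
  for (t in sort(unique(tm[ev == 1]))) {
    at <- tm >= t
    n <- sum(at); n1 <- sum(at & gr == 1)
    d <- sum(tm == t & ev == 1); d1 <- sum(tm == t & ev == 1 & gr == 1)
    O1 <- O1 + d1; E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oracle <- (O1 - E1)^2 / V
  lr <- logrank_test(tm, ev, gr)
  expect_equal(lr$statistic, oracle, tolerance = 1e-12)
  expect_equal(lr$p, stats::pchisq(oracle, 1, lower.tail = FALSE))
})

test_that("log-rank agrees with the survival package to 1e-8", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    tm <- stats::rexp(n)
    ev <- stats::rbinom(n, 1, 0.7)
    gr <- stats::rbinom(n, 1, 0.5)
    if (length(unique(gr)) < 2 || sum(ev) == 0) next
    mine <- logrank_test(tm, ev, gr)$statistic
    ref <- survival::survdiff(survival::Surv(tm, ev) ~ gr)$chisq
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("identical survival in both groups gives chi-squared 0, p 1", {
  tm <- rep(c(3, 6, 9, 12), 2)
  ev <- rep(c(1, 0, 1, 1), 2)
  gr <- rep(c(0, 1), each = 4)
  lr <- logrank_test(tm, ev, gr)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p, 1)
})

test_that("survival screen enforces the 5/5 rule and corrects per endpoint", {
  patients <- sprintf("P%02d", 1:20)
  pm <- matrix(c(rep(c(TRUE, FALSE), c(4, 16)),     # 4 positives: untested
                 rep(c(TRUE, FALSE), c(10, 10))),   # 10/10: tested
               ncol = 2, dimnames = list(patients, c("few", "ok")))
  attr(pm, "cohort") <- factor(rep("case", 20), c("case", "control"))
  attr(pm, "kind") <- "protein"
  sv <- withr::with_seed(42, tibble::tibble(
    patient_id = rep(patients, 2),
    endpoint = rep(c("overall", "disease_free"), each = 20),
    time = stats::rexp(40, 1 / 500),
    event = stats::rbinom(40, 1, 0.8)))
  res <- survival_screen(pm, sv)
  expect_false(any(res$tested[res$feature == "few"]))
  expect_true(all(is.na(res$p[res$feature == "few"])))
  expect_true(all(res$tested[res$feature == "ok"]))
  expect_true(all(!is.na(res$q[res$feature == "ok"])))
  # patients without clinical data are excluded before the 5/5 count:
  # keeping records for patients 1-12 leaves "ok" with only 2 negatives
  sv_short <- sv[sv$patient_id %in% patients[1:12], ]
  res2 <- survival_screen(pm, sv_short)
  ok_row <- res2[res2$feature == "ok" & res2$endpoint == "overall", ]
  expect_equal(ok_row$n_neg, 2L)
  expect_false(ok_row$tested)
})

test_that("host gene screen applies all three selection rules", {
  set.seed(51)
  n <- 30
  grp <- rep(c(TRUE, FALSE), each = n)
  expr <- rbind(
    up = c(rnorm(n, 2), rnorm(n, 0)),        # passes all three
    null = rnorm(2 * n),                      # fails p
    flat = rep(5, 2 * n),                     # constant: p = 1
    # separates (small p) but the negative group's median z stays above 0
    negmed = c(rnorm(n, 1, 0.2), 0.6 + rnorm(20, 0, 0.02),
               rnorm(10, -3, 0.2)))
  res <- host_gene_screen(expr, grp)
  expect_true(res$selected[res$gene == "up"])
  expect_false(res$selected[res$gene == "null"])
  expect_equal(res$p[res$gene == "flat"], 1)
  expect_false(res$selected[res$gene == "flat"])
  expect_lt(res$p[res$gene == "negmed"], 0.05)
  expect_gt(res$median_z_neg[res$gene == "negmed"], 0)
  expect_false(res$selected[res$gene == "negmed"])
})

test_that("host gene selection is invariant to monotone rescaling", {
  set.seed(52)
  n <- 25
  grp <- rep(c(TRUE, FALSE), each = n)
  expr <- rbind(a = c(rnorm(n, 1.2), rnorm(n, -0.3)),
                b = rnorm(2 * n),
                c = c(rnorm(n, -1), rnorm(n, 0.8)))
  res1 <- host_gene_screen(expr, grp)
  rescaled <- expr * 7 + 100  # per-gene affine map, monotone
  res2 <- host_gene_screen(rescaled, grp)
  expect_identical(res1$selected, res2$selected)
})

test_that("gene-set enrichment matches the hypergeometric tail", {
  universe <- paste0("g", 1:20)
  selection <- paste0("g", 1:10)
  sets <- list(hit = paste0("g", c(1:4, 15)),
               disjoint = paste0("g", 16:19))
  res <- geneset_enrichment(selection, sets, universe)
  # exhaustive sum: P(X >= 4), X ~ Hypergeom(N=20, K=5, n=10)
  brute <- sum(vapply(4:5, function(k) {
    choose(5, k) * choose(15, 10 - k) / choose(20, 10)
  }, numeric(1)))
  expect_equal(res$p[res$set == "hit"], brute, tolerance = 1e-12)
  expect_equal(round(brute, 4), 0.1517)
  expect_gt(res$p[res$set == "disjoint"], 0.99)
  # empty selection: all p = 1
  res0 <- geneset_enrichment(character(0), sets, universe)
  expect_true(all(res0$p == 1))
  # selection equal to the set attains that configuration's minimum
  resmin <- geneset_enrichment(sets$hit, sets["hit"], universe)
  expect_equal(resmin$p, choose(15, 0) * choose(5, 5) / choose(20, 5),
               tolerance = 1e-12)
})

test_that("union grouping ORs the listed features", {
  pm <- matrix(c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE,
                 FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
               nrow = 6,
               dimnames = list(sprintf("p%d", 1:6), c("f1", "f2", "f3")))
  g <- group_by_feature_union(pm, c("f1", "f2", "f3"))
  brute <- apply(pm, 1, any)
  expect_identical(g, brute)
  expect_identical(group_by_feature_union(pm, "f2"), pm[, "f2"])
  expect_error(group_by_feature_union(pm, character(0)), "non-empty")
  expect_error(group_by_feature_union(pm, "nope"), "not in matrix")
})
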