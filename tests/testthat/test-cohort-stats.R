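test_that("presence pooling ORs samples within a patient", {
  per_sample <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s5"),
    feature = c("G1", "G1", "G2", "G2"))
  s2p <- c(s1 = "p1", s2 = "p1", s3 = "p2", s4 = "p2", s5 = "p3", s6 = "p3")
  labs <- c(p1 = "case", p2 = "case", p3 = "control")
  pm <- build_presence_matrix(per_sample, s2p, labs)
  # hand-pooled truth
  expect_identical(unname(pm["p1", ]), c(TRUE, FALSE))
  expect_identical(unname(pm["p2", ]), c(FALSE, TRUE))
  expect_identical(unname(pm["p3", ]), c(FALSE, TRUE))
  expect_identical(levels(microseek:::pm_cohort(pm)), c("case", "control"))
  expect_error(build_presence_matrix(
    tibble::tibble(sample_id = "zz", feature = "G1"), s2p, labs),
    "no patient mapping")
})

test_that("the 10% prevalence filter keeps boundary features", {
  patients <- sprintf("p%02d", 1:30)
  labs <- stats::setNames(rep(c("case", "control"), c(10, 20)), patients)
  long <- dplyr::bind_rows(
    tibble::tibble(sample_id = "p01", feature = "exactly10"),   # 1/10 cases
    tibble::tibble(sample_id = sprintf("p%02d", 11:12),
                   feature = "ctrl10"),                          # 2/20 controls
    tibble::tibble(sample_id = "p11", feature = "below"))        # 0/10, 1/20
  s2p <- stats::setNames(patients, patients)
  pm <- build_presence_matrix(long, s2p, labs)
  kept <- filter_features(pm, 0.10)
  expect_true("exactly10" %in% kept)
  expect_true("ctrl10" %in% kept)
  expect_false("below" %in% kept)
})

test_that("binomial test matches exhaustive pmf summation with clamping", {
  pmf_sum <- function(k, n, p0, dir) {
    js <- if (dir == "greater") k:n else 0:k
    sum(choose(n, js) * p0^js * (1 - p0)^(n - js))
  }
  for (p_raw in c(0, 0.0001, 0.05, 0.5, 0.97, 0.9999, 1)) {
    p0 <- min(max(p_raw, 1e-4), 1 - 1e-4)
    for (n in c(5, 17, 30)) {
      for (k in c(0, 1, n %/% 2, n)) {
        expect_equal(binomial_prevalence_test(k, n, p_raw, "greater"),
                     pmf_sum(k, n, p0, "greater"), tolerance = 1e-12)
        expect_equal(binomial_prevalence_test(k, n, p_raw, "less"),
                     pmf_sum(k, n, p0, "less"), tolerance = 1e-12)
      }
    }
  }
  # the paper-scale clamped case: zero control prevalence, no case hits
  expect_equal(binomial_prevalence_test(0, 161, 0, "less"),
               (1 - 1e-4)^161, tolerance = 1e-12)
  # single-term upper tail
  expect_equal(binomial_prevalence_test(20, 20, 0.3, "greater"), 0.3^20)
  # monotone in k for direction greater
  ps <- binomial_prevalence_test(0:30, 30, 0.4, "greater")
  expect_true(all(diff(ps) <= 1e-15))
  expect_error(binomial_prevalence_test(1, 10, 0.5, "sideways"))
})

test_that("BH correction reproduces hand step-up results", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # classic worked example: q_i = min_{j >= i} p_j * m / j
  m <- length(p)
  hand <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(bh_fdr(p), hand)
  # permutation invariance and never-decreasing
  perm <- sample(seq_along(p))
  expect_equal(bh_fdr(p[perm]), hand[perm])
  expect_true(all(bh_fdr(p) >= p))
})

test_that("weighted chi-squared reduces to the closed 2x2 form at unit weights", {
  pres <- rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 20, 20, 10))
  coh <- rep(c("case", "control"), each = 30)
  r <- ipw_weighted_chisq(pres, coh, rep(0.5, 60),
                          truncate_quantiles = NULL)
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(r$p, stats::pchisq(20 / 3, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # ESS correction is a no-op at unit weights
  r2 <- ipw_weighted_chisq(pres, coh, rep(0.5, 60),
                           truncate_quantiles = NULL, ess_correction = TRUE)
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-12)
  # degenerate margin -> missing p
  r3 <- ipw_weighted_chisq(rep(TRUE, 60), coh, rep(0.5, 60))
  expect_true(is.na(r3$p))
})

test_that("propensity model recovers separation structure", {
  set.seed(31)
  n <- 500
  coh <- rep(c("case", "control"), each = n / 2)
  # null case, averaged over replicates for stability
  aucs <- vapply(1:6, function(i) {
    cov0 <- tibble::tibble(age = rnorm(n), weight = rnorm(n))
    fit_propensity(cov0, coh, rng_seed = i)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # perfectly separating covariate
  sep <- tibble::tibble(x = (coh == "case") + rnorm(n, 0, 0.01))
  expect_gt(fit_propensity(sep, coh, rng_seed = 2)$auc, 0.99)
  # known log-odds structure: ranking correlates with true propensity
  z <- rnorm(n)
  lp <- 1.5 * z
  y <- stats::rbinom(n, 1, stats::plogis(lp))
  coh2 <- ifelse(y == 1, "case", "control")
  fp <- fit_propensity(tibble::tibble(z = z), coh2, rng_seed = 3)
  expect_gt(stats::cor(fp$propensity, stats::plogis(lp),
                       method = "spearman"), 0.8)
  expect_error(fit_propensity(tibble::tibble(z = z), rep("case", n)),
               "constant")
})

test_that("IPW weighting corrects covariate-driven cohort association", {
  # reduced-replicate version of the calibration experiment (the full
  # 500-rep run lives with the acceptance checks)
  reps <- 40
  out <- t(vapply(seq_len(reps), function(s) {
    cs <- cohort_spec(250, 250,
                      covariate_effects = c(age = 0.8, weight = 0.8,
                                            smoking = 0.8),
                      rng_seed = 5000 + s)
    cv <- make_cohort(cs)$covariates
    lp <- 0.3 * scale(cv$age)[, 1] + 0.3 * scale(cv$weight)[, 1] +
      0.5 * (cv$smoking == "ever") - 0.4
    pres <- withr::with_seed(6000 + s, simulate_confounded_feature(lp))
    X <- cv[, c("race", "age", "sex", "weight", "smoking", "seq_depth")]
    pu <- ipw_weighted_chisq(pres, cv$cohort, rep(0.5, nrow(cv)),
                             truncate_quantiles = NULL)$p
    fp <- fit_propensity(X, cv$cohort, rng_seed = 7000 + s)
    r <- ipw_weighted_chisq(pres, cv$cohort, fp$propensity,
                            ess_correction = TRUE)
    smd <- mean(covariate_balance(X, cv$cohort,
                                  attr(r, "weights"))$abs_smd)
    c(pu < 0.05, r$p < 0.05, smd)
  }, numeric(3)))
  expect_gt(mean(out[, 1]), 0.5)    # unweighted test is fooled
  expect_lt(mean(out[, 2]), 0.175)  # IPW+ESS near nominal (loose at 40 reps)
  expect_lt(mean(out[, 3]), 0.1)    # weighted covariates balanced
})
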