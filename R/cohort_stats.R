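#' Build a patient-level presence matrix
#'
#' Samples are pooled to patients by OR: a patient is positive for a
#' feature iff any of their samples is positive.
#'
#' @param per_sample_presence Tibble with columns `sample_id`, `feature`
#'   (one row per positive sample-feature pair).
#' @param sample_to_patient Named character vector mapping sample_id to
#'   patient_id; every sample (including all-negative ones) must appear.
#' @param cohort_labels Named character vector mapping patient_id to
#'   `"case"` / `"control"`.
#' @param kind Feature kind: `"genus"`, `"species"` or `"protein"`.
#' @return A `presence_matrix`: logical patients x features matrix with
#'   attributes `cohort` (factor aligned to rows) and `kind`.
#' @export
build_presence_matrix <- function(per_sample_presence, sample_to_patient,
                                  cohort_labels, kind = "genus") {
  unmapped <- setdiff(unique(per_sample_presence$sample_id),
                      names(sample_to_patient))
  if (length(unmapped) > 0) {
    stop("sample(s) with no patient mapping: ", paste(unmapped, collapse = ", "))
  }
  patients <- sort(unique(unname(sample_to_patient)))
  missing_lab <- setdiff(patients, names(cohort_labels))
  if (length(missing_lab) > 0) {
    stop("patient(s) with no cohort label: ", paste(missing_lab, collapse = ", "))
  }
  features <- sort(unique(per_sample_presence$feature))
  M <- matrix(FALSE, length(patients), length(features),
              dimnames = list(patients, features))
  if (nrow(per_sample_presence) > 0) {
    pid <- unname(sample_to_patient[per_sample_presence$sample_id])
    M[cbind(match(pid, patients),
            match(per_sample_presence$feature, features))] <- TRUE
  }
  structure(M,
            cohort = factor(unname(cohort_labels[patients]),
                            levels = c("case", "control")),
            kind = kind, class = c("presence_matrix", "matrix", "array"))
}

pm_cohort <- function(pm) attr(pm, "cohort")

#' Filter features by minimum prevalence in either cohort
#'
#' Keeps features present in at least `min_prevalence` of cases OR of
#' controls (boundary inclusive).
#'
#' @param pm A [build_presence_matrix()] result.
#' @param min_prevalence Default 0.10.
#' @return Character vector of retained feature names.
#' @export
filter_features <- function(pm, min_prevalence = 0.10) {
  cohort <- pm_cohort(pm)
  if (!all(c("case", "control") %in% cohort)) {
    stop("both cohorts must be non-empty")
  }
  prev_case <- colMeans(pm[cohort == "case", , drop = FALSE])
  prev_ctrl <- colMeans(pm[cohort == "control", , drop = FALSE])
  tol <- 1e-12  # boundary "at least" robust to floating division
  colnames(pm)[prev_case >= min_prevalence - tol |
               prev_ctrl >= min_prevalence - tol]
}

#' One-tailed binomial prevalence test with clamped null probability
#'
#' The null probability is the control-cohort prevalence clamped into
#' `[0.0001, 0.9999]` (exactly 0 or 1 would force a p-value of 0);
#' `p = P(X >= k)` for direction `"greater"`, `P(X <= k)` for `"less"`,
#' with `X ~ Binomial(n_case, p0)`. Vectorized over features.
#'
#' @param k_case Number of positive case patients.
#' @param n_case Number of case patients (trials).
#' @param prevalence_control Control prevalence in `[0, 1]`.
#' @param direction `"greater"` or `"less"`.
#' @param clamp Length-2 clamp bounds, default `c(0.0001, 0.9999)`.
#' @return p-value(s) in `[0, 1]`.
#' @export
binomial_prevalence_test <- function(k_case, n_case, prevalence_control,
                                     direction = c("greater", "less"),
                                     clamp = c(1e-4, 1 - 1e-4)) {
  direction <- match.arg(direction)
  stopifnot(all(k_case >= 0), all(k_case <= n_case),
            all(prevalence_control >= 0), all(prevalence_control <= 1))
  p0 <- pmin(pmax(prevalence_control, clamp[1]), clamp[2])
  if (direction == "greater") {
    stats::pbinom(k_case - 1, n_case, p0, lower.tail = FALSE)
  } else {
    stats::pbinom(k_case, n_case, p0)
  }
}

#' Benjamini-Hochberg FDR correction
#'
#' Standard step-up procedure with monotonicity enforcement.
#'
#' @param p_values Numeric vector in `[0, 1]` (NAs passed through).
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Differential prevalence analysis (binomial path)
#'
#' For each feature: direction is `"greater"` when case prevalence
#' exceeds control prevalence, else `"less"`; one-tailed binomial test
#' against the clamped control prevalence; BH FDR across features.
#'
#' @param pm A [build_presence_matrix()] result.
#' @param features Features to test (default: the 10%-prevalence subset
#'   from [filter_features()]).
#' @param min_prevalence Passed to [filter_features()] when `features`
#'   is NULL.
#' @return Tibble: feature, kind, n_case_present, n_case,
#'   n_control_present, n_control, p_control, p0, direction, p, q,
#'   analysis.
#' @export
prevalence_analysis <- function(pm, features = NULL, min_prevalence = 0.10) {
  if (is.null(features)) features <- filter_features(pm, min_prevalence)
  cohort <- pm_cohort(pm)
  n_case <- sum(cohort == "case"); n_ctrl <- sum(cohort == "control")
  res <- lapply(features, function(f) {
    k <- sum(pm[cohort == "case", f])
    kc <- sum(pm[cohort == "control", f])
    p_ctrl <- kc / n_ctrl
    dir <- if (k / n_case >= p_ctrl) "greater" else "less"
    tibble::tibble(feature = f, kind = attr(pm, "kind"),
                   n_case_present = k, n_case = n_case,
                   n_control_present = kc, n_control = n_ctrl,
                   p_control = p_ctrl,
                   p0 = pmin(pmax(p_ctrl, 1e-4), 1 - 1e-4),
                   direction = dir,
                   p = binomial_prevalence_test(k, n_case, p_ctrl, dir))
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) > 0) out$q <- bh_fdr(out$p) else out$q <- numeric(0)
  out$analysis <- rep("binomial", nrow(out))
  out
}

#' Fit a boosted logistic propensity model
#'
#' Gradient boosting with logistic loss (depth-2 trees, 200 rounds,
#' learning rate 0.05 by default) estimating the probability of case
#' membership from the covariates. Propensities are cross-fitted:
#' each patient's probability comes from a model trained on the other
#' folds, so pure-noise covariates yield AUC near 0.5 rather than an
#' overfit in-sample score, and downstream inverse-probability weights
#' are not contaminated by overfitting. The reported AUC is computed on
#' the cross-fitted probabilities.
#'
#' @param covariates Tibble/data.frame of covariates only (factors and
#'   numerics; character columns are treated as factors). Patients with
#'   missing values must be excluded beforehand.
#' @param cohort Character/factor vector of `"case"` / `"control"`.
#' @param nrounds,max_depth,eta Boosting hyperparameters.
#' @param folds Number of cross-fitting folds (default 5). `folds = 1`
#'   falls back to in-sample fitting.
#' @param rng_seed Seed for fold assignment and the deterministic fits.
#' @return List: `propensity` (P(case) per row, in (0,1)), `auc`,
#'   `model` (fit on all rows, for inspection).
#' @export
fit_propensity <- function(covariates, cohort, nrounds = 200L,
                           max_depth = 2L, eta = 0.05, folds = 5L,
                           rng_seed = 1L) {
  y <- as.integer(cohort == "case")
  if (length(unique(y)) < 2) stop("cohort label is constant; cannot fit")
  df <- as.data.frame(covariates)
  if (anyNA(df)) stop("covariates contain missing values; exclude those patients")
  for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  X <- stats::model.matrix(~ . - 1, data = df)
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = eta, nthread = 1, seed = rng_seed)
  train_on <- function(idx) {
    xgboost::xgb.train(params = params,
                       data = xgboost::xgb.DMatrix(X[idx, , drop = FALSE],
                                                   label = y[idx]),
                       nrounds = nrounds, verbose = 0)
  }
  p <- with_seed(rng_seed, {
    if (folds <= 1L) {
      stats::predict(train_on(seq_along(y)), xgboost::xgb.DMatrix(X))
    } else {
      fold <- sample(rep_len(seq_len(folds), length(y)))
      out <- numeric(length(y))
      for (k in seq_len(folds)) {
        hold <- fold == k
        if (length(unique(y[!hold])) < 2) {
          out[hold] <- mean(y[!hold])
          next
        }
        fit_k <- train_on(which(!hold))
        out[hold] <- stats::predict(
          fit_k, xgboost::xgb.DMatrix(X[hold, , drop = FALSE]))
      }
      out
    }
  })
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  full <- with_seed(rng_seed, train_on(seq_along(y)))
  list(propensity = p, auc = auroc(p, y == 1), model = full)
}

#' Inverse-probability-weighted chi-squared test of presence vs cohort
#'
#' Each patient is weighted by the inverse of the estimated probability
#' of their *observed* cohort (`1/p` for cases, `1/(1-p)` for controls).
#' Weights are truncated at configurable quantiles and stabilized
#' (normalized to mean 1) by default, then a 2x2 cohort x presence table
#' of summed weights is tested with the plain df-1 Pearson chi-squared
#' statistic (no continuity correction).
#'
#' @param feature_presence Logical vector (or matrix patients x features).
#' @param cohort `"case"` / `"control"` per patient.
#' @param propensities P(case) per patient, in (0, 1).
#' @param truncate_quantiles Length-2 weight truncation quantiles,
#'   default `c(0.01, 0.99)`; `NULL` disables truncation.
#' @param normalize Normalize weights to mean 1 (stabilized weights),
#'   default TRUE.
#' @param ess_correction Rescale the statistic by the Kish effective
#'   sample size, `(sum w)^2 / sum(w^2)`, relative to the weighted total.
#'   The plain statistic treats weighted counts as real counts and is
#'   anti-conservative when weights vary; the ESS-rescaled variant
#'   restores type-I calibration and reduces to the plain statistic at
#'   unit weights. Default FALSE (the minimal weighted chi-squared).
#' @return Tibble: feature, statistic, p (NA when a weighted margin is
#'   zero), plus the weight vector as attribute `weights`.
#' @export
ipw_weighted_chisq <- function(feature_presence, cohort, propensities,
                               truncate_quantiles = c(0.01, 0.99),
                               normalize = TRUE, ess_correction = FALSE) {
  stopifnot(all(propensities > 0 & propensities < 1))
  is_case <- cohort == "case"
  w <- ifelse(is_case, 1 / propensities, 1 / (1 - propensities))
  if (!is.null(truncate_quantiles)) {
    qs <- stats::quantile(w, truncate_quantiles, names = FALSE)
    w <- pmin(pmax(w, qs[1]), qs[2])
  }
  if (normalize) w <- w / mean(w)
  # ESS per cohort: weight variability costs information within each arm
  ess_factor <- if (ess_correction) {
    ess <- sum(vapply(list(w[is_case], w[!is_case]), function(wg) {
      sum(wg)^2 / sum(wg^2)
    }, numeric(1)))
    ess / sum(w)
  } else 1
  M <- if (is.matrix(feature_presence)) feature_presence else
    matrix(feature_presence, ncol = 1,
           dimnames = list(NULL, "feature"))
  res <- lapply(colnames(M), function(f) {
    pres <- as.logical(M[, f])
    a <- sum(w[is_case & pres]);  b <- sum(w[is_case & !pres])
    c_ <- sum(w[!is_case & pres]); d <- sum(w[!is_case & !pres])
    n <- a + b + c_ + d
    margins <- c(a + b, c_ + d, a + c_, b + d)
    if (any(margins == 0)) {
      return(tibble::tibble(feature = f, statistic = NA_real_, p = NA_real_))
    }
    stat <- ess_factor * n * (a * d - b * c_)^2 / prod(margins)
    tibble::tibble(feature = f, statistic = stat,
                   p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(res)
  attr(out, "weights") <- w
  out
}

#' Confounder-corrected prevalence analysis
#'
#' The paper's corrected path: boosted-logistic propensities from the
#' covariates, inverse-probability weights, weighted chi-squared per
#' feature over *all* features with any abundance (no 10% filter), BH
#' FDR.
#'
#' @param pm A [build_presence_matrix()] result.
#' @param covariates Covariate tibble aligned to `rownames(pm)` (the
#'   usual set: race, age, sex, weight, smoking, seq_depth).
#' @param ... Passed to [fit_propensity()] / [ipw_weighted_chisq()].
#' @return Tibble: feature, kind, statistic, p, q, analysis, plus
#'   attributes `auc` and `weights`.
#' @export
corrected_prevalence_analysis <- function(pm, covariates,
                                          truncate_quantiles = c(0.01, 0.99),
                                          rng_seed = 1L, ...) {
  cohort <- as.character(pm_cohort(pm))
  fit <- fit_propensity(covariates, cohort, rng_seed = rng_seed, ...)
  keep <- colnames(pm)[colSums(pm) > 0]
  res <- ipw_weighted_chisq(pm[, keep, drop = FALSE], cohort,
                            fit$propensity,
                            truncate_quantiles = truncate_quantiles)
  res$kind <- attr(pm, "kind")
  res$q <- bh_fdr(res$p)
  res$analysis <- "ipw_chisq"
  out <- res[, c("feature", "kind", "statistic", "p", "q", "analysis")]
  attr(out, "auc") <- fit$auc
  attr(out, "weights") <- attr(res, "weights")
  out
}

#' Weighted standardized mean differences of covariates across cohorts
#'
#' The balance diagnostic for the IPW analysis: after weighting, each
#' covariate's weighted means should be close across cohorts
#' (|SMD| < 0.1 is the usual benchmark).
#'
#' @param covariates Covariate tibble (factors expanded to dummies).
#' @param cohort `"case"` / `"control"` per row.
#' @param weights IPW weights per row.
#' @return Tibble: covariate, smd (signed), abs_smd.
#' @export
covariate_balance <- function(covariates, cohort, weights) {
  df <- as.data.frame(covariates)
  for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  X <- stats::model.matrix(~ . - 1, data = df)
  is_case <- cohort == "case"
  wmean <- function(x, w) sum(x * w) / sum(w)
  res <- lapply(colnames(X), function(j) {
    x <- X[, j]
    m1 <- wmean(x[is_case], weights[is_case])
    m0 <- wmean(x[!is_case], weights[!is_case])
    s <- sqrt((stats::var(x[is_case]) + stats::var(x[!is_case])) / 2)
    smd <- if (s == 0) 0 else (m1 - m0) / s
    tibble::tibble(covariate = j, smd = smd, abs_smd = abs(smd))
  })
  dplyr::bind_rows(res)
}
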