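#' Specify a synthetic two-cohort study
#'
#' Covariate effects are standardized shifts applied to the case arm's
#' covariate distributions (location shift in SD units for continuous
#' covariates, logit shift for binary and categorical ones), which makes
#' each nonzero entry act as a log-odds contribution to cohort membership
#' and produces genuine confounding by construction.
#'
#' @param n_case,n_control Arm sizes (each >= 1).
#' @param covariate_effects Named numeric vector over a subset of
#'   `race`, `age`, `sex`, `weight`, `smoking`, `seq_depth`.
#' @param feature_hazard Named numeric vector: log hazard ratio on
#'   survival per presence-matrix feature.
#' @param censoring_rate Fraction in `[0, 1]`.
#' @param baseline_hazard Baseline exponential event rate per day.
#' @param rng_seed Integer seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_case, n_control, covariate_effects = numeric(0),
                        feature_hazard = numeric(0), censoring_rate = 0.2,
                        baseline_hazard = 1 / 1000, rng_seed = 1L) {
  stopifnot(n_case >= 1, n_control >= 1)
  if (censoring_rate < 0 || censoring_rate > 1) {
    stop("`censoring_rate` must be in [0, 1]")
  }
  known <- c("race", "age", "sex", "weight", "smoking", "seq_depth")
  bad <- setdiff(names(covariate_effects), known)
  if (length(bad) > 0) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 covariate_effects = covariate_effects,
                 feature_hazard = feature_hazard,
                 censoring_rate = censoring_rate,
                 baseline_hazard = baseline_hazard,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Simulate confounded covariate and survival tables
#'
#' Covariates are drawn with cohort-dependent distributions according to
#' `covariate_effects`; zero effects give identical distributions across
#' arms. Survival times for both endpoints (overall and disease-free) are
#' exponential with per-patient hazard
#' `baseline_hazard * exp(sum(feature_hazard * presence))`, independently
#' censored by an exponential clock calibrated so that roughly
#' `censoring_rate` of baseline-hazard patients are censored.
#'
#' @param spec A [cohort_spec()].
#' @param presence_matrix Optional logical patients x features matrix with
#'   rownames equal to the generated patient ids (`P0001`, ... cases
#'   first). Required when `feature_hazard` is non-empty; every hazard
#'   feature must be one of its columns.
#' @return A list with `covariates` (tibble: patient_id, cohort, race,
#'   age, sex, weight, smoking, seq_depth) and `survival` (tibble:
#'   patient_id, endpoint, time, event).
#' @export
make_cohort <- function(spec, presence_matrix = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_case + spec$n_control
  patient_id <- sprintf("P%04d", seq_len(n))
  cohort <- rep(c("case", "control"), c(spec$n_case, spec$n_control))
  if (length(spec$feature_hazard) > 0) {
    if (is.null(presence_matrix)) {
      stop("`presence_matrix` required when feature_hazard is non-empty")
    }
    miss <- setdiff(names(spec$feature_hazard), colnames(presence_matrix))
    if (length(miss) > 0) {
      stop("feature_hazard feature(s) not in presence matrix: ",
           paste(miss, collapse = ", "))
    }
    if (!all(patient_id %in% rownames(presence_matrix))) {
      stop("presence matrix patients do not match generated patients")
    }
  }
  eff <- function(name) unname(spec$covariate_effects[name] %|NA|% 0)
  is_case <- cohort == "case"
  with_seed(spec$rng_seed, {
    race_levels <- c("groupA", "groupB", "groupC", "groupD")
    base_logit <- c(0.6, 0, -0.4, -0.8)
    race <- vapply(is_case, function(case) {
      lg <- base_logit
      if (case) lg[1] <- lg[1] + eff("race")
      sample(race_levels, 1, prob = exp(lg) / sum(exp(lg)))
    }, character(1))
    age <- stats::rnorm(n, 55 + 10 * eff("age") * is_case, 10)
    sex <- stats::rbinom(n, 1, stats::plogis(0 + eff("sex") * is_case))
    weight <- stats::rnorm(n, 75 + 12 * eff("weight") * is_case, 12)
    smoking <- stats::rbinom(n, 1, stats::plogis(-0.85 + eff("smoking") * is_case))
    seq_depth <- stats::rlnorm(n, log(3e7) + 0.4 * eff("seq_depth") * is_case, 0.4)
    covariates <- tibble::tibble(
      patient_id = patient_id, cohort = cohort, race = race, age = age,
      sex = c("female", "male")[sex + 1L], weight = weight,
      smoking = c("never", "ever")[smoking + 1L], seq_depth = seq_depth)

    lp <- rep(0, n)
    if (length(spec$feature_hazard) > 0) {
      pm <- presence_matrix[patient_id, names(spec$feature_hazard), drop = FALSE]
      lp <- as.vector(pm %*% spec$feature_hazard)
    }
    hazard <- spec$baseline_hazard * exp(lp)
    cr <- spec$censoring_rate
    surv <- lapply(c("overall", "disease_free"), function(ep) {
      t_event <- stats::rexp(n, hazard)
      t_cens <- if (cr == 0) {
        rep(Inf, n)
      } else if (cr >= 1) {
        t_event * stats::runif(n)  # censor everyone strictly before the event
      } else {
        stats::rexp(n, spec$baseline_hazard * cr / (1 - cr))
      }
      tibble::tibble(patient_id = patient_id, endpoint = ep,
                     time = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens))
    })
    list(covariates = covariates, survival = dplyr::bind_rows(surv))
  })
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Simulate a presence feature driven by a covariate, not by cohort
#'
#' Generates a boolean feature whose probability depends on a linear
#' predictor over covariates only. When those covariates differ between
#' cohorts, the feature is marginally associated with cohort purely
#' through confounding -- the generator-truth null for the
#' confounder-corrected analysis.
#'
#' @param linear_predictor Numeric vector (one value per patient) on the
#'   logit scale; `plogis(linear_predictor)` is the presence probability.
#' @return Logical vector of presence calls.
#' @export
simulate_confounded_feature <- function(linear_predictor) {
  stats::runif(length(linear_predictor)) < stats::plogis(linear_predictor)
}
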