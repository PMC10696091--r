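#' Two-group log-rank test
#'
#' Observed-minus-expected log-rank statistic with the hypergeometric
#' variance, chi-squared with 1 df. Implemented directly so an
#' independent reference implementation can serve as a cross-check.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param group Logical or two-level vector splitting patients.
#' @return List: `statistic`, `p` (both NA when undefined, e.g. no events
#'   or a single group).
#' @export
logrank_test <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  if (length(unique(g)) != 2 || sum(event) == 0) {
    return(list(statistic = NA_real_, p = NA_real_))
  }
  dtimes <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in dtimes) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1L)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) {
    # identical risk sets (e.g. identical curves with all mass in one
    # configuration) -- no evidence against the null
    return(list(statistic = 0, p = 1))
  }
  stat <- (O1 - E1)^2 / V
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Presence-based survival screen
#'
#' For each feature with at least `min_pos` positive and `min_neg`
#' negative patients (after excluding patients with no clinical data),
#' tests presence vs absence with the log-rank test per endpoint, then
#' BH-corrects over tested features within the endpoint. Features failing
#' the 5/5 rule are reported as untested.
#'
#' @param pm A [build_presence_matrix()] result (typically restricted to
#'   case patients).
#' @param survival_records Tibble: patient_id, endpoint, time, event.
#' @param endpoints Endpoints to screen, default both.
#' @param min_pos,min_neg Minimum group sizes, default 5 and 5.
#' @return Tibble: feature, endpoint, n_pos, n_neg, tested, statistic,
#'   p, q.
#' @export
survival_screen <- function(pm, survival_records,
                            endpoints = c("overall", "disease_free"),
                            min_pos = 5L, min_neg = 5L) {
  stopifnot(all(survival_records$time > 0))
  out <- list()
  for (ep in endpoints) {
    sv <- survival_records[survival_records$endpoint == ep, , drop = FALSE]
    sv <- sv[sv$patient_id %in% rownames(pm), , drop = FALSE]
    feats <- colnames(pm)
    rows <- lapply(feats, function(f) {
      pos <- rownames(pm)[pm[, f]]
      sub <- sv[!is.na(sv$time), , drop = FALSE]
      grp <- sub$patient_id %in% pos
      n_pos <- sum(grp); n_neg <- sum(!grp)
      if (n_pos < min_pos || n_neg < min_neg) {
        return(tibble::tibble(feature = f, endpoint = ep, n_pos = n_pos,
                              n_neg = n_neg, tested = FALSE,
                              statistic = NA_real_, p = NA_real_))
      }
      lr <- logrank_test(sub$time, sub$event, grp)
      tibble::tibble(feature = f, endpoint = ep, n_pos = n_pos,
                     n_neg = n_neg, tested = TRUE,
                     statistic = lr$statistic, p = lr$p)
    })
    tab <- dplyr::bind_rows(rows)
    tab$q <- NA_real_
    tested <- tab$tested & !is.na(tab$p)
    tab$q[tested] <- bh_fdr(tab$p[tested])
    out[[ep]] <- tab
  }
  dplyr::bind_rows(out)
}

#' Kaplan-Meier curve coordinates for external plotting
#'
#' @param time,event,group As in [logrank_test()].
#' @return Tibble: group, time, n_risk, n_event, surv.
#' @export
km_curve <- function(time, event, group) {
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(fit$strata) %||% "all",
                fit$strata %||% length(fit$time))
  tibble::tibble(group = sub("^group=", "", strata), time = fit$time,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 surv = fit$surv)
}

#' Screen host genes for association with a patient grouping
#'
#' Per-gene z-scores are computed across patients (mean 0, sd 1); a gene
#' is selected when the two-sided rank-sum p-value (normal approximation
#' with tie correction) is below `p_max` (unadjusted), the median z-score
#' in the positive group exceeds `z_pos_min`, and the median z-score in
#' the negative group is below `z_neg_max`.
#'
#' @param expression Numeric genes x patients matrix (normalized
#'   expression, e.g. RSEM-like values).
#' @param group_labels Logical vector (length = patients): positive
#'   group membership. Both groups need at least 2 patients.
#' @param p_max,z_pos_min,z_neg_max Selection thresholds (defaults 0.05,
#'   0.2, 0).
#' @return Tibble: gene, p, median_z_pos, median_z_neg, selected.
#' @export
host_gene_screen <- function(expression, group_labels, p_max = 0.05,
                             z_pos_min = 0.2, z_neg_max = 0) {
  stopifnot(is.matrix(expression), ncol(expression) == length(group_labels))
  if (sum(group_labels) < 2 || sum(!group_labels) < 2) {
    stop("each group needs at least 2 patients")
  }
  z <- t(scale(t(expression)))
  rows <- lapply(seq_len(nrow(expression)), function(i) {
    x <- expression[i, group_labels]
    y <- expression[i, !group_labels]
    p <- if (stats::sd(expression[i, ]) == 0) {
      1  # constant gene: never selected
    } else {
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    }
    mzp <- stats::median(z[i, group_labels])
    mzn <- stats::median(z[i, !group_labels])
    tibble::tibble(gene = rownames(expression)[i] %||% as.character(i),
                   p = p, median_z_pos = mzp, median_z_neg = mzn,
                   selected = !is.na(p) & p < p_max & !is.na(mzp) &
                     mzp > z_pos_min & mzn < z_neg_max)
  })
  dplyr::bind_rows(rows)
}

#' Hypergeometric over-representation of gene sets
#'
#' One-sided hypergeometric tail per set (probability of at least the
#' observed overlap), BH FDR across sets. Stands in for a live
#' pathway-enrichment service: sets are user-supplied.
#'
#' @param selected_genes Character vector, subset of `universe`.
#' @param gene_sets Named list of character vectors (subsets of
#'   `universe`).
#' @param universe Character vector of all testable genes.
#' @return Tibble: set, n_set, n_selected, overlap, p, q.
#' @export
geneset_enrichment <- function(selected_genes, gene_sets, universe) {
  if (!all(selected_genes %in% universe)) {
    stop("selected_genes must be a subset of universe")
  }
  N <- length(universe); n_sel <- length(selected_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(set, selected_genes))
    p <- if (n_sel == 0) 1 else
      stats::phyper(k - 1, length(set), N - length(set), n_sel,
                    lower.tail = FALSE)
    tibble::tibble(set = nm, n_set = length(set), n_selected = n_sel,
                   overlap = k, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Group patients by union presence over a feature list
#'
#' A patient is positive iff positive for at least one listed feature
#' (the grouping used, e.g., for iron-related protein families).
#'
#' @param pm A [build_presence_matrix()] result.
#' @param feature_list Non-empty character vector of features in `pm`.
#' @return Named logical vector over patients.
#' @export
group_by_feature_union <- function(pm, feature_list) {
  if (length(feature_list) == 0) stop("`feature_list` must be non-empty")
  missing <- setdiff(feature_list, colnames(pm))
  if (length(missing) > 0) {
    stop("feature(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  rowSums(pm[, feature_list, drop = FALSE]) > 0
}
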