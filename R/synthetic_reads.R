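#' Specify one simulated RNA-seq sample
#'
#' @param sample_id Unique sample identifier.
#' @param patient_id Patient the sample belongs to.
#' @param cohort `"case"` or `"control"`.
#' @param planted Named numeric vector: mean fold-coverage per planted
#'   reference accession (all coverages must be >= 0). May be empty.
#' @param read_length 75 or 76 bases.
#' @param n_rate Per-base probability of corruption to `N`, in `[0, 0.05]`.
#' @param host_read_count Number of background reads drawn from
#'   human-labeled references.
#' @param rng_seed Integer seed for this sample's read draw.
#' @return A `sample_spec` object.
#' @export
sample_spec <- function(sample_id, patient_id, cohort = c("case", "control"),
                        planted = numeric(0), read_length = 75L,
                        n_rate = 0, host_read_count = 0L, rng_seed = 1L) {
  cohort <- match.arg(cohort)
  if (!read_length %in% c(75L, 76L)) stop("`read_length` must be 75 or 76")
  if (n_rate < 0 || n_rate > 0.05) stop("`n_rate` must be in [0, 0.05]")
  if (length(planted) > 0 && (is.null(names(planted)) || any(planted < 0))) {
    stop("`planted` must be a named vector of non-negative coverages")
  }
  if (host_read_count < 0) stop("`host_read_count` must be >= 0")
  structure(list(sample_id = sample_id, patient_id = patient_id,
                 cohort = cohort, planted = planted,
                 read_length = as.integer(read_length), n_rate = n_rate,
                 host_read_count = as.integer(host_read_count),
                 rng_seed = as.integer(rng_seed)),
            class = "sample_spec")
}

#' Simulate a sample's read set
#'
#' Shotgun model: each planted transcript contributes
#' `Poisson(coverage * length / read_length)` reads at uniform positions;
#' host reads are drawn from human-labeled references with probability
#' proportional to reference length. Each base is independently corrupted
#' to `N` with probability `n_rate`. Quality is constant `I` when written
#' to FASTQ (the method never uses quality).
#'
#' @param spec A [sample_spec()].
#' @param references Reference tibble from [make_references()]; all planted
#'   accessions must be present.
#' @return A tibble with columns `read_id`, `sequence`, `source_accession`,
#'   `source_start`.
#' @export
make_reads <- function(spec, references) {
  stopifnot(inherits(spec, "sample_spec"))
  missing <- setdiff(names(spec$planted), references$accession)
  if (length(missing) > 0) {
    stop("planted accession(s) not found in references: ",
         paste(missing, collapse = ", "))
  }
  rl <- spec$read_length
  with_seed(spec$rng_seed, {
    src <- character(0); start <- integer(0); seqs <- character(0)
    for (acc in names(spec$planted)) {
      tseq <- references$sequence[references$accession == acc]
      L <- nchar(tseq)
      if (L < rl) stop("planted reference ", acc, " is shorter than the read length")
      n_reads <- stats::rpois(1, spec$planted[[acc]] * L / rl)
      if (n_reads == 0) next
      pos <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
      src <- c(src, rep(acc, n_reads))
      start <- c(start, pos)
      seqs <- c(seqs, substr(rep(tseq, n_reads), pos, pos + rl - 1L))
    }
    if (spec$host_read_count > 0) {
      hosts <- references[references$label == "human", ]
      if (nrow(hosts) == 0) stop("host reads requested but no human references")
      lens <- nchar(hosts$sequence)
      ok <- lens >= rl
      hosts <- hosts[ok, ]; lens <- lens[ok]
      ridx <- sample.int(nrow(hosts), spec$host_read_count, replace = TRUE,
                         prob = lens - rl + 1)
      pos <- floor(stats::runif(spec$host_read_count) * (lens[ridx] - rl + 1)) + 1L
      src <- c(src, hosts$accession[ridx])
      start <- c(start, as.integer(pos))
      seqs <- c(seqs, substr(hosts$sequence[ridx], pos, pos + rl - 1L))
    }
    if (length(seqs) > 0 && spec$n_rate > 0) {
      chars <- seq_to_chars(seqs)
      n_total <- length(seqs) * rl
      hit <- stats::runif(n_total) < spec$n_rate
      if (any(hit)) {
        flat <- unlist(chars, use.names = FALSE)
        flat[hit] <- "N"
        # reads are all `rl` long: one column per read
        seqs <- apply(matrix(flat, nrow = rl), 2, paste, collapse = "")
      }
    }
    tibble::tibble(
      read_id = if (length(seqs)) sprintf("%s_R%06d", spec$sample_id,
                                          seq_along(seqs)) else character(0),
      sequence = seqs,
      source_accession = src,
      source_start = start
    )
  })
}
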