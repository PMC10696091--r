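#' Remove reads that exactly match the host reference
#'
#' Desk-scale stand-in for host-genome alignment: a read is removed when
#' it occurs verbatim (full length, either strand) in any host reference
#' sequence. On synthetic data with compositionally disjoint origins this
#' is equivalent to alignment-based host subtraction; on real data an
#' external aligner would be plugged in behind the same interface.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param host_references Tibble of references; rows with
#'   `label == "human"` are used (or all rows if no `label` column).
#'   `NULL` or zero host rows skips filtering with a warning.
#' @return The retained reads; removed reads are attached as
#'   `attr(, "removed")`.
#' @export
filter_host_reads <- function(reads, host_references) {
  empty_removed <- function(x) { attr(x, "removed") <- x[0, ]; x }
  if (is.null(host_references)) {
    warning("no host reference supplied: host filtering skipped")
    return(empty_removed(reads))
  }
  host <- if ("label" %in% names(host_references)) {
    host_references$sequence[host_references$label == "human"]
  } else host_references$sequence
  if (length(host) == 0 || nrow(reads) == 0) {
    return(empty_removed(reads))
  }
  lens <- sort(unique(nchar(reads$sequence)))
  kmers <- character(0)
  for (L in lens) {
    for (h in host) {
      if (nchar(h) < L) next
      starts <- seq_len(nchar(h) - L + 1L)
      kmers <- c(kmers, substring(h, starts, starts + L - 1L))
    }
  }
  rc <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  }
  hit <- reads$sequence %in% kmers | rc(reads$sequence) %in% kmers
  out <- reads[!hit, , drop = FALSE]
  attr(out, "removed") <- reads[hit, , drop = FALSE]
  out
}
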