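#' Segmentation configuration for classifier training data
#'
#' Reference sequences are split into train/validation/test sets *before*
#' segmentation (so no segment of a held-out reference can leak into
#' training), then cut into fixed-length segments at a per-class stride.
#' The default strides (human 26, viral 2, bacterial 130) balance per-class
#' segment counts when the class total lengths are in roughly 13 : 1 : 65
#' proportion, mirroring the relative sizes of a host transcriptome, a
#' viral transcript collection and a bacterial genome collection.
#'
#' @param segment_length Segment size in bases (the classifier input
#'   width), default 76.
#' @param stride_by_class Named integer vector of per-class strides.
#' @param split_fractions Named numeric vector `(train, val, test)`
#'   summing to 1.
#' @return A `segmentation_config` object.
#' @export
segmentation_config <- function(segment_length = 76L,
                                stride_by_class = c(human = 26L, viral = 2L,
                                                    bacterial = 130L),
                                split_fractions = c(train = 0.7, val = 0.15,
                                                    test = 0.15)) {
  if (segment_length <= 0) stop("`segment_length` must be positive")
  if (any(stride_by_class < 1)) stop("strides must be >= 1")
  if (abs(sum(split_fractions) - 1) > 1e-9) {
    stop("`split_fractions` must sum to 1")
  }
  if (!all(c("train", "val", "test") %in% names(split_fractions))) {
    stop("`split_fractions` needs names train, val, test")
  }
  structure(list(segment_length = as.integer(segment_length),
                 stride_by_class = stride_by_class,
                 split_fractions = split_fractions),
            class = "segmentation_config")
}

#' Cut a sequence into fixed-length segments at a stride
#'
#' Segments start at offsets 0, stride, 2*stride, ...; only full-length
#' segments are returned, and any segment containing `N` is dropped.
#'
#' @param sequence A single DNA string over `A,C,G,T,N`.
#' @param segment_length Segment size (must be positive).
#' @param stride Step between segment starts (>= 1).
#' @return Character vector of segments (possibly empty).
#' @export
segment_reference <- function(sequence, segment_length = 76L, stride = 1L) {
  if (segment_length <= 0) stop("`segment_length` must be positive")
  if (stride < 1) stop("`stride` must be >= 1")
  L <- nchar(sequence)
  if (L < segment_length) return(character(0))
  starts <- seq.int(1L, L - segment_length + 1L, by = stride)
  segs <- substring(sequence, starts, starts + segment_length - 1L)
  segs[!grepl("N", segs, fixed = TRUE)]
}

#' Build labeled train/validation/test segment sets
#'
#' Each reference is assigned to exactly one split (drawn with the
#' configured fractions), then segmented with its class stride.
#'
#' @param references Tibble with `accession`, `label`, `sequence`; every
#'   class in `stride_by_class` must have at least one reference.
#' @param config A [segmentation_config()].
#' @param rng_seed Integer seed controlling the split.
#' @return List of three tibbles (`train`, `val`, `test`), each with
#'   columns `segment`, `label`, `accession`.
#' @export
build_dataset <- function(references, config = segmentation_config(),
                          rng_seed = 1L) {
  stopifnot(inherits(config, "segmentation_config"))
  classes <- names(config$stride_by_class)
  present <- unique(references$label)
  missing <- setdiff(classes, present)
  if (length(missing) > 0) {
    stop("class(es) with no references: ", paste(missing, collapse = ", "))
  }
  splits <- with_seed(rng_seed, {
    sample(c("train", "val", "test"), nrow(references), replace = TRUE,
           prob = config$split_fractions[c("train", "val", "test")])
  })
  out <- lapply(c(train = "train", val = "val", test = "test"), function(sp) {
    idx <- which(splits == sp)
    if (length(idx) == 0) {
      return(tibble::tibble(segment = character(0), label = character(0),
                            accession = character(0)))
    }
    segs <- lapply(idx, function(i) {
      s <- segment_reference(references$sequence[i], config$segment_length,
                             config$stride_by_class[[references$label[i]]])
      if (length(s) == 0) return(NULL)
      tibble::tibble(segment = s, label = references$label[i],
                     accession = references$accession[i])
    })
    dplyr::bind_rows(segs)
  })
  out
}

#' Normalize reads for scoring
#'
#' Applies the method's N-handling rules: reads with more than one `N` are
#' excluded; a single `N` is replaced with a random nucleotide *for
#' scoring only*; 75-base reads are padded with one random 3' nucleotide
#' to reach the expected 76 bases. Stored read sequences are never
#' altered -- the randomized sequence exists only in the scoring path.
#' Draws come from the caller's RNG stream (seed before calling for
#' reproducibility).
#'
#' @param sequences Character vector of reads over `A,C,G,T,N`.
#' @param expected_length Model input width, default 76. Reads of
#'   `expected_length` or `expected_length - 1` bases are accepted; any
#'   other length is an input error.
#' @return Tibble with columns `sequence` (the stored read, unchanged),
#'   `scoring_sequence` (`NA` when excluded), `excluded` (logical),
#'   `n_fill` (the base substituted for a single `N`, else `NA`).
#' @export
normalize_reads <- function(sequences, expected_length = 76L) {
  lens <- nchar(sequences)
  if (any(lens > expected_length)) {
    stop("read(s) longer than expected_length (", expected_length, ")")
  }
  if (any(lens < expected_length - 1L)) {
    stop("read(s) shorter than expected_length - 1 (", expected_length - 1L, ")")
  }
  n_ns <- count_n(sequences)
  excluded <- n_ns > 1L
  scoring <- sequences
  n_fill <- rep(NA_character_, length(sequences))
  one_n <- which(n_ns == 1L & !excluded)
  for (i in one_n) {
    b <- sample(DNA_BASES, 1L)
    n_fill[i] <- b
    scoring[i] <- sub("N", b, scoring[i], fixed = TRUE)
  }
  short <- which(lens == expected_length - 1L & !excluded)
  for (i in short) {
    scoring[i] <- paste0(scoring[i], sample(DNA_BASES, 1L))
  }
  scoring[excluded] <- NA_character_
  tibble::tibble(sequence = sequences, scoring_sequence = scoring,
                 excluded = excluded, n_fill = n_fill)
}
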