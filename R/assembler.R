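#' Assembly parameters
#'
#' @param seed_threshold Minimum bacterial or viral score for a read to
#'   seed a contig (default 0.46). Exposed as a parameter; sensitivity to
#'   it can be explored directly.
#' @param min_overlap Minimum exact overlap (bases) for extension;
#'   must be smaller than the read length.
#' @param max_contig_length Hard cap on contig length (bases).
#' @param k_index Word size of the prefix/suffix hash index; defaults to
#'   `min_overlap`.
#' @return An `assembly_params` object.
#' @export
assembly_params <- function(seed_threshold = 0.46, min_overlap = 24L,
                            max_contig_length = 2000L, k_index = min_overlap) {
  stopifnot(seed_threshold > 0, seed_threshold < 1, min_overlap >= 2,
            max_contig_length >= 1, k_index <= min_overlap)
  structure(list(seed_threshold = seed_threshold,
                 min_overlap = as.integer(min_overlap),
                 max_contig_length = as.integer(max_contig_length),
                 k_index = as.integer(k_index)),
            class = "assembly_params")
}

#' Select and order seed reads
#'
#' A read is a seed when its bacterial or viral score reaches the
#' threshold. Seeds are ordered to prioritize likely-bacterial sequences:
#' all bacterial-class seeds first in descending bacterial score, then
#' viral-class seeds in descending viral score; ties break on `read_id`.
#' A read whose bacterial score reaches the threshold is classed
#' bacterial even if its viral score is higher.
#'
#' @param scored_reads Tibble from [score_reads()] (columns `read_id`,
#'   `p_viral`, `p_bacterial`, `excluded`).
#' @param seed_threshold Score threshold, default 0.46.
#' @return Tibble of seeds with `seed_class` and `seed_score`, in
#'   processing order.
#' @export
select_and_sort_seeds <- function(scored_reads, seed_threshold = 0.46) {
  sr <- scored_reads[!scored_reads$excluded, , drop = FALSE]
  is_b <- !is.na(sr$p_bacterial) & sr$p_bacterial >= seed_threshold
  is_v <- !is_b & !is.na(sr$p_viral) & sr$p_viral >= seed_threshold
  seeds <- sr[is_b | is_v, , drop = FALSE]
  if (nrow(seeds) == 0) {
    return(dplyr::mutate(seeds, seed_class = character(0),
                         seed_score = numeric(0)))
  }
  seeds$seed_class <- ifelse(is_b[is_b | is_v], "bacterial", "viral")
  seeds$seed_score <- ifelse(seeds$seed_class == "bacterial",
                             seeds$p_bacterial, seeds$p_viral)
  ord <- order(match(seeds$seed_class, c("bacterial", "viral")),
               -seeds$seed_score, seeds$read_id, method = "radix")
  seeds[ord, , drop = FALSE]
}

# --- internal: read pool with prefix/suffix word hash indices ------------

# Expand a word containing up to `max_n` N's into all concrete variants.
expand_n <- function(word, max_n = 2L) {
  npos <- which(strsplit(word, "")[[1]] == "N")
  if (length(npos) == 0) return(word)
  if (length(npos) > max_n) return(character(0))
  out <- word
  for (p in npos) {
    out <- unlist(lapply(out, function(w) {
      vapply(DNA_BASES, function(b) `substr<-`(w, p, p, value = b), "")
    }), use.names = FALSE)
  }
  out
}

build_read_index <- function(sequences, k) {
  pre <- new.env(hash = TRUE, parent = emptyenv())
  suf <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(env, word, i) {
    for (w in expand_n(word, 1L)) {
      env[[w]] <- c(env[[w]], i)
    }
  }
  lens <- nchar(sequences)
  for (i in seq_along(sequences)) {
    if (lens[i] < k) next
    add(pre, substr(sequences[i], 1L, k), i)
    add(suf, substr(sequences[i], lens[i] - k + 1L, lens[i]), i)
  }
  list(prefix = pre, suffix = suf)
}

# wildcard-aware comparison of two equal-length character vectors
wild_match <- function(a, b) {
  all(a == b | a == "N" | b == "N")
}

#' Greedily extend one seed read into a contig
#'
#' At each end, candidate reads whose prefix (right end) or suffix (left
#' end) overlaps the contig by at least `min_overlap` with an exact match
#' (N matches anything on either side) are found through the word index;
#' the read giving the longest extension is appended, ties broken by
#' higher seed-class score and then `read_id`. Wherever an N aligns
#' against a base the base is kept. Each read is used at most once.
#' After extension stops, unused reads fully contained in the contig are
#' absorbed as members, so a reconstructed molecule consumes its whole
#' read pool and cannot re-seed duplicate contigs. Any N still unresolved
#' is replaced by the base used for that read's N in the scoring path
#' (`n_fill`) and the contig is flagged `unresolved_N`.
#'
#' @param seed_idx Index of the seed read within `pool`.
#' @param pool Tibble with `read_id`, `sequence`, `n_fill`, and the score
#'   column of the seed class; rows are the un-mutated stored reads.
#' @param params An [assembly_params()].
#' @param index Optional precomputed [build_read_index()] over
#'   `pool$sequence`.
#' @param used Logical vector marking reads already consumed.
#' @param seed_class `"bacterial"` or `"viral"` (tie-break score column).
#' @return List: `sequence`, `members` (tibble read_id/offset/strand),
#'   `used` (updated), `left_extensions`, `right_extensions`, `flags`.
#' @export
extend_seed <- function(seed_idx, pool, params, index = NULL,
                        used = rep(FALSE, nrow(pool)),
                        seed_class = "bacterial") {
  k <- params$k_index
  if (is.null(index)) index <- build_read_index(pool$sequence, k)
  score_col <- if (seed_class == "bacterial") "p_bacterial" else "p_viral"
  tie_score <- if (score_col %in% names(pool)) pool[[score_col]] else
    rep(0, nrow(pool))
  lens <- nchar(pool$sequence)
  read_chars <- seq_to_chars(pool$sequence)

  contig <- read_chars[[seed_idx]]
  # contig position -> fill base for any N contributed by a member read
  fill_at <- list()
  note_fills <- function(fill_at, chars, offset, fill) {
    npos <- which(chars == "N")
    for (p in npos) fill_at[[as.character(offset + p - 1L)]] <- fill
    fill_at
  }
  fill_at <- note_fills(fill_at, contig, 1L, pool$n_fill[seed_idx])
  used[seed_idx] <- TRUE
  members <- list(list(read_id = pool$read_id[seed_idx], offset = 1L))
  offset0 <- 1L  # contig coordinate of original seed start (for reporting)
  n_left <- 0L; n_right <- 0L
  maxlen <- params$max_contig_length

  lookup <- function(env, word) {
    ids <- integer(0)
    for (w in expand_n(word, 2L)) ids <- c(ids, env[[w]])
    unique(ids)
  }

  repeat {  # right extension
    L <- length(contig)
    if (L >= maxlen) break
    best <- NULL
    p_lo <- max(1L, L - max(lens) + 1L)
    p_hi <- L - params$min_overlap + 1L
    if (p_hi < p_lo) break
    for (p in p_lo:p_hi) {
      if (p + k - 1L > L) next
      word <- chars_to_seq(contig[p:(p + k - 1L)])
      for (i in lookup(index$prefix, word)) {
        if (used[i]) next
        o <- L - p + 1L
        if (o >= lens[i] || o < params$min_overlap) next
        rc <- read_chars[[i]]
        if (!wild_match(rc[seq_len(o)], contig[p:L])) next
        ext <- lens[i] - o
        if (is.null(best) || ext > best$ext ||
            (ext == best$ext && (tie_score[i] > best$score ||
                                 (tie_score[i] == best$score &&
                                  pool$read_id[i] < best$read_id)))) {
          best <- list(i = i, p = p, o = o, ext = ext,
                       score = tie_score[i], read_id = pool$read_id[i])
        }
      }
    }
    if (is.null(best)) break
    rc <- read_chars[[best$i]]
    ov <- best$p:L
    resolve <- contig[ov] == "N" & rc[seq_len(best$o)] != "N"
    contig[ov][resolve] <- rc[seq_len(best$o)][resolve]
    contig <- c(contig, rc[(best$o + 1L):lens[best$i]])
    fill_at <- note_fills(fill_at, rc, best$p, pool$n_fill[best$i])
    used[best$i] <- TRUE
    members[[length(members) + 1L]] <- list(read_id = pool$read_id[best$i],
                                            offset = best$p)
    n_right <- n_right + 1L
  }

  repeat {  # left extension (mirror image)
    L <- length(contig)
    if (L >= maxlen) break
    best <- NULL
    e_lo <- params$min_overlap
    e_hi <- min(L, max(lens) - 1L)
    if (e_hi < e_lo) break
    for (e in e_lo:e_hi) {
      if (e - k + 1L < 1L) next
      word <- chars_to_seq(contig[(e - k + 1L):e])
      for (i in lookup(index$suffix, word)) {
        if (used[i]) next
        if (e >= lens[i]) next
        rc <- read_chars[[i]]
        tail_ix <- (lens[i] - e + 1L):lens[i]
        if (!wild_match(rc[tail_ix], contig[seq_len(e)])) next
        ext <- lens[i] - e
        if (is.null(best) || ext > best$ext ||
            (ext == best$ext && (tie_score[i] > best$score ||
                                 (tie_score[i] == best$score &&
                                  pool$read_id[i] < best$read_id)))) {
          best <- list(i = i, e = e, ext = ext,
                       score = tie_score[i], read_id = pool$read_id[i])
        }
      }
    }
    if (is.null(best)) break
    rc <- read_chars[[best$i]]
    ov <- seq_len(best$e)
    tail_ix <- (lens[best$i] - best$e + 1L):lens[best$i]
    resolve <- contig[ov] == "N" & rc[tail_ix] != "N"
    contig[ov][resolve] <- rc[tail_ix][resolve]
    contig <- c(rc[seq_len(best$ext)], contig)
    used[best$i] <- TRUE
    # shift all recorded offsets right by the extension length
    for (j in seq_along(members)) {
      members[[j]]$offset <- members[[j]]$offset + best$ext
    }
    if (length(fill_at) > 0) {
      names(fill_at) <- as.character(as.integer(names(fill_at)) + best$ext)
    }
    fill_at <- note_fills(fill_at, rc, 1L, pool$n_fill[best$i])
    offset0 <- offset0 + best$ext
    members[[length(members) + 1L]] <- list(read_id = pool$read_id[best$i],
                                            offset = 1L)
    n_left <- n_left + 1L
  }

  # absorb unused reads fully contained in the contig
  L <- length(contig)
  if (L >= k) {
    for (p in seq_len(L - k + 1L)) {
      word <- chars_to_seq(contig[p:(p + k - 1L)])
      for (i in lookup(index$prefix, word)) {
        if (used[i]) next
        if (p + lens[i] - 1L > L) next
        rc <- read_chars[[i]]
        ov <- p:(p + lens[i] - 1L)
        if (!wild_match(rc, contig[ov])) next
        resolve <- contig[ov] == "N" & rc != "N"
        contig[ov][resolve] <- rc[resolve]
        fill_at <- note_fills(fill_at, rc, p, pool$n_fill[i])
        used[i] <- TRUE
        members[[length(members) + 1L]] <- list(read_id = pool$read_id[i],
                                                offset = p)
      }
    }
  }

  flags <- character(0)
  npos <- which(contig == "N")
  if (length(npos) > 0) {
    for (p in npos) {
      fb <- fill_at[[as.character(p)]]
      contig[p] <- if (!is.null(fb) && !is.na(fb)) fb else "A"
    }
    flags <- "unresolved_N"
  }
  members <- dplyr::bind_rows(lapply(members, tibble::as_tibble))
  members$strand <- "+"
  list(sequence = chars_to_seq(contig), members = members, used = used,
       left_extensions = n_left, right_extensions = n_right,
       flags = if (length(flags)) paste(flags, collapse = ",") else ".")
}

#' Assemble a sample's scored reads into contigs
#'
#' Seeds are processed in [select_and_sort_seeds()] order; a read consumed
#' by an earlier contig is never reused (neither as member nor as a later
#' seed). Deterministic for fixed inputs and parameters.
#'
#' @param scored_reads Tibble from [score_reads()] (must include
#'   `sequence`).
#' @param params An [assembly_params()].
#' @return List with `contigs` (tibble: contig_id, sequence, seed_read_id,
#'   seed_class, n_reads, left_extensions, right_extensions, flags) and
#'   `members` (tibble: contig_id, read_id, offset, strand).
#' @export
assemble_sample <- function(scored_reads, params = assembly_params()) {
  pool <- scored_reads[!scored_reads$excluded, , drop = FALSE]
  seeds <- select_and_sort_seeds(pool, params$seed_threshold)
  contigs <- list(); members <- list()
  if (nrow(seeds) > 0) {
    index <- build_read_index(pool$sequence, params$k_index)
    used <- rep(FALSE, nrow(pool))
    row_of <- stats::setNames(seq_len(nrow(pool)), pool$read_id)
    cid <- 0L
    for (s in seq_len(nrow(seeds))) {
      i <- row_of[[seeds$read_id[s]]]
      if (used[i]) next
      res <- extend_seed(i, pool, params, index = index, used = used,
                         seed_class = seeds$seed_class[s])
      used <- res$used
      cid <- cid + 1L
      id_str <- sprintf("ctg%04d", cid)
      contigs[[cid]] <- tibble::tibble(
        contig_id = id_str, sequence = res$sequence,
        seed_read_id = seeds$read_id[s], seed_class = seeds$seed_class[s],
        n_reads = nrow(res$members),
        left_extensions = res$left_extensions,
        right_extensions = res$right_extensions, flags = res$flags)
      members[[cid]] <- tibble::tibble(contig_id = id_str,
                                       read_id = res$members$read_id,
                                       offset = res$members$offset,
                                       strand = res$members$strand)
    }
  }
  if (length(contigs) == 0) {
    return(list(
      contigs = tibble::tibble(contig_id = character(0),
                               sequence = character(0),
                               seed_read_id = character(0),
                               seed_class = character(0),
                               n_reads = integer(0),
                               left_extensions = integer(0),
                               right_extensions = integer(0),
                               flags = character(0)),
      members = tibble::tibble(contig_id = character(0),
                               read_id = character(0), offset = integer(0),
                               strand = character(0))))
  }
  list(contigs = dplyr::bind_rows(contigs),
       members = dplyr::bind_rows(members))
}

#' Write contigs to FASTA with structured headers
#'
#' Header fields: `contig_id seed_class n_reads flags`.
#' @param contigs Contig tibble from [assemble_sample()].
#' @param path Output path.
#' @export
write_contig_fasta <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(contigs$sequence)
  names(x) <- paste(contigs$contig_id, contigs$seed_class, contigs$n_reads,
                    contigs$flags)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
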