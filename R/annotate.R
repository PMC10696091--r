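#' Contig annotation against nucleotide and protein reference collections
#'
#' The default backend is a built-in ungapped seed-and-extend local
#' aligner: word hits (11-mers for nucleotide, exact 3-mers for protein)
#' define diagonals, and the best ungapped local segment on a diagonal is
#' the maximum-sum subarray of the per-position substitution scores
#' (match +2 / mismatch -3 for nucleotide, BLOSUM62 for protein).
#' Significance uses Karlin-Altschul statistics,
#' `E = K * m * n * exp(-lambda * S)`, with `lambda` solved from the
#' scoring scheme and background composition and the standard ungapped
#' `K` constants. An external BLAST+ backend (`blastn` / `blastx`) is
#' available behind the same interface via `backend = "blast"`.
#'
#' @name contig-annotation
NULL

# lambda for a match/mismatch scheme under uniform base composition
nt_karlin_lambda <- function(match = 2, mismatch = -3) {
  f <- function(lam) 0.25 * exp(lam * match) + 0.75 * exp(lam * mismatch) - 1
  stats::uniroot(f, c(1e-6, 5), tol = 1e-12)$root
}

NT_KARLIN <- list(lambda = NULL, K = 0.41)   # lambda filled lazily
AA_KARLIN <- list(lambda = 0.3176, K = 0.134)  # standard ungapped BLOSUM62

nt_lambda <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- nt_karlin_lambda()
    cache
  }
})

# Best ungapped local alignment of query vs subject restricted to the
# diagonals on which they share an indexed word. Returns the single best
# segment (score, coordinates, identity).
diagonal_hits <- function(qchars, schars, diags, score_fun) {
  m <- length(qchars); n <- length(schars)
  best <- NULL
  for (d in diags) {
    # diagonal d: query position i aligns subject position i + d
    i_lo <- max(1L, 1L - d); i_hi <- min(m, n - d)
    if (i_hi < i_lo) next
    qs <- qchars[i_lo:i_hi]
    ss <- schars[(i_lo + d):(i_hi + d)]
    sc <- score_fun(qs, ss)
    # max-sum subarray with positions (Kadane via prefix sums)
    pref <- cumsum(sc)
    p0 <- c(0, pref[-length(pref)])  # prefix sum before each position
    lo_run <- cummin(p0)
    gains <- pref - lo_run
    j <- which.max(gains)
    s_best <- gains[j]
    if (s_best <= 0) next
    # the segment starts where the running prefix minimum was attained
    start <- max(which(p0[seq_len(j)] == lo_run[j]))
    ident <- mean(qs[start:j] == ss[start:j])
    cand <- list(score = s_best, q_start = i_lo + start - 1L,
                 q_end = i_lo + j - 1L, s_start = i_lo + d + start - 1L,
                 s_end = i_lo + j + d - 1L, identity = ident)
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  best
}

# word -> positions hash for one subject sequence
word_positions <- function(chars, w) {
  L <- length(chars)
  if (L < w) return(character(0))
  starts <- seq_len(L - w + 1L)
  words <- substring(paste(chars, collapse = ""), starts, starts + w - 1L)
  words
}

# Shared diagonals between query and subject via word matching.
shared_diagonals <- function(qwords, swords) {
  common <- intersect(qwords, swords)
  if (length(common) == 0) return(integer(0))
  qpos <- split(seq_along(qwords), factor(qwords, levels = common))
  spos <- split(seq_along(swords), factor(swords, levels = common))
  d <- unlist(lapply(common, function(wd) {
    as.vector(outer(spos[[wd]], qpos[[wd]], `-`))
  }), use.names = FALSE)
  unique(d)
}

nt_score_fun <- function(match = 2, mismatch = -3) {
  function(a, b) ifelse(a == b, match, mismatch)
}

aa_score_fun <- function() {
  mat <- get_blosum62()
  function(a, b) {
    s <- rep(-30, length(a))  # stops ('*') and ambiguity break extension hard
    ok <- a %in% rownames(mat) & b %in% colnames(mat) & a != "*" & b != "*"
    s[ok] <- mat[cbind(a[ok], b[ok])]
    s
  }
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Best hit of one query against a database tibble (sequence column given
# as character), ungapped, via word-seeded diagonals.
best_db_hit <- function(query, db_seqs, word, score_fun, lambda, K) {
  qchars <- strsplit(query, "")[[1]]
  qwords <- word_positions(qchars, word)
  n_total <- sum(nchar(db_seqs))
  best <- NULL
  for (j in seq_along(db_seqs)) {
    schars <- strsplit(db_seqs[j], "")[[1]]
    swords <- word_positions(schars, word)
    diags <- shared_diagonals(qwords, swords)
    if (length(diags) == 0) next
    hit <- diagonal_hits(qchars, schars, diags, score_fun)
    if (is.null(hit)) next
    hit$db_index <- j
    if (is.null(best) || hit$score > best$score) best <- hit
  }
  if (is.null(best)) return(NULL)
  best$bit_score <- (lambda * best$score - log(K)) / log(2)
  best$e_value <- K * nchar(query) * n_total * exp(-lambda * best$score)
  best
}

#' Nucleotide search of contigs against an annotation database
#'
#' Per contig, database hits with `e_value < e_max` are ranked by
#' e-value (ties: higher bit score, then lexicographically smallest
#' accession) and the top hit is retained; contigs with no qualifying hit
#' are unassigned (absent from the result).
#'
#' @param contigs Tibble with `contig_id`, `sequence` (N-free).
#' @param nucleotide_db Tibble with `accession`, `sequence`, `species`,
#'   `genus`, `kind`.
#' @param e_max E-value cutoff, default 0.01.
#' @param backend `"builtin"` or `"blast"` (requires `blastn` on PATH).
#' @param word Word size of the built-in index.
#' @return Tibble of top hits: `contig_id`, `accession`, `e_value`,
#'   `bit_score`, `identity`, `species`, `genus`, `kind`.
#' @export
nucleotide_search <- function(contigs, nucleotide_db, e_max = 0.01,
                              backend = c("builtin", "blast"), word = 11L) {
  backend <- match.arg(backend)
  if (nrow(nucleotide_db) == 0) {
    warning("empty nucleotide database: all contigs unassigned")
    return(empty_nt_hits())
  }
  if (nrow(contigs) == 0) return(empty_nt_hits())
  if (any(grepl("N", contigs$sequence, fixed = TRUE))) {
    stop("contigs must be N-free before annotation")
  }
  if (backend == "blast") {
    return(blast_nucleotide_search(contigs, nucleotide_db, e_max))
  }
  lambda <- nt_lambda(); K <- NT_KARLIN$K
  sf <- nt_score_fun()
  n_total <- sum(nchar(nucleotide_db$sequence))
  db_chars <- seq_to_chars(nucleotide_db$sequence)
  db_words <- lapply(db_chars, word_positions, w = word)
  hits <- list()
  for (i in seq_len(nrow(contigs))) {
    per_db <- list()
    qchars <- strsplit(contigs$sequence[i], "")[[1]]
    qwords <- word_positions(qchars, word)
    for (j in seq_len(nrow(nucleotide_db))) {
      schars <- db_chars[[j]]
      diags <- shared_diagonals(qwords, db_words[[j]])
      if (length(diags) == 0) next
      h <- diagonal_hits(qchars, schars, diags, sf)
      if (is.null(h)) next
      e <- K * length(qchars) * n_total * exp(-lambda * h$score)
      if (e >= e_max) next
      per_db[[length(per_db) + 1L]] <- tibble::tibble(
        contig_id = contigs$contig_id[i],
        accession = nucleotide_db$accession[j],
        e_value = e, bit_score = (lambda * h$score - log(K)) / log(2),
        identity = h$identity,
        species = nucleotide_db$species[j],
        genus = nucleotide_db$genus[j],
        kind = nucleotide_db$kind[j])
    }
    if (length(per_db) == 0) next
    tab <- dplyr::bind_rows(per_db)
    tab <- tab[order(tab$e_value, -tab$bit_score, tab$accession), , drop = FALSE]
    hits[[length(hits) + 1L]] <- tab[1, , drop = FALSE]
  }
  if (length(hits) == 0) return(empty_nt_hits())
  dplyr::bind_rows(hits)
}

empty_nt_hits <- function() {
  tibble::tibble(contig_id = character(0), accession = character(0),
                 e_value = numeric(0), bit_score = numeric(0),
                 identity = numeric(0), species = character(0),
                 genus = character(0), kind = character(0))
}

empty_aa_hits <- function() {
  tibble::tibble(contig_id = character(0), accession = character(0),
                 e_value = numeric(0), bit_score = numeric(0),
                 identity = numeric(0), family = character(0),
                 frame = integer(0))
}

# translate one frame; frame in {1,2,3,-1,-2,-3}
translate_frame <- function(sequence, frame) {
  s <- if (frame < 0) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
  } else sequence
  off <- abs(frame) - 1L
  s <- substr(s, 1L + off, nchar(s))
  s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
  if (nchar(s) < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}

#' Translated six-frame search of contigs against a protein database
#'
#' All six reading frames are searched; the top protein-family hit per
#' contig under `e_max` is retained, with the winning frame recorded.
#'
#' @param contigs Tibble with `contig_id`, `sequence` (N-free).
#' @param protein_db Tibble with `accession`, `sequence` (amino acids),
#'   `family`.
#' @param e_max E-value cutoff, default 1e-5.
#' @param backend `"builtin"` or `"blast"` (requires `blastx` on PATH).
#' @param word Amino-acid word size of the built-in index.
#' @return Tibble of top hits: `contig_id`, `accession`, `e_value`,
#'   `bit_score`, `identity`, `family`, `frame`.
#' @export
translated_search <- function(contigs, protein_db, e_max = 1e-5,
                              backend = c("builtin", "blast"), word = 3L) {
  backend <- match.arg(backend)
  if (nrow(protein_db) == 0) {
    warning("empty protein database: all contigs unassigned")
    return(empty_aa_hits())
  }
  if (nrow(contigs) == 0) return(empty_aa_hits())
  if (any(grepl("N", contigs$sequence, fixed = TRUE))) {
    stop("contigs must be N-free before annotation")
  }
  if (backend == "blast") {
    return(blast_translated_search(contigs, protein_db, e_max))
  }
  lambda <- AA_KARLIN$lambda; K <- AA_KARLIN$K
  sf <- aa_score_fun()
  n_total <- sum(nchar(protein_db$sequence))
  db_chars <- seq_to_chars(protein_db$sequence)
  db_words <- lapply(db_chars, word_positions, w = word)
  hits <- list()
  for (i in seq_len(nrow(contigs))) {
    best <- NULL
    m_aa <- nchar(contigs$sequence[i]) %/% 3L
    if (m_aa < word) next
    for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      aa <- translate_frame(contigs$sequence[i], fr)
      if (nchar(aa) < word) next
      qchars <- strsplit(aa, "")[[1]]
      qwords <- word_positions(qchars, word)
      for (j in seq_len(nrow(protein_db))) {
        diags <- shared_diagonals(qwords, db_words[[j]])
        if (length(diags) == 0) next
        h <- diagonal_hits(qchars, db_chars[[j]], diags, sf)
        if (is.null(h)) next
        e <- K * m_aa * n_total * exp(-lambda * h$score)
        if (e >= e_max) next
        cand <- list(e = e, score = h$score, identity = h$identity,
                     j = j, frame = fr)
        if (is.null(best) || cand$e < best$e ||
            (cand$e == best$e &&
             protein_db$accession[j] < protein_db$accession[best$j])) {
          best <- cand
        }
      }
    }
    if (is.null(best)) next
    hits[[length(hits) + 1L]] <- tibble::tibble(
      contig_id = contigs$contig_id[i],
      accession = protein_db$accession[best$j],
      e_value = best$e,
      bit_score = (lambda * best$score - log(K)) / log(2),
      identity = best$identity,
      family = protein_db$family[best$j],
      frame = best$frame)
  }
  if (length(hits) == 0) return(empty_aa_hits())
  dplyr::bind_rows(hits)
}

#' Remove hits assigned to known contaminant genera
#'
#' @param hits Hit tibble carrying a `genus` column.
#' @param contaminant_taxa Character vector of genus names (may be empty).
#' @return The filtered tibble; removed hits are attached as
#'   `attr(, "removed")` and reported via a message.
#' @export
screen_contaminants <- function(hits, contaminant_taxa = character(0)) {
  if (length(contaminant_taxa) == 0 || nrow(hits) == 0) {
    attr(hits, "removed") <- hits[0, , drop = FALSE]
    return(hits)
  }
  drop <- hits$genus %in% contaminant_taxa
  if (any(drop)) {
    message(sum(drop), " hit(s) removed as contaminants (",
            paste(unique(hits$genus[drop]), collapse = ", "), ")")
  }
  out <- hits[!drop, , drop = FALSE]
  attr(out, "removed") <- hits[drop, , drop = FALSE]
  out
}

#' Pool species-level hits to genus presence
#'
#' @param hits Hit tibble with a `genus` column (one sample's hits).
#' @return Sorted character vector of distinct genera with at least one
#'   assigned contig. Idempotent and order-independent.
#' @export
pool_to_genus <- function(hits) {
  if (nrow(hits) == 0) return(character(0))
  sort(unique(hits$genus[!is.na(hits$genus)]))
}

# --- external BLAST+ backend --------------------------------------------

blast_available <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

blast_nucleotide_search <- function(contigs, nucleotide_db, e_max) {
  td <- tempfile("blastnt"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  dbf <- file.path(td, "db.fasta"); qf <- file.path(td, "q.fasta")
  write_nucleotide_db_fasta(dplyr::mutate(nucleotide_db,
                                          species = gsub(" ", "_", species)),
                            dbf)
  writeLines(paste0(">", contigs$contig_id, "\n", contigs$sequence), qf)
  system2("makeblastdb", c("-in", dbf, "-dbtype", "nucl"),
          stdout = FALSE, stderr = FALSE)
  out <- system2("blastn", c("-query", qf, "-db", dbf, "-evalue",
                             format(e_max, scientific = FALSE),
                             "-outfmt", shQuote("6 qseqid sseqid evalue bitscore pident")),
                 stdout = TRUE)
  parse_blast_hits(out, nucleotide_db, e_max, translated = FALSE)
}

blast_translated_search <- function(contigs, protein_db, e_max) {
  td <- tempfile("blastaa"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  dbf <- file.path(td, "db.fasta"); qf <- file.path(td, "q.fasta")
  write_protein_db_fasta(protein_db, dbf)
  writeLines(paste0(">", contigs$contig_id, "\n", contigs$sequence), qf)
  system2("makeblastdb", c("-in", dbf, "-dbtype", "prot"),
          stdout = FALSE, stderr = FALSE)
  out <- system2("blastx",
                 c("-query", qf, "-db", dbf, "-evalue", format(e_max),
                   "-outfmt",
                   shQuote("6 qseqid sseqid evalue bitscore pident sframe qframe")),
                 stdout = TRUE)
  parse_blast_hits(out, protein_db, e_max, translated = TRUE)
}

parse_blast_hits <- function(lines, db, e_max, translated) {
  if (length(lines) == 0) {
    return(if (translated) empty_aa_hits() else empty_nt_hits())
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  tab <- tibble::tibble(
    contig_id = vapply(f, `[`, "", 1),
    sseqid = vapply(f, `[`, "", 2),
    e_value = as.numeric(vapply(f, `[`, "", 3)),
    bit_score = as.numeric(vapply(f, `[`, "", 4)),
    identity = as.numeric(vapply(f, `[`, "", 5)) / 100)
  if (translated) {
    tab$frame <- as.integer(vapply(f, `[`, "", 7))
  }
  tab$accession <- vapply(strsplit(tab$sseqid, "|", fixed = TRUE), `[`, "", 1)
  tab <- tab[tab$e_value < e_max, , drop = FALSE]
  tab <- tab[order(tab$contig_id, tab$e_value, -tab$bit_score, tab$accession), ,
             drop = FALSE]
  tab <- tab[!duplicated(tab$contig_id), , drop = FALSE]
  if (translated) {
    tab$family <- db$family[match(tab$accession, db$accession)]
    tab[, c("contig_id", "accession", "e_value", "bit_score", "identity",
            "family", "frame")]
  } else {
    m <- match(tab$accession, db$accession)
    tab$species <- db$species[m]; tab$genus <- db$genus[m]
    tab$kind <- db$kind[m]
    tab[, c("contig_id", "accession", "e_value", "bit_score", "identity",
            "species", "genus", "kind")]
  }
}
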