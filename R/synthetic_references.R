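#' Generate a labeled synthetic reference collection
#'
#' Emits `n_per_class` reference sequences per origin model, with lengths
#' drawn uniformly from `length_range`. These play the role of the three
#' source collections used to train the read classifier (a host
#' transcriptome, viral transcripts, bacterial genomes) at desk scale.
#'
#' @param origin_models Named list of [origin_model()] objects with unique
#'   labels.
#' @param n_per_class Number of references per class (0 allowed, yielding
#'   an empty collection).
#' @param length_range Length-2 integer vector, minimum 200 bases.
#' @param rng_seed Integer seed; identical seeds give byte-identical output.
#' @return A tibble with columns `accession`, `label`, `sequence`.
#' @export
make_references <- function(origin_models, n_per_class,
                            length_range = c(500L, 2000L), rng_seed = 1L) {
  labels <- vapply(origin_models, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("origin model labels must be unique")
  for (m in origin_models) {
    if (!inherits(m, "origin_model")) stop("all models must be origin_model objects")
  }
  stopifnot(n_per_class >= 0, length(length_range) == 2)
  if (n_per_class > 0 && min(length_range) < 200) {
    stop("reference lengths must be at least 200 bases")
  }
  if (n_per_class == 0) {
    return(tibble::tibble(accession = character(0), label = character(0),
                          sequence = character(0)))
  }
  prefix <- c(human = "HUM", viral = "VIR", bacterial = "BAC")
  with_seed(rng_seed, {
    out <- lapply(origin_models, function(m) {
      lens <- length_range[1] - 1L +
        sample.int(length_range[2] - length_range[1] + 1L, n_per_class,
                   replace = TRUE)
      tibble::tibble(
        accession = sprintf("%s_%04d", prefix[[m$label]], seq_len(n_per_class)),
        label = m$label,
        sequence = markov_sequences(m, lens)
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Attach taxonomy to bacterial/viral references to form a nucleotide
#' annotation database
#'
#' Assigns synthetic species and genus names to bacterial references
#' (round-robin over `n_genera` genera) and marks viral references as
#' reference viruses, producing the structured records the contig
#' annotation layer searches against.
#'
#' @param references Tibble from [make_references()].
#' @param n_genera Number of bacterial genera to spread species across.
#' @return A tibble with columns `accession`, `sequence`, `species`,
#'   `genus`, `kind`.
#' @export
make_annotation_db <- function(references, n_genera = 5L) {
  bact <- references[references$label == "bacterial", ]
  vir <- references[references$label == "viral", ]
  db <- list()
  if (nrow(bact) > 0) {
    genus <- sprintf("Genus%02d", ((seq_len(nrow(bact)) - 1L) %% n_genera) + 1L)
    species_no <- stats::ave(seq_len(nrow(bact)), genus, FUN = seq_along)
    db$bact <- tibble::tibble(
      accession = bact$accession, sequence = bact$sequence,
      species = sprintf("%s species%02d", genus, species_no),
      genus = genus, kind = "bacterial")
  }
  if (nrow(vir) > 0) {
    db$vir <- tibble::tibble(
      accession = vir$accession, sequence = vir$sequence,
      species = sprintf("Virus%02d", seq_len(nrow(vir))),
      genus = sprintf("Virus%02d", seq_len(nrow(vir))),
      kind = "viral_reference")
  }
  dplyr::bind_rows(db)
}

#' Derive a protein family database from reference sequences
#'
#' For each selected reference, translates an in-frame window into an
#' amino-acid record and assigns it a family name, emulating a
#' non-redundant microbial protein collection. Windows containing stop
#' codons are shifted forward until a stop-free window is found.
#'
#' @param references Tibble from [make_references()].
#' @param accessions Accessions to derive families from (default: all
#'   bacterial references).
#' @param family_names Optional character vector of family names, recycled
#'   against `accessions`; defaults to `Fam01`, `Fam02`, ...
#' @param window_aa Length of the protein record in amino acids.
#' @return A tibble with columns `accession`, `sequence` (amino acids),
#'   `family`, `source_accession`, `nt_start` (1-based start of the coding
#'   window on the source reference).
#' @export
make_protein_db <- function(references, accessions = NULL,
                            family_names = NULL, window_aa = 60L) {
  if (is.null(accessions)) {
    accessions <- references$accession[references$label == "bacterial"]
  }
  missing <- setdiff(accessions, references$accession)
  if (length(missing) > 0) {
    stop("accessions not in references: ", paste(missing, collapse = ", "))
  }
  if (is.null(family_names)) {
    family_names <- sprintf("Fam%02d", seq_along(accessions))
  }
  family_names <- rep_len(family_names, length(accessions))
  recs <- lapply(seq_along(accessions), function(i) {
    nt <- references$sequence[references$accession == accessions[i]]
    win_nt <- 3L * window_aa
    start <- 1L
    aa <- NULL
    while (start + win_nt - 1L <= nchar(nt)) {
      cand <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(nt, start, start + win_nt - 1L))))
      if (!grepl("*", cand, fixed = TRUE)) { aa <- cand; break }
      start <- start + 3L
    }
    if (is.null(aa)) return(NULL)  # no stop-free window in this reference
    tibble::tibble(accession = sprintf("WP_%s", accessions[i]),
                   sequence = aa, family = family_names[i],
                   source_accession = accessions[i], nt_start = start)
  })
  dplyr::bind_rows(recs)
}
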