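#' Sequence and table I/O
#'
#' FASTA headers carry structured, pipe-delimited metadata:
#' `accession|label` for origin-labeled references,
#' `accession|species|genus|kind` for nucleotide annotation databases,
#' `accession|family` for protein databases, and
#' `contig_id seed_class n_reads flags` (space-delimited) for contigs.
#' FASTQ qualities are written as constant `I`; the method never reads
#' quality.
#'
#' @name microseek-io
NULL

#' @rdname microseek-io
#' @param references Tibble with `accession`, `label`, `sequence`.
#' @param path Output file path.
#' @export
write_reference_fasta <- function(references, path) {
  x <- Biostrings::DNAStringSet(references$sequence)
  names(x) <- paste(references$accession, references$label, sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname microseek-io
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  tibble::tibble(accession = vapply(parts, `[`, character(1), 1),
                 label = vapply(parts, `[`, character(1), 2),
                 sequence = as.character(x))
}

#' @rdname microseek-io
#' @param db Nucleotide annotation DB tibble
#'   (`accession`, `sequence`, `species`, `genus`, `kind`).
#' @export
write_nucleotide_db_fasta <- function(db, path) {
  x <- Biostrings::DNAStringSet(db$sequence)
  names(x) <- paste(db$accession, db$species, db$genus, db$kind, sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname microseek-io
#' @export
read_nucleotide_db_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  tibble::tibble(accession = vapply(parts, `[`, character(1), 1),
                 sequence = as.character(x),
                 species = vapply(parts, `[`, character(1), 2),
                 genus = vapply(parts, `[`, character(1), 3),
                 kind = vapply(parts, `[`, character(1), 4))
}

#' @rdname microseek-io
#' @export
write_protein_db_fasta <- function(db, path) {
  x <- Biostrings::AAStringSet(db$sequence)
  names(x) <- paste(db$accession, db$family, sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname microseek-io
#' @export
read_protein_db_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  tibble::tibble(accession = vapply(parts, `[`, character(1), 1),
                 sequence = as.character(x),
                 family = vapply(parts, `[`, character(1), 2))
}

#' @rdname microseek-io
#' @param reads Tibble with `read_id`, `sequence`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname microseek-io
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = names(x), sequence = as.character(x))
}

# Deterministic TSV writers (fixed column order, no quoting, no rownames)
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                      check.names = FALSE))
}
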