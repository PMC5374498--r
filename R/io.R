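#' Read a FASTQ file into a tibble
#'
#' Loads a (optionally gzipped) FASTQ file as a two-column tibble. Quality
#' strings are not retained: no step of the pipeline uses base qualities.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fastq_tbl <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(id = names(x), sequence = as.character(x))
}

#' Read a FASTA file into a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names truncated at the first
#'   whitespace, as mapping tools conventionally do).
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  setNames(as.character(x), nm)
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# fast 4-line FASTQ writer for simulated libraries; constant quality because
# the pipeline is quality-blind
write_fastq_lines <- function(ids, seqs, path, qual_char = "I") {
  n <- length(ids)
  stopifnot(length(seqs) == n)
  quals <- vapply(nchar(seqs), function(w) strrep(qual_char, w), character(1))
  rec <- character(4L * n)
  if (n > 0) {
    rec[seq(1L, by = 4L, length.out = n)] <- paste0("@", ids)
    rec[seq(2L, by = 4L, length.out = n)] <- seqs
    rec[seq(3L, by = 4L, length.out = n)] <- "+"
    rec[seq(4L, by = 4L, length.out = n)] <- quals
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
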