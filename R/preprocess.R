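# Read cleaning: drop ambiguous reads, trim the 3' adapter together with the
# HD signature (degenerate bases ligated next to the adapter), apply the
# minimum-length filter and collapse surviving inserts to unique tags.

# Illumina TruSeq small-RNA 3' adapter
DEFAULT_ADAPTER_3P <- "TGGAATTCTCGGGTGCCAAGG"

#' Drop reads containing ambiguous (N) bases
#'
#' @param reads Tibble with a `sequence` column (e.g. from
#'   [read_fastq_tbl()]).
#' @return The input tibble restricted to reads without any `N`, in the
#'   original order.
#' @export
discard_ambiguous <- function(reads) {
  dplyr::filter(reads, !grepl("N", .data$sequence, fixed = TRUE))
}

#' Trim the 3' adapter and HD signature from reads
#'
#' Finds the leftmost occurrence of the first `min_overlap` adapter bases
#' (exact match) starting at a position that leaves at least `hd_length`
#' preceding bases, then removes the adapter match and the `hd_length`
#' degenerate bases immediately before it. The remaining 5' prefix is the
#' insert. Reads without such an occurrence get an `NA` insert (the
#' no-adapter outcome).
#'
#' @param reads Tibble with a `sequence` column, or a character vector of
#'   read sequences.
#' @param adapter 3' adapter sequence.
#' @param min_overlap Minimum adapter prefix length that must match.
#' @param hd_length Number of degenerate (HD) bases preceding the adapter.
#' @return For tibble input, the tibble with an added `insert` column; for
#'   character input, a character vector of inserts (`NA` = no adapter).
#' @export
trim_adapter_and_hd <- function(reads, adapter = DEFAULT_ADAPTER_3P,
                                min_overlap = 7, hd_length = 4) {
  stopifnot(nzchar(adapter), min_overlap >= 1,
            nchar(adapter) >= min_overlap, hd_length >= 0)
  if (is.data.frame(reads)) {
    return(dplyr::mutate(reads, insert = trim_adapter_and_hd(
      .data$sequence, adapter, min_overlap, hd_length)))
  }
  probe <- substr(adapter, 1, min_overlap)
  # search only past the first hd_length bases: an adapter occurrence there
  # has room for the HD signature before it
  pos <- regexpr(probe, substr(reads, hd_length + 1, nchar(reads)),
                 fixed = TRUE)
  insert <- rep(NA_character_, length(reads))
  hit <- pos > 0
  insert[hit] <- substr(reads[hit], 1, pos[hit] - 1)
  insert
}

#' Keep sequences of at least a minimum length
#'
#' @param x Character vector, or tibble with the column named by `col`.
#' @param l_min Minimum length kept (inclusive).
#' @param col Column holding the sequences when `x` is a tibble.
#' @return `x` restricted to entries of length >= `l_min`.
#' @export
length_filter <- function(x, l_min = 16, col = "sequence") {
  if (is.data.frame(x)) {
    return(x[!is.na(x[[col]]) & nchar(x[[col]]) >= l_min, , drop = FALSE])
  }
  x[!is.na(x) & nchar(x) >= l_min]
}

#' Collapse inserts to unique tags with counts
#'
#' One row per distinct sequence; the sum of counts (redundant total) equals
#' the number of input inserts, the number of rows is the non-redundant
#' total. The result is sorted by decreasing count, ties by sequence, so
#' output is independent of input order.
#'
#' @param inserts Character vector of insert sequences, or tibble with a
#'   `insert` or `sequence` column.
#' @return Tibble with columns `sequence` and `count`.
#' @export
collapse_tags <- function(inserts) {
  if (is.data.frame(inserts)) {
    col <- if ("insert" %in% names(inserts)) "insert" else "sequence"
    inserts <- inserts[[col]]
  }
  if (length(inserts) == 0) {
    return(tibble::tibble(sequence = character(0), count = integer(0)))
  }
  tc <- table(inserts)
  out <- tibble::tibble(sequence = names(tc), count = as.integer(tc))
  dplyr::arrange(out, dplyr::desc(.data$count), .data$sequence)
}

#' Clean one library: filter, trim, length-select and collapse
#'
#' Runs the full preprocessing chain on one library and accounts for every
#' read: `input = ambiguous + no_adapter + short + accepted`. Reads whose
#' adapter was found but whose insert is shorter than `l_min` (including
#' empty inserts) count as `discarded_short`.
#'
#' @param reads FASTQ path or tibble with `sequence` (see
#'   [read_fastq_tbl()]).
#' @param adapter,min_overlap,hd_length See [trim_adapter_and_hd()].
#' @param l_min Minimum insert length kept.
#' @return List with `tags` (tibble `sequence`, `count`) and `stats` (one-row
#'   tibble: `input_reads`, `discarded_ambiguous`, `discarded_no_adapter`,
#'   `discarded_short`, `accepted_reads`, `l_min`, `hd_length`).
#' @export
preprocess_library <- function(reads, adapter = DEFAULT_ADAPTER_3P,
                               min_overlap = 7, hd_length = 4, l_min = 16) {
  if (is.character(reads) && length(reads) == 1) {
    reads <- read_fastq_tbl(reads)
  }
  n_input <- nrow(reads)
  unambig <- discard_ambiguous(reads)
  n_ambig <- n_input - nrow(unambig)
  inserts <- trim_adapter_and_hd(unambig$sequence, adapter, min_overlap,
                                 hd_length)
  n_noad <- sum(is.na(inserts))
  inserts <- inserts[!is.na(inserts)]
  kept <- length_filter(inserts, l_min)
  n_short <- length(inserts) - length(kept)
  stats <- tibble::tibble(
    input_reads = n_input, discarded_ambiguous = n_ambig,
    discarded_no_adapter = n_noad, discarded_short = n_short,
    accepted_reads = length(kept), l_min = as.integer(l_min),
    hd_length = as.integer(hd_length)
  )
  list(tags = collapse_tags(kept), stats = stats)
}

#' Write collapsed tags as a count-annotated FASTA file
#'
#' Headers follow the `>tag_<i>_x<count>` dialect common to collapsed
#' small-RNA tag files.
#'
#' @param tags Tibble with `sequence` and `count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags_fasta <- function(tags, path) {
  seqs <- setNames(tags$sequence,
                   sprintf("tag_%d_x%d", seq_len(nrow(tags)), tags$count))
  write_fasta_seqs(seqs, path)
}

#' Read a count-annotated tag FASTA file
#'
#' @param path Path written by [write_tags_fasta()].
#' @return Tibble with `sequence` and `count`.
#' @export
read_tags_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(
    sequence = unname(as.character(x)),
    count = as.integer(sub("^.*_x(\\d+)$", "\\1", names(x)))
  )
}
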