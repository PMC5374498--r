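# Full-length, ungapped, mismatch-bounded matching of tags against reference
# sequences, and the two pipeline uses of it: genome mapping (<= 1 mismatch,
# both strands) and mature-miRNA assignment (<= 2 mismatches, sense strand).

#' Match tags full-length and ungapped within a mismatch bound
#'
#' Reports every position at which a tag aligns over its whole length, with
#' no gaps, to a window of a reference sequence at Hamming distance at most
#' `k`. Minus-strand hits align the reverse complement of the tag; the
#' reported offset is always on the reference's forward coordinates. The hit
#' set is exactly what an exhaustive scan returns (the seed-and-extend index
#' is an implementation detail with an oracle-equivalence contract).
#'
#' @param tags Character vector of tag sequences, or tibble with a
#'   `sequence` column.
#' @param references Named character vector of reference sequences.
#' @param k Maximum number of mismatches (>= 0).
#' @param strands Strands to search, subset of `c("+", "-")`.
#' @return Tibble with columns `tag` (sequence), `reference` (name),
#'   `offset` (0-based start of the alignment window), `strand` and
#'   `mismatches`.
#' @export
mir_match <- function(tags, references, k = 0, strands = c("+", "-")) {
  if (is.data.frame(tags)) tags <- tags$sequence
  stopifnot(k >= 0, length(strands) >= 1, all(strands %in% c("+", "-")))
  ref_names <- names(references)
  if (is.null(ref_names)) ref_names <- as.character(seq_along(references))
  if (length(tags) == 0 || length(references) == 0) {
    return(tibble::tibble(tag = character(0), reference = character(0),
                          offset = integer(0), strand = character(0),
                          mismatches = integer(0)))
  }
  h <- match_tags_cpp(as.character(tags), unname(as.character(references)),
                      as.integer(k), "-" %in% strands)
  out <- tibble::tibble(
    tag_index = h$tag, tag = as.character(tags)[h$tag],
    reference = ref_names[h$ref], offset = h$offset, strand = h$strand,
    mismatches = h$mismatches
  )
  out <- dplyr::filter(out, .data$strand %in% strands)
  out <- dplyr::arrange(out, .data$tag_index, .data$reference, .data$offset,
                        .data$strand)
  dplyr::select(out, -"tag_index")
}

#' Map tags to a genome and compute mapping statistics
#'
#' A tag is genome-matching iff it has at least one full-length ungapped hit
#' at `k` mismatches or fewer on either strand. Statistics are reported both
#' redundantly (count-weighted, i.e. over all reads) and non-redundantly
#' (over unique tags).
#'
#' @param tags Tibble with `sequence` and `count` (see [collapse_tags()]).
#' @param genome Named character vector of genome contigs.
#' @param k Maximum mismatches (default 1).
#' @return List with `tags` (input plus logical `mapped` column), `hits`
#'   (tibble as in [mir_match()]) and `stats` (one-row tibble with
#'   `n_tags`, `n_reads`, `mapped_tags`, `mapped_reads`, `redundant_pct`,
#'   `nonredundant_pct`; percentages are `NA` on empty input).
#' @export
map_to_genome <- function(tags, genome, k = 1) {
  hits <- mir_match(tags$sequence, genome, k = k, strands = c("+", "-"))
  mapped_seqs <- unique(hits$tag)
  tags <- dplyr::mutate(tags, mapped = .data$sequence %in% mapped_seqs)
  n_tags <- nrow(tags)
  n_reads <- sum(tags$count)
  stats <- tibble::tibble(
    n_tags = n_tags, n_reads = n_reads,
    mapped_tags = sum(tags$mapped),
    mapped_reads = sum(tags$count[tags$mapped]),
    redundant_pct = if (n_reads > 0) 100 * sum(tags$count[tags$mapped]) / n_reads else NA_real_,
    nonredundant_pct = if (n_tags > 0) 100 * sum(tags$mapped) / n_tags else NA_real_
  )
  list(tags = tags, hits = hits, stats = stats)
}

#' Assign tags to mature miRNAs
#'
#' A tag is incident to a mature miRNA iff it aligns ungapped, sense strand,
#' over its full length within the mature sequence (the mature may overhang
#' the tag, never the reverse) with at most `k_m` mismatches. Only the
#' minimal-mismatch stratum per tag is kept (perfect hits suppress mismatched
#' ones), and a tag matching `m` distinct miRNAs contributes `count / m` to
#' each.
#'
#' @param tags Tibble with `sequence` and `count`.
#' @param catalog Tibble with `name` and `sequence` columns (mature miRNAs).
#' @param k_m Maximum mismatches (default 2).
#' @return List with `assignments` (tibble `sequence`, `count`, `mirna`,
#'   `mismatches`, `contribution`) and `totals` (tibble `mirna`, `count`
#'   summing contributions; every catalog miRNA appears, absent ones at 0).
#' @export
assign_to_mirbase <- function(tags, catalog, k_m = 2) {
  stopifnot(nrow(catalog) > 0)
  hits <- mir_match(tags$sequence, setNames(catalog$sequence, catalog$name),
                    k = k_m, strands = "+")
  if (nrow(hits) == 0) {
    return(list(
      assignments = tibble::tibble(sequence = character(0),
                                   count = integer(0), mirna = character(0),
                                   mismatches = integer(0),
                                   contribution = numeric(0)),
      totals = tibble::tibble(mirna = catalog$name, count = 0)))
  }
  asn <- hits %>%
    dplyr::distinct(.data$tag, .data$reference, .data$mismatches) %>%
    dplyr::group_by(.data$tag) %>%
    dplyr::filter(.data$mismatches == min(.data$mismatches)) %>%
    dplyr::distinct(.data$tag, .data$reference, .keep_all = TRUE) %>%
    dplyr::mutate(n_mirnas = dplyr::n_distinct(.data$reference)) %>%
    dplyr::ungroup() %>%
    dplyr::rename(sequence = "tag", mirna = "reference") %>%
    dplyr::inner_join(tags[, c("sequence", "count")], by = "sequence") %>%
    dplyr::mutate(contribution = .data$count / .data$n_mirnas) %>%
    dplyr::select("sequence", "count", "mirna", "mismatches", "contribution")
  totals <- asn %>%
    dplyr::group_by(mirna = .data$mirna) %>%
    dplyr::summarise(count = sum(.data$contribution), .groups = "drop") %>%
    tidyr::complete(mirna = catalog$name, fill = list(count = 0)) %>%
    dplyr::arrange(match(.data$mirna, catalog$name))
  list(assignments = asn, totals = totals)
}

#' Count-weighted miRNA incidence among genome-matching reads
#'
#' Fraction (percent) of the genome-matching redundant read count carried by
#' tags assigned to at least one mature miRNA.
#'
#' @param mapped_tags Tibble with `sequence`, `count`, `mapped` (from
#'   [map_to_genome()]).
#' @param assignments Assignment tibble from [assign_to_mirbase()].
#' @return A single percentage (`NA` if no reads map).
#' @export
mirna_incidence <- function(mapped_tags, assignments) {
  mapped <- mapped_tags[mapped_tags$mapped, , drop = FALSE]
  denom <- sum(mapped$count)
  if (denom == 0) return(NA_real_)
  100 * sum(mapped$count[mapped$sequence %in% assignments$sequence]) / denom
}
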