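# miRNA x library count matrix, read-count-per-total normalization to a
# fixed library size, and a replicate-consistency screen of libraries.

#' Assemble the miRNA x library count matrix
#'
#' @param assignment_totals Named list (one entry per library id) of tibbles
#'   with `mirna` and `count` (from [assign_to_mirbase()]'s `totals`).
#' @param sample_sheet Tibble with `library_id` (unique) and `phenotype`.
#' @param mirnas Optional character vector fixing the miRNA universe (absent
#'   miRNA/library pairs become 0); defaults to the union observed.
#' @return Long tibble with `mirna`, `library_id`, `count` covering every
#'   miRNA x library combination.
#' @export
build_matrix <- function(assignment_totals, sample_sheet, mirnas = NULL) {
  if (anyDuplicated(sample_sheet$library_id)) {
    stop("duplicate library ids in sample sheet: ",
         paste(unique(sample_sheet$library_id[
           duplicated(sample_sheet$library_id)]), collapse = ", "))
  }
  missing <- setdiff(sample_sheet$library_id, names(assignment_totals))
  if (length(missing) > 0) {
    stop("no assignments supplied for libraries: ",
         paste(missing, collapse = ", "))
  }
  long <- purrr::imap_dfr(
    assignment_totals[sample_sheet$library_id],
    function(tbl, lib) dplyr::mutate(tbl, library_id = lib, .before = 1)
  )
  if (is.null(mirnas)) mirnas <- unique(long$mirna)
  long %>%
    dplyr::filter(.data$mirna %in% mirnas) %>%
    tidyr::complete(library_id = sample_sheet$library_id, mirna = mirnas,
                    fill = list(count = 0)) %>%
    dplyr::select("mirna", "library_id", "count") %>%
    dplyr::arrange(match(.data$mirna, mirnas),
                   match(.data$library_id, sample_sheet$library_id))
}

#' Choose the normalization total from accepted-read totals
#'
#' The median of the per-library accepted-read totals, rounded up to the
#' nearest million (an even number of libraries takes the mean of the two
#' central values before rounding).
#'
#' @param accepted_totals Positive per-library accepted-read totals.
#' @return The normalization total (a multiple of 1e6).
#' @export
choose_normalization_total <- function(accepted_totals) {
  if (length(accepted_totals) == 0) stop("no accepted-read totals supplied")
  stopifnot(all(accepted_totals > 0))
  ceiling(median(accepted_totals) / 1e6) * 1e6
}

#' Normalize counts by read count per total
#'
#' Scales each library so its accepted-read total becomes `n_norm`:
#' `norm = count * n_norm / accepted_total`. Values are kept real-valued
#' (never rounded).
#'
#' @param counts Long tibble with `mirna`, `library_id`, `count`.
#' @param totals Tibble with `library_id` and `accepted_reads`.
#' @param n_norm Normalization total (default 4 million reads).
#' @return The input tibble with an added `norm_count` column.
#' @export
normalize_per_total <- function(counts, totals, n_norm = 4e6) {
  bad <- totals$library_id[totals$accepted_reads <= 0]
  if (length(bad) > 0) {
    stop("zero accepted-read total for library: ", paste(bad, collapse = ", "))
  }
  missing <- setdiff(unique(counts$library_id), totals$library_id)
  if (length(missing) > 0) {
    stop("no accepted-read total for library: ",
         paste(missing, collapse = ", "))
  }
  counts %>%
    dplyr::left_join(totals[, c("library_id", "accepted_reads")],
                     by = "library_id") %>%
    dplyr::mutate(norm_count = .data$count * n_norm / .data$accepted_reads) %>%
    dplyr::select(-"accepted_reads")
}

#' Screen libraries for replicate consistency after normalization
#'
#' For each library, considers the miRNAs reaching the abundance floor in at
#' least one replicate of its phenotype and scores the fraction whose log2
#' offset fold change against the phenotype's replicate-median profile stays
#' below 1 in magnitude. Libraries scoring under `score_threshold` are
#' flagged excluded. An explicit `exclude` list overrides the scores: exactly
#' the listed libraries are excluded.
#'
#' @param norm_counts Long tibble with `mirna`, `library_id`, `norm_count`.
#' @param sample_sheet Tibble with `library_id` and `phenotype`.
#' @param score_threshold Minimum score to keep a library.
#' @param abundance_floor Normalized-count floor defining scored miRNAs.
#' @param offset OFC offset (see [offset_fold_change()]).
#' @param exclude Optional character vector of library ids to exclude
#'   regardless of score.
#' @return Tibble with `library_id`, `phenotype`, `score`, `excluded`.
#'   Phenotypes with a single replicate get `NA` scores (and a warning).
#' @export
screen_libraries <- function(norm_counts, sample_sheet, score_threshold = 0.8,
                             abundance_floor = 200, offset = 20,
                             exclude = NULL) {
  x <- dplyr::inner_join(norm_counts,
                         sample_sheet[, c("library_id", "phenotype")],
                         by = "library_id")
  singles <- sample_sheet %>%
    dplyr::count(.data$phenotype) %>%
    dplyr::filter(.data$n < 2)
  if (nrow(singles) > 0) {
    warning("phenotype(s) with a single replicate, scores undefined: ",
            paste(singles$phenotype, collapse = ", "))
  }
  scored <- x %>%
    dplyr::group_by(.data$phenotype, .data$mirna) %>%
    dplyr::mutate(ref = median(.data$norm_count),
                  eligible = max(.data$norm_count) >= abundance_floor,
                  n_rep = dplyr::n()) %>%
    dplyr::ungroup() %>%
    dplyr::filter(.data$eligible, .data$n_rep >= 2) %>%
    dplyr::group_by(.data$library_id) %>%
    dplyr::summarise(score = mean(
      abs(offset_fold_change(.data$norm_count, .data$ref, offset)) < 1),
      .groups = "drop")
  out <- sample_sheet %>%
    dplyr::select("library_id", "phenotype") %>%
    dplyr::left_join(scored, by = "library_id") %>%
    dplyr::left_join(dplyr::count(sample_sheet, .data$phenotype),
                     by = "phenotype") %>%
    dplyr::mutate(score = dplyr::if_else(.data$n < 2, NA_real_,
                                         dplyr::coalesce(.data$score, 1)),
                  excluded = if (!is.null(exclude)) {
                    .data$library_id %in% exclude
                  } else {
                    !is.na(.data$score) & .data$score < score_threshold
                  }) %>%
    dplyr::select("library_id", "phenotype", "score", "excluded")
  out
}
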