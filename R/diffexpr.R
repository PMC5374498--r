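# Differential expression by the maximal expression interval approach with a
# log2 offset fold change (OFC) threshold and an abundance floor. A miRNA is
# called DE for a phenotype pair when the [min, max] intervals of its
# normalized counts across the two phenotypes' replicates are disjoint, the
# |log2 OFC| of the phenotype means reaches the threshold, and the larger
# mean clears the abundance floor.

#' Maximal expression interval of replicate values
#'
#' @param values Normalized counts across one phenotype's replicates.
#' @return Named numeric `c(lo = min, hi = max)`.
#' @export
expression_interval <- function(values) {
  if (length(values) == 0) stop("no values: an expression interval needs at least one replicate")
  c(lo = min(values), hi = max(values))
}

#' Log2 offset fold change
#'
#' `log2((a + offset) / (b + offset))`; the offset stabilizes ratios at low
#' counts. Antisymmetric in its arguments. Vectorized.
#'
#' @param a,b Nonnegative expression values.
#' @param offset Positive offset added to both values (default 20).
#' @return Signed log2 offset fold change.
#' @export
offset_fold_change <- function(a, b, offset = 20) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    stop("offset_fold_change requires nonnegative expression values")
  }
  stopifnot(offset > 0)
  log2((a + offset) / (b + offset))
}

#' The default 2x2 comparison design
#'
#' Caste within instar (EW vs EQ, LW vs LQ) and instar within caste
#' (EW vs LW, EQ vs LQ).
#'
#' @return Tibble with `label`, `phenotype_a`, `phenotype_b`.
#' @export
default_comparisons <- function() {
  tibble::tribble(
    ~label,       ~phenotype_a, ~phenotype_b,
    "EW_vs_EQ",   "EW",         "EQ",
    "LW_vs_LQ",   "LW",         "LQ",
    "EW_vs_LW",   "EW",         "LW",
    "EQ_vs_LQ",   "EQ",         "LQ"
  )
}

#' Call differential expression per miRNA per comparison
#'
#' For each comparison, intervals and means are computed over the included
#' (non-excluded) replicate libraries of each phenotype. A miRNA is DE when
#' (a) the two intervals are strictly disjoint, (b) `|ofc| >=
#' ofc_threshold` (inclusive) and (c) the larger phenotype mean is at least
#' `abundance_floor` (inclusive). The `"mean"` OFC variant compares
#' phenotype means; the conservative `"edge"` variant compares the nearest
#' interval edges (0 when intervals overlap).
#'
#' @param norm_counts Long tibble with `mirna`, `library_id`, `norm_count`.
#' @param sample_sheet Tibble with `library_id` and `phenotype`.
#' @param qualities Optional tibble with `library_id` and `excluded` (from
#'   [screen_libraries()]); excluded libraries take no part in any call.
#' @param comparisons Tibble with `label`, `phenotype_a`, `phenotype_b`;
#'   defaults to [default_comparisons()] restricted to phenotypes present.
#' @param ofc_threshold DE threshold on `|ofc|` (default 1).
#' @param abundance_floor Normalized-count floor (default 200 per normalized
#'   library total).
#' @param offset OFC offset (default 20).
#' @param variant `"mean"` or `"edge"` OFC (see above).
#' @return Tibble with one row per miRNA per comparison: `mirna`,
#'   `comparison`, `phenotype_a`, `phenotype_b`, `mean_a`, `mean_b`,
#'   `lo_a`, `hi_a`, `lo_b`, `hi_b`, `ofc`, `fold_change` (`2^|ofc|`),
#'   `intervals_disjoint`, `abundance_pass`, `de`, `direction` (higher
#'   phenotype, `NA` when `ofc` is 0). Comparisons where either phenotype
#'   retains fewer than two included libraries are skipped with a warning.
#' @export
call_de <- function(norm_counts, sample_sheet, qualities = NULL,
                    comparisons = NULL, ofc_threshold = 1,
                    abundance_floor = 200, offset = 20,
                    variant = c("mean", "edge")) {
  variant <- match.arg(variant)
  included <- sample_sheet$library_id
  if (!is.null(qualities)) {
    included <- setdiff(included,
                        qualities$library_id[qualities$excluded])
  }
  if (is.null(comparisons)) {
    comparisons <- dplyr::filter(
      default_comparisons(),
      .data$phenotype_a %in% sample_sheet$phenotype &
        .data$phenotype_b %in% sample_sheet$phenotype)
  }
  x <- norm_counts %>%
    dplyr::filter(.data$library_id %in% included) %>%
    dplyr::inner_join(sample_sheet[, c("library_id", "phenotype")],
                      by = "library_id")
  per_phen <- x %>%
    dplyr::group_by(.data$phenotype, .data$mirna) %>%
    dplyr::summarise(lo = min(.data$norm_count), hi = max(.data$norm_count),
                     mean = mean(.data$norm_count), n_rep = dplyr::n(),
                     .groups = "drop")
  out <- purrr::pmap_dfr(comparisons, function(label, phenotype_a,
                                               phenotype_b, ...) {
    a <- dplyr::filter(per_phen, .data$phenotype == phenotype_a)
    b <- dplyr::filter(per_phen, .data$phenotype == phenotype_b)
    if (nrow(a) == 0 || nrow(b) == 0 || min(a$n_rep) < 2 || min(b$n_rep) < 2) {
      warning("comparison ", label,
              " skipped: fewer than 2 included libraries in a phenotype")
      return(NULL)
    }
    dplyr::inner_join(
      dplyr::select(a, "mirna", lo_a = "lo", hi_a = "hi", mean_a = "mean"),
      dplyr::select(b, "mirna", lo_b = "lo", hi_b = "hi", mean_b = "mean"),
      by = "mirna") %>%
      dplyr::mutate(comparison = label, phenotype_a = phenotype_a,
                    phenotype_b = phenotype_b, .after = "mirna")
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(
      mirna = character(0), comparison = character(0),
      phenotype_a = character(0), phenotype_b = character(0),
      lo_a = numeric(0), hi_a = numeric(0), mean_a = numeric(0),
      lo_b = numeric(0), hi_b = numeric(0), mean_b = numeric(0),
      ofc = numeric(0), fold_change = numeric(0),
      intervals_disjoint = logical(0), abundance_pass = logical(0),
      de = logical(0), direction = character(0)))
  }
  out %>%
    dplyr::mutate(
      intervals_disjoint = .data$hi_a < .data$lo_b | .data$hi_b < .data$lo_a,
      ofc = if (variant == "mean") {
        offset_fold_change(.data$mean_a, .data$mean_b, offset)
      } else {
        dplyr::case_when(
          .data$hi_b < .data$lo_a ~
            offset_fold_change(.data$lo_a, .data$hi_b, offset),
          .data$hi_a < .data$lo_b ~
            offset_fold_change(.data$hi_a, .data$lo_b, offset),
          TRUE ~ 0
        )
      },
      fold_change = 2^abs(.data$ofc),
      abundance_pass = pmax(.data$mean_a, .data$mean_b) >= abundance_floor,
      de = .data$intervals_disjoint & .data$abundance_pass &
        abs(.data$ofc) >= ofc_threshold,
      direction = dplyr::case_when(
        .data$ofc > 0 ~ .data$phenotype_a,
        .data$ofc < 0 ~ .data$phenotype_b,
        TRUE ~ NA_character_
      )
    ) %>%
    dplyr::select("mirna", "comparison", "phenotype_a", "phenotype_b",
                  "mean_a", "mean_b", "lo_a", "hi_a", "lo_b", "hi_b",
                  "ofc", "fold_change", "intervals_disjoint",
                  "abundance_pass", "de", "direction")
}

#' Run all pairwise comparisons and rank the results
#'
#' Calls [call_de()] and returns per-comparison tables ranked by decreasing
#' `|ofc|` (ties broken by miRNA name) plus a cross-comparison DE summary.
#'
#' @inheritParams call_de
#' @return An object of class `mir_de`: a list with `results` (the full
#'   [call_de()] tibble, ranked), `tables` (named list of per-comparison
#'   tibbles), `summary` (DE calls across comparisons) and `params`.
#' @export
run_comparisons <- function(norm_counts, sample_sheet, qualities = NULL,
                            comparisons = NULL, ofc_threshold = 1,
                            abundance_floor = 200, offset = 20,
                            variant = c("mean", "edge")) {
  variant <- match.arg(variant)
  res <- call_de(norm_counts, sample_sheet, qualities, comparisons,
                 ofc_threshold, abundance_floor, offset, variant) %>%
    dplyr::arrange(.data$comparison, dplyr::desc(abs(.data$ofc)),
                   .data$mirna)
  tables <- split(res, res$comparison)
  summary <- res %>%
    dplyr::filter(.data$de) %>%
    dplyr::select("mirna", "comparison", "direction", "ofc", "fold_change") %>%
    dplyr::arrange(.data$comparison, dplyr::desc(abs(.data$ofc)))
  structure(list(results = res, tables = tables, summary = summary,
                 params = list(ofc_threshold = ofc_threshold,
                               abundance_floor = abundance_floor,
                               offset = offset, variant = variant)),
            class = "mir_de")
}

#' @export
print.mir_de <- function(x, ...) {
  cat("<mir_de> ", length(x$tables), " comparison(s), ",
      dplyr::n_distinct(x$results$mirna), " miRNA(s), ",
      nrow(x$summary), " DE call(s)\n", sep = "")
  cat("OFC variant: ", x$params$variant, "; |log2(OFC)| >= ",
      x$params$ofc_threshold, "; abundance floor ",
      x$params$abundance_floor, "; offset ", x$params$offset, "\n",
      sep = "")
  if (nrow(x$summary) > 0) {
    print(x$summary, n = min(nrow(x$summary), 20))
  }
  invisible(x)
}

#' Tidy a `mir_de` object into its ranked result table
#'
#' @param x A `mir_de` object from [run_comparisons()].
#' @param ... Unused.
#' @return The ranked results tibble (one row per miRNA per comparison).
#' @exportS3Method generics::tidy
tidy.mir_de <- function(x, ...) x$results

#' One-row summary of a `mir_de` object
#'
#' @param x A `mir_de` object from [run_comparisons()].
#' @param ... Unused.
#' @return A one-row tibble: number of miRNAs, comparisons, DE calls and
#'   distinct DE miRNAs.
#' @exportS3Method generics::glance
glance.mir_de <- function(x, ...) {
  tibble::tibble(
    n_mirnas = dplyr::n_distinct(x$results$mirna),
    n_comparisons = length(x$tables),
    n_de_calls = nrow(x$summary),
    n_de_mirnas = dplyr::n_distinct(x$summary$mirna)
  )
}
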