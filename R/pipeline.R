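# Pipeline orchestration: a declarative config, file-based stages
# (preprocess -> map -> quantify -> de) that are independently re-runnable
# from a run directory, a manifest with checksums and read accounting, and a
# plain-text report.

config_defaults <- function() {
  list(
    genome = NULL, mirna_fasta = NULL, sample_sheet = NULL,
    out_dir = ".",
    adapter = DEFAULT_ADAPTER_3P, hd_length = 4L, min_overlap = 7L,
    l_min = 16L, k_genome = 1L, k_mirbase = 2L,
    normalization_total = 4e6, offset = 20, ofc_threshold = 1,
    abundance_floor = 200, score_threshold = 0.8, exclude = NULL,
    ofc_variant = "mean", seed = 1L, simulate = NULL
  )
}

#' Build a validated pipeline configuration
#'
#' All analysis parameters default to the values of the reference protocol:
#' 4 HD bases, minimum insert length 16, genome mapping at 1 mismatch,
#' mature-miRNA assignment at 2 mismatches, normalization total 4 million
#' (or `"auto-median"` for the median accepted total rounded up to the
#' nearest million), OFC offset 20, DE threshold `|log2(OFC)| >= 1`,
#' abundance floor 200.
#'
#' @param ... Named configuration values overriding the defaults; unknown
#'   names are an error. Required for a run: `genome` (FASTA),
#'   `mirna_fasta` (mature catalog FASTA), `sample_sheet` (TSV with
#'   `library_id`, `phenotype`, `replicate`, `path`). An optional `simulate`
#'   list (see [simulate_from_config()]) generates these inputs instead.
#' @return A list of class `mircaste_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  defs <- config_defaults()
  unknown <- setdiff(names(over), names(defs))
  if (length(unknown) > 0) {
    stop("unknown configuration parameter(s): ",
         paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defs, over, keep.null = TRUE)
  if (!(identical(cfg$normalization_total, "auto-median") ||
        (is.numeric(cfg$normalization_total) &&
         cfg$normalization_total > 0))) {
    stop("normalization_total must be a positive number or \"auto-median\"")
  }
  stopifnot(cfg$ofc_variant %in% c("mean", "edge"),
            cfg$hd_length >= 0, cfg$l_min >= 1, cfg$min_overlap >= 1,
            cfg$k_genome >= 0, cfg$k_mirbase >= 0, cfg$offset > 0,
            cfg$abundance_floor >= 0)
  structure(cfg, class = "mircaste_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys are [pipeline_config()] parameters. Unknown
#'   keys fail validation before anything runs.
#' @return A `mircaste_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  pipeline_config(yaml::read_yaml(path))
}

#' Generate the synthetic inputs a config's `simulate` block describes
#'
#' The `simulate` list understands: `n_mirnas`, `genome_length`,
#' `phenotypes`, `replicates_per_phenotype`, `depth`, `error_rate`,
#' `junk_fraction`, `dispersion`, and a spike description `spike_n`,
#' `spike_fold`, `spike_comparison`, `spike_up_in` (see [default_spikes()];
#' `spike_n = 0` disables spiking). Reference and libraries are written
#' under `out_dir/sim` and the config paths are pointed at them.
#'
#' @param config A `mircaste_config` with a non-NULL `simulate` entry.
#' @return The config with `genome`, `mirna_fasta` and `sample_sheet`
#'   filled in; the experiment truth tables are written beside the FASTQs.
#' @export
simulate_from_config <- function(config) {
  s <- config$simulate
  if (is.null(s)) stop("config has no `simulate` block")
  get_or <- function(name, default) if (!is.null(s[[name]])) s[[name]] else default
  sim_dir <- file.path(config$out_dir, "sim")
  dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- generate_reference(seed = config$seed,
                            n_mirnas = get_or("n_mirnas", 60),
                            genome_length = get_or("genome_length", 50000))
  genome_path <- file.path(sim_dir, "genome.fa")
  mirna_path <- file.path(sim_dir, "mirna.fa")
  write_fasta_seqs(ref$genome, genome_path)
  write_fasta_seqs(setNames(ref$catalog$sequence, ref$catalog$name),
                   mirna_path)
  spike_n <- get_or("spike_n", 6)
  spikes <- if (spike_n > 0) {
    default_spikes(ref$catalog, n = spike_n,
                   fold = get_or("spike_fold", 16),
                   comparison = get_or("spike_comparison", "LW_vs_LQ"),
                   up_in = get_or("spike_up_in", "LQ"))
  } else NULL
  design <- sim_design(
    ref$catalog,
    phenotypes = get_or("phenotypes", c("EW", "LW", "EQ", "LQ")),
    replicates_per_phenotype = get_or("replicates_per_phenotype", 4),
    spikes = spikes,
    depth = get_or("depth", 500000),
    error_rate = get_or("error_rate", 0.005),
    junk_fraction = get_or("junk_fraction", 0.25),
    dispersion = get_or("dispersion", 0.2),
    seed = config$seed
  )
  make_experiment(design, dir = sim_dir)
  config$genome <- genome_path
  config$mirna_fasta <- mirna_path
  config$sample_sheet <- file.path(sim_dir, "sample_sheet.tsv")
  config
}

read_sheet <- function(config) {
  sheet <- readr::read_tsv(config$sample_sheet, show_col_types = FALSE)
  need <- c("library_id", "phenotype", "replicate", "path")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet ", config$sample_sheet, " must have columns: ",
         paste(need, collapse = ", "))
  }
  # FASTQ paths are taken relative to the sample sheet's directory
  sheet$path <- ifelse(file.exists(sheet$path), sheet$path,
                       file.path(dirname(config$sample_sheet), sheet$path))
  sheet
}

check_inputs <- function(config, sheet) {
  for (f in c(config$genome, config$mirna_fasta, config$sample_sheet,
              sheet$path)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  invisible(TRUE)
}

#' Run the preprocessing stage
#'
#' Cleans every library of the sample sheet and writes collapsed tags
#' (`tags/<library>.fasta`) plus `preprocess_stats.tsv` under `run_dir`.
#'
#' @param config A `mircaste_config`.
#' @param run_dir Run directory.
#' @return The per-library stats tibble, invisibly.
#' @export
stage_preprocess <- function(config, run_dir) {
  sheet <- read_sheet(config)
  dir.create(file.path(run_dir, "tags"), recursive = TRUE,
             showWarnings = FALSE)
  stats <- purrr::map_dfr(seq_len(nrow(sheet)), function(i) {
    pp <- preprocess_library(sheet$path[i], adapter = config$adapter,
                             min_overlap = config$min_overlap,
                             hd_length = config$hd_length,
                             l_min = config$l_min)
    write_tags_fasta(pp$tags, file.path(run_dir, "tags",
                                        paste0(sheet$library_id[i], ".fasta")))
    dplyr::mutate(pp$stats, library_id = sheet$library_id[i], .before = 1)
  })
  readr::write_tsv(stats, file.path(run_dir, "preprocess_stats.tsv"))
  invisible(stats)
}

#' Run the genome-mapping stage
#'
#' Maps each library's tags to the genome (full length, ungapped, at most
#' `k_genome` mismatches, both strands), writing `mapped/<library>.tsv`
#' (tag, count, mapped flag), `hits/<library>.tsv` (per-hit table) and the
#' per-library `mapping_stats.tsv`.
#'
#' @inheritParams stage_preprocess
#' @return The mapping-stats tibble, invisibly.
#' @export
stage_map <- function(config, run_dir) {
  sheet <- read_sheet(config)
  genome <- read_fasta_seqs(config$genome)
  dir.create(file.path(run_dir, "mapped"), showWarnings = FALSE)
  dir.create(file.path(run_dir, "hits"), showWarnings = FALSE)
  stats <- purrr::map_dfr(seq_len(nrow(sheet)), function(i) {
    lib <- sheet$library_id[i]
    tags <- read_tags_fasta(file.path(run_dir, "tags",
                                      paste0(lib, ".fasta")))
    m <- map_to_genome(tags, genome, k = config$k_genome)
    readr::write_tsv(m$tags, file.path(run_dir, "mapped",
                                       paste0(lib, ".tsv")))
    readr::write_tsv(m$hits, file.path(run_dir, "hits",
                                       paste0(lib, ".tsv")))
    dplyr::mutate(m$stats, library_id = lib, .before = 1)
  })
  readr::write_tsv(stats, file.path(run_dir, "mapping_stats.tsv"))
  invisible(stats)
}

#' Run the quantification stage
#'
#' Assigns tags to the mature-miRNA catalog (sense strand, at most
#' `k_mirbase` mismatches, minimal-mismatch stratum, equal split over
#' multi-hits), builds the raw count matrix, normalizes to the configured
#' total, screens libraries and records the per-library miRNA incidence.
#' Writes `counts_raw.tsv`, `counts_norm.tsv` (wide, miRNAs as rows),
#' `library_quality.tsv` and `incidence.tsv`.
#'
#' @inheritParams stage_preprocess
#' @return List with `counts` (long, raw + normalized), `qualities`,
#'   `incidence` and `n_norm`, invisibly.
#' @export
stage_quantify <- function(config, run_dir) {
  sheet <- read_sheet(config)
  cat_seqs <- read_fasta_seqs(config$mirna_fasta)
  catalog <- tibble::tibble(name = names(cat_seqs),
                            sequence = unname(cat_seqs))
  pp_stats <- readr::read_tsv(file.path(run_dir, "preprocess_stats.tsv"),
                              show_col_types = FALSE)
  totals <- vector("list", nrow(sheet))
  incidence <- numeric(nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    lib <- sheet$library_id[i]
    mapped <- readr::read_tsv(file.path(run_dir, "mapped",
                                        paste0(lib, ".tsv")),
                              show_col_types = FALSE)
    asn <- assign_to_mirbase(mapped, catalog, k_m = config$k_mirbase)
    totals[[i]] <- asn$totals
    incidence[i] <- mirna_incidence(mapped, asn$assignments)
  }
  names(totals) <- sheet$library_id
  counts <- build_matrix(totals, sheet, mirnas = catalog$name)
  acc <- dplyr::select(pp_stats, "library_id", "accepted_reads")
  n_norm <- if (identical(config$normalization_total, "auto-median")) {
    choose_normalization_total(acc$accepted_reads)
  } else config$normalization_total
  counts <- normalize_per_total(counts, acc, n_norm)
  qual <- screen_libraries(counts, sheet,
                           score_threshold = config$score_threshold,
                           abundance_floor = config$abundance_floor,
                           offset = config$offset, exclude = config$exclude)
  inc <- tibble::tibble(library_id = sheet$library_id,
                        mirna_incidence_pct = incidence)
  write_wide <- function(value, path) {
    counts %>%
      dplyr::select("mirna", "library_id", dplyr::all_of(value)) %>%
      tidyr::pivot_wider(names_from = "library_id",
                         values_from = dplyr::all_of(value)) %>%
      readr::write_tsv(path)
  }
  write_wide("count", file.path(run_dir, "counts_raw.tsv"))
  write_wide("norm_count", file.path(run_dir, "counts_norm.tsv"))
  readr::write_tsv(qual, file.path(run_dir, "library_quality.tsv"))
  readr::write_tsv(inc, file.path(run_dir, "incidence.tsv"))
  writeLines(format(n_norm, scientific = FALSE),
             file.path(run_dir, "normalization_total.txt"))
  invisible(list(counts = counts, qualities = qual, incidence = inc,
                 n_norm = n_norm))
}

read_wide_counts <- function(path, value_name) {
  readr::read_tsv(path, show_col_types = FALSE) %>%
    tidyr::pivot_longer(-"mirna", names_to = "library_id",
                        values_to = value_name)
}

#' Run the differential-expression stage
#'
#' Runs the 2x2 comparison design on the normalized matrix over the included
#' libraries and writes one ranked table per comparison under `de/` plus a
#' cross-comparison `de_summary.tsv`.
#'
#' @inheritParams stage_preprocess
#' @return The `mir_de` object, invisibly.
#' @export
stage_de <- function(config, run_dir) {
  sheet <- read_sheet(config)
  counts <- read_wide_counts(file.path(run_dir, "counts_norm.tsv"),
                             "norm_count")
  qual <- readr::read_tsv(file.path(run_dir, "library_quality.tsv"),
                          show_col_types = FALSE)
  de <- run_comparisons(counts, sheet, qualities = qual,
                        ofc_threshold = config$ofc_threshold,
                        abundance_floor = config$abundance_floor,
                        offset = config$offset,
                        variant = config$ofc_variant)
  dir.create(file.path(run_dir, "de"), showWarnings = FALSE)
  for (label in names(de$tables)) {
    readr::write_tsv(de$tables[[label]],
                     file.path(run_dir, "de", paste0(label, ".tsv")))
  }
  readr::write_tsv(de$summary, file.path(run_dir, "de_summary.tsv"))
  invisible(de)
}

#' Run the whole pipeline
#'
#' Validates all inputs up front (failing before any stage runs), then runs
#' preprocess, map, quantify and de in order and writes a `manifest.json`
#' with input checksums, effective parameters and per-stage read accounting.
#' Rerunning with an identical config and inputs reproduces identical DE
#' tables.
#'
#' @param config A `mircaste_config` (or path to a YAML config file).
#' @param run_dir Run directory; defaults to a timestamped directory under
#'   the config's `out_dir`.
#' @param stages Stages to run, in pipeline order.
#' @return An object of class `mircaste_run`: list with `run_dir`, `config`
#'   and the `mir_de` object when the de stage ran.
#' @export
run_pipeline <- function(config, run_dir = NULL,
                         stages = c("preprocess", "map", "quantify", "de")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "mircaste_config"),
            all(stages %in% c("preprocess", "map", "quantify", "de")))
  if (!is.null(config$simulate) && is.null(config$genome)) {
    config <- simulate_from_config(config)
  }
  sheet <- read_sheet(config)
  check_inputs(config, sheet)
  if (is.null(run_dir)) {
    run_dir <- file.path(config$out_dir,
                         format(Sys.time(), "run_%Y%m%d_%H%M%S"))
  }
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  de <- NULL
  for (st in intersect(c("preprocess", "map", "quantify", "de"), stages)) {
    message("[mircaste] stage: ", st)
    res <- switch(st,
                  preprocess = stage_preprocess(config, run_dir),
                  map = stage_map(config, run_dir),
                  quantify = stage_quantify(config, run_dir),
                  de = stage_de(config, run_dir))
    if (st == "de") de <- res
  }
  manifest <- list(
    parameters = unclass(config)[setdiff(names(config), "simulate")],
    inputs = as.list(tools::md5sum(c(config$genome, config$mirna_fasta,
                                     config$sample_sheet, sheet$path))),
    stages = stages,
    accounting = tryCatch(
      as.list(colSums(readr::read_tsv(
        file.path(run_dir, "preprocess_stats.tsv"),
        show_col_types = FALSE)[, c("input_reads", "discarded_ambiguous",
                                    "discarded_no_adapter",
                                    "discarded_short", "accepted_reads")])),
      error = function(e) NULL)
  )
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(run_dir = run_dir, config = config, de = de),
            class = "mircaste_run")
}

#' Summarize a completed run as human-readable text
#'
#' Per-library preprocessing and mapping statistics (redundant and
#' non-redundant mapped percentages, miRNA incidence) and the DE summary.
#' Missing stage outputs are reported as explicit gaps rather than errors,
#' but an empty or nonexistent run directory is an error.
#'
#' @param run_dir A run directory from [run_pipeline()].
#' @return The report lines, invisibly; also printed.
#' @export
pipeline_report <- function(run_dir) {
  if (!dir.exists(run_dir) || length(list.files(run_dir)) == 0) {
    stop("not a run directory (missing or empty): ", run_dir)
  }
  lines <- c(paste0("mircaste run report: ", basename(run_dir)), "")
  rd <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) readr::read_tsv(p, show_col_types = FALSE) else NULL
  }
  pp <- rd("preprocess_stats.tsv")
  mp <- rd("mapping_stats.tsv")
  inc <- rd("incidence.tsv")
  if (!is.null(pp) && !is.null(mp)) {
    tab <- dplyr::left_join(pp, mp, by = "library_id")
    if (!is.null(inc)) tab <- dplyr::left_join(tab, inc, by = "library_id")
    lines <- c(lines, paste0("libraries: ", nrow(tab)), "")
    hdr <- sprintf("%-10s %12s %12s %10s %10s %10s",
                   "library", "input", "accepted", "red.map%", "nonred.%",
                   "miRNA%")
    lines <- c(lines, hdr)
    for (i in seq_len(nrow(tab))) {
      lines <- c(lines, sprintf(
        "%-10s %12d %12d %10.1f %10.1f %10.1f",
        tab$library_id[i], tab$input_reads[i], tab$accepted_reads[i],
        tab$redundant_pct[i], tab$nonredundant_pct[i],
        if (!is.null(inc)) tab$mirna_incidence_pct[i] else NA_real_))
    }
  } else {
    lines <- c(lines, "[gap] preprocessing/mapping statistics not available")
  }
  qual <- rd("library_quality.tsv")
  if (!is.null(qual)) {
    lines <- c(lines, "", paste0(
      "excluded libraries: ",
      if (any(qual$excluded)) {
        paste(qual$library_id[qual$excluded], collapse = ", ")
      } else "none"))
  }
  des <- rd("de_summary.tsv")
  de_files <- list.files(file.path(run_dir, "de"), pattern = "\\.tsv$")
  if (!is.null(des)) {
    lines <- c(lines, "",
               paste0("comparisons: ", length(de_files)),
               paste0("DE calls: ", nrow(des)))
    for (i in seq_len(nrow(des))) {
      lines <- c(lines, sprintf("  %-12s %-14s up in %-4s log2(OFC) %6.2f",
                                des$mirna[i], des$comparison[i],
                                des$direction[i], des$ofc[i]))
    }
  } else {
    lines <- c(lines, "", "[gap] differential-expression summary not available")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.mircaste_run <- function(x, ...) {
  cat("<mircaste_run> ", x$run_dir, "\n", sep = "")
  if (!is.null(x$de)) print(x$de)
  invisible(x)
}
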