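# Synthetic small-RNA experiments: a random genome with embedded mature
# miRNAs, and multi-library FASTQ sets with known abundances, spiked fold
# changes, replicate dispersion, sequencing error and non-genomic junk.

# TruSeq small-RNA 3' adapter plus its downstream primer context; simulated
# 50 nt reads with a 16 nt insert and 4 HD bases need >= 30 adapter bases.
SIM_ADAPTER_3P <- "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC"

BASES <- c("A", "C", "G", "T")

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

random_seqs <- function(lengths) {
  if (length(lengths) == 0) return(character(0))
  big <- paste(sample(BASES, sum(lengths), replace = TRUE), collapse = "")
  ends <- cumsum(lengths)
  substring(big, ends - lengths + 1, ends)
}

# TRUE unless an adapter-prefix occurrence starting inside the mature could
# truncate a trimmed insert below the length filter. Trimming also removes
# the hd_length bases before the match, so occurrences at positions up to
# l_min + hd_length are dangerous. An occurrence may be completed past the
# mature's end by the degenerate HD bases (which can take any value) and,
# beyond those, by the adapter itself.
adapter_safe <- function(seq, probe, adapter, hd_length = 4, l_min = 16) {
  l <- nchar(seq)
  np <- nchar(probe)
  for (p in seq(hd_length + 1, min(l_min + hd_length, l))) {
    j <- min(l - p + 1, np)  # probe bases falling inside the mature
    if (substr(seq, p, p + j - 1) != substr(probe, 1, j)) next
    if (j >= np) return(FALSE)
    # the next hd_length probe positions are free (degenerate bases); any
    # remainder must coincide with the adapter start to be reachable
    tail_len <- np - j - hd_length
    if (tail_len <= 0) return(FALSE)
    if (substr(probe, j + hd_length + 1, np) ==
        substr(adapter, 1, tail_len)) return(FALSE)
  }
  TRUE
}

#' Generate a synthetic genome with an embedded mature-miRNA catalog
#'
#' Builds a random background genome and embeds `n_mirnas` random mature
#' miRNA sequences (20-24 nt) at non-overlapping recorded positions, one per
#' equal-width genome bin. Candidate sequences are resampled if they fall
#' within 2 mismatches of an already-accepted catalog entry (full-length
#' ungapped containment, either direction), so every catalog sequence is
#' unambiguously assignable at the pipeline's 2-mismatch bound, or if they
#' carry an internal 3' adapter prefix that trimming could mistake for the
#' real adapter junction and truncate the insert below the length filter.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_mirnas Number of catalog entries.
#' @param genome_length Total genome length (single contig); must be at least
#'   `200 * n_mirnas` so the placement bins fit.
#' @param contig Contig name.
#' @param adapter 3' adapter the simulated reads will carry (used for the
#'   adapter-artifact safety check).
#' @param min_overlap,hd_length,l_min Trimming parameters the safety check
#'   assumes (see [trim_adapter_and_hd()]).
#' @return A list with `genome` (named character vector of length 1) and
#'   `catalog`, a tibble with columns `name`, `sequence`, `contig`, `start`
#'   (0-based) and `strand`.
#' @export
generate_reference <- function(seed = 1, n_mirnas = 60, genome_length = 50000,
                               contig = "contig_1", adapter = SIM_ADAPTER_3P,
                               min_overlap = 7, hd_length = 4, l_min = 16) {
  probe <- substr(adapter, 1, min_overlap)
  stopifnot(n_mirnas >= 0, genome_length >= 1)
  if (n_mirnas > 0 && genome_length < 200 * n_mirnas) {
    stop("impossible packing: genome_length ", genome_length,
         " cannot hold ", n_mirnas, " miRNAs (needs >= ", 200 * n_mirnas, ")")
  }
  with_seed(seed, {
    genome <- random_seqs(genome_length)
    if (n_mirnas == 0) {
      return(list(
        genome = setNames(genome, contig),
        catalog = tibble::tibble(name = character(0), sequence = character(0),
                                 contig = character(0), start = integer(0),
                                 strand = character(0))
      ))
    }
    seqs <- character(n_mirnas)
    for (i in seq_len(n_mirnas)) {
      repeat {
        cand <- random_seqs(sample(20:24, 1))
        if (!adapter_safe(cand, probe, adapter, hd_length, l_min)) next
        prior <- seqs[seq_len(i - 1)][nzchar(seqs[seq_len(i - 1)])]
        if (length(prior) == 0) break
        fwd <- match_tags_cpp(cand, prior, 2L, FALSE)
        rev <- match_tags_cpp(prior, cand, 2L, FALSE)
        if (length(fwd$tag) == 0 && length(rev$tag) == 0) break
      }
      seqs[i] <- cand
    }
    bin <- genome_length %/% n_mirnas
    starts0 <- integer(n_mirnas)
    for (i in seq_len(n_mirnas)) {
      room <- bin - nchar(seqs[i])
      starts0[i] <- (i - 1L) * bin + sample.int(room, 1) - 1L
      substr(genome, starts0[i] + 1L,
             starts0[i] + nchar(seqs[i])) <- seqs[i]
    }
    list(
      genome = setNames(genome, contig),
      catalog = tibble::tibble(
        name = sprintf("mir-%03d", seq_len(n_mirnas)),
        sequence = seqs, contig = contig, start = starts0, strand = "+"
      )
    )
  })
}

#' Describe a simulated small-RNA experiment
#'
#' Captures the experimental design: phenotype groups and replicate counts,
#' per-miRNA baseline abundance weights, spiked fold changes, sequencing
#' depth, error and junk rates, and the read structure (insert + `hd_length`
#' degenerate bases + 3' adapter, truncated to `read_length`).
#'
#' Defaults describe a 4-phenotype (EW/LW/EQ/LQ) x 4-replicate larval
#' experiment: 500,000 reads per library, 0.5% per-base substitution error,
#' 25% non-genomic junk reads, log-normal replicate dispersion 0.2 (sd of the
#' natural-log abundance factor), 4 HD bases and 50 nt reads.
#'
#' @param catalog Catalog tibble from [generate_reference()].
#' @param phenotypes Ordered phenotype labels.
#' @param replicates_per_phenotype Replicates per phenotype.
#' @param base_abundance Positive baseline abundance weights, one per catalog
#'   entry (any scale; normalized internally). Default is a power-law profile
#'   (weight `rank^-1.5`), mimicking the strongly skewed abundance
#'   distribution of real miRNA libraries where a few species dominate.
#' @param spikes Tibble of spiked fold changes with columns `mirna`,
#'   `comparison` (label `"A_vs_B"`), `fold` (linear, >= 1) and `up_in`
#'   (phenotype whose abundance is multiplied); see [default_spikes()].
#' @param depth Reads per library.
#' @param error_rate Per-base substitution probability.
#' @param junk_fraction Proportion of reads drawn from random non-genomic
#'   inserts (length 16-30 nt).
#' @param adapter 3' adapter sequence appended after the HD bases.
#' @param hd_length Number of degenerate (HD) bases between insert and
#'   adapter.
#' @param read_length Fixed sequencer read length.
#' @param dispersion Standard deviation of the per-replicate natural-log
#'   abundance factor.
#' @param seed Integer seed; per-library seeds are derived from it.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(catalog,
                       phenotypes = c("EW", "LW", "EQ", "LQ"),
                       replicates_per_phenotype = 4,
                       base_abundance = NULL,
                       spikes = NULL,
                       depth = 500000,
                       error_rate = 0.005,
                       junk_fraction = 0.25,
                       adapter = SIM_ADAPTER_3P,
                       hd_length = 4,
                       read_length = 50,
                       dispersion = 0.2,
                       seed = 1) {
  stopifnot(is.data.frame(catalog), nrow(catalog) >= 0,
            replicates_per_phenotype >= 1, depth >= 1,
            error_rate >= 0, error_rate < 1,
            junk_fraction >= 0, junk_fraction < 1,
            hd_length >= 0, read_length >= 1, dispersion >= 0)
  if (is.null(base_abundance)) {
    base_abundance <- if (nrow(catalog) > 0) {
      seq_len(nrow(catalog))^-1.5
    } else numeric(0)
  }
  stopifnot(length(base_abundance) == nrow(catalog), all(base_abundance >= 0))
  if (!is.null(spikes)) {
    stopifnot(is.data.frame(spikes),
              all(c("mirna", "comparison", "fold", "up_in") %in% names(spikes)),
              all(spikes$mirna %in% catalog$name),
              all(spikes$up_in %in% phenotypes),
              all(spikes$fold >= 1))
  } else {
    spikes <- tibble::tibble(mirna = character(0), comparison = character(0),
                             fold = numeric(0), up_in = character(0))
  }
  min_insert <- min(c(nchar(catalog$sequence), 16L))
  if (min_insert + hd_length + nchar(adapter) < read_length) {
    stop("adapter too short to fill the read length: insert ", min_insert,
         " + hd ", hd_length, " + adapter ", nchar(adapter), " < ",
         read_length)
  }
  structure(list(
    catalog = catalog, phenotypes = phenotypes,
    replicates_per_phenotype = as.integer(replicates_per_phenotype),
    base_abundance = base_abundance, spikes = spikes,
    depth = as.integer(depth), error_rate = error_rate,
    junk_fraction = junk_fraction, adapter = adapter,
    hd_length = as.integer(hd_length), read_length = as.integer(read_length),
    dispersion = dispersion, seed = as.integer(seed)
  ), class = "sim_design")
}

#' Default spike table for a simulated experiment
#'
#' Picks `n` lower-abundance catalog miRNAs (evenly spaced through the lower
#' abundance stratum, so the added spike mass stays a small fraction of the
#' library and does not compositionally depress the other miRNAs) and spikes
#' each `fold`-fold up in one phenotype of one comparison.
#'
#' @param catalog Catalog tibble.
#' @param n Number of spiked miRNAs.
#' @param fold Linear fold change applied to the `up_in` phenotype.
#' @param comparison Comparison label the spike targets (`"A_vs_B"`).
#' @param up_in Phenotype whose abundance is multiplied.
#' @return Spike tibble suitable for [sim_design()].
#' @export
default_spikes <- function(catalog, n = 6, fold = 16,
                           comparison = "LW_vs_LQ", up_in = "LQ") {
  stopifnot(nrow(catalog) >= n)
  lo <- min(ceiling(0.7 * nrow(catalog)), nrow(catalog) - n + 1)
  hi <- max(nrow(catalog) - 1, lo + n - 1)
  ranks <- unique(round(seq(lo, hi, length.out = n)))
  stopifnot(length(ranks) == n)
  tibble::tibble(mirna = catalog$name[ranks], comparison = comparison,
                 fold = fold, up_in = up_in)
}

# expected per-miRNA abundance weights for one phenotype (spikes applied)
expected_weights <- function(design, phenotype) {
  w <- design$base_abundance
  sp <- design$spikes[design$spikes$up_in == phenotype, ]
  if (nrow(sp) > 0) {
    i <- match(sp$mirna, design$catalog$name)
    w[i] <- w[i] * sp$fold
  }
  w
}

# expected proportion of reads per miRNA in one phenotype's libraries
expected_proportions <- function(design, phenotype) {
  w <- expected_weights(design, phenotype)
  if (length(w) == 0 || sum(w) == 0) return(w)
  (1 - design$junk_fraction) * w / sum(w)
}

library_seed <- function(design, phenotype, replicate) {
  p <- match(phenotype, design$phenotypes)
  (abs(design$seed) + 7919L * (p * 31L + as.integer(replicate))) %% 2147483647L
}

#' Simulate one small-RNA sequencing library
#'
#' Draws per-miRNA read counts from a multinomial around the design's
#' (spiked, log-normally dispersed) expected proportions, assembles each read
#' as insert + HD bases + adapter truncated to the read length, applies
#' per-base substitution errors, and shuffles read order. Output is
#' deterministic for a given design seed, phenotype and replicate.
#'
#' @param catalog Catalog tibble from [generate_reference()].
#' @param design A [sim_design()].
#' @param phenotype Phenotype label (must appear in `design$phenotypes`).
#' @param replicate Replicate index (1-based).
#' @param path Optional FASTQ output path (gzipped if it ends in `.gz`).
#' @return A list with `reads` (tibble `id`, `sequence`), `true_counts`
#'   (tibble `mirna`, `count` of generated reads per miRNA), `junk_count`,
#'   and `path`.
#' @export
simulate_library <- function(catalog, design, phenotype, replicate,
                             path = NULL) {
  stopifnot(phenotype %in% design$phenotypes,
            replicate >= 1, replicate <= design$replicates_per_phenotype)
  n_mir <- nrow(catalog)
  with_seed(library_seed(design, phenotype, replicate), {
    w <- expected_weights(design, phenotype)
    if (design$dispersion > 0 && n_mir > 0) {
      w <- w * exp(rnorm(n_mir, 0, design$dispersion))
    }
    p_insert <- if (n_mir > 0 && sum(w) > 0) {
      (1 - design$junk_fraction) * w / sum(w)
    } else numeric(0)
    probs <- c(p_insert, design$junk_fraction)
    if (sum(probs) == 0) stop("design has no read sources")
    counts <- as.vector(rmultinom(1, design$depth, probs))
    mir_counts <- counts[seq_len(n_mir)]
    junk_count <- counts[n_mir + 1L]

    inserts <- c(rep(catalog$sequence, mir_counts),
                 random_seqs(sample(16:30, junk_count, replace = TRUE)))
    n <- length(inserts)
    hd <- random_seqs(rep(design$hd_length, n))
    reads <- substr(paste0(inserts, hd, design$adapter), 1L,
                    design$read_length)
    if (any(nchar(reads) < design$read_length)) {
      stop("adapter too short to fill the read length")
    }
    if (design$error_rate > 0) {
      reads <- mutate_reads_cpp(reads, design$error_rate)
    }
    ord <- sample.int(n)
    reads <- reads[ord]
    ids <- sprintf("%s%d:%07d", phenotype, replicate, seq_len(n))
    if (!is.null(path)) write_fastq_lines(ids, reads, path)
    list(
      reads = tibble::tibble(id = ids, sequence = reads),
      true_counts = tibble::tibble(mirna = catalog$name, count = mir_counts),
      junk_count = junk_count,
      path = path
    )
  })
}

#' Simulate a full multi-library experiment
#'
#' Writes one FASTQ file per phenotype x replicate library plus a TSV sample
#' sheet, per-library true counts and a spike truth table. Rerunning with the
#' same design produces byte-identical outputs.
#'
#' @param design A [sim_design()].
#' @param dir Output directory (created if needed).
#' @param compress Write gzipped FASTQ files.
#' @return A list with `sample_sheet` (tibble `library_id`, `phenotype`,
#'   `replicate`, `path`), `truth_counts` (tibble `library_id`, `mirna`,
#'   `true_count`), `truth_junk` (tibble `library_id`, `junk_count`),
#'   `truth_de` (tibble `mirna`, `comparison`, `up_in`, `spiked_fold`,
#'   `true_fc`, `true_de` — one row per spiked miRNA per spiked comparison;
#'   `true_fc` is the expected proportion ratio after renormalization), and
#'   `dir`.
#' @export
make_experiment <- function(design, dir = tempfile("mircaste_sim_"),
                            compress = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".fastq.gz" else ".fastq"
  grid <- expand.grid(replicate = seq_len(design$replicates_per_phenotype),
                      phenotype = design$phenotypes,
                      stringsAsFactors = FALSE)[, c("phenotype", "replicate")]
  sheet <- tibble::tibble(
    library_id = paste0(grid$phenotype, grid$replicate),
    phenotype = grid$phenotype,
    replicate = grid$replicate,
    path = file.path(dir, paste0(grid$phenotype, grid$replicate, ext))
  )
  counts <- vector("list", nrow(sheet))
  junk <- integer(nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    lib <- simulate_library(design$catalog, design, sheet$phenotype[i],
                            sheet$replicate[i], path = sheet$path[i])
    counts[[i]] <- dplyr::mutate(lib$true_counts,
                                 library_id = sheet$library_id[i],
                                 .before = 1)
    junk[i] <- lib$junk_count
  }
  truth_counts <- dplyr::bind_rows(counts) %>%
    dplyr::rename(true_count = "count")
  truth_junk <- tibble::tibble(library_id = sheet$library_id,
                               junk_count = junk)
  truth_de <- truth_table(design)
  readr::write_tsv(sheet, file.path(dir, "sample_sheet.tsv"))
  readr::write_tsv(truth_counts, file.path(dir, "truth_counts.tsv"))
  readr::write_tsv(truth_de, file.path(dir, "truth_de.tsv"))
  list(sample_sheet = sheet, truth_counts = truth_counts,
       truth_junk = truth_junk, truth_de = truth_de, dir = dir)
}

# expected fold changes for the spiked (miRNA, comparison) pairs
truth_table <- function(design) {
  sp <- design$spikes
  if (nrow(sp) == 0) {
    return(tibble::tibble(mirna = character(0), comparison = character(0),
                          up_in = character(0), spiked_fold = numeric(0),
                          true_fc = numeric(0), true_de = logical(0)))
  }
  fc <- vapply(seq_len(nrow(sp)), function(i) {
    phens <- strsplit(sp$comparison[i], "_vs_", fixed = TRUE)[[1]]
    stopifnot(length(phens) == 2, sp$up_in[i] %in% phens)
    other <- setdiff(phens, sp$up_in[i])
    j <- match(sp$mirna[i], design$catalog$name)
    expected_proportions(design, sp$up_in[i])[j] /
      expected_proportions(design, other)[j]
  }, numeric(1))
  tibble::tibble(mirna = sp$mirna, comparison = sp$comparison,
                 up_in = sp$up_in, spiked_fold = sp$fold,
                 true_fc = fc, true_de = fc >= 2)
}
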