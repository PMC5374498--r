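# The synthetic-data generator: reference construction, library simulation,
# determinism and count conservation.

test_that("generate_reference embeds every catalog sequence verbatim", {
  ref <- generate_reference(seed = 2, n_mirnas = 10, genome_length = 10000)
  expect_equal(nrow(ref$catalog), 10)
  expect_false(anyDuplicated(ref$catalog$name) > 0)
  for (i in seq_len(10)) {
    sq <- ref$catalog$sequence[i]
    # independent check: exact string search of the genome
    found <- gregexpr(sq, ref$genome[[ref$catalog$contig[i]]],
                      fixed = TRUE)[[1]]
    expect_true((ref$catalog$start[i] + 1L) %in% as.integer(found))
  }
  expect_true(all(nchar(ref$catalog$sequence) >= 16))
})

test_that("generate_reference handles the empty catalog and rejects impossible packing", {
  ref <- generate_reference(seed = 1, n_mirnas = 0, genome_length = 1000)
  expect_equal(nrow(ref$catalog), 0)
  expect_equal(nchar(ref$genome[[1]]), 1000)
  expect_error(generate_reference(seed = 1, n_mirnas = 50,
                                  genome_length = 5000),
               "impossible packing")
})

test_that("generate_reference is deterministic for a seed", {
  a <- generate_reference(seed = 1, n_mirnas = 15, genome_length = 12000)
  b <- generate_reference(seed = 1, n_mirnas = 15, genome_length = 12000)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta_seqs(a$genome, f1); write_fasta_seqs(b$genome, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("catalog sequences are mutually separated beyond the assignment bound", {
  ref <- tiny_reference()
  for (i in seq_len(nrow(ref$catalog))) {
    others <- ref$catalog$sequence[-i]
    h <- mir_match(ref$catalog$sequence[i], setNames(others, seq_along(others)),
                   k = 2, strands = "+")
    expect_equal(nrow(h), 0)
  }
})

test_that("noiseless reads round-trip to catalog sequences and counts conserve depth", {
  ref <- tiny_reference()
  des <- tiny_noiseless_design(ref, depth = 1000)
  lib <- simulate_library(ref$catalog, des, "EW", 1)
  expect_equal(nrow(lib$reads), 1000)
  expect_equal(sum(lib$true_counts$count) + lib$junk_count, 1000)
  # strip adapter + 4 HD bases by construction and compare to the catalog
  naked <- vapply(lib$reads$sequence, function(r) {
    p <- regexpr(substr(des$adapter, 1, 7), substr(r, 5, nchar(r)),
                 fixed = TRUE)
    substr(r, 1, p - 1)
  }, character(1), USE.NAMES = FALSE)
  expect_true(all(naked %in% ref$catalog$sequence))
  tab <- table(naked)
  tc <- lib$true_counts[lib$true_counts$count > 0, ]
  seqs <- ref$catalog$sequence[match(tc$mirna, ref$catalog$name)]
  expect_equal(as.integer(tab[seqs]), tc$count)
})

test_that("simulate_library rejects an adapter too short to fill the read", {
  ref <- tiny_reference()
  expect_error(
    sim_design(ref$catalog, depth = 100, adapter = "TGGAATTCTCGG",
               error_rate = 0, junk_fraction = 0),
    "adapter too short")
})

test_that("spiked true counts scale by the expected fold within sampling error", {
  # one spiked miRNA, dispersion 0, no errors: the count ratio between the
  # two phenotypes is binomial around the expected proportion ratio; assert
  # within 3 delta-method standard deviations
  ref <- generate_reference(seed = 7, n_mirnas = 2, genome_length = 1000)
  spikes <- tibble::tibble(mirna = "mir-002", comparison = "LW_vs_LQ",
                           fold = 16, up_in = "LQ")
  des <- sim_design(ref$catalog, base_abundance = c(1, 1), spikes = spikes,
                    depth = 300000, error_rate = 0, junk_fraction = 0,
                    dispersion = 0, seed = 9)
  up <- simulate_library(ref$catalog, des, "LQ", 1)
  base <- simulate_library(ref$catalog, des, "LW", 1)
  p_up <- mircaste:::expected_proportions(des, "LQ")[2]
  p_base <- mircaste:::expected_proportions(des, "LW")[2]
  true_ratio <- p_up / p_base
  x_up <- up$true_counts$count[2]
  x_base <- base$true_counts$count[2]
  ratio <- x_up / x_base
  # delta method: Var(X/Y) ~ (EX/EY)^2 (CVx^2 + CVy^2) for independent bins
  n <- des$depth
  cv2 <- function(p) (1 - p) / (n * p)
  sd_ratio <- true_ratio * sqrt(cv2(p_up) + cv2(p_base))
  expect_lt(abs(ratio - true_ratio), 3 * sd_ratio)
})

test_that("make_experiment writes one FASTQ per library and is deterministic", {
  ref <- tiny_reference()
  des <- tiny_noiseless_design(ref, depth = 300, replicates = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  e1 <- make_experiment(des, dir = d1)
  e2 <- make_experiment(des, dir = d2)
  expect_equal(nrow(e1$sample_sheet), 4)  # 4 phenotypes x 1 replicate
  expect_true(all(file.exists(e1$sample_sheet$path)))
  expect_equal(e1$truth_de, e2$truth_de)
  expect_equal(e1$truth_counts, e2$truth_counts)
  expect_identical(readBin(e1$sample_sheet$path[1], "raw", 1e7),
                   readBin(e2$sample_sheet$path[1], "raw", 1e7))
  # no spikes -> empty truth table
  expect_equal(nrow(e1$truth_de), 0)
})

test_that("default experiment dimensions follow the 4 x 4 design", {
  ref <- tiny_reference()
  des <- sim_design(ref$catalog, depth = 50, error_rate = 0,
                    junk_fraction = 0, seed = 3)
  d <- withr::local_tempdir()
  e <- make_experiment(des, dir = d, compress = FALSE)
  expect_equal(nrow(e$sample_sheet), 16)
  expect_equal(sort(unique(e$sample_sheet$phenotype)),
               sort(c("EW", "LW", "EQ", "LQ")))
  expect_equal(length(list.files(d, pattern = "\\.fastq$")), 16)
})
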