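# Read cleaning: ambiguous-read exclusion, adapter + HD trimming, length
# filter, tag collapsing and the read-accounting identity.

adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("discard_ambiguous keeps exactly the N-free reads in order", {
  reads <- tibble::tibble(id = c("a", "b", "c"),
                          sequence = c("ACGT", "ACNT", "TTTT"))
  out <- discard_ambiguous(reads)
  expect_equal(out$sequence, c("ACGT", "TTTT"))
  expect_equal(out$id, c("a", "c"))
  all_n <- tibble::tibble(id = "x", sequence = "NNNN")
  expect_equal(nrow(discard_ambiguous(all_n)), 0)
})

test_that("ambiguous discard rate matches the closed-form expectation", {
  withr::local_seed(55)
  len <- 30; p <- 0.02; n <- 20000
  seqs <- rand_seq(n, len)
  # sprinkle Ns independently per base
  mat <- matrix(runif(n * len) < p, nrow = n)
  has_n <- rowSums(mat) > 0
  seqs[has_n] <- vapply(which(has_n), function(i) {
    s <- strsplit(seqs[i], "")[[1]]; s[mat[i, ]] <- "N"
    paste(s, collapse = "")
  }, character(1))
  kept <- discard_ambiguous(tibble::tibble(sequence = seqs))
  frac_discarded <- 1 - nrow(kept) / n
  expected <- 1 - (1 - p)^len
  tol <- 4 * sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac_discarded - expected), tol)
})

test_that("trimming removes the adapter and the HD signature", {
  read <- paste0(strrep("T", 20), "ACGT", "TGGAATTCTCGG")
  expect_equal(trim_adapter_and_hd(read, adapter), strrep("T", 20))
  # tibble interface adds an insert column
  tb <- trim_adapter_and_hd(tibble::tibble(sequence = read), adapter)
  expect_equal(tb$insert, strrep("T", 20))
  # no adapter prefix of sufficient overlap anywhere -> NA
  expect_true(is.na(trim_adapter_and_hd(strrep("A", 40), adapter)))
  # adapter present but with fewer than min_overlap bases -> NA
  tail_only <- paste0(strrep("C", 30), substr(adapter, 1, 5))
  expect_true(is.na(trim_adapter_and_hd(tail_only, adapter)))
  # adapter occurrence leaving no room for the HD bases is not used
  early <- paste0("AC", substr(adapter, 1, 10), strrep("G", 20))
  expect_true(is.na(trim_adapter_and_hd(early, adapter)))
  # leftmost eligible occurrence wins
  twice <- paste0(strrep("T", 16), "ACGT", substr(adapter, 1, 8),
                  "AAAA", substr(adapter, 1, 8))
  expect_equal(trim_adapter_and_hd(twice, adapter), strrep("T", 16))
})

test_that("simulated noiseless reads trim back to their generating catalog sequences", {
  ref <- tiny_reference()
  des <- tiny_noiseless_design(ref, depth = 1000)
  lib <- simulate_library(ref$catalog, des, "LQ", 2)
  inserts <- trim_adapter_and_hd(lib$reads$sequence, des$adapter,
                                 hd_length = des$hd_length)
  expect_false(anyNA(inserts))
  expect_true(all(inserts %in% ref$catalog$sequence))
  # insert is always a prefix of the raw read
  expect_true(all(substr(lib$reads$sequence, 1, nchar(inserts)) == inserts))
})

test_that("length filter boundary is inclusive at the minimum", {
  expect_equal(length_filter(c(strrep("A", 15), strrep("C", 16))),
               strrep("C", 16))
  expect_equal(length_filter(character(0)), character(0))
  mixed <- vapply(10:30, function(l) strrep("A", l), character(1))
  expect_equal(length(length_filter(mixed)), 15)  # lengths 16..30 of 10..30
})

test_that("collapse produces unique tags whose counts sum to the input size", {
  a <- strrep("A", 16); b <- strrep("C", 16)
  out <- collapse_tags(c(a, a, b))
  expect_equal(nrow(out), 2)          # non-redundant
  expect_equal(sum(out$count), 3)     # redundant
  expect_equal(out$count[out$sequence == a], 2)
  # all distinct
  withr::local_seed(77)
  xs <- unique(rand_seq(50, 20))
  out2 <- collapse_tags(xs)
  expect_equal(nrow(out2), length(xs))
  expect_true(all(out2$count == 1))
  # order invariance
  perm <- sample(c(a, a, b))
  expect_equal(collapse_tags(perm), out)
})

test_that("preprocess accounting identity holds and empty inserts count as short", {
  reads <- tibble::tibble(
    id = as.character(1:5),
    sequence = c(
      paste0(strrep("T", 20), "ACGT", substr(adapter, 1, 12)),  # accepted
      paste0(strrep("T", 10), "ACGT", substr(adapter, 1, 12)),  # short (10)
      paste0("ACGT", substr(adapter, 1, 12)),                   # empty insert
      "ACGNACGTACGTACGTACGT",                                   # ambiguous
      strrep("G", 30)                                           # no adapter
    ))
  pp <- preprocess_library(reads, adapter = adapter)
  s <- pp$stats
  expect_equal(s$input_reads, 5)
  expect_equal(s$discarded_ambiguous, 1)
  expect_equal(s$discarded_no_adapter, 1)
  expect_equal(s$discarded_short, 2)
  expect_equal(s$accepted_reads, 1)
  expect_equal(s$input_reads,
               s$discarded_ambiguous + s$discarded_no_adapter +
                 s$discarded_short + s$accepted_reads)
  expect_equal(pp$tags$sequence, strrep("T", 20))
})

test_that("collapsed counts on a noiseless library equal the simulator truth", {
  ref <- tiny_reference()
  des <- tiny_noiseless_design(ref, depth = 1500)
  lib <- simulate_library(ref$catalog, des, "EQ", 1)
  pp <- preprocess_library(lib$reads, adapter = des$adapter)
  expect_equal(pp$stats$accepted_reads, 1500)
  got <- pp$tags[match(ref$catalog$sequence, pp$tags$sequence), ]
  counts <- ifelse(is.na(got$count), 0L, got$count)
  expect_equal(counts, lib$true_counts$count)
})

test_that("tag FASTA round-trips through the count-annotated dialect", {
  tags <- tibble::tibble(sequence = c(strrep("A", 16), strrep("CT", 10)),
                         count = c(12L, 3L))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_tags_fasta(tags, f)
  expect_equal(read_tags_fasta(f), tags)
})
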