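# Independent brute-force oracle for full-length ungapped Hamming matching,
# plus small sequence helpers shared across tests. The oracle deliberately
# shares no code with the package's seed-and-extend matcher: it enumerates
# every window of every reference and counts mismatches on integer-coded
# bases.

rc_base <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

rand_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

brute_match <- function(tags, refs, k, strands = c("+", "-")) {
  ref_names <- names(refs)
  if (is.null(ref_names)) ref_names <- as.character(seq_along(refs))
  rows <- list()
  for (ri in seq_along(refs)) {
    ra <- utf8ToInt(refs[[ri]])
    for (ti in seq_along(tags)) {
      for (strand in strands) {
        s <- if (strand == "+") tags[[ti]] else rc_base(tags[[ti]])
        sa <- utf8ToInt(s)
        L <- length(sa)
        n_off <- length(ra) - L + 1
        if (n_off < 1) next
        win <- matrix(ra[outer(seq_len(n_off) - 1L, seq_len(L), "+")],
                      nrow = n_off)
        mm <- rowSums(win != matrix(sa, nrow = n_off, ncol = L, byrow = TRUE))
        hit <- which(mm <= k)
        if (length(hit) > 0) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            tag = tags[[ti]], reference = ref_names[ri],
            offset = hit - 1L, strand = strand,
            mismatches = as.integer(mm[hit]))
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(tag = character(0), reference = character(0),
                          offset = integer(0), strand = character(0),
                          mismatches = integer(0)))
  }
  dplyr::bind_rows(rows)
}

# canonical ordering so hit tables can be compared with expect_equal
sort_hits <- function(h) {
  h <- dplyr::arrange(h, tag, reference, offset, strand)
  tibble::as_tibble(h[, c("tag", "reference", "offset", "strand",
                          "mismatches")])
}

# a small shared reference + noiseless design used by several test files
tiny_reference <- function(seed = 11, n = 12, len = 6000) {
  generate_reference(seed = seed, n_mirnas = n, genome_length = len)
}

tiny_noiseless_design <- function(ref, depth = 2000, replicates = 2,
                                  spikes = NULL, dispersion = 0) {
  sim_design(ref$catalog, replicates_per_phenotype = replicates,
             depth = depth, error_rate = 0, junk_fraction = 0,
             dispersion = dispersion, spikes = spikes, seed = 5)
}
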