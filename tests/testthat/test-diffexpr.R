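# Interval + OFC differential-expression calling.

# build a long normalized-count tibble from per-phenotype replicate vectors
de_fixture <- function(..., mirna = "m1") {
  groups <- list(...)
  sheet <- purrr::imap_dfr(groups, function(vals, phen) {
    tibble::tibble(library_id = paste0(phen, seq_along(vals)),
                   phenotype = phen, replicate = seq_along(vals))
  })
  counts <- purrr::imap_dfr(groups, function(vals, phen) {
    tibble::tibble(mirna = mirna,
                   library_id = paste0(phen, seq_along(vals)),
                   norm_count = vals)
  })
  list(sheet = sheet, counts = counts)
}

test_that("expression_interval is the replicate min/max, order-invariant", {
  expect_equal(expression_interval(c(260, 300, 280)), c(lo = 260, hi = 300))
  expect_equal(expression_interval(5), c(lo = 5, hi = 5))
  expect_equal(expression_interval(c(300, 260, 280)),
               expression_interval(c(260, 280, 300)))
  expect_error(expression_interval(numeric(0)))
})

test_that("offset fold change identities hold", {
  for (x in c(0, 10, 543.2)) expect_equal(offset_fold_change(x, x), 0)
  expect_equal(offset_fold_change(1000, 50, 20), log2(1020 / 70))
  expect_equal(offset_fold_change(300, 140, 20), 1)
  # antisymmetry on random pairs
  withr::local_seed(41)
  a <- runif(50, 0, 5000); b <- runif(50, 0, 5000)
  expect_equal(offset_fold_change(a, b), -offset_fold_change(b, a))
  # exact invariance under joint scaling of means and offset
  expect_equal(offset_fold_change(2 * 300, 2 * 140, 2 * 20), 1)
  expect_error(offset_fold_change(-1, 5))
  expect_error(offset_fold_change(5, 5, offset = 0))
})

test_that("the full DE criterion matches the worked example", {
  fx <- de_fixture(EW = c(260, 300, 280), EQ = c(30, 40, 50))
  res <- call_de(fx$counts, fx$sheet)
  row <- res[res$comparison == "EW_vs_EQ", ]
  expect_true(row$intervals_disjoint)
  expect_equal(row$mean_a, 280)
  expect_equal(row$mean_b, 40)
  expect_equal(row$ofc, log2(300 / 60))
  expect_equal(row$fold_change, 5)
  expect_true(row$abundance_pass)
  expect_true(row$de)
  expect_equal(row$direction, "EW")
})

test_that("identical replicate sets are never DE; low abundance blocks DE", {
  fx <- de_fixture(EW = c(250, 300), EQ = c(250, 300))
  res <- call_de(fx$counts, fx$sheet)
  expect_false(res$intervals_disjoint)
  expect_equal(res$ofc, 0)
  expect_false(res$de)

  fx2 <- de_fixture(EW = c(100, 120), EQ = c(10, 12))
  res2 <- call_de(fx2$counts, fx2$sheet)
  expect_true(res2$intervals_disjoint)
  expect_equal(res2$ofc, log2(130 / 31))
  expect_true(abs(res2$ofc) >= 1)
  expect_false(res2$abundance_pass)  # max mean 110 < 200
  expect_false(res2$de)
})

test_that("threshold boundaries are inclusive for OFC and abundance, strict for intervals", {
  # OFC exactly 1 counts as DE
  fx <- de_fixture(EW = c(300, 300), EQ = c(140, 140))
  res <- call_de(fx$counts, fx$sheet)
  expect_equal(res$ofc, 1)
  expect_true(res$de)
  # abundance 199.99 fails, 200 passes
  scale <- function(top) de_fixture(EW = c(top, top), EQ = c(1, 1))
  expect_false(call_de(scale(199.99)$counts, scale(199.99)$sheet)$de)
  expect_true(call_de(scale(200)$counts, scale(200)$sheet)$de)
  # touching intervals (hi_b == lo_a) are not disjoint
  fx3 <- de_fixture(EW = c(300, 400), EQ = c(100, 300))
  expect_false(call_de(fx3$counts, fx3$sheet)$intervals_disjoint)
})

test_that("swapping phenotypes negates ofc and flips direction but not the call", {
  fx <- de_fixture(EW = c(260, 300, 280), EQ = c(30, 40, 50))
  fwd <- call_de(fx$counts, fx$sheet)
  swapped <- tibble::tibble(label = "EW_vs_EQ", phenotype_a = "EQ",
                            phenotype_b = "EW")
  rev <- call_de(fx$counts, fx$sheet, comparisons = swapped)
  expect_equal(rev$ofc, -fwd$ofc[fwd$comparison == "EW_vs_EQ"])
  expect_equal(rev$de, fwd$de[fwd$comparison == "EW_vs_EQ"])
  expect_equal(rev$direction, "EW")
})

test_that("raising one phenotype never decreases |ofc| once disjoint", {
  fx <- de_fixture(EW = c(400, 500), EQ = c(50, 60))
  base <- call_de(fx$counts, fx$sheet)
  for (c_mult in c(1.5, 3, 10)) {
    boosted <- fx$counts
    up <- boosted$library_id %in% c("EW1", "EW2")
    boosted$norm_count[up] <- boosted$norm_count[up] * c_mult
    res <- call_de(boosted, fx$sheet)
    expect_gte(abs(res$ofc), abs(base$ofc))
  }
})

test_that("excluded libraries take no part in DE calls", {
  fx <- de_fixture(EW = c(300, 310, 5000), EQ = c(100, 110, 120))
  qual <- tibble::tibble(library_id = "EW3", excluded = TRUE)
  res <- call_de(fx$counts, fx$sheet, qualities = qual)
  expect_equal(res$hi_a, 310)  # the 5000 outlier is gone
  comp_skip <- tibble::tibble(label = "x", phenotype_a = "EW",
                              phenotype_b = "EQ")
  qual2 <- tibble::tibble(library_id = c("EW2", "EW3"),
                          excluded = c(TRUE, TRUE))
  expect_warning(res2 <- call_de(fx$counts, fx$sheet, qualities = qual2,
                                 comparisons = comp_skip), "skipped")
  expect_equal(nrow(res2), 0)
})

test_that("the edge OFC variant uses nearest interval edges and zero on overlap", {
  fx <- de_fixture(EW = c(260, 300, 280), EQ = c(30, 40, 50))
  res <- call_de(fx$counts, fx$sheet, variant = "edge")
  row <- res[res$comparison == "EW_vs_EQ", ]
  expect_equal(row$ofc, log2((260 + 20) / (50 + 20)))
  fx2 <- de_fixture(EW = c(100, 300), EQ = c(200, 400))
  expect_equal(call_de(fx2$counts, fx2$sheet, variant = "edge")$ofc, 0)
})

test_that("run_comparisons ranks by |ofc|, produces one table per comparison and tidies", {
  withr::local_seed(61)
  phens <- c("EW", "LW", "EQ", "LQ")
  sheet <- tidyr::expand_grid(phenotype = phens, replicate = 1:2) %>%
    dplyr::mutate(library_id = paste0(phenotype, replicate))
  counts <- tidyr::expand_grid(mirna = paste0("m", 1:6),
                               library_id = sheet$library_id) %>%
    dplyr::mutate(norm_count = runif(dplyr::n(), 100, 5000))
  de <- run_comparisons(counts, sheet)
  expect_s3_class(de, "mir_de")
  expect_equal(sort(names(de$tables)),
               sort(default_comparisons()$label))
  for (tb in de$tables) {
    expect_false(is.unsorted(rev(abs(tb$ofc))))
  }
  expect_equal(tidy(de), de$results)
  g <- glance(de)
  expect_equal(g$n_mirnas, 6)
  expect_equal(g$n_comparisons, 4)
  # empty matrix -> empty tables
  empty <- suppressWarnings(run_comparisons(counts[0, ], sheet))
  expect_equal(nrow(tidy(empty)), 0)
})

test_that("autoplot returns a ggplot without error", {
  fx <- de_fixture(EW = c(260, 300), EQ = c(30, 40))
  de <- run_comparisons(fx$counts, fx$sheet)
  p <- ggplot2::autoplot(de)
  expect_s3_class(p, "ggplot")
  p2 <- plot_expression_intervals(fx$counts, fx$sheet)
  expect_s3_class(p2, "ggplot")
})
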