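# Allele-count algebra and Fisher exact burden testing.

test_that("cohort subtraction is elementwise with absent ids as zero", {
  d <- subtract_counts(counts_df("v1", 5, 100, "general"),
                       counts_df("v1", 3, 60, "non-cancer"))
  expect_equal(d$ac, 2L)
  expect_equal(d$an, 40L)
  expect_equal(d$cohort, "general - non-cancer")
  # the single-carrier derivation: one allele in the cancer subset survives
  d2 <- subtract_counts(counts_df("v2", 1, 14000), counts_df("v9", 0, 1000))
  expect_equal(d2$ac, 1L)
  expect_equal(d2$an, 14000L)
  expect_error(subtract_counts(counts_df("v1", 3, 100),
                               counts_df("v1", 4, 60)),
               "v1", class = "varcoseg_data_error")
  expect_warning(
    d3 <- subtract_counts(counts_df("v1", 3, 100), counts_df("v1", 4, 60),
                          clamp = TRUE), "clamped")
  expect_equal(d3$ac, 0L)
})

test_that("subtract then add back restores the minuend exactly", {
  set.seed(31)
  n <- 200
  ids <- sprintf("1:%d:A:G", seq_len(n))
  an_sub <- sample(50:100, n, TRUE)
  ac_sub <- rbinom(n, an_sub, 0.1)
  an_min <- an_sub + sample(10:50, n, TRUE)
  ac_min <- ac_sub + rbinom(n, an_min - an_sub, 0.1)
  minuend <- counts_df(ids, ac_min, an_min, "general")
  subtrahend <- counts_df(ids, ac_sub, an_sub, "non-cancer")
  d <- subtract_counts(minuend, subtrahend)
  expect_equal(d$ac + subtrahend$ac, minuend$ac)
  expect_equal(d$an + subtrahend$an, minuend$an)
})

test_that("derived germline subset equals the row-wise oracle", {
  set.seed(41)
  n <- 100
  ids <- sprintf("2:%d:C:T", seq_len(n))
  ac_comp <- rpois(n, 1)
  extra <- rpois(n, 0.7)
  full <- counts_df(ids, ac_comp + extra, 5000, "full")
  # drop some ids from the complement entirely
  keep <- runif(n) < 0.8
  complement <- counts_df(ids[keep], ac_comp[keep], 4000, "complement")
  got <- derive_germline_subset(full, complement)
  oracle <- ids[ifelse(keep, extra, ac_comp + extra) > 0]
  expect_setequal(got, oracle)
  # boundary cases
  expect_length(derive_germline_subset(counts_df("v", 2, 10),
                                       counts_df("v", 2, 10)), 0)
  expect_equal(derive_germline_subset(counts_df("v", 1, 10),
                                      counts_df("w", 0, 10)), "v")
})

test_that("quality filter keeps variants passing in every source present", {
  rows <- data.frame(
    variant_id = c("v1", "v1", "v2", "v2", "v3"),
    cohort = "x",
    ac = 1L, an = 10L,
    filter_status = c("pass", "pass", "pass", "non-pass", "pass"),
    stringsAsFactors = FALSE)
  kept <- quality_filter(rows)
  expect_setequal(unique(kept$variant_id), c("v1", "v3"))
})

test_that("Fisher p matches the enumeration oracle on hand cases", {
  expect_equal(fisher_exact_2x2(0, 10, 0, 10)$p, 1)
  # a single carrier in a ~7000-sample cancer cohort versus none in ~60000
  # controls (allele-level scale)
  got <- fisher_exact_2x2(1, 6999, 0, 60000)
  expect_equal(got$p, fisher_oracle(1, 6999, 0, 60000), tolerance = 1e-12)
  expect_identical(got$odds_ratio, Inf)
  expect_equal(fisher_exact_2x2(5, 5, 1, 9)$p, fisher_oracle(5, 5, 1, 9),
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), class = "varcoseg_data_error")
})

test_that("Fisher p agrees with stats::fisher.test and is swap-symmetric", {
  set.seed(17)
  for (i in 1:200) {
    tb <- sample(0:25, 4, TRUE)
    p <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])$p
    pref <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value
    expect_equal(p, min(1, pref), tolerance = 1e-9)
    # simultaneous row and column swap preserves p
    p_sw <- fisher_exact_2x2(tb[4], tb[3], tb[2], tb[1])$p
    expect_equal(p, p_sw, tolerance = 1e-12)
  }
})

test_that("gene burden aggregates carriers and a conservative allele number", {
  ta <- counts_df(c("v1", "v2"), c(1, 2), c(100, 90), "cancer")
  tb <- counts_df(c("v1", "v2"), c(0, 1), c(500, 400), "control")
  br <- gene_burden(c("v1", "v2"), ta, tb, gene = "G")
  expect_equal(unname(br$table[1, ]), c(3L, 97L))
  expect_equal(unname(br$table[2, ]), c(1L, 499L))
  # single-variant gene reduces to the per-variant Fisher test
  br1 <- gene_burden("v1", ta, tb)
  expect_equal(br1$p, fisher_exact_2x2(1, 99, 0, 500)$p)
  # empty gene
  br0 <- gene_burden(character(), ta, tb)
  expect_equal(br0$p, 1)
  expect_true(all(br0$table == 0L))
  # carriers exceeding trials is a data inconsistency
  bad <- counts_df(c("v1", "v2"), c(3, 2), c(3, 2), "x")
  expect_error(gene_burden(c("v1", "v2"), bad, tb),
               class = "varcoseg_data_error")
})

test_that("burden scan reports BH-adjusted q-values ordered by p", {
  set.seed(8)
  ids <- sprintf("3:%d:A:C", 1:30)
  gm <- data.frame(variant_id = ids, gene = rep(sprintf("G%d", 1:10), 3),
                   stringsAsFactors = FALSE)
  ta <- counts_df(ids, rbinom(30, 50, 0.2), 1000)
  tb <- counts_df(ids, rbinom(30, 50, 0.1), 2000)
  out <- burden_scan(gm, ta, tb)
  expect_equal(out$q, stats::p.adjust(out$p, method = "BH"))
  expect_false(is.unsorted(out$p))
})
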