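# Variant data model: normalization, VCF round trips, hard filtering,
# pedigree reading.

test_that("allele normalization trims suffix then prefix with anchor base", {
  v <- normalize_variant(list(chrom = "1", pos = 100, ref = "CT", alt = "CA"))
  expect_equal(v[c("pos", "ref", "alt")], list(pos = 101L, ref = "T", alt = "A"))
  snv <- normalize_variant(list(chrom = "1", pos = 100, ref = "A", alt = "G"))
  expect_equal(snv$variant_id, "1:100:A:G")
  indel <- normalize_variant(list(chrom = "1", pos = 100, ref = "GCC", alt = "GC"))
  expect_equal(indel[c("pos", "ref", "alt")],
               list(pos = 100L, ref = "GC", alt = "G"))
  expect_error(normalize_variant(list(chrom = "1", pos = 1, ref = "", alt = "A")),
               class = "varcoseg_data_error")
})

test_that("normalization is idempotent on random indels", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    ref <- paste(sample(bases, sample(1:6, 1), TRUE), collapse = "")
    alt <- paste(sample(bases, sample(1:6, 1), TRUE), collapse = "")
    if (ref == alt) next
    v1 <- normalize_variant(list(chrom = "2", pos = 500, ref = ref, alt = alt))
    v2 <- normalize_variant(v1)
    expect_identical(v1[c("pos", "ref", "alt")], v2[c("pos", "ref", "alt")])
  }
})

test_that("multi-allelic records decompose into per-alt het calls", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    "1\t100\t.\tA\tG,T\t50\tPASS\t.\tGT\t1/2"), f)
  got <- read_vcf_calls(f)
  expect_equal(got$variants$variant_id, c("1:100:A:G", "1:100:A:T"))
  expect_equal(got$calls$gt, c("het", "het"))
})

test_that("empty VCF body reads as empty tables", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t")), f)
  got <- read_vcf_calls(f)
  expect_equal(nrow(got$variants), 0L)
  expect_equal(nrow(got$calls), 0L)
})

test_that("write -> read round trip preserves canonical ids and genotypes", {
  cfg <- sim_config(seed = 3, n_background_variants = 50,
                    n_planted_shared = 2,
                    pedigree_layout = data.frame(pedigree_id = "P1",
                                                 n_affected = 1L,
                                                 kinship = 0.25))
  b <- simulate_pedigree_dataset(cfg)
  sid <- names(b$samples)[1]
  f <- tempfile(fileext = ".vcf")
  write_sample_vcf(b$variants, b$samples[[sid]], sid, f)
  got <- read_vcf_calls(f)
  expect_setequal(got$variants$variant_id, b$samples[[sid]]$variant_id)
  m <- match(got$calls$variant_id, b$samples[[sid]]$variant_id)
  expect_equal(got$calls$gt, b$samples[[sid]]$gt[m])
})

test_that("malformed VCF rows raise parse errors with a line number", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    "1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/1",
    "1\t101\t.\tA"), f)
  expect_error(read_vcf_calls(f), "line 4", class = "varcoseg_parse_error")
})

test_that("hard filter lists every violated threshold and passes boundaries", {
  calls <- data.frame(gt = "het", dp = 3L, gq = 50L)
  v <- list(qual = 29.9)
  r <- hard_filter(v, calls, filter_thresholds(min_depth = 8, min_qual = 30))
  expect_false(r$pass)
  expect_setequal(r$reasons, c("min_depth", "min_qual"))
  # >= passes: value exactly at the threshold
  r2 <- hard_filter(list(qual = 30), data.frame(gt = "het", dp = 8L, gq = 0L),
                    filter_thresholds(min_depth = 8, min_qual = 30))
  expect_true(r2$pass)
  # vacuous filter
  r3 <- hard_filter(v, calls, filter_thresholds())
  expect_true(r3$pass)
  # missing genotype carries no depth requirement
  r4 <- hard_filter(list(qual = 99),
                    data.frame(gt = "missing", dp = 0L, gq = 0L),
                    filter_thresholds(min_depth = 8, min_gq = 20))
  expect_true(r4$pass)
  expect_error(
    hard_filter(list(qual = 50), calls,
                filter_thresholds(site_rules = list(
                  list(field = "QD", op = ">=", value = 2)))),
    class = "varcoseg_config_error")
})

test_that("hard filter is monotone in its thresholds", {
  set.seed(5)
  for (i in 1:50) {
    v <- list(qual = runif(1, 0, 60))
    calls <- data.frame(gt = "het", dp = sample(0:40, 1), gq = sample(0:99, 1))
    lo <- filter_thresholds(sample(0:20, 1), sample(0:50, 1), runif(1, 0, 40))
    hi <- filter_thresholds(lo$min_depth + sample(0:10, 1),
                            lo$min_gq + sample(0:10, 1),
                            lo$min_qual + runif(1, 0, 10))
    if (!hard_filter(v, calls, lo)$pass)
      expect_false(hard_filter(v, calls, hi)$pass)
  }
})

test_that("vectorized table filter agrees with the per-variant filter", {
  cfg <- sim_config(seed = 9, n_background_variants = 80,
                    pedigree_layout = data.frame(pedigree_id = "P1",
                                                 n_affected = 2L,
                                                 kinship = 0.25))
  b <- simulate_pedigree_dataset(cfg)
  calls <- do.call(rbind, unname(b$samples))
  calls$variant_id <- as.character(calls$variant_id)
  thr <- filter_thresholds(min_depth = 55, min_gq = 65, min_qual = 200)
  tab <- varcoseg:::hard_filter_table(b$variants, calls, thr)
  for (i in seq_len(nrow(b$variants))) {
    one <- hard_filter(b$variants[i, ],
                       calls[calls$variant_id == b$variants$variant_id[i], ],
                       thr)
    expect_equal(tab$pass[i], one$pass)
    expect_setequal(as.character(unlist(tab$reasons[i])), one$reasons)
  }
})

test_that("pedigree reading keeps affected sequenced samples and kinship", {
  ped <- tempfile(); kin <- tempfile()
  writeLines(c("F2887\tF2887_S1\t0\t0\t2\t2",
               "F2887\tF2887_S2\t0\t0\t2\t2",
               "F2887\tF2887_U1\t0\t0\t1\t1"), ped)
  writeLines(c("pedigree_id\tkinship", "F2887\t0.03"), kin)
  got <- read_pedigree(ped, kin, vcf_samples = c("F2887_S1", "F2887_S2"))
  expect_equal(nrow(got), 2L)
  expect_equal(unique(got$pedigree_id), "F2887")
  expect_equal(unique(got$kinship), 0.03)
  # unaffected-only file yields no pedigrees
  writeLines("F1\tA\t0\t0\t2\t1", ped)
  writeLines(c("pedigree_id\tkinship", "F1\t0.1"), kin)
  expect_equal(nrow(read_pedigree(ped, kin)), 0L)
  # duplicates and unknown VCF samples are errors
  writeLines(c("F1\tA\t0\t0\t2\t2", "F1\tA\t0\t0\t2\t2"), ped)
  expect_error(read_pedigree(ped, kin), class = "varcoseg_data_error")
  writeLines("F1\tA\t0\t0\t2\t2", ped)
  expect_error(read_pedigree(ped, kin, vcf_samples = "B"),
               class = "varcoseg_data_error")
})
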