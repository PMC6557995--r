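# Synthetic-data generators: determinism, planted structure, conservation.

pair_layout <- data.frame(pedigree_id = "P1", n_affected = 2L, kinship = 0.25)

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(planted_af_max = 2), "planted_af_max",
               class = "varcoseg_config_error")
  expect_error(sim_config(hotspot_positions = 400, pssm_length = 377),
               "hotspot_positions", class = "varcoseg_config_error")
  expect_error(sim_config(cohort_sizes = c(general = 100, `non-cancer` = 200,
                                           control = 10, full = 100,
                                           complement = 50)),
               "cohort_sizes", class = "varcoseg_config_error")
  expect_error(sim_config(enrichment_odds = 0), "enrichment_odds",
               class = "varcoseg_config_error")
})

test_that("pedigree generator plants het rare non-silent variants in every affected", {
  cfg <- sim_config(seed = 21, n_background_variants = 400,
                    n_planted_shared = 3, pedigree_layout = pair_layout)
  b <- simulate_pedigree_dataset(cfg)
  expect_equal(nrow(b$truth$planted), 3L)
  ann <- b$annotation[match(b$truth$planted$variant_id,
                            b$annotation$variant_id), ]
  expect_true(all(ann$consequence %in%
                  c("missense", "frameshift", "stopgain", "splicing")))
  expect_true(all(ann$af_control <= cfg$planted_af_max))
  for (sid in names(b$samples)) {
    gt <- b$samples[[sid]]$gt[match(b$truth$planted$variant_id,
                                    b$samples[[sid]]$variant_id)]
    expect_true(all(gt == "het"))
  }
})

test_that("nothing planted when n_planted_shared is zero; single-sample sharing is presence", {
  cfg0 <- sim_config(seed = 4, n_background_variants = 100,
                     n_planted_shared = 0, pedigree_layout = pair_layout)
  expect_length(simulate_pedigree_dataset(cfg0)$truth$planted_shared_variant_ids, 0)
  cfg1 <- sim_config(seed = 4, n_background_variants = 100,
                     n_planted_shared = 3,
                     pedigree_layout = data.frame(pedigree_id = "P1",
                                                  n_affected = 1L,
                                                  kinship = 0.25))
  b <- simulate_pedigree_dataset(cfg1)
  sid <- names(b$samples)[1]
  expect_true(all(b$truth$planted$variant_id %in%
                  b$samples[[sid]]$variant_id))
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 77, n_background_variants = 200,
                    pedigree_layout = pair_layout)
  b1 <- simulate_pedigree_dataset(cfg)
  b2 <- simulate_pedigree_dataset(cfg)
  expect_identical(b1$variants, b2$variants)
  expect_identical(b1$samples, b2$samples)
  expect_identical(simulate_cohort_counts(cfg)$ac,
                   simulate_cohort_counts(cfg)$ac)
  p1 <- simulate_pssm(40, 0.5, seed = 5)
  p2 <- simulate_pssm(40, 0.5, seed = 5)
  expect_identical(p1$scores, p2$scores)
  f1 <- tempfile(); f2 <- tempfile()
  write_pssm_ascii(p1, f1); write_pssm_ascii(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("shared rare non-silent variants equal the intersection oracle", {
  cfg <- sim_config(seed = 7, n_background_variants = 1000,
                    n_planted_shared = 5, pedigree_layout = pair_layout)
  b <- simulate_pedigree_dataset(cfg)
  members <- b$pedigrees$sample_id
  oracle <- intersection_oracle(b$samples, members)
  planted <- sort(b$truth$planted$variant_id)
  collisions <- sort(b$truth$shared_background$variant_id)
  expect_setequal(oracle, union(planted, collisions))
  expect_true(all(planted %in% oracle))
})

test_that("cohort counts obey the construction identity and echo configured AN", {
  cfg <- sim_config(seed = 12,
                    cohort_sizes = c(general = 100, `non-cancer` = 60,
                                     control = 80, full = 100,
                                     complement = 60))
  tab <- simulate_cohort_counts(cfg)
  by <- split(tab, tab$cohort)
  expect_true(all(by$general$an == 100))
  expect_true(all(by$`non-cancer`$an == 60))
  latent <- attr(tab, "latent_cancer")
  m <- match(by$general$variant_id, latent$variant_id)
  expect_equal(by$general$ac, by$`non-cancer`$ac + latent$ac[m])
  expect_true(all(tab$ac >= 0 & tab$ac <= tab$an))
})

test_that("enrichment odds of 1 leaves cancer and non-cancer frequencies equal", {
  ann <- data.frame(variant_id = sprintf("1:%d:A:G", 1:40),
                    gene = rep(c("NCK1", "OTHER"), each = 20),
                    af_control = 0.005, stringsAsFactors = FALSE)
  ac_cancer <- 0; an_cancer <- 0; ac_nc <- 0; an_nc <- 0
  for (s in 1:200) {
    cfg <- sim_config(seed = s, enrichment_odds = 1,
                      cohort_sizes = c(general = 3000, `non-cancer` = 2000,
                                       control = 1000, full = 1000,
                                       complement = 800))
    tab <- simulate_cohort_counts(cfg, annotation = ann)
    latent <- attr(tab, "latent_cancer")
    nck <- latent$variant_id %in% ann$variant_id[ann$gene == "NCK1"]
    ac_cancer <- ac_cancer + sum(latent$ac[nck])
    an_cancer <- an_cancer + sum(latent$an[nck])
    nc <- tab[tab$cohort == "non-cancer", ]
    nckn <- nc$variant_id %in% ann$variant_id[ann$gene == "NCK1"]
    ac_nc <- ac_nc + sum(nc$ac[nckn])
    an_nc <- an_nc + sum(nc$an[nckn])
  }
  # both pooled estimates are binomial draws at the same frequency
  p_hat <- (ac_cancer + ac_nc) / (an_cancer + an_nc)
  se <- sqrt(p_hat * (1 - p_hat) * (1 / an_cancer + 1 / an_nc))
  expect_lt(abs(ac_cancer / an_cancer - ac_nc / an_nc), 3 * se)
})

test_that("simulated PSSM has wild-type maxima at conserved positions and round-trips", {
  m <- simulate_pssm(30, conserved_fraction = 1, seed = 8)
  wt_idx <- match(m$wild_type, varcoseg:::AA_ALPHABET)
  for (i in seq_len(m$length))
    expect_equal(unname(which.max(m$scores[i, ])), wt_idx[i])
  f <- tempfile()
  write_pssm_ascii(m, f)
  m2 <- parse_pssm_ascii(f)
  expect_identical(m2$scores, m$scores)
  expect_identical(m2$wild_type, m$wild_type)
  expect_error(simulate_pssm(0), class = "varcoseg_config_error")
})

test_that("somatic spectrum conserves counts and honors hotspot mass", {
  sp <- simulate_somatic_spectrum(100, 250, hotspots = c(10, 42),
                                  hotspot_mass = 0.4, seed = 6)
  expect_equal(sum(sp$missense_counts), 250L)
  expect_equal(sp$n_nonsilent, 250L)
  sp0 <- simulate_somatic_spectrum(50, 0, seed = 1)
  expect_true(all(sp0$missense_counts == 0L))
  expect_error(simulate_somatic_spectrum(50, 10, hotspots = 5,
                                         hotspot_mass = 1.2),
               class = "varcoseg_config_error")
})

test_that("hotspot-free spectra are uniform multinomials (chi-square sweep)", {
  fails <- 0L
  for (s in 1:100) {
    sp <- simulate_somatic_spectrum(20, 200, seed = s)
    p <- suppressWarnings(
      stats::chisq.test(sp$missense_counts, p = rep(1 / 20, 20))$p.value)
    if (p < 0.01) fails <- fails + 1L
  }
  expect_lte(fails, 5L)
})

test_that("somatic TSV round trip reproduces the spectrum", {
  m <- simulate_pssm(60, 0.5, seed = 2)
  sp <- simulate_somatic_spectrum(60, 80, hotspots = 7, hotspot_mass = 0.3,
                                  seed = 3, n_truncating = 10)
  f <- tempfile()
  set.seed(1)
  write_somatic_tsv(sp, f, pssm = m)
  muts <- read_somatic_tsv(f)
  sp2 <- spectrum_from_mutations(muts, 60,
                                 type_totals = stats::setNames(
                                   sp$per_cancer_type$total,
                                   sp$per_cancer_type$cancer_type))
  expect_equal(sp2$missense_counts, sp$missense_counts)
  expect_equal(sp2$truncating_count, sp$truncating_count)
  expect_equal(sp2$per_cancer_type$mutated[
    order(sp2$per_cancer_type$cancer_type)],
    sp$per_cancer_type$mutated[order(sp$per_cancer_type$cancer_type)])
})
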