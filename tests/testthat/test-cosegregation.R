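# Co-segregation filtering, the germline co-occurrence check, and the
# ACMG-style evidence/verdict machinery.

two_sample_calls <- function(a, b) {
  list(A = data.frame(variant_id = names(a), gt = unname(a),
                      stringsAsFactors = FALSE),
       B = data.frame(variant_id = names(b), gt = unname(b),
                      stringsAsFactors = FALSE))
}

test_that("sharing requires carrier status in every affected sample", {
  s <- two_sample_calls(c(v1 = "het", v2 = "het", v3 = "hom_alt"),
                        c(v2 = "het", v3 = "het", v4 = "het"))
  expect_setequal(shared_candidates(s, c("A", "B")), c("v2", "v3"))
  # absence and hom-ref both exclude
  s2 <- two_sample_calls(c(v1 = "het"), c(v1 = "hom_ref"))
  expect_length(shared_candidates(s2, c("A", "B")), 0)
  # missing excludes by default, counts as carrier only when relaxed
  s3 <- two_sample_calls(c(v1 = "het"), c(v1 = "missing"))
  expect_length(shared_candidates(s3, c("A", "B")), 0)
  expect_equal(shared_candidates(s3, c("A", "B"),
                                 missing_as_carrier = TRUE), "v1")
  expect_error(shared_candidates(s3, c("A", "C")),
               class = "varcoseg_data_error")
})

test_that("shared candidates equal the brute-force intersection oracle", {
  cfg <- sim_config(seed = 19, n_background_variants = 1000,
                    n_planted_shared = 5,
                    pedigree_layout = data.frame(pedigree_id = "P1",
                                                 n_affected = 2L,
                                                 kinship = 0.0625))
  b <- simulate_pedigree_dataset(cfg)
  members <- b$pedigrees$sample_id
  expect_identical(shared_candidates(b$samples, members),
                   intersection_oracle(b$samples, members))
})

test_that("rare non-silent filter applies consequence and frequency rules", {
  ann <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4"),
    consequence = c("synonymous", "missense", "missense", "frameshift"),
    af_control = c(0, NA, 0.002, 0.0005),
    stringsAsFactors = FALSE)
  r <- filter_rare_nonsilent(c("v1", "v2", "v3", "v4", "v5"), ann,
                             af_max = 0.001)
  expect_setequal(r$kept, c("v2", "v4"))
  expect_equal(r$rejected$reason[r$rejected$variant_id == "v1"], "silent")
  expect_equal(r$rejected$reason[r$rejected$variant_id == "v3"], "common")
  expect_equal(r$rejected$reason[r$rejected$variant_id == "v5"],
               "unannotated")
})

test_that("filters commute: any order yields the same candidate set", {
  cfg <- sim_config(seed = 23, n_background_variants = 600,
                    n_planted_shared = 2,
                    pedigree_layout = data.frame(pedigree_id = "P1",
                                                 n_affected = 2L,
                                                 kinship = 0.25))
  b <- simulate_pedigree_dataset(cfg)
  members <- b$pedigrees$sample_id
  shared_first <- filter_rare_nonsilent(
    shared_candidates(b$samples, members), b$annotation)$kept
  all_ids <- unique(unlist(lapply(b$samples, `[[`, "variant_id")))
  rare_first <- intersect(filter_rare_nonsilent(all_ids, b$annotation)$kept,
                          shared_candidates(b$samples, members))
  expect_setequal(shared_first, rare_first)
})

test_that("co-occurrence is membership in the derived germline set", {
  flags <- cohort_cooccurrence(c("v1", "v2"), c("v1", "v9"))
  expect_identical(unname(flags), c(TRUE, FALSE))
})

test_that("evidence assignment follows the documented mapping", {
  ev <- assign_evidence("frameshift", control_af = NA,
                        known_lof_gene = TRUE)
  expect_setequal(ev$code, c("PVS1", "PM2"))
  ev2 <- assign_evidence("synonymous", control_af = 0.2)
  expect_equal(ev2$code, "BA1")
  ev3 <- assign_evidence("missense", control_af = 0.01)
  expect_equal(nrow(ev3), 0L)
  ev4 <- assign_evidence("missense", control_af = NA, insilico = "damaging",
                         shared_in_pedigree = TRUE)
  expect_setequal(ev4$code, c("PM2", "PP1", "PP3"))
})

test_that("verdict combination matches the published table on key cases", {
  vs <- function(...) combine_acmg(evidence_from_counts(...))$tier
  expect_equal(combine_acmg(evidence_from_counts(0, 0, 0, 0, 0, 0, 0))$tier,
               "uncertain_significance")
  expect_equal(vs(1, 0, 2, 0, 0, 0, 0), "pathogenic")      # PVS + 2 PM
  expect_equal(vs(1, 0, 1, 0, 0, 0, 0), "likely_pathogenic") # PVS + 1 PM
  expect_equal(vs(0, 1, 1, 0, 0, 0, 0), "likely_pathogenic")
  expect_equal(vs(0, 0, 0, 0, 1, 0, 0), "benign")          # BA stand-alone
  expect_equal(vs(0, 0, 0, 0, 0, 1, 1), "likely_benign")
  expect_equal(vs(1, 1, 0, 0, 1, 0, 0), "uncertain_significance") # conflict
  expect_error(combine_acmg(data.frame(code = "x", direction = "pathogenic",
                                       strength = "stand_alone")),
               class = "varcoseg_data_error")
})
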