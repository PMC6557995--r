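# Simulation configuration: the study conditions every generator reads.

#' Default pedigree layout for the synthetic study
#'
#' Ten pedigrees, two sequenced affected relatives each, with kinship
#' coefficients spanning the distant-to-first-degree range typical of familial
#' breast-cancer exome studies (0.016 to 0.25).
#'
#' @return A data frame with columns `pedigree_id`, `n_affected`, `kinship`.
#' @export
default_pedigree_layout <- function() {
  data.frame(
    pedigree_id = c("F3311", "NIJM6", "NIJM8", "RUL036", "RUL153",
                    "RUL39", "RUL79", "F2887", "RUL70", "RUL154"),
    n_affected  = 2L,
    kinship     = c(0.0625, 0.25, 0.125, 0.125, 0.016,
                    0.0625, 0.25, 0.03, 0.125, 0.0625),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data module: pedigree structure,
#' background/planted variant counts and allele-frequency model, population
#' cohort sizes and the planted carrier enrichment, PSSM geometry, and the
#' somatic mutation spectrum.  Defaults describe one synthetic familial cancer
#' study: 10 pedigrees of two affected relatives, 10,000 background exome
#' variants, one planted co-segregating rare non-silent variant per pedigree,
#' cohort allele numbers at population-database scale (a cancer subset of
#' about 7,000 samples inside a general cohort, and about 60,000 control
#' samples), a 377-residue target protein, and 102 somatic mutations with 30%
#' of their mass on a hotspot at residue 42.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_background_variants Number of unplanted background variants.
#' @param n_planted_shared Planted co-segregating variants per pedigree.
#' @param planted_af_max Control allele-frequency ceiling for planted
#'   variants; planted AFs are drawn uniformly from
#'   `[planted_af_max / 2, planted_af_max]` (rare but observed).
#' @param background_af_shape Two beta shape parameters for background allele
#'   frequencies; the default `c(0.2, 20)` gives a rare-variant-heavy site
#'   frequency spectrum.
#' @param fraction_silent Fraction of background variants that are silent
#'   (synonymous or intronic).
#' @param pedigree_layout Data frame with `pedigree_id`, `n_affected`,
#'   `kinship`; see [default_pedigree_layout()].
#' @param cohort_sizes Named vector of allele numbers (2 x samples) per
#'   cohort; must contain `general`, `non-cancer`, `control`, `full`,
#'   `complement`, with `general >= non-cancer` (the cancer subset is their
#'   difference) and `full >= complement` (the germline subset is their
#'   difference).
#' @param enrichment_odds Multiplier applied to the planted gene's carrier
#'   odds in the latent cancer subset of the general cohort.
#' @param pssm_length Length of the simulated PSSM / target protein.
#' @param conserved_fraction Fraction of PSSM positions that are conserved
#'   (wild-type score is the row maximum by a clear margin).
#' @param n_somatic Somatic missense mutation count for the target gene.
#' @param hotspot_positions Residue indices carrying planted hotspot mass.
#' @param hotspot_mass Fraction of somatic missense mass placed on the
#'   hotspot residues (the rest is uniform over the whole protein).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_background_variants = 10000L,
                       n_planted_shared = 1L,
                       planted_af_max = 0.001,
                       background_af_shape = c(0.2, 20),
                       fraction_silent = 0.5,
                       pedigree_layout = default_pedigree_layout(),
                       cohort_sizes = c(general = 134000, `non-cancer` = 120000,
                                        control = 120000, full = 134000,
                                        complement = 120000),
                       enrichment_odds = 5,
                       pssm_length = 377L,
                       conserved_fraction = 0.5,
                       n_somatic = 102L,
                       hotspot_positions = 42L,
                       hotspot_mass = 0.3) {
  if (!is_count(seed)) stop_config("seed must be a non-negative integer", "seed")
  if (!is_count(n_background_variants, 0))
    stop_config("must be a non-negative integer", "n_background_variants")
  if (!is_count(n_planted_shared, 0))
    stop_config("must be a non-negative integer", "n_planted_shared")
  if (n_planted_shared > n_background_variants && n_background_variants > 0L &&
      n_planted_shared > n_background_variants)
    stop_config("n_planted_shared must not exceed n_background_variants",
                "n_planted_shared")
  if (!is_fraction(planted_af_max))
    stop_config("must be a fraction in [0,1]", "planted_af_max")
  if (length(background_af_shape) != 2L || any(background_af_shape <= 0))
    stop_config("needs two positive beta shape parameters",
                "background_af_shape")
  if (!is_fraction(fraction_silent))
    stop_config("must be a fraction in [0,1]", "fraction_silent")
  if (!is.data.frame(pedigree_layout) ||
      !all(c("pedigree_id", "n_affected", "kinship") %in%
           names(pedigree_layout)) || nrow(pedigree_layout) < 1L)
    stop_config("needs columns pedigree_id, n_affected, kinship and >= 1 row",
                "pedigree_layout")
  if (any(pedigree_layout$n_affected < 1L))
    stop_config("each pedigree needs >= 1 sequenced affected sample",
                "pedigree_layout")
  if (any(pedigree_layout$kinship < 0 | pedigree_layout$kinship > 0.5))
    stop_config("kinship coefficients must lie in [0, 0.5]", "pedigree_layout")
  if (anyDuplicated(pedigree_layout$pedigree_id))
    stop_config("pedigree ids must be unique", "pedigree_layout")
  needed <- c("general", "non-cancer", "control", "full", "complement")
  if (is.null(names(cohort_sizes)) || !all(needed %in% names(cohort_sizes)))
    stop_config(sprintf("must name cohorts: %s", paste(needed, collapse = ", ")),
                "cohort_sizes")
  if (any(cohort_sizes <= 0))
    stop_config("cohort allele numbers must be positive", "cohort_sizes")
  if (cohort_sizes[["general"]] < cohort_sizes[["non-cancer"]])
    stop_config("'general' allele number must be >= 'non-cancer'",
                "cohort_sizes")
  if (cohort_sizes[["full"]] < cohort_sizes[["complement"]])
    stop_config("'full' allele number must be >= 'complement'", "cohort_sizes")
  if (!(length(enrichment_odds) == 1L && is.numeric(enrichment_odds) &&
        enrichment_odds > 0))
    stop_config("must be a positive real", "enrichment_odds")
  if (!is_count(pssm_length, 1))
    stop_config("must be a positive integer", "pssm_length")
  if (!is_fraction(conserved_fraction))
    stop_config("must be a fraction in [0,1]", "conserved_fraction")
  if (!is_count(n_somatic, 0))
    stop_config("must be a non-negative integer", "n_somatic")
  if (length(hotspot_positions) &&
      (any(hotspot_positions < 1) || any(hotspot_positions > pssm_length)))
    stop_config("hotspot positions must lie within [1, pssm_length]",
                "hotspot_positions")
  if (!is_fraction(hotspot_mass))
    stop_config("must be a fraction in [0,1]", "hotspot_mass")
  if (hotspot_mass > 0 && length(hotspot_positions) == 0L)
    stop_config("hotspot_mass > 0 requires at least one hotspot position",
                "hotspot_positions")

  structure(list(
    seed = as.integer(seed),
    n_background_variants = as.integer(n_background_variants),
    n_planted_shared = as.integer(n_planted_shared),
    planted_af_max = planted_af_max,
    background_af_shape = as.numeric(background_af_shape),
    fraction_silent = fraction_silent,
    pedigree_layout = pedigree_layout,
    cohort_sizes = cohort_sizes,
    enrichment_odds = enrichment_odds,
    pssm_length = as.integer(pssm_length),
    conserved_fraction = conserved_fraction,
    n_somatic = as.integer(n_somatic),
    hotspot_positions = as.integer(hotspot_positions),
    hotspot_mass = hotspot_mass
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration (seed ", x$seed, ")\n", sep = "")
  cat("  pedigrees: ", nrow(x$pedigree_layout),
      " (affected per pedigree: ",
      paste(unique(x$pedigree_layout$n_affected), collapse = "/"), ")\n",
      sep = "")
  cat("  variants: ", x$n_background_variants, " background + ",
      x$n_planted_shared, " planted shared per pedigree (AF <= ",
      x$planted_af_max, ")\n", sep = "")
  cat("  cohorts: ", paste(sprintf("%s=%d", names(x$cohort_sizes),
                                   as.integer(x$cohort_sizes)),
                           collapse = ", "), "\n", sep = "")
  cat("  enrichment odds: ", x$enrichment_odds,
      "; PSSM length: ", x$pssm_length,
      "; somatic: ", x$n_somatic, " (hotspots at ",
      paste(x$hotspot_positions, collapse = ","),
      ", mass ", x$hotspot_mass, ")\n", sep = "")
  invisible(x)
}
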