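# Synthetic population cohort allele-count tables.  Emulates a gnomAD-style
# release (general / non-cancer / control cohorts, where cancer = general -
# non-cancer) and an ExAC-style full-vs-complement pair (full / complement,
# where the germline subset = full - complement).

#' Simulate cohort allele-count tables with a planted enriched gene
#'
#' For every variant, latent cancer-subset and non-cancer allele counts are
#' drawn binomially; the released `general` cohort is their elementwise sum,
#' so subtraction recovers the cancer subset exactly. The planted gene's
#' allele odds in the latent cancer subset are multiplied by
#' `enrichment_odds`; all other variants have equal frequencies in both
#' subsets. A `full`/`complement` table pair is generated the same way, with
#' every planted co-segregating variant guaranteed at least one
#' cancer-germline allele (so it survives the germline-subset derivation).
#'
#' @param config A [sim_config()] object (cohort sizes, enrichment odds,
#'   seed).
#' @param annotation Optional annotation table (`variant_id`, `gene`,
#'   `af_control`); when omitted, a free-standing table of 20 genes x 5
#'   variants is generated from the config seed.
#' @param enriched_gene Gene whose cancer-subset carrier odds are multiplied;
#'   defaults to `"NCK1"` when present in the annotation, else the first
#'   gene.
#' @param planted_ids Variant ids guaranteed a positive derived germline
#'   count (>= 1 cancer-only allele in the full/complement pair).
#' @return A data frame of class `cohort_table` with columns `variant_id`,
#'   `cohort` (general, non-cancer, control, full, complement), `ac`, `an`,
#'   `filter_status`; the latent cancer-subset counts and the enriched gene
#'   are attached as attributes `latent_cancer` and `enriched_gene`.
#' @export
simulate_cohort_counts <- function(config, annotation = NULL,
                                   enriched_gene = NULL,
                                   planted_ids = character()) {
  if (!inherits(config, "sim_config"))
    stop_config("config must be a sim_config object", "config")
  if (any(config$cohort_sizes == 0))
    stop_config("cohort size of 0", "cohort_sizes")
  with_seed(child_seed(config$seed, 2L), {
    if (is.null(annotation)) {
      n_genes <- 20L
      per_gene <- 5L
      gene <- rep(sprintf("GENE%04d", seq_len(n_genes)), each = per_gene)
      gene[seq_len(per_gene)] <- "NCK1"
      annotation <- data.frame(
        variant_id = sprintf("%d:%d:A:G", sample(1:22, n_genes * per_gene, TRUE),
                             sample.int(2L^28L, n_genes * per_gene)),
        gene = gene,
        af_control = stats::rbeta(n_genes * per_gene,
                                  config$background_af_shape[1L],
                                  config$background_af_shape[2L]) *
          config$planted_af_max * 2,
        stringsAsFactors = FALSE)
    }
    if (is.null(enriched_gene))
      enriched_gene <- if ("NCK1" %in% annotation$gene) "NCK1"
                       else annotation$gene[1L]

    af <- pmin(pmax(annotation$af_control, 1e-6), 0.999)
    n <- length(af)
    sizes <- config$cohort_sizes
    an_nc <- as.integer(sizes[["non-cancer"]])
    an_cancer <- as.integer(sizes[["general"]] - sizes[["non-cancer"]])
    an_control <- as.integer(sizes[["control"]])
    an_compl <- as.integer(sizes[["complement"]])
    an_cgl <- as.integer(sizes[["full"]] - sizes[["complement"]])

    # odds-scale enrichment of the planted gene in the latent cancer subset
    odds <- af / (1 - af)
    af_cancer <- ifelse(annotation$gene == enriched_gene,
                        odds * config$enrichment_odds /
                          (1 + odds * config$enrichment_odds),
                        af)

    ac_nc <- stats::rbinom(n, an_nc, af)
    ac_cancer <- stats::rbinom(n, an_cancer, af_cancer)
    ac_control <- stats::rbinom(n, an_control, af)
    ac_compl <- stats::rbinom(n, an_compl, af)
    ac_cgl <- stats::rbinom(n, an_cgl, af_cancer)
    force_in <- annotation$variant_id %in% planted_ids
    ac_cgl[force_in] <- pmax(1L, ac_cgl[force_in])

    mk <- function(cohort, ac, an) {
      data.frame(variant_id = annotation$variant_id,
                 cohort = rep(cohort, n),
                 ac = as.integer(ac), an = rep(as.integer(an), length.out = n),
                 filter_status = rep("pass", n), stringsAsFactors = FALSE)
    }
    out <- rbind(
      mk("general", ac_nc + ac_cancer, an_nc + an_cancer),
      mk("non-cancer", ac_nc, an_nc),
      mk("control", ac_control, an_control),
      mk("full", ac_compl + ac_cgl, an_compl + an_cgl),
      mk("complement", ac_compl, an_compl))
    attr(out, "latent_cancer") <- data.frame(
      variant_id = annotation$variant_id, ac = as.integer(ac_cancer),
      an = rep(an_cancer, length.out = n), stringsAsFactors = FALSE)
    attr(out, "enriched_gene") <- enriched_gene
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Write / read a cohort allele-count TSV
#'
#' Columns: `variant_id`, `cohort`, `ac`, `an`, `filter_status`.
#'
#' @param counts Cohort count data frame.
#' @param path File path.
#' @return `write_cohort_tsv`: the path, invisibly; `read_cohort_tsv`: the
#'   counts data frame.
#' @export
write_cohort_tsv <- function(counts, path) {
  write_tsv_(as.data.frame(counts)[, c("variant_id", "cohort", "ac", "an",
                                       "filter_status")], path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  counts <- read_tsv_(path)
  need <- c("variant_id", "cohort", "ac", "an")
  if (!all(need %in% names(counts)))
    stop_parse(sprintf("cohort table must contain columns: %s",
                       paste(need, collapse = ", ")))
  if (!"filter_status" %in% names(counts)) counts$filter_status <- "pass"
  counts$ac <- as.integer(counts$ac)
  counts$an <- as.integer(counts$an)
  if (any(counts$ac < 0 | counts$ac > counts$an))
    stop_data("allele counts must satisfy 0 <= ac <= an")
  counts
}
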