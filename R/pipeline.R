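# Orchestration: one config drives read -> normalize -> hard filter ->
# co-segregation -> rarity/consequence filter -> germline-subset
# co-occurrence -> ACMG verdicts -> cohort burden -> substitution tolerance
# -> somatic recurrence, with per-stage conservation logging and a
# consolidated report.

#' Default run configuration
#'
#' Returns the full nested configuration with every stage parameter at its
#' default; callers (or a YAML file) override what they need. File inputs
#' are left empty.
#'
#' @param seed Integer seed used by the stochastic stages (Monte Carlo
#'   null).
#' @param outdir Optional output directory for report files.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1L, outdir = NULL) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    inputs = list(vcf = character(), ped = NULL, kinship = NULL,
                  annotation = NULL, cohort = NULL, pssm = NULL,
                  somatic = NULL, type_totals = NULL),
    stages = list(cosegregate = TRUE, burden = TRUE, tolerance = TRUE,
                  recurrence = TRUE),
    filters = list(min_depth = 0, min_gq = 0, min_qual = 0),
    rarity = list(af_max = 0.001),
    sharing = list(missing_as_carrier = FALSE),
    cooccurrence = list(require = TRUE),
    acmg = list(benign_af = 0.05, absent_af = 1e-5,
                lof_genes = c("CHEK2", "ATM", "MRE11", "CTR9", "MUTYH",
                              "XRCC2", "PALB2", "STK11", "TP53")),
    burden = list(cohort_a = "general", cohort_a_subtract = "non-cancer",
                  cohort_b = "control"),
    tolerance = list(gene = "NCK1", set_size = 3L, n_sets = 10000L),
    recurrence = list(gene = "NCK1", protein_length = NULL,
                      window_halfwidth = 2L, alpha = 0.001,
                      recurrence_min = 2L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration from YAML
#'
#' Values in the file override [default_run_config()]; everything else keeps
#' its default. Referenced input files must exist.
#'
#' @param path Path to the YAML configuration.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_config(sprintf("config file not found: %s", path))
  cfg <- merge_config(default_run_config(), yaml::read_yaml(path))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  paths <- c(cfg$inputs$vcf, cfg$inputs$ped, cfg$inputs$kinship,
             cfg$inputs$annotation, cfg$inputs$cohort, cfg$inputs$pssm,
             cfg$inputs$somatic, cfg$inputs$type_totals)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing))
    stop_config(sprintf("input file(s) not found: %s",
                        paste(missing, collapse = ", ")), "inputs")
  if (!is_fraction(cfg$rarity$af_max))
    stop_config("must lie in [0,1]", "rarity.af_max")
  if (!is_fraction(cfg$recurrence$alpha))
    stop_config("must lie in [0,1]", "recurrence.alpha")
  if (!is_count(cfg$tolerance$set_size, 1))
    stop_config("must be >= 1", "tolerance.set_size")
  if (!is_count(cfg$tolerance$n_sets, 1))
    stop_config("must be >= 1", "tolerance.n_sets")
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, varcoseg_error = function(e) {
    stop(errorCondition(sprintf("stage '%s': %s", stage,
                                conditionMessage(e)),
                        class = class(e)))
  })
}

#' Run the full prioritization pipeline
#'
#' Executes, in order: VCF reading/normalization, site-level hard filtering,
#' per-pedigree co-segregation, the rare/non-silent filter, co-occurrence
#' with the derived cancer-germline subset, ACMG-style verdicts, the
#' cohort-subtraction burden scan, substitution-tolerance scoring with its
#' Monte Carlo null, and somatic recurrence statistics. Every stage logs
#' kept/rejected counts; rejected records keep their reasons. Deterministic
#' under the configured seed.
#'
#' @param config A configuration list ([default_run_config()] /
#'   [read_run_config()]) or a path to a YAML file.
#' @param quiet Suppress one-line per-stage progress messages.
#' @return Object of class `coseg_report`: `candidates`, `burden`,
#'   `tolerance`, `recurrence` (`hotspots`, `classification`, `enrichment`),
#'   `rejects`, `stage_counts`, `provenance`. Written as TSV/JSON files when
#'   `config$outdir` is set.
#' @export
run_all <- function(config, quiet = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(merge_config(default_run_config(), config))
  say <- function(...) if (!quiet) message(sprintf(...))
  counts_log <- list()
  log_stage <- function(stage, n_in, n_kept) {
    counts_log[[length(counts_log) + 1L]] <<-
      data.frame(stage = stage, n_in = n_in, n_kept = n_kept,
                 n_rejected = n_in - n_kept, stringsAsFactors = FALSE)
    say("%-18s in=%d kept=%d rejected=%d", stage, n_in, n_kept, n_in - n_kept)
  }
  rejects <- list()

  # --- read & normalize ---------------------------------------------------
  vcfs <- run_stage("read", lapply(config$inputs$vcf, read_vcf_calls))
  samples <- list()
  variants <- NULL
  for (v in vcfs) {
    for (s in v$samples)
      samples[[s]] <- v$calls[v$calls$sample_id == s,
                              c("variant_id", "gt", "dp", "gq")]
    variants <- rbind(variants, v$variants)
  }
  if (is.null(variants))
    variants <- data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           variant_id = character(), qual = numeric(),
                           stringsAsFactors = FALSE)
  variants <- variants[!duplicated(variants$variant_id), , drop = FALSE]
  log_stage("read", nrow(variants), nrow(variants))

  # --- hard filter --------------------------------------------------------
  thr <- filter_thresholds(config$filters$min_depth, config$filters$min_gq,
                           config$filters$min_qual)
  all_calls <- if (length(samples)) do.call(rbind, unname(samples)) else NULL
  fail_ids <- character()
  if (nrow(variants)) {
    res <- run_stage("hard_filter",
                     hard_filter_table(variants, all_calls, thr))
    fail_ids <- variants$variant_id[!res$pass]
    if (length(fail_ids))
      rejects$hard_filter <- data.frame(
        variant_id = fail_ids,
        reason = vapply(res$reasons[!res$pass], paste, character(1),
                        collapse = ";"),
        stringsAsFactors = FALSE)
  }
  log_stage("hard_filter", nrow(variants), nrow(variants) - length(fail_ids))
  samples <- lapply(samples, function(calls)
    calls[!calls$variant_id %in% fail_ids, , drop = FALSE])

  annotation <- if (!is.null(config$inputs$annotation))
    run_stage("annotation", read_annotation_tsv(config$inputs$annotation))
  else NULL

  # cohort tables (used by co-occurrence and burden)
  cohorts <- NULL
  germline_ids <- NULL
  if (!is.null(config$inputs$cohort)) {
    cohorts <- run_stage("cohort", {
      raw <- read_cohort_tsv(config$inputs$cohort)
      quality_filter(raw)
    })
    by_cohort <- split(cohorts, cohorts$cohort)
    if (all(c("full", "complement") %in% names(by_cohort)))
      germline_ids <- run_stage("germline_subset",
        derive_germline_subset(by_cohort$full, by_cohort$complement))
  }

  # --- co-segregation + classification ------------------------------------
  candidates <- data.frame()
  if (isTRUE(config$stages$cosegregate) && !is.null(config$inputs$ped)) {
    peds <- run_stage("pedigree",
      read_pedigree(config$inputs$ped, config$inputs$kinship,
                    vcf_samples = names(samples)))
    for (pid in unique(peds$pedigree_id)) {
      members <- peds$sample_id[peds$pedigree_id == pid]
      shared <- run_stage("shared_candidates",
        shared_candidates(samples, members,
                          config$sharing$missing_as_carrier))
      fr <- run_stage("rare_nonsilent",
        filter_rare_nonsilent(shared, annotation, config$rarity$af_max))
      if (nrow(fr$rejected)) {
        fr$rejected$pedigree_id <- pid
        rejects$rare_nonsilent <- rbind(rejects$rare_nonsilent, fr$rejected)
      }
      kept <- fr$kept
      cooc <- if (!is.null(germline_ids)) cohort_cooccurrence(kept, germline_ids)
              else stats::setNames(rep(NA, length(kept)), kept)
      if (isTRUE(config$cooccurrence$require) && !is.null(germline_ids)) {
        dropped <- kept[!cooc]
        if (length(dropped))
          rejects$cooccurrence <- rbind(rejects$cooccurrence,
            data.frame(variant_id = dropped, reason = "not_in_germline_subset",
                       pedigree_id = pid, stringsAsFactors = FALSE))
        kept <- kept[cooc[kept]]
      }
      log_stage(paste0("candidates:", pid), length(shared), length(kept))
      if (!length(kept)) next
      ann <- annotation[match(kept, annotation$variant_id), , drop = FALSE]
      verdicts <- lapply(seq_len(nrow(ann)), function(i) {
        ev <- assign_evidence(
          consequence = ann$consequence[i],
          control_af = ann$af_control[i],
          insilico = if ("insilico" %in% names(ann)) ann$insilico[i]
                     else "unknown",
          shared_in_pedigree = length(members) >= 2L,
          known_lof_gene = ann$gene[i] %in% config$acmg$lof_genes,
          benign_af = config$acmg$benign_af,
          absent_af = config$acmg$absent_af)
        v <- combine_acmg(ev)
        list(tier = v$tier, rule = v$triggered_rule,
             codes = paste(ev$code, collapse = ","))
      })
      gts <- vapply(kept, function(id) {
        g <- unique(vapply(members, function(s) {
          calls <- samples[[s]]
          gt <- calls$gt[calls$variant_id == id]
          if (length(gt)) gt[1] else "hom_ref"
        }, character(1)))
        if (identical(g, "het")) "Het" else paste(g, collapse = "/")
      }, character(1))
      candidates <- rbind(candidates, data.frame(
        pedigree_id = pid, kinship = peds$kinship[match(pid, peds$pedigree_id)],
        variant_id = kept, gene = ann$gene,
        evaluation = vapply(verdicts, `[[`, character(1), "tier"),
        triggered_rule = vapply(verdicts, `[[`, character(1), "rule"),
        evidence = vapply(verdicts, `[[`, character(1), "codes"),
        genotype = gts, consequence = ann$consequence,
        transcript = ann$transcript, exon = ann$exon,
        hgvs_c = ann$hgvs_c, hgvs_p = ann$hgvs_p,
        flag_shared = TRUE, flag_rare = TRUE, flag_nonsilent = TRUE,
        flag_cooccurring = unname(cooc[kept]),
        stringsAsFactors = FALSE, row.names = NULL))
    }
  }

  # --- burden -------------------------------------------------------------
  burden <- NULL
  if (isTRUE(config$stages$burden) && !is.null(cohorts) && nrow(cohorts)) {
    burden <- run_stage("burden", {
      by_cohort <- split(cohorts, cohorts$cohort)
      a_name <- config$burden$cohort_a
      if (!a_name %in% names(by_cohort))
        stop_data(sprintf("cohort '%s' not in cohort table", a_name))
      table_a <- by_cohort[[a_name]]
      if (!is.null(config$burden$cohort_a_subtract) &&
          config$burden$cohort_a_subtract %in% names(by_cohort))
        table_a <- subtract_counts(table_a,
                                   by_cohort[[config$burden$cohort_a_subtract]])
      b_name <- config$burden$cohort_b
      if (!b_name %in% names(by_cohort))
        stop_data(sprintf("cohort '%s' not in cohort table", b_name))
      gene_map <- annotation[annotation$variant_id %in% table_a$variant_id,
                             c("variant_id", "gene")]
      burden_scan(gene_map, table_a, by_cohort[[b_name]])
    })
    log_stage("burden", length(unique(burden$gene)), nrow(burden))
  }

  # --- tolerance ----------------------------------------------------------
  tolerance <- NULL
  if (isTRUE(config$stages$tolerance) && !is.null(config$inputs$pssm)) {
    tolerance <- run_stage("tolerance", {
      mat <- parse_pssm_ascii(config$inputs$pssm)
      gene <- config$tolerance$gene
      muts <- data.frame(position = integer(), wt = character(),
                         mut = character(), source = character(),
                         stringsAsFactors = FALSE)
      if (nrow(candidates)) {
        cand <- candidates[candidates$gene == gene &
                           candidates$consequence == "missense" &
                           !is.na(candidates$hgvs_p), , drop = FALSE]
        if (nrow(cand)) {
          parsed <- parse_hgvs_p(cand$hgvs_p)
          parsed$source <- "germline"
          muts <- rbind(muts, parsed)
        }
      }
      if (!is.null(config$inputs$somatic)) {
        som <- read_somatic_tsv(config$inputs$somatic)
        som <- som[som$gene == gene & som$consequence == "missense" &
                   !is.na(som$aa_alt), , drop = FALSE]
        if (nrow(som))
          muts <- rbind(muts, data.frame(position = som$protein_pos,
                                         wt = som$aa_ref, mut = som$aa_alt,
                                         source = "somatic",
                                         stringsAsFactors = FALSE))
      }
      if (nrow(muts) == 0L) NULL else {
        muts$delta_s <- vapply(seq_len(nrow(muts)), function(i)
          delta_s(mat, muts$position[i], muts$wt[i], muts$mut[i])$delta_s,
          integer(1))
        null <- sample_null(mat, config$tolerance$set_size,
                            config$tolerance$n_sets,
                            seed = child_seed(config$seed, 9L))
        observed <- mean(muts$delta_s)
        list(gene = gene, mutations = muts, observed_mean = observed,
             null = null, expected_null_mean = expected_delta_s(mat),
             empirical_p = empirical_p(observed, null))
      }
    })
    if (!is.null(tolerance))
      log_stage("tolerance", nrow(tolerance$mutations),
                nrow(tolerance$mutations))
  }

  # --- recurrence ---------------------------------------------------------
  recurrence <- NULL
  if (isTRUE(config$stages$recurrence) && !is.null(config$inputs$somatic)) {
    recurrence <- run_stage("recurrence", {
      som <- read_somatic_tsv(config$inputs$somatic)
      L <- config$recurrence$protein_length
      if (is.null(L) && !is.null(config$inputs$pssm))
        L <- parse_pssm_ascii(config$inputs$pssm)$length
      if (is.null(L)) stop_config("protein_length required",
                                  "recurrence.protein_length")
      totals <- NULL
      if (!is.null(config$inputs$type_totals)) {
        tt <- read_tsv_(config$inputs$type_totals)
        totals <- stats::setNames(as.integer(tt$total), tt$cancer_type)
      }
      spec <- spectrum_from_mutations(som, L, gene = config$recurrence$gene,
                                      type_totals = totals)
      list(spectrum = spec,
           hotspots = hotspot_scan(spec, config$recurrence$window_halfwidth,
                                   config$recurrence$alpha),
           classification = classify_20_20(spec,
                                           config$recurrence$recurrence_min),
           enrichment = if (!is.null(totals)) cancer_type_enrichment(spec)
                        else NULL)
    })
    log_stage("recurrence", recurrence$spectrum$n_nonsilent,
              sum(recurrence$hotspots$is_hotspot))
  }

  stage_counts <- if (length(counts_log)) do.call(rbind, counts_log)
                  else data.frame()
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config[setdiff(names(config), "outdir")], cfg_file)
  provenance <- list(seed = config$seed,
                     config_hash = unname(tools::md5sum(cfg_file)),
                     package_version = as.character(
                       utils::packageVersion("varcoseg")))
  unlink(cfg_file)

  report <- structure(list(candidates = candidates, burden = burden,
                           tolerance = tolerance, recurrence = recurrence,
                           rejects = rejects, stage_counts = stage_counts,
                           provenance = provenance, config = config),
                      class = "coseg_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' Write a report's tables to a directory
#'
#' @param report A `coseg_report` from [run_all()].
#' @param outdir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(report$candidates))
    write_tsv_(report$candidates, file.path(outdir, "candidates.tsv"))
  if (!is.null(report$burden))
    write_tsv_(report$burden, file.path(outdir, "burden.tsv"))
  if (!is.null(report$tolerance))
    write_tsv_(report$tolerance$mutations,
               file.path(outdir, "tolerance.tsv"))
  if (!is.null(report$recurrence)) {
    write_tsv_(report$recurrence$hotspots, file.path(outdir, "hotspots.tsv"))
    if (!is.null(report$recurrence$enrichment))
      write_tsv_(report$recurrence$enrichment,
                 file.path(outdir, "enrichment.tsv"))
  }
  for (nm in names(report$rejects))
    write_tsv_(report$rejects[[nm]],
               file.path(outdir, sprintf("rejects_%s.tsv", nm)))
  summary <- list(
    n_candidates = nrow(report$candidates),
    candidates = report$candidates,
    top_burden_gene = if (!is.null(report$burden)) report$burden$gene[1L],
    top_burden_p = if (!is.null(report$burden)) report$burden$p[1L],
    tolerance = if (!is.null(report$tolerance))
      list(gene = report$tolerance$gene,
           observed_mean = report$tolerance$observed_mean,
           empirical_p = report$tolerance$empirical_p),
    classification = if (!is.null(report$recurrence))
      report$recurrence$classification[c("label", "oncogene_fraction",
                                         "tsg_fraction")],
    stage_counts = report$stage_counts,
    provenance = report$provenance)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.coseg_report <- function(x, ...) {
  cat("Co-segregation prioritization report\n")
  cat("  candidates:", nrow(x$candidates), "across",
      length(unique(x$candidates$pedigree_id)), "pedigree(s)\n")
  if (!is.null(x$burden))
    cat(sprintf("  top burden gene: %s (p = %.3g)\n", x$burden$gene[1L],
                x$burden$p[1L]))
  if (!is.null(x$tolerance))
    cat(sprintf("  tolerance: %s mean delta S = %.2f (empirical p = %.3g)\n",
                x$tolerance$gene, x$tolerance$observed_mean,
                x$tolerance$empirical_p))
  if (!is.null(x$recurrence)) {
    hs <- x$recurrence$hotspots
    top <- hs[order(hs$p_adjusted), ][1L, ]
    cat(sprintf("  recurrence: %s; top hotspot residue %d (adj p = %.3g)\n",
                x$recurrence$classification$label, top$residue,
                top$p_adjusted))
  }
  invisible(x)
}

#' Write a complete, ready-to-run synthetic input bundle
#'
#' Generates every input the pipeline consumes -- per-sample VCFs, PED and
#' kinship sidecar, annotation TSV, cohort allele-count TSV (with the
#' full/complement germline pair), PSI-BLAST ASCII PSSM, somatic mutation
#' TSV with per-type totals, truth JSON, and a run.yaml -- from one config
#' and seed. Identical seeds give byte-identical bundles.
#'
#' @param outdir Writable output directory (created if needed).
#' @param seed Integer seed (used when `config` is not supplied).
#' @param config Optional [sim_config()]; defaults to `sim_config(seed)`.
#' @return List with `config_path`, `truth`, `bundle` (invisible).
#' @export
make_demo <- function(outdir, seed = 1L, config = NULL) {
  if (is.null(config)) config <- sim_config(seed = seed)
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop_config(sprintf("cannot create output directory: %s", outdir))
  vcf_dir <- file.path(outdir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)

  bundle <- simulate_pedigree_dataset(config)
  mat <- simulate_pssm(config$pssm_length, config$conserved_fraction,
                       seed = child_seed(config$seed, 3L))
  cohort <- simulate_cohort_counts(config, annotation = bundle$annotation,
                                   planted_ids =
                                     bundle$truth$planted$variant_id)
  n_trunc <- round(config$n_somatic * 0.12)
  spectrum <- simulate_somatic_spectrum(
    config$pssm_length, config$n_somatic - n_trunc,
    hotspots = config$hotspot_positions, hotspot_mass = config$hotspot_mass,
    seed = child_seed(config$seed, 4L), n_truncating = n_trunc,
    gene = bundle$truth$planted_enriched_gene)

  vcf_paths <- vapply(names(bundle$samples), function(sid) {
    p <- file.path(vcf_dir, paste0(sid, ".vcf"))
    write_sample_vcf(bundle$variants, bundle$samples[[sid]], sid, p)
    p
  }, character(1))
  write_ped(bundle$pedigrees, file.path(outdir, "pedigree.ped"))
  write_kinship_tsv(bundle$pedigrees, file.path(outdir, "kinship.tsv"))
  write_annotation_tsv(bundle$annotation, file.path(outdir, "annotation.tsv"))
  write_cohort_tsv(cohort, file.path(outdir, "cohort.tsv"))
  write_pssm_ascii(mat, file.path(outdir, "pssm.txt"))
  with_seed(child_seed(config$seed, 5L),
            write_somatic_tsv(spectrum, file.path(outdir, "somatic.tsv"),
                              pssm = mat))
  write_tsv_(spectrum$per_cancer_type[, c("cancer_type", "total")],
             file.path(outdir, "type_totals.tsv"))
  write_truth_json(bundle$truth, file.path(outdir, "truth.json"))

  run_cfg <- default_run_config(seed = config$seed,
                                outdir = file.path(outdir, "results"))
  run_cfg$inputs <- list(vcf = unname(vcf_paths),
                         ped = file.path(outdir, "pedigree.ped"),
                         kinship = file.path(outdir, "kinship.tsv"),
                         annotation = file.path(outdir, "annotation.tsv"),
                         cohort = file.path(outdir, "cohort.tsv"),
                         pssm = file.path(outdir, "pssm.txt"),
                         somatic = file.path(outdir, "somatic.tsv"),
                         type_totals = file.path(outdir, "type_totals.tsv"))
  run_cfg$tolerance$gene <- bundle$truth$planted_enriched_gene
  run_cfg$recurrence$gene <- bundle$truth$planted_enriched_gene
  run_cfg$recurrence$protein_length <- config$pssm_length
  config_path <- file.path(outdir, "run.yaml")
  yaml::write_yaml(run_cfg, config_path)
  invisible(list(config_path = config_path, truth = bundle$truth,
                 bundle = bundle))
}
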