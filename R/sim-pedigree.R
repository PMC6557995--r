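# Synthetic pedigree dataset: planted co-segregating rare non-silent variants
# against a background of unshared/common/silent variants, written as
# per-sample VCFs plus PED/kinship/annotation sidecars and a truth table.

CANCER_GENE_POOL <- c("NCK1", "MRE11", "CTR9", "CHEK2", "ATM", "XRCC2",
                      "IGF2R", "CHRNA3", "MUTYH", "PALB2", "STK11", "TP53")

# Background consequence mix among non-silent classes.
NONSILENT_WEIGHTS <- c(missense = 0.70, frameshift = 0.10,
                       stopgain = 0.10, splicing = 0.10)

random_hgvs_p <- function(consequence, wt_seq) {
  L <- length(wt_seq)
  pos <- sample.int(L, length(consequence), replace = TRUE)
  wt <- wt_seq[pos]
  mut <- vapply(wt, function(w) sample(setdiff(AA_ALPHABET, w), 1L),
                character(1))
  out <- rep(NA_character_, length(consequence))
  mis <- consequence == "missense"
  out[mis] <- sprintf("p.%s%d%s", wt[mis], pos[mis], mut[mis])
  fs <- consequence == "frameshift"
  out[fs] <- sprintf("p.%s%dfs", wt[fs], pos[fs])
  sg <- consequence == "stopgain"
  out[sg] <- sprintf("p.%s%dX", wt[sg], pos[sg])
  out
}

#' Simulate a full pedigree variant dataset with planted ground truth
#'
#' Generates, for every pedigree in the layout, `n_planted_shared`
#' co-segregating variants — rare (control AF within
#' `[planted_af_max/2, planted_af_max]`), non-silent, and heterozygous in
#' every sequenced affected sample of that pedigree — against
#' `n_background_variants` background variants whose carrier status is drawn
#' independently per sample under Hardy-Weinberg from a beta-distributed site
#' frequency spectrum. Background variants that end up shared by chance
#' within a pedigree are recorded in the truth table. Deterministic under the
#' config seed.
#'
#' Planted variants are assigned to well-known cancer genes; the first
#' planted gene (`NCK1` by convention) is also the cohort-enrichment and
#' tolerance/recurrence target, and its planted missense HGVS protein
#' notation is made consistent with the PSSM generated from the same config
#' (same wild-type residue at the same position).
#'
#' @param config A [sim_config()] object.
#' @return A list of class `coseg_bundle`:
#'   * `variants`: data frame of all loci (`chrom`, `pos`, `ref`, `alt`,
#'     `variant_id`, `qual`, `af`),
#'   * `samples`: named list, one genotype-call data frame per sample
#'     (`variant_id`, `gt`, `dp`, `gq`) listing carried/missing sites only,
#'   * `annotation`: ANNOVAR-style annotation table,
#'   * `pedigrees`: data frame `pedigree_id`, `sample_id`, `kinship`,
#'   * `truth`: list with `planted` (data frame `pedigree_id`, `variant_id`,
#'     `gene`), `planted_shared_variant_ids`, `planted_enriched_gene`,
#'     `shared_background` (data frame `pedigree_id`, `variant_id` of
#'     chance-shared background variants).
#' @export
simulate_pedigree_dataset <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_config("config must be a sim_config object", "config")
  with_seed(child_seed(config$seed, 1L), {
    layout <- config$pedigree_layout
    n_ped <- nrow(layout)
    nb <- config$n_background_variants
    npl <- config$n_planted_shared
    n_total <- nb + npl * n_ped

    # unique loci: distinct genomic positions guarantee distinct ids
    chrom <- sample(as.character(1:22), n_total, replace = TRUE)
    pos <- sample.int(2L^28L, n_total, replace = FALSE)
    ref <- sample(c("A", "C", "G", "T"), n_total, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                  character(1), USE.NAMES = FALSE)
    qual <- round(stats::rgamma(n_total, shape = 30, scale = 8), 2)

    planted_idx <- if (npl * n_ped > 0L) nb + seq_len(npl * n_ped) else integer()
    af <- stats::rbeta(n_total, config$background_af_shape[1L],
                       config$background_af_shape[2L])
    # planted variants sit in the upper half of the rarity window: rare, but
    # frequent enough to be observed once in a database-scale cohort
    af[planted_idx] <- stats::runif(length(planted_idx),
                                    config$planted_af_max / 2,
                                    config$planted_af_max)

    consequence <- character(n_total)
    silent <- stats::runif(nb) < config$fraction_silent
    consequence[seq_len(nb)][silent] <-
      sample(SILENT_CLASSES, sum(silent), replace = TRUE, prob = c(0.7, 0.3))
    consequence[seq_len(nb)][!silent] <-
      sample(names(NONSILENT_WEIGHTS), sum(!silent), replace = TRUE,
             prob = NONSILENT_WEIGHTS)
    consequence[planted_idx] <-
      sample(names(NONSILENT_WEIGHTS), length(planted_idx), replace = TRUE,
             prob = NONSILENT_WEIGHTS)

    # frameshift loci become 1-bp deletions (anchor base retained)
    is_fs <- consequence == "frameshift"
    ref[is_fs] <- paste0(ref[is_fs],
                         sample(c("A", "C", "G", "T"), sum(is_fs), TRUE))
    alt[is_fs] <- substr(ref[is_fs], 1L, 1L)
    ids <- variant_id(chrom, pos, ref, alt)

    # gene assignment: background from a generic pool; planted variants of
    # pedigree i get the i-th cancer gene (recycled), pedigree-constant
    n_genes <- max(20L, ceiling(n_total / 20))
    gene_pool <- sprintf("GENE%04d", seq_len(n_genes))
    gene <- sample(gene_pool, n_total, replace = TRUE)
    planted_genes <- rep(CANCER_GENE_POOL,
                         length.out = n_ped)
    # the tolerance/burden target gene goes to pedigree F2887 when present
    tgt <- match("F2887", layout$pedigree_id)
    if (!is.na(tgt) && tgt != 1L) {
      planted_genes[c(1L, tgt)] <- planted_genes[c(tgt, 1L)]
    }
    if (length(planted_idx))
      gene[planted_idx] <- rep(planted_genes, each = npl)
    enriched_gene <- planted_genes[if (!is.na(tgt)) tgt else 1L]

    # wild-type sequence of the target protein: shared with simulate_pssm so
    # planted missense HGVS.p agrees with the PSSM fixture
    wt_seq <- pssm_wild_type(config$pssm_length, config$conserved_fraction,
                             child_seed(config$seed, 3L))
    transcript <- sprintf("NM_%06d.1",
                          as.integer(factor(gene, levels = unique(gene))))
    exon <- sprintf("Exon %d", sample.int(25L, n_total, replace = TRUE))
    hgvs_c <- sprintf("c.%d%s>%s", sample.int(5000L, n_total, TRUE), ref, alt)
    hgvs_p <- random_hgvs_p(consequence, wt_seq)
    hgvs_p[consequence %in% c("splicing", SILENT_CLASSES)] <- NA_character_
    insilico <- sample(c("damaging", "tolerated", "unknown"), n_total,
                       replace = TRUE, prob = c(0.25, 0.35, 0.40))
    insilico[planted_idx] <- sample(c("damaging", "unknown"),
                                    length(planted_idx), replace = TRUE,
                                    prob = c(0.7, 0.3))

    annotation <- data.frame(
      variant_id = ids, gene = gene, transcript = transcript, exon = exon,
      hgvs_c = hgvs_c, hgvs_p = hgvs_p, consequence = consequence,
      af_control = signif(af, 4), insilico = insilico,
      stringsAsFactors = FALSE)

    variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                           variant_id = ids, qual = qual, af = af,
                           stringsAsFactors = FALSE)

    # genotypes: background under per-sample HWE; planted het in all
    # affected samples of the owning pedigree
    pedigrees <- do.call(rbind, lapply(seq_len(n_ped), function(i) {
      data.frame(pedigree_id = layout$pedigree_id[i],
                 sample_id = sprintf("%s_S%d", layout$pedigree_id[i],
                                     seq_len(layout$n_affected[i])),
                 kinship = layout$kinship[i], stringsAsFactors = FALSE)
    }))

    p_het <- 2 * af * (1 - af)
    p_hom <- af^2
    samples <- list()
    carrier_sets <- list()
    for (s in seq_len(nrow(pedigrees))) {
      sid <- pedigrees$sample_id[s]
      u <- stats::runif(nb)
      gt <- character(nb)
      gt[u < p_hom[seq_len(nb)]] <- "hom_alt"
      gt[u >= p_hom[seq_len(nb)] & u < (p_hom + p_het)[seq_len(nb)]] <- "het"
      idx <- which(nzchar(gt))
      ped_i <- match(pedigrees$pedigree_id[s], layout$pedigree_id)
      own_planted <- if (npl > 0L) nb + (ped_i - 1L) * npl + seq_len(npl)
                     else integer()
      all_idx <- c(idx, own_planted)
      all_gt <- c(gt[idx], rep("het", length(own_planted)))
      ord <- order(all_idx)
      calls <- data.frame(
        variant_id = ids[all_idx][ord], gt = all_gt[ord],
        dp = stats::rpois(length(all_idx), 60) + 1L,
        gq = pmin(99L, stats::rpois(length(all_idx), 70L)),
        stringsAsFactors = FALSE)
      samples[[sid]] <- calls
      carrier_sets[[sid]] <- ids[idx]
    }

    planted <- if (length(planted_idx))
      data.frame(pedigree_id = rep(layout$pedigree_id, each = npl),
                 variant_id = ids[planted_idx], gene = gene[planted_idx],
                 stringsAsFactors = FALSE)
    else
      data.frame(pedigree_id = character(), variant_id = character(),
                 gene = character(), stringsAsFactors = FALSE)

    shared_bg <- do.call(rbind, lapply(unique(pedigrees$pedigree_id),
      function(pid) {
        members <- pedigrees$sample_id[pedigrees$pedigree_id == pid]
        shared <- Reduce(intersect, carrier_sets[members])
        if (length(shared))
          data.frame(pedigree_id = pid, variant_id = shared,
                     stringsAsFactors = FALSE)
        else NULL
      }))
    if (is.null(shared_bg))
      shared_bg <- data.frame(pedigree_id = character(),
                              variant_id = character(),
                              stringsAsFactors = FALSE)

    structure(list(
      variants = variants,
      samples = samples,
      annotation = annotation,
      pedigrees = pedigrees,
      truth = list(planted = planted,
                   planted_shared_variant_ids = planted$variant_id,
                   planted_enriched_gene = enriched_gene,
                   shared_background = shared_bg,
                   planted_hotspots = config$hotspot_positions)
    ), class = "coseg_bundle")
  })
}

#' @export
print.coseg_bundle <- function(x, ...) {
  cat("Synthetic pedigree bundle:", nrow(x$variants), "variants,",
      length(x$samples), "samples,",
      length(unique(x$pedigrees$pedigree_id)), "pedigrees,",
      nrow(x$truth$planted), "planted shared variants\n")
  invisible(x)
}

#' Write one sample's genotype calls as a VCF 4.2 file
#'
#' Emits only the sites present in the sample's call table (carried or
#' missing), with `GT:DP:GQ` genotypes.
#'
#' @param variants Variant table of the bundle (`chrom`, `pos`, `ref`,
#'   `alt`, `variant_id`, `qual`).
#' @param calls One sample's call data frame (`variant_id`, `gt`, `dp`,
#'   `gq`).
#' @param sample_id Sample name for the VCF column header.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sample_vcf <- function(variants, calls, sample_id, path) {
  m <- match(calls$variant_id, variants$variant_id)
  if (anyNA(m)) stop_data("call table references unknown variant ids")
  v <- variants[m, , drop = FALSE]
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=varcoseg-synthetic",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t"))
  rows <- sprintf("%s\t%d\t%s\t%s\t%s\t%.2f\tPASS\t.\tGT:DP:GQ\t%s:%d:%d",
                  v$chrom, v$pos, v$variant_id, v$ref, v$alt, v$qual,
                  gt_code[calls$gt], calls$dp, calls$gq)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write pedigree membership as a 6-column PED file
#'
#' @param pedigrees Data frame `pedigree_id`, `sample_id` (all rows are
#'   sequenced affected individuals).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ped <- function(pedigrees, path) {
  rows <- sprintf("%s\t%s\t0\t0\t2\t2", pedigrees$pedigree_id,
                  pedigrees$sample_id)
  writeLines(rows, path)
  invisible(path)
}

#' Write the kinship sidecar TSV
#'
#' @param pedigrees Data frame with `pedigree_id` and `kinship`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_kinship_tsv <- function(pedigrees, path) {
  kin <- unique(pedigrees[, c("pedigree_id", "kinship")])
  write_tsv_(kin, path)
}

#' Write / read the ANNOVAR-style annotation table
#'
#' Columns: `variant_id`, `gene`, `transcript`, `exon`, `hgvs_c`, `hgvs_p`,
#' `consequence`, `af_control`, `insilico`; tab-separated, `.` for missing.
#'
#' @param annotation Annotation data frame.
#' @param path File path.
#' @return `write_annotation_tsv`: the path, invisibly;
#'   `read_annotation_tsv`: the annotation data frame.
#' @export
write_annotation_tsv <- function(annotation, path) {
  write_tsv_(annotation, path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  ann <- read_tsv_(path)
  need <- c("variant_id", "gene", "consequence")
  if (!all(need %in% names(ann)))
    stop_parse(sprintf("annotation table must contain columns: %s",
                       paste(need, collapse = ", ")))
  if (!"af_control" %in% names(ann)) ann$af_control <- NA_real_
  ann$af_control <- as.numeric(ann$af_control)
  bad <- !is.na(ann$af_control) &
    (ann$af_control < 0 | ann$af_control > 1)
  if (any(bad))
    stop_data("af_control outside [0,1] in annotation table")
  ann
}

#' Write the truth table as JSON
#'
#' @param truth Truth list of a [simulate_pedigree_dataset()] bundle (extra
#'   elements such as planted hotspots are preserved).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a truth JSON file
#' @param path Path written by [write_truth_json()].
#' @return The truth list (data frames restored).
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
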