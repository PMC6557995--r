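# Core variant/pedigree data model: canonical ids, allele normalization,
# VCF/PED readers, and site-level hard filtering.
#
# Conventions (used everywhere downstream):
#   * coordinates are VCF-style 1-based inclusive;
#   * the canonical variant id is "chrom:pos:ref:alt" on the NORMALIZED
#     representation;
#   * a call passes a threshold when value >= threshold (strict fail below).

#' Canonical variant identifier
#'
#' Builds the canonical `"chrom:pos:ref:alt"` id from normalized coordinates.
#'
#' @param chrom,pos,ref,alt Vectors describing one variant per element.
#' @return Character vector of canonical ids.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s:%s", as.character(chrom), as.integer(pos),
          as.character(ref), as.character(alt))
}

# Vectorized allele normalization. Returns list(pos, ref, alt, symbolic).
normalize_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop_data("empty allele in variant record")
  symbolic <- grepl("[^ACGT]", ref) | grepl("[^ACGT]", alt)
  for (i in which(!symbolic)) {
    r <- strsplit(ref[i], "", fixed = TRUE)[[1]]
    a <- strsplit(alt[i], "", fixed = TRUE)[[1]]
    # trim shared suffix, keeping at least one base on each side
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # trim shared prefix, keeping a single anchor base for indels
    p <- pos[i]
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      p <- p + 1L
    }
    pos[i] <- p
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  if (any(!symbolic & ref == alt))
    stop_data("ref and alt alleles are identical after normalization")
  list(pos = pos, ref = ref, alt = alt, symbolic = symbolic)
}

#' Normalize a variant to its minimal representation
#'
#' Trims the shared allele suffix, then the shared prefix (keeping one anchor
#' base for indels) while advancing the position. Idempotent. Variants with
#' symbolic (non-ACGT) alleles are flagged, not dropped: they are returned
#' unchanged with `symbolic = TRUE`.
#'
#' @param variant A list or one-row data frame with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @return A list with `chrom`, `pos`, `ref`, `alt`, `variant_id`,
#'   `symbolic`.
#' @examples
#' normalize_variant(list(chrom = "1", pos = 100, ref = "CT", alt = "CA"))
#' @export
normalize_variant <- function(variant) {
  n <- normalize_alleles(variant$pos, variant$ref, variant$alt)
  list(chrom = as.character(variant$chrom), pos = n$pos, ref = n$ref,
       alt = n$alt,
       variant_id = variant_id(variant$chrom, n$pos, n$ref, n$alt),
       symbolic = n$symbolic)
}

gt_class <- function(alleles, alt_index) {
  # alleles: character vector of allele indices from one GT field
  if (any(alleles == ".")) return("missing")
  copies <- sum(alleles == as.character(alt_index))
  if (copies == 0L) "hom_ref"
  else if (copies == length(alleles)) "hom_alt"
  else "het"
}

#' Read variants and genotype calls from a VCF file
#'
#' Parses a VCF 4.x file (via vcfR), decomposes multi-allelic records into one
#' variant per alternate allele, normalizes alleles, and returns canonical
#' ids. Genotype phase is ignored; a genotype is classified relative to each
#' alternate allele as hom_ref / het / hom_alt / missing.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @return A list with two data frames -- `variants` (`chrom`, `pos`, `ref`,
#'   `alt`, `variant_id`, `qual`, `filter`, `symbolic`; input order
#'   preserved) and `calls` (`variant_id`, `sample_id`, `gt`, `dp`, `gq`) --
#'   plus `samples`, the sample names declared in the header (present even
#'   when the body is empty).
#' @export
read_vcf_calls <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("VCF file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#"))
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L)
    stop_parse("missing #CHROM header row",
               line = if (length(lines)) length(lines) else 1L)
  hdr_fields <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  ncol_expect <- length(hdr_fields)
  hdr_samples <- if (ncol_expect > 9L) hdr_fields[-(1:9)] else character()
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != ncol_expect)
      stop_parse(sprintf("expected %d tab-separated fields, found %d",
                         ncol_expect, nf), line = i)
  }
  empty <- list(
    variants = data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          variant_id = character(), qual = numeric(),
                          filter = character(), symbolic = logical(),
                          stringsAsFactors = FALSE),
    calls = data.frame(variant_id = character(), sample_id = character(),
                       gt = character(), dp = integer(), gq = integer(),
                       stringsAsFactors = FALSE),
    samples = hdr_samples)
  if (length(body) == 0L) return(empty)

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_mat <- if (ncol(v@gt) > 1L) v@gt else NULL
  samples <- if (!is.null(gt_mat)) colnames(gt_mat)[-1L] else character()

  # decompose multi-allelic records: one expanded row per (record, alt)
  alts_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alts <- lengths(alts_list)
  rec <- rep(seq_len(nrow(fix)), n_alts)
  alt_index <- sequence(n_alts)
  norm <- normalize_alleles(fix[rec, "POS"], fix[rec, "REF"],
                            unlist(alts_list))
  ids <- variant_id(fix[rec, "CHROM"], norm$pos, norm$ref, norm$alt)
  variants <- data.frame(
    chrom = fix[rec, "CHROM"], pos = norm$pos, ref = norm$ref,
    alt = norm$alt, variant_id = ids,
    qual = suppressWarnings(as.numeric(fix[rec, "QUAL"])),
    filter = fix[rec, "FILTER"], symbolic = norm$symbolic,
    stringsAsFactors = FALSE, row.names = NULL)

  calls <- empty$calls
  if (length(samples)) {
    fmt_list <- strsplit(gt_mat[, 1L], ":", fixed = TRUE)
    per_sample <- lapply(samples, function(s) {
      f <- strsplit(gt_mat[, s], ":", fixed = TRUE)
      gt_raw <- dp <- gq <- rep(NA_character_, nrow(fix))
      for (r in seq_len(nrow(fix))) {
        fmt <- fmt_list[[r]]
        gt_i <- match("GT", fmt); dp_i <- match("DP", fmt)
        gq_i <- match("GQ", fmt)
        fr <- f[[r]]
        if (!is.na(gt_i) && length(fr) >= gt_i) gt_raw[r] <- fr[gt_i]
        if (!is.na(dp_i) && length(fr) >= dp_i) dp[r] <- fr[dp_i]
        if (!is.na(gq_i) && length(fr) >= gq_i) gq[r] <- fr[gq_i]
      }
      alleles <- strsplit(ifelse(is.na(gt_raw), ".", gt_raw), "[/|]")
      gt <- vapply(seq_along(rec), function(k)
        gt_class(alleles[[rec[k]]], alt_index[k]), character(1))
      data.frame(variant_id = ids, sample_id = s, gt = gt,
                 dp = suppressWarnings(as.integer(dp[rec])),
                 gq = suppressWarnings(as.integer(gq[rec])),
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    calls <- do.call(rbind, per_sample)
  }
  list(variants = variants, calls = calls, samples = hdr_samples)
}

#' Hard-filter thresholds
#'
#' Site/genotype-level thresholds for [hard_filter()]. The boundary
#' convention is: a value passes when `value >= threshold` for minimum-type
#' thresholds; site rules state their own comparator. The exact values used
#' by any given study are configuration, not constants; defaults are
#' permissive (everything passes).
#'
#' @param min_depth,min_gq,min_qual Non-negative minima for genotype depth,
#'   genotype quality, and site QUAL.
#' @param site_rules List of rules, each a list with `field`, `op` (one of
#'   `>=`, `<=`, `>`, `<`, `==`), and `value`, evaluated against named site
#'   fields (e.g. INFO-derived annotations such as QD or FS).
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_depth = 0L, min_gq = 0L, min_qual = 0,
                              site_rules = list()) {
  if (min_depth < 0 || min_gq < 0 || min_qual < 0)
    stop_config("thresholds must be non-negative")
  for (rule in site_rules) {
    if (!all(c("field", "op", "value") %in% names(rule)))
      stop_config("each site rule needs field, op, value", "site_rules")
    if (!rule$op %in% c(">=", "<=", ">", "<", "=="))
      stop_config(sprintf("unsupported comparator '%s'", rule$op),
                  "site_rules")
  }
  structure(list(min_depth = min_depth, min_gq = min_gq, min_qual = min_qual,
                 site_rules = site_rules), class = "filter_thresholds")
}

#' Site-level hard filter
#'
#' Applies hard thresholds to one variant and its genotype calls. A record
#' fails iff any threshold is violated; every violated threshold is listed as
#' a reason. Missing genotypes carry no depth/quality requirement. Pure
#' function of its inputs.
#'
#' @param variant List/one-row data frame with at least `qual`; additional
#'   named site fields (or a nested `info` list) are visible to site rules.
#' @param calls Data frame of genotype calls with `gt`, `dp`, `gq`.
#' @param thresholds A [filter_thresholds()] object.
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   violated threshold names).
#' @export
hard_filter <- function(variant, calls, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  reasons <- character()
  genotyped <- calls[!is.na(calls$gt) & calls$gt != "missing", , drop = FALSE]
  if (nrow(genotyped)) {
    dp <- genotyped$dp[!is.na(genotyped$dp)]
    gq <- genotyped$gq[!is.na(genotyped$gq)]
    if (length(dp) && any(dp < thresholds$min_depth))
      reasons <- c(reasons, "min_depth")
    if (length(gq) && any(gq < thresholds$min_gq))
      reasons <- c(reasons, "min_gq")
  }
  qual <- variant$qual
  if (!is.null(qual) && !is.na(qual) && qual < thresholds$min_qual)
    reasons <- c(reasons, "min_qual")
  site <- variant
  if (!is.null(variant$info)) site <- c(variant, variant$info)
  for (rule in thresholds$site_rules) {
    val <- site[[rule$field]]
    if (is.null(val))
      stop_config(sprintf("unknown site field '%s' in filter expression",
                          rule$field), "site_rules")
    ok <- switch(rule$op,
                 ">=" = val >= rule$value,
                 "<=" = val <= rule$value,
                 ">"  = val >  rule$value,
                 "<"  = val <  rule$value,
                 "==" = val == rule$value)
    if (!isTRUE(ok)) reasons <- c(reasons, rule$field)
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

# Vectorized equivalent of hard_filter() over a whole variant table; used by
# the pipeline. Site rules are delegated to hard_filter() row by row only
# when rules are configured.
hard_filter_table <- function(variants, calls, thresholds) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  n <- nrow(variants)
  reasons <- vector("list", n)
  if (!is.null(calls) && nrow(calls)) {
    genotyped <- calls[!is.na(calls$gt) & calls$gt != "missing", ,
                       drop = FALSE]
    if (nrow(genotyped)) {
      min_dp <- tapply(genotyped$dp, genotyped$variant_id, min, na.rm = TRUE)
      min_gq <- tapply(genotyped$gq, genotyped$variant_id, min, na.rm = TRUE)
      dp <- min_dp[variants$variant_id]
      gq <- min_gq[variants$variant_id]
      dp_fail <- !is.na(dp) & is.finite(dp) & dp < thresholds$min_depth
      gq_fail <- !is.na(gq) & is.finite(gq) & gq < thresholds$min_gq
      for (i in which(dp_fail)) reasons[[i]] <- c(reasons[[i]], "min_depth")
      for (i in which(gq_fail)) reasons[[i]] <- c(reasons[[i]], "min_gq")
    }
  }
  q_fail <- !is.na(variants$qual) & variants$qual < thresholds$min_qual
  for (i in which(q_fail)) reasons[[i]] <- c(reasons[[i]], "min_qual")
  if (length(thresholds$site_rules)) {
    for (i in seq_len(n)) {
      r <- hard_filter(variants[i, ],
                       data.frame(gt = character(), dp = integer(),
                                  gq = integer()),
                       filter_thresholds(site_rules = thresholds$site_rules))
      reasons[[i]] <- c(reasons[[i]], r$reasons)
    }
  }
  list(pass = lengths(reasons) == 0L, reasons = reasons)
}

#' Read pedigree membership and kinship
#'
#' Reads a 6-column pre-MAKEPED PED file (family, individual, father, mother,
#' sex, affection; affection 2 = affected) plus a kinship sidecar TSV
#' (`pedigree_id`, `kinship`). Only affected individuals that are sequenced
#' (present in `vcf_samples`, when given) enter a pedigree's sample list.
#'
#' @param ped_path Path to the PED file.
#' @param kinship_path Path to the kinship sidecar TSV.
#' @param vcf_samples Optional character vector of sample ids present in the
#'   VCF set; every such sample must appear in the PED file.
#' @return Data frame with one row per sequenced affected sample:
#'   `pedigree_id`, `sample_id`, `kinship`. Pedigrees with no such sample are
#'   dropped.
#' @export
read_pedigree <- function(ped_path, kinship_path, vcf_samples = NULL) {
  ped <- utils::read.table(ped_path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("pedigree_id", "sample_id",
                                         "father", "mother", "sex",
                                         "affection"))
  if (anyDuplicated(ped$sample_id))
    stop_data(sprintf("duplicate sample id in PED: %s",
                      ped$sample_id[duplicated(ped$sample_id)][1L]))
  kin <- read_tsv_(kinship_path)
  if (!all(c("pedigree_id", "kinship") %in% names(kin)))
    stop_data("kinship sidecar needs columns pedigree_id, kinship")
  if (!is.null(vcf_samples)) {
    unknown <- setdiff(vcf_samples, ped$sample_id)
    if (length(unknown))
      stop_data(sprintf("VCF sample(s) not present in PED: %s",
                        paste(unknown, collapse = ", ")))
  }
  keep <- ped$affection == 2
  if (!is.null(vcf_samples)) keep <- keep & ped$sample_id %in% vcf_samples
  out <- ped[keep, c("pedigree_id", "sample_id")]
  out$kinship <- kin$kinship[match(out$pedigree_id, kin$pedigree_id)]
  rownames(out) <- NULL
  out
}
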