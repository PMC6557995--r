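# Synthetic somatic mutation spectrum with planted hotspot residues, plus the
# MAF-like TSV dialect used to exchange mutation lists.

DEFAULT_TYPE_TOTALS <- c(UCEC = 500L, STAD = 440L, SKCM = 360L,
                         BRCA = 1000L, COAD = 600L, LUAD = 560L)
DEFAULT_TYPE_ENRICHMENT <- c(UCEC = 8, STAD = 4, SKCM = 4)

#' Construct a somatic mutation spectrum
#'
#' @param gene Gene symbol.
#' @param protein_length Protein length L (>= 1).
#' @param missense_counts Integer vector of per-residue missense counts
#'   (length L).
#' @param truncating_count Number of truncating (frameshift / stopgain /
#'   splice) mutations.
#' @param per_cancer_type Optional data frame `cancer_type`, `mutated`,
#'   `total` (mutated sample count and cohort size per cancer type).
#' @param n_fusion Fusion events observed (reported, excluded from all
#'   statistics).
#' @return Object of class `mutation_spectrum` with the total non-silent
#'   count `n_nonsilent = sum(missense_counts) + truncating_count`.
#' @export
mutation_spectrum <- function(gene, protein_length, missense_counts,
                              truncating_count = 0L, per_cancer_type = NULL,
                              n_fusion = 0L) {
  if (!is_count(protein_length, 1))
    stop_config("protein_length must be >= 1", "protein_length")
  missense_counts <- as.integer(missense_counts)
  if (length(missense_counts) != protein_length)
    stop_data("missense_counts must have one entry per residue")
  if (any(missense_counts < 0) || truncating_count < 0)
    stop_data("mutation counts must be non-negative")
  if (!is.null(per_cancer_type)) {
    if (!all(c("cancer_type", "mutated", "total") %in% names(per_cancer_type)))
      stop_data("per_cancer_type needs cancer_type, mutated, total")
    if (any(per_cancer_type$mutated > per_cancer_type$total))
      stop_data("mutated sample count exceeds cancer-type total")
  }
  structure(list(gene = gene, protein_length = as.integer(protein_length),
                 missense_counts = missense_counts,
                 truncating_count = as.integer(truncating_count),
                 n_nonsilent = sum(missense_counts) +
                   as.integer(truncating_count),
                 per_cancer_type = per_cancer_type,
                 n_fusion = as.integer(n_fusion)),
            class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("Somatic spectrum of ", x$gene, ": ", sum(x$missense_counts),
      " missense + ", x$truncating_count, " truncating over ",
      x$protein_length, " residues", sep = "")
  if (x$n_fusion) cat(" (+", x$n_fusion, "fusions, excluded)")
  cat("\n")
  invisible(x)
}

#' Simulate a somatic mutation spectrum with planted hotspots
#'
#' Missense positions are drawn from the mixture
#' `hotspot_mass` x uniform(hotspots) + `(1 - hotspot_mass)` x uniform(1..L),
#' so total counts are conserved exactly and `hotspot_mass = 0` reduces to a
#' uniform multinomial over residues. Mutations are assigned to cancer types
#' and patient samples (a few patients carry two mutations); optional
#' truncating mutations take uniform positions.
#'
#' @param length Protein length L.
#' @param n_mutations Number of somatic missense mutations.
#' @param hotspots Residue indices within `[1, length]`.
#' @param hotspot_mass Fraction of missense mass placed on the hotspots.
#' @param seed Integer seed.
#' @param n_truncating Truncating mutation count (default 0).
#' @param type_totals Named integer vector of per-cancer-type sample totals.
#' @param type_enrichment Named multipliers inflating selected types'
#'   mutation share (emulating type-specific enrichment).
#' @param gene Gene symbol for the spectrum.
#' @return A [mutation_spectrum()]; the individual mutation rows (columns
#'   `gene`, `protein_pos`, `consequence`, `cancer_type`, `sample_id`) are
#'   attached as attribute `mutations`.
#' @export
simulate_somatic_spectrum <- function(length, n_mutations,
                                      hotspots = integer(),
                                      hotspot_mass = 0, seed = 1L,
                                      n_truncating = 0L,
                                      type_totals = DEFAULT_TYPE_TOTALS,
                                      type_enrichment = DEFAULT_TYPE_ENRICHMENT,
                                      gene = "NCK1") {
  if (!is_count(length, 1)) stop_config("length must be >= 1", "length")
  if (!is_fraction(hotspot_mass))
    stop_config("hotspot_mass must lie in [0,1]", "hotspot_mass")
  hotspots <- as.integer(hotspots)
  if (any(hotspots < 1L | hotspots > length))
    stop_config("hotspot positions must lie within [1, length]", "hotspots")
  if (hotspot_mass > 0 && !length(hotspots))
    stop_config("hotspot_mass > 0 requires hotspot positions", "hotspots")
  with_seed(seed, {
    prob <- rep((1 - hotspot_mass) / length, length)
    if (length(hotspots))
      prob[hotspots] <- prob[hotspots] + hotspot_mass / base::length(hotspots)
    counts <- if (n_mutations > 0)
      as.integer(stats::rmultinom(1L, n_mutations, prob))
    else integer(length)

    n_all <- n_mutations + n_truncating
    pos <- c(rep(seq_len(length), counts),
             if (n_truncating > 0) sample.int(length, n_truncating, TRUE))
    consequence <- c(rep("missense", n_mutations),
                     if (n_truncating > 0)
                       sample(TRUNCATING_CLASSES, n_truncating, TRUE))
    mult <- rep(1, base::length(type_totals))
    names(mult) <- names(type_totals)
    mult[names(type_enrichment)] <- type_enrichment
    mutations <- if (n_all > 0) {
      types <- sample(names(type_totals), n_all, replace = TRUE,
                      prob = as.numeric(type_totals) * mult)
      # ~5% of patients carry two mutations
      pool <- sprintf("T%05d", seq_len(max(1L, round(n_all * 0.95))))
      data.frame(gene = gene, protein_pos = pos, consequence = consequence,
                 cancer_type = types,
                 sample_id = sample(pool, n_all, replace = TRUE),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = character(), protein_pos = integer(),
                 consequence = character(), cancer_type = character(),
                 sample_id = character(), stringsAsFactors = FALSE)
    }
    per_type <- data.frame(
      cancer_type = names(type_totals),
      mutated = vapply(names(type_totals), function(tt)
        base::length(unique(mutations$sample_id[mutations$cancer_type == tt])),
        integer(1)),
      total = as.integer(type_totals),
      stringsAsFactors = FALSE, row.names = NULL)
    out <- mutation_spectrum(gene, length, counts,
                             truncating_count = n_truncating,
                             per_cancer_type = per_type)
    attr(out, "mutations") <- mutations
    out
  })
}

#' Write / read a somatic mutation list (minimal MAF-like TSV)
#'
#' Columns: `gene`, `protein_pos`, `aa_ref`, `aa_alt`, `consequence`,
#' `cancer_type`, `sample_id`. When a PSSM is supplied to the writer,
#' `aa_ref` is the PSSM wild-type residue at the mutated position (so the
#' list is scoreable against that matrix).
#'
#' @param spectrum A [mutation_spectrum()] carrying a `mutations` attribute,
#'   or a mutation data frame with the columns above (minus `aa_ref`,
#'   `aa_alt`).
#' @param path File path.
#' @param pssm Optional [pssm()] used to fill `aa_ref` consistently.
#' @return `write_somatic_tsv`: the path, invisibly; `read_somatic_tsv`: the
#'   mutation data frame.
#' @export
write_somatic_tsv <- function(spectrum, path, pssm = NULL) {
  muts <- if (inherits(spectrum, "mutation_spectrum"))
    attr(spectrum, "mutations") else spectrum
  if (is.null(muts)) stop_data("spectrum carries no mutation rows")
  n <- nrow(muts)
  if (is.null(muts$aa_ref)) {
    muts$aa_ref <- if (!is.null(pssm)) pssm$wild_type[muts$protein_pos]
    else sample(AA_ALPHABET, n, replace = TRUE)
  }
  if (is.null(muts$aa_alt)) {
    muts$aa_alt <- vapply(muts$aa_ref, function(w)
      sample(setdiff(AA_ALPHABET, w), 1L), character(1), USE.NAMES = FALSE)
  }
  not_mis <- muts$consequence != "missense"
  muts$aa_alt[not_mis] <- NA_character_
  write_tsv_(muts[, c("gene", "protein_pos", "aa_ref", "aa_alt",
                      "consequence", "cancer_type", "sample_id")], path)
}

#' @rdname write_somatic_tsv
#' @export
read_somatic_tsv <- function(path) {
  muts <- read_tsv_(path)
  need <- c("gene", "protein_pos", "consequence")
  if (!all(need %in% names(muts)))
    stop_parse(sprintf("somatic table must contain columns: %s",
                       paste(need, collapse = ", ")))
  muts$protein_pos <- as.integer(muts$protein_pos)
  muts
}

#' Build a mutation spectrum from a somatic mutation list
#'
#' Missense rows become per-residue counts; frameshift/stopgain/splicing rows
#' are counted as truncating; fusion rows are tallied separately and excluded
#' from all statistics. Per-cancer-type mutated sample counts are derived
#' from the list; cohort totals come from `type_totals`.
#'
#' @param mutations Mutation data frame (see [read_somatic_tsv()]).
#' @param protein_length Protein length L.
#' @param gene Gene to subset to (default: the only gene present).
#' @param type_totals Optional named vector of per-cancer-type sample totals;
#'   when omitted, `per_cancer_type` is left `NULL`.
#' @return A [mutation_spectrum()].
#' @export
spectrum_from_mutations <- function(mutations, protein_length, gene = NULL,
                                    type_totals = NULL) {
  if (is.null(gene)) {
    genes <- unique(mutations$gene)
    if (length(genes) > 1L)
      stop_data("mutation list covers several genes; pass `gene`")
    gene <- if (length(genes)) genes else NA_character_
  }
  muts <- mutations[is.na(mutations$gene) | mutations$gene == gene, ,
                    drop = FALSE]
  n_fusion <- sum(muts$consequence == "fusion")
  muts <- muts[muts$consequence != "fusion", , drop = FALSE]
  if (any(!is.na(muts$protein_pos) &
          (muts$protein_pos < 1L | muts$protein_pos > protein_length)))
    stop_data("protein position outside [1, protein_length]")
  mis <- muts[muts$consequence == "missense", , drop = FALSE]
  counts <- tabulate(mis$protein_pos, nbins = protein_length)
  truncating <- sum(muts$consequence %in% TRUNCATING_CLASSES)
  per_type <- NULL
  if (!is.null(type_totals)) {
    per_type <- data.frame(
      cancer_type = names(type_totals),
      mutated = vapply(names(type_totals), function(tt)
        length(unique(muts$sample_id[muts$cancer_type == tt])), integer(1)),
      total = as.integer(type_totals),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  mutation_spectrum(gene, protein_length, counts,
                    truncating_count = truncating,
                    per_cancer_type = per_type, n_fusion = n_fusion)
}
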