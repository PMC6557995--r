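# Pedigree co-segregation filtering: variants carried by every sequenced
# affected relative, restricted to rare non-silent consequences, optionally
# intersected with a cancer-germline variant set.
#
# "Shared" means carrier status (>= 1 alternate allele, het or hom-alt) in
# every sequenced affected sample, evaluated on the decomposed, normalized
# representation -- a dominant-model criterion, not genotype identity. A
# missing genotype excludes the variant (precision-favoring) unless
# `missing_as_carrier` relaxes it.

#' Variants shared by all affected relatives of a pedigree
#'
#' @param samples Named list of per-sample call data frames (`variant_id`,
#'   `gt`), e.g. the `samples` element of a bundle or per-sample
#'   [read_vcf_calls()] results. A variant absent from a sample's table is a
#'   non-carrier for that sample.
#' @param pedigree_samples Character vector of the pedigree's sequenced
#'   affected sample ids; each must be present in `samples`.
#' @param missing_as_carrier Treat missing genotypes as carriers (default
#'   `FALSE`: missing excludes).
#' @return Sorted character vector of canonical variant ids carried by every
#'   listed sample.
#' @export
shared_candidates <- function(samples, pedigree_samples,
                              missing_as_carrier = FALSE) {
  if (length(pedigree_samples) < 1L)
    stop_data("pedigree has no sequenced affected samples")
  absent <- setdiff(pedigree_samples, names(samples))
  if (length(absent))
    stop_data(sprintf("pedigree sample(s) absent from call set: %s",
                      paste(absent, collapse = ", ")))
  carrier_gt <- c("het", "hom_alt", if (missing_as_carrier) "missing")
  sets <- lapply(pedigree_samples, function(s) {
    calls <- samples[[s]]
    unique(calls$variant_id[calls$gt %in% carrier_gt])
  })
  sort(Reduce(intersect, sets))
}

#' Keep rare non-silent variants
#'
#' Retains variants whose consequence is protein-altering (missense,
#' frameshift, stopgain, splicing) and whose control allele frequency is
#' absent (treated as rare) or at most `af_max`. Variants missing from the
#' annotation are routed to the reject list with reason `"unannotated"`, not
#' raised as errors.
#'
#' @param ids Character vector of canonical variant ids.
#' @param annotation Annotation data frame (`variant_id`, `consequence`,
#'   `af_control`).
#' @param af_max Rarity threshold on the control allele frequency.
#' @return List with `kept` (character vector) and `rejected` (data frame
#'   `variant_id`, `reason` in `unannotated` / `silent` / `common`).
#' @export
filter_rare_nonsilent <- function(ids, annotation, af_max = 0.001) {
  if (!is_fraction(af_max)) stop_config("af_max must lie in [0,1]", "af_max")
  m <- match(ids, annotation$variant_id)
  reason <- rep(NA_character_, length(ids))
  reason[is.na(m)] <- "unannotated"
  known <- !is.na(m)
  cons <- annotation$consequence[m[known]]
  af <- annotation$af_control[m[known]]
  silent <- !(cons %in% NONSILENT_CLASSES)
  common <- !silent & !is.na(af) & af > af_max
  reason[known][silent] <- "silent"
  reason[known][common] <- "common"
  list(kept = ids[is.na(reason)],
       rejected = data.frame(variant_id = ids[!is.na(reason)],
                             reason = reason[!is.na(reason)],
                             stringsAsFactors = FALSE))
}

#' Co-occurrence with a derived cancer-germline variant set
#'
#' @param ids Canonical variant ids to test.
#' @param germline_ids Variant id set produced by
#'   [derive_germline_subset()].
#' @return Named logical vector: `TRUE` where the id occurs in the derived
#'   set.
#' @export
cohort_cooccurrence <- function(ids, germline_ids) {
  stats::setNames(ids %in% germline_ids, ids)
}
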