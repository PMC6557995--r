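# ACMG-AMP-style five-tier classification.
#
# Two deliberately separate layers:
#   * combine_acmg() -- the published evidence-combination table, faithful
#     and exhaustively tested;
#   * assign_evidence() -- a simplified, configuration-driven mapping from
#     variant context to evidence codes (the per-criterion usage of any given
#     study is rarely recoverable; this mapping is this package's documented
#     choice).
# Any co-fired pathogenic- and benign-direction evidence yields uncertain
# significance (the conservative conflict reading).

PATH_STRENGTHS <- c("very_strong", "strong", "moderate", "supporting")
BENIGN_STRENGTHS <- c("stand_alone", "strong", "supporting")
ACMG_TIERS <- c("benign", "likely_benign", "uncertain_significance",
                "likely_pathogenic", "pathogenic")

#' Construct an evidence code
#'
#' @param code Label (e.g. `"PVS1"`, `"PM2"`, `"BA1"`).
#' @param direction `"pathogenic"` or `"benign"`.
#' @param strength One of `very_strong`, `strong`, `moderate`, `supporting`
#'   (pathogenic direction) or `stand_alone`, `strong`, `supporting` (benign
#'   direction). `stand_alone` is benign-only; `very_strong` is
#'   pathogenic-only.
#' @return One-row data frame `code`, `direction`, `strength`.
#' @export
evidence_code <- function(code, direction, strength) {
  if (!direction %in% c("pathogenic", "benign"))
    stop_data(sprintf("unknown evidence direction '%s'", direction))
  ok <- if (direction == "pathogenic") strength %in% PATH_STRENGTHS
        else strength %in% BENIGN_STRENGTHS
  if (!ok)
    stop_data(sprintf("strength '%s' is not valid for %s evidence",
                      strength, direction))
  data.frame(code = code, direction = direction, strength = strength,
             stringsAsFactors = FALSE)
}

#' Assign evidence codes from variant context
#'
#' Deterministic simplified mapping:
#' * truncating consequence in a known loss-of-function gene -> `PVS1`
#'   (very strong pathogenic);
#' * absent in controls (control AF missing or below `absent_af`) -> `PM2`
#'   (moderate pathogenic);
#' * co-segregation across affected relatives -> `PP1` (supporting);
#' * in-silico damaging -> `PP3` (supporting);
#' * common in controls (control AF > `benign_af`) -> `BA1` (stand-alone
#'   benign).
#'
#' @param consequence Consequence class of the variant.
#' @param control_af Control allele frequency (`NA` when unobserved).
#' @param insilico `"damaging"`, `"tolerated"` or `"unknown"`.
#' @param shared_in_pedigree Did the variant co-segregate among affected
#'   relatives?
#' @param known_lof_gene Is the gene a known loss-of-function disease gene?
#' @param benign_af Stand-alone benign frequency threshold.
#' @param absent_af Frequency below which a variant counts as absent from
#'   controls.
#' @return Data frame of evidence codes (possibly 0 rows).
#' @export
assign_evidence <- function(consequence, control_af = NA,
                            insilico = "unknown",
                            shared_in_pedigree = FALSE,
                            known_lof_gene = FALSE,
                            benign_af = 0.05, absent_af = 1e-5) {
  ev <- list()
  if (consequence %in% TRUNCATING_CLASSES && isTRUE(known_lof_gene))
    ev <- c(ev, list(evidence_code("PVS1", "pathogenic", "very_strong")))
  absent <- is.na(control_af) || control_af < absent_af
  common <- !is.na(control_af) && control_af > benign_af
  if (absent)
    ev <- c(ev, list(evidence_code("PM2", "pathogenic", "moderate")))
  if (isTRUE(shared_in_pedigree))
    ev <- c(ev, list(evidence_code("PP1", "pathogenic", "supporting")))
  if (identical(insilico, "damaging"))
    ev <- c(ev, list(evidence_code("PP3", "pathogenic", "supporting")))
  if (common)
    ev <- c(ev, list(evidence_code("BA1", "benign", "stand_alone")))
  if (length(ev)) do.call(rbind, ev)
  else data.frame(code = character(), direction = character(),
                  strength = character(), stringsAsFactors = FALSE)
}

#' Combine evidence codes into a five-tier verdict
#'
#' Implements the published ACMG-AMP combining table. Empty evidence, an
#' unmatched combination, or any conflict (at least one pathogenic-direction
#' and one benign-direction code fired) gives uncertain significance.
#'
#' @param evidence Data frame with `direction` and `strength` (e.g. from
#'   [assign_evidence()] or rbind-ed [evidence_code()] rows).
#' @return List with `tier` (one of `pathogenic`, `likely_pathogenic`,
#'   `uncertain_significance`, `likely_benign`, `benign`) and
#'   `triggered_rule` (name of the combination that fired).
#' @export
combine_acmg <- function(evidence) {
  if (nrow(evidence) == 0L)
    return(list(tier = "uncertain_significance",
                triggered_rule = "no_evidence"))
  for (i in seq_len(nrow(evidence))) {
    evidence_code(evidence$code[i], evidence$direction[i],
                  evidence$strength[i])  # validates the pair
  }
  path <- evidence[evidence$direction == "pathogenic", , drop = FALSE]
  ben <- evidence[evidence$direction == "benign", , drop = FALSE]
  if (nrow(path) && nrow(ben))
    return(list(tier = "uncertain_significance",
                triggered_rule = "conflicting_evidence"))
  pvs <- sum(path$strength == "very_strong")
  ps  <- sum(path$strength == "strong")
  pm  <- sum(path$strength == "moderate")
  pp  <- sum(path$strength == "supporting")
  ba  <- sum(ben$strength == "stand_alone")
  bs  <- sum(ben$strength == "strong")
  bp  <- sum(ben$strength == "supporting")

  verdict <- function(tier, rule) list(tier = tier, triggered_rule = rule)
  # pathogenic combinations
  if (pvs >= 1 && ps >= 1) return(verdict("pathogenic", "PVS+PS"))
  if (pvs >= 1 && pm >= 2) return(verdict("pathogenic", "PVS+2PM"))
  if (pvs >= 1 && pm >= 1 && pp >= 1)
    return(verdict("pathogenic", "PVS+PM+PP"))
  if (pvs >= 1 && pp >= 2) return(verdict("pathogenic", "PVS+2PP"))
  if (ps >= 2) return(verdict("pathogenic", "2PS"))
  if (ps >= 1 && pm >= 3) return(verdict("pathogenic", "PS+3PM"))
  if (ps >= 1 && pm >= 2 && pp >= 2)
    return(verdict("pathogenic", "PS+2PM+2PP"))
  if (ps >= 1 && pm >= 1 && pp >= 4)
    return(verdict("pathogenic", "PS+PM+4PP"))
  # likely pathogenic combinations
  if (pvs >= 1 && pm >= 1) return(verdict("likely_pathogenic", "PVS+PM"))
  if (ps >= 1 && pm >= 1) return(verdict("likely_pathogenic", "PS+PM"))
  if (ps >= 1 && pp >= 2) return(verdict("likely_pathogenic", "PS+2PP"))
  if (pm >= 3) return(verdict("likely_pathogenic", "3PM"))
  if (pm >= 2 && pp >= 2) return(verdict("likely_pathogenic", "2PM+2PP"))
  if (pm >= 1 && pp >= 4) return(verdict("likely_pathogenic", "PM+4PP"))
  # benign combinations
  if (ba >= 1) return(verdict("benign", "BA_standalone"))
  if (bs >= 2) return(verdict("benign", "2BS"))
  if (bs >= 1 && bp >= 1) return(verdict("likely_benign", "BS+BP"))
  if (bp >= 2) return(verdict("likely_benign", "2BP"))
  verdict("uncertain_significance", "no_rule_met")
}
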