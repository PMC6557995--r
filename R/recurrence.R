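# Somatic recurrence statistics: windowed binomial hotspot scan,
# 20/20-rule oncogene / tumor-suppressor classification, and per-cancer-type
# binomial enrichment.

#' Windowed binomial hotspot scan
#'
#' For each residue `i`, counts missense mutations in the window
#' `[i - w, i + w]` clipped to `[1, L]` and computes the upper-tail binomial
#' probability `P(X >= count)` with `X ~ Binomial(N_missense, |window| / L)`
#' (the length-normalized background). P-values are Bonferroni-adjusted over
#' the `L` tests; a residue is a hotspot when the adjusted p-value is below
#' `alpha`. The transparent fixed-halfwidth window replaces boundary
#' heuristics of dedicated hotspot packages.
#'
#' @param spectrum A [mutation_spectrum()].
#' @param window_halfwidth Non-negative integer half-width `w` (default 2).
#' @param alpha Family-wise significance level (default 0.001).
#' @return Data frame `residue`, `window_start`, `window_end`,
#'   `count_in_window`, `p_raw`, `p_adjusted`, `is_hotspot`.
#' @export
hotspot_scan <- function(spectrum, window_halfwidth = 2L, alpha = 0.001) {
  stopifnot(inherits(spectrum, "mutation_spectrum"))
  w <- window_halfwidth
  if (!is_count(w, 0)) stop_config("window_halfwidth must be >= 0",
                                   "window_halfwidth")
  if (!is_fraction(alpha)) stop_config("alpha must lie in [0,1]", "alpha")
  L <- spectrum$protein_length
  counts <- spectrum$missense_counts
  n_mis <- sum(counts)
  i <- seq_len(L)
  lo <- pmax(1L, i - w)
  hi <- pmin(L, i + w)
  cs <- cumsum(c(0L, counts))
  in_window <- cs[hi + 1L] - cs[lo]
  size <- hi - lo + 1L
  # upper tail P(X >= x); x = 0 gives 1 exactly
  p_raw <- stats::pbinom(in_window - 1L, n_mis, size / L,
                         lower.tail = FALSE)
  p_raw[in_window == 0L] <- 1
  p_adj <- pmin(1, L * p_raw)
  data.frame(residue = i, window_start = lo, window_end = hi,
             count_in_window = in_window, p_raw = p_raw,
             p_adjusted = p_adj, is_hotspot = p_adj < alpha)
}

#' 20/20-rule oncogene / tumor-suppressor classification
#'
#' A residue is recurrent when it carries at least `recurrence_min` missense
#' mutations. The oncogene fraction is the share of missense mutations at
#' recurrent residues among all missense mutations; the tumor-suppressor
#' fraction is the share of truncating mutations among all non-silent
#' mutations. Labels require the fraction to be strictly greater than
#' `threshold` ("more than 20 percent"); a gene exceeding both thresholds is
#' `"both"`, one exceeding neither is `"neither"`.
#'
#' @param spectrum A [mutation_spectrum()] with at least one non-silent
#'   mutation.
#' @param recurrence_min Minimum missense count defining a recurrent residue
#'   (default 2).
#' @param threshold Classification threshold (default 0.20).
#' @return List with `label` (`oncogene_like`, `tsg_like`, `both`,
#'   `neither`), `oncogene_fraction`, `tsg_fraction`, `recurrent_residues`.
#' @export
classify_20_20 <- function(spectrum, recurrence_min = 2L, threshold = 0.20) {
  stopifnot(inherits(spectrum, "mutation_spectrum"))
  if (spectrum$n_nonsilent < 1L)
    stop_data("spectrum has no non-silent mutations")
  counts <- spectrum$missense_counts
  n_mis <- sum(counts)
  recurrent <- which(counts >= recurrence_min)
  onco_frac <- if (n_mis > 0) sum(counts[recurrent]) / n_mis else 0
  tsg_frac <- spectrum$truncating_count / spectrum$n_nonsilent
  onco <- onco_frac > threshold   # strictly "more than"
  tsg <- tsg_frac > threshold
  label <- if (onco && tsg) "both"
           else if (onco) "oncogene_like"
           else if (tsg) "tsg_like"
           else "neither"
  list(label = label, oncogene_fraction = onco_frac, tsg_fraction = tsg_frac,
       recurrent_residues = recurrent)
}

#' Per-cancer-type binomial enrichment
#'
#' For each cancer type with `x` mutated samples out of `n`, computes the
#' upper-tail exact binomial probability `P(X >= x | n, rate)`. The
#' background rate defaults to the pooled mutated fraction across all types;
#' Benjamini-Hochberg adjustment is applied across types.
#'
#' @param spectrum A [mutation_spectrum()] with a `per_cancer_type` table.
#' @param background_rate Optional fixed background rate; default pooled.
#' @return Data frame `cancer_type`, `mutated`, `total`, `rate`, `p_raw`,
#'   `p_adjusted`, ordered by `p_raw`.
#' @export
cancer_type_enrichment <- function(spectrum, background_rate = NULL) {
  stopifnot(inherits(spectrum, "mutation_spectrum"))
  tab <- spectrum$per_cancer_type
  if (is.null(tab) || nrow(tab) == 0L)
    stop_data("spectrum has no per-cancer-type table")
  if (any(tab$total <= 0)) stop_data("cancer-type totals must be positive")
  if (any(tab$mutated > tab$total))
    stop_data("mutated sample count exceeds total")
  rate <- if (is.null(background_rate)) sum(tab$mutated) / sum(tab$total)
          else background_rate
  if (!is_fraction(rate)) stop_config("background rate must lie in [0,1]",
                                      "background_rate")
  p_raw <- stats::pbinom(tab$mutated - 1L, tab$total, rate,
                         lower.tail = FALSE)
  p_raw[tab$mutated == 0L] <- 1
  out <- data.frame(cancer_type = tab$cancer_type, mutated = tab$mutated,
                    total = tab$total, rate = rate, p_raw = p_raw,
                    p_adjusted = stats::p.adjust(p_raw, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_raw, out$cancer_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}
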