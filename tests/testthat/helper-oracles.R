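# Independent oracles used across the suite.  Each recomputes the quantity
# under test from first principles, by a different route than the package.

# Two-sided Fisher p by explicit enumeration of every admissible table with
# the observed margins; log-probabilities from binomial coefficients.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || k == 0 || k == n) return(1)
  xs <- max(0, k - r2):min(k, r1)
  lp <- lchoose(r1, xs) + lchoose(r2, k - xs) - lchoose(n, k)
  pr <- exp(lp)
  obs <- pr[xs == a]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Upper-tail binomial P(X >= x) by term-wise summation of the density.
binom_tail_oracle <- function(x, n, p) {
  if (x <= 0) return(1)
  if (x > n) return(0)
  ks <- x:n
  if (p == 0) return(0)
  if (p == 1) return(1)
  sum(exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)))
}

# Hand-coded ACMG-AMP combining table over evidence-strength counts
# (pvs, ps, pm, pp pathogenic; ba, bs, bp benign).  Data-driven encoding,
# independent of the package's rule cascade.
acmg_oracle <- function(pvs, ps, pm, pp, ba, bs, bp) {
  if ((pvs + ps + pm + pp) > 0 && (ba + bs + bp) > 0)
    return("uncertain_significance")
  path_rules <- list(c(1, 1, 0, 0), c(1, 0, 2, 0), c(1, 0, 1, 1),
                     c(1, 0, 0, 2), c(0, 2, 0, 0), c(0, 1, 3, 0),
                     c(0, 1, 2, 2), c(0, 1, 1, 4))
  lp_rules <- list(c(1, 0, 1, 0), c(0, 1, 1, 0), c(0, 1, 0, 2),
                   c(0, 0, 3, 0), c(0, 0, 2, 2), c(0, 0, 1, 4))
  have <- c(pvs, ps, pm, pp)
  for (r in path_rules) if (all(have >= r)) return("pathogenic")
  for (r in lp_rules) if (all(have >= r)) return("likely_pathogenic")
  if (ba >= 1) return("benign")
  if (bs >= 2) return("benign")
  if (bs >= 1 && bp >= 1) return("likely_benign")
  if (bp >= 2) return("likely_benign")
  "uncertain_significance"
}

# Evidence data frame from strength counts.
evidence_from_counts <- function(pvs, ps, pm, pp, ba, bs, bp) {
  rows <- c(
    rep(list(evidence_code("PVS1", "pathogenic", "very_strong")), pvs),
    rep(list(evidence_code("PSx", "pathogenic", "strong")), ps),
    rep(list(evidence_code("PMx", "pathogenic", "moderate")), pm),
    rep(list(evidence_code("PPx", "pathogenic", "supporting")), pp),
    rep(list(evidence_code("BA1", "benign", "stand_alone")), ba),
    rep(list(evidence_code("BSx", "benign", "strong")), bs),
    rep(list(evidence_code("BPx", "benign", "supporting")), bp))
  if (length(rows)) do.call(rbind, rows)
  else data.frame(code = character(), direction = character(),
                  strength = character(), stringsAsFactors = FALSE)
}

# Brute-force carrier-set intersection across a pedigree's samples.
intersection_oracle <- function(samples, members) {
  sets <- lapply(members, function(s) {
    calls <- samples[[s]]
    calls$variant_id[calls$gt %in% c("het", "hom_alt")]
  })
  sort(Reduce(intersect, sets))
}

# Small hand-built PSSM: wild type given per position, score overrides as a
# list of (position, residue, value); everything else zero.
toy_pssm <- function(wild_type, overrides = list()) {
  L <- length(wild_type)
  scores <- matrix(0L, L, 20,
                   dimnames = list(seq_len(L), varcoseg:::AA_ALPHABET))
  for (ov in overrides) scores[ov[[1]], ov[[2]]] <- as.integer(ov[[3]])
  pssm(wild_type, scores)
}

# Count data frame shorthand.
counts_df <- function(ids, ac, an, cohort = "x") {
  data.frame(variant_id = ids, cohort = cohort, ac = as.integer(ac),
             an = as.integer(an), stringsAsFactors = FALSE)
}
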