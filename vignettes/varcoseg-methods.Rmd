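---
title: "Methods: co-segregation variant prioritization, cohort burden, substitution tolerance, and somatic recurrence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-segregation variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varcoseg)
```

## The problem

Small familial cancer studies sequence a handful of affected relatives per
pedigree and ask which rare germline variants track with disease. With two
sequenced patients per family there is no power for formal linkage, so
practical prioritization stacks weaker, orthogonal filters:

1. **Co-segregation**: keep variants carried by *every* sequenced affected
   relative of a pedigree.
2. **Rarity and consequence**: keep protein-altering variants (missense,
   frameshift, stop-gain, splice-site) whose control allele frequency is
   below a rarity ceiling.
3. **Cancer-germline co-occurrence**: keep variants that also appear in a
   cancer-cohort germline variant set derived from population databases.
4. **Five-tier classification**: combine ACMG-AMP-style weighted evidence
   into pathogenic / likely pathogenic / VUS / likely benign / benign.

Around the candidate gene, three quantitative analyses ask whether the gene
behaves like a cancer gene at population and somatic scale: a
**cohort-subtraction burden test**, a **PSSM substitution-tolerance score**
with a Monte Carlo null, and **somatic recurrence statistics** (hotspot
scan, 20/20 classification, per-cancer-type enrichment).

Real inputs of this kind (pedigree exomes, population database releases)
are access-restricted and snapshot-dependent, so the package ships a
synthetic-data module that generates every input format with planted ground
truth; all tests and the acceptance script run against it.

## Co-segregation and classification

**Sharing** is carrier-based, not genotype-identity-based: a variant
co-segregates when every sequenced affected sample carries at least one
alternate allele (het or hom-alt) on the decomposed, normalized
representation. This is the natural criterion under a dominant model, which
is also what reported familial candidates (uniformly heterozygous) imply. A
missing genotype *excludes* the variant - precision is favored over recall -
with `missing_as_carrier` as the documented relaxation.

**Normalization** trims the shared allele suffix, then the shared prefix
keeping one anchor base for indels, adjusting the position; canonical ids
are `chrom:pos:ref:alt` on this minimal form. Coordinates are VCF-style
1-based throughout. The operation is idempotent and property-tested.

**Hard filtering** is configurable, not constant: minimum depth, genotype
quality, and site QUAL plus arbitrary site-level comparator rules. A value
passes at `value >= threshold` (strict fail below); the boundary convention
is tested. Model-based recalibration (VQSR-style) is out of scope; only the
hard-filter leg is implemented.

**Rarity** defaults to a control allele frequency ceiling of `af_max =
0.001`; absent frequencies count as rare. The stand-alone benign threshold
is 0.05. Both are configuration because published pipelines rarely disclose
their exact values.

**The ACMG engine** deliberately separates two layers:

* `combine_acmg()` implements the published combining table over evidence
  strengths (very strong / strong / moderate / supporting on the pathogenic
  side; stand-alone / strong / supporting on the benign side). It is
  exhaustively tested against an independently hand-coded oracle over every
  evidence multiset of size up to four, together with a monotonicity
  property (appending pathogenic-direction evidence to a conflict-free set
  never moves the verdict toward benign).
* `assign_evidence()` maps variant context to codes: truncating consequence
  in a known loss-of-function gene gives PVS1; absence from controls gives
  PM2; co-segregation across affected relatives gives PP1; an in-silico
  damaging call gives PP3; a common variant gives BA1. This mapping is a
  documented simplification - per-criterion usage in published studies is
  generally not recoverable - and is configuration-driven.

Any simultaneous firing of pathogenic- and benign-direction evidence yields
uncertain significance: the conservative reading of conflict resolution.

## Cohort subtraction and the burden test

Population releases publish allele counts (AC) and allele numbers (AN) per
cohort, including nested cohorts. Two subtractions are used:

* **cancer cohort = general - non-cancer** (elementwise AC and AN), giving
  cancer-cohort counts that the release does not publish directly;
* **cancer-germline set = full - complement**, the variant ids with a
  positive derived count, used as the co-occurrence filter.

Subtraction errors on negative differences by default (real releases
contain subset inconsistencies; silently clamping would hide them); a
`clamp` flag converts them to zero with a warning. Only rows flagged `pass`
in every source present survive the quality filter; a variant observed in a
single source needs only that one pass.

The **gene burden test** sums a gene's allele counts per cohort (carriers)
and takes the cohort's *maximum* AN over the gene's variants as the trial
count - the call-rate-conservative choice that never double-counts
chromosomes. The 2x2 table (carriers / non-carriers x cohort A / cohort B)
is tested with a two-sided Fisher exact test: the p-value sums
hypergeometric probabilities of all tables with the observed margins whose
probability does not exceed the observed one (probabilities within one part
in 1e7 count as tied, the standard convention). The implementation is
verified against full hypergeometric enumeration for every table with both
margins up to 30 (about 246,000 tables, max |dp| below 1e-14) and
cross-checked against `stats::fisher.test`. Allele-count tables approximate
carrier counts for rare variants; this is documented rather than corrected.
Across genes, Benjamini-Hochberg q-values are reported alongside raw p.

## Substitution tolerance

A PSI-BLAST position-specific scoring matrix gives per-position log-odds
for all 20 residues. For a missense mutation the tolerance score is

$$\Delta S = S_{\text{mutation}} - S_{\text{wild type}}$$

at that position; negative values mean the profile tolerates the mutant
residue less. The observed statistic for a mutation set is the mean of its
per-mutation scores. The null distribution draws sets of `k` random
mutations - position uniform on 1..L, mutant residue uniform over the 19
alternatives at that position, with replacement within and across sets
(10,000 sets of three by default) - and the empirical p-value is the
lower-tail add-one estimate $(1 + \#\{\bar{S}_{\text{null}} \le
\bar{S}_{\text{obs}}\})/(n+1)$, which never reports zero. Codon structure
and CDS weighting are deliberately ignored: the null is defined at the
residue level, and that definition is part of the method. The null mean is
tested against the exact full-enumeration expectation
$\sum_{p,a \ne wt(p)} \Delta S(p,a) / (19L)$ within three standard errors,
and $\Delta S$ of every identity substitution is zero by construction. The
wild-type letter supplied with each mutation must match the matrix - a
mismatch is an error, guarding against HGVS/PSSM misalignment.

## Somatic recurrence

The **hotspot scan** counts missense mutations in a fixed window of
half-width `w` (default 2) around each residue, clipped to the protein, and
computes the upper-tail binomial probability of that count under a
length-normalized uniform background, Bonferroni-adjusted over all `L`
residues. A transparent fixed window with family-wise control replaces the
boundary heuristics of dedicated hotspot packages; this divergence is
intentional and documented. Tail probabilities are verified against exact
term-wise summation to 1e-12.

The **20/20 rule** calls a gene oncogene-like when strictly more than 20%
of its missense mutations sit at recurrent residues (>= 2 missense at the
same residue, configurable) and tumor-suppressor-like when strictly more
than 20% of its non-silent mutations are truncating (frameshift, stop-gain,
splice). Exactly 20% is "neither" - the rule says *more than*. Fusion
events are reported but excluded from all three statistics.

**Per-cancer-type enrichment** compares each type's mutated-sample count to
an upper-tail exact binomial at the pooled mutated fraction (the default
background; a fixed rate can be supplied), with Benjamini-Hochberg across
types. Whether published per-type p-values used a pooled or
burden-adjusted background is generally unstated; pooled is this package's
default and exposed as configuration.

## The synthetic study

`sim_config()` defaults define one synthetic familial cancer study, chosen
once:

* **10 pedigrees, two sequenced affected relatives each**, kinship
  coefficients 0.016-0.25 - the range observed in familial breast-cancer
  exome reports;
* **10,000 background variants** per study; allele frequencies from
  Beta(0.2, 20), a rare-variant-heavy site frequency spectrum; half the
  background is silent;
* **one planted co-segregating variant per pedigree**: non-silent,
  heterozygous in every affected sample, control AF drawn uniformly from
  the upper half of the rarity window `[af_max/2, af_max]` - rare but
  observable once in a database-scale cohort;
* **cohort allele numbers at population-database scale**: a general cohort
  of 134,000 alleles containing a cancer subset of 14,000 (about 7,000
  samples) and 120,000 control alleles (about 60,000 samples), matching the
  printed scale of the motivating setting; the planted gene's carrier odds
  are multiplied by 5 in the latent cancer subset;
* **a 377-position PSSM** (the length of the NCK1 adaptor protein) with
  half its positions conserved;
* **102 somatic mutations** with 30% of the missense mass on a hotspot at
  residue 42 and 12% truncating.

Background genotypes are drawn independently per sample under
Hardy-Weinberg, so rare non-silent background variants are occasionally
shared within a pedigree by chance (about 2% of studies at these sizes);
the generator records these collisions in the truth table, and tests treat
them as genuinely shared rather than as errors. The released `general`
cohort is constructed as the elementwise sum of latent cancer and
non-cancer draws, so subtraction recovers the cancer subset *exactly* - a
construction identity the tests assert. In the somatic generator, missense
positions follow the mixture `hotspot_mass` x uniform(hotspots) +
`(1 - hotspot_mass)` x uniform(all residues); with `hotspot_mass = 0` this
is exactly a uniform multinomial, and the hotspot expectation is
`hotspot_mass * N` plus the small uniform-component share.

What the generator does **not** emulate - and what passing tests therefore
do not show about real data: linkage and haplotype structure, sequencing
error and coverage artifacts, population stratification between cohorts,
codon-level mutational biases, and annotation error. The planted-recovery
results certify the machinery, not performance on real exomes.

All generators are pure functions of `(config, seed)`; child streams are
derived from the one global seed by fixed offsets, so adding a generator
never perturbs earlier streams. The PSSM wild-type sequence is drawn from
the same child stream in both the PSSM generator and the annotation
generator, which keeps planted missense HGVS.p notation consistent with the
matrix.

## Numerical choices and degenerate inputs

* Fisher: zero-margin tables return p = 1 with the odds ratio flagged
  undefined; the odds ratio is `+Inf` when `bc = 0` and `ad > 0`.
* Binomial tails at zero observed counts are exactly 1.
* Ties in the Fisher two-sided sum use the `1 + 1e-7` relative tolerance
  shared with standard implementations.
* Empty evidence sets and rule misses are VUS; malformed
  direction/strength pairs are errors, not silent coercions.
* Empty VCF bodies, empty genes, and zero-mutation spectra flow through as
  empty results, never as crashes; a mutation set must be non-empty before
  a mean score is defined.
* Symbolic (non-ACGT) alleles are flagged and carried, not dropped.

## Problem sizes used by the test suite

The suite exercises: the full Fisher sweep (all 2x2 tables with both
margins <= 30), 1,000 randomized binomial tail cases up to n = 200, a
10,000-background-variant co-segregation study, all evidence multisets of
size <= 4, a 377-position PSSM with 10,000 null sets of three, 1,000-variant
cohort round trips, 100 + 200 seed replicates for hotspot recovery and
family-wise error, and 100 end-to-end pipeline replicates for burden power
at analytic power >= 0.95. These sizes were chosen to make Monte Carlo
assertions statistically decisive at three standard errors.

## Known limitations

* Evidence assignment is a five-code simplification of the full ACMG-AMP
  criteria catalogue; verdicts on real variants require the full catalogue
  and expert review.
* Allele-count burden ignores genotype-level correlation and covariates;
  it is not a substitute for regression-based burden frameworks.
* The hotspot background is uniform within the protein; trinucleotide or
  3-D-structure-aware backgrounds are out of scope.
* The shipped PSSM is a synthetic fixture; scores from a live PSI-BLAST
  search are database- and version-dependent, and runs against a real
  matrix are an optional documented path (`parse_pssm_ascii()` reads the
  `-out_ascii_pssm` dialect directly).

## A minimal run

```{r demo, eval = FALSE}
dir <- tempfile("study")
demo <- make_demo(dir, seed = 1)
report <- run_all(file.path(dir, "run.yaml"))
print(report)
report$candidates[, c("pedigree_id", "gene", "evaluation", "consequence")]
```
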