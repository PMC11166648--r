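---
title: "Models and methods behind flightomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flightomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flightomics)
```

# Scope

flightomics analyzes longitudinal whole-blood transcriptome and
epitranscriptome profiles from short-duration crewed missions sampled at
seven draws: three pre-flight (L-92, L-44, L-3 days before launch), the day
of landing (R+1), and three recovery draws (R+45, R+82, R+194). Four crew
members, one sample per subject per draw, is the default design
(`mission_design()`), and every analysis accepts an alternative label→day
map for reuse on other missions.

The package deliberately begins *after* the sequencing-specific heavy
machinery: basecalling, alignment, expression quantification, NB-GLM
differential-expression engines, site-level m6A probability calling, and
transcript assembly/annotation matching are all upstream tools whose
*outputs* (count tables, site tables, `.tracking` catalogs) this package
consumes. What it owns is the downstream statistics: pathway z-trajectories
and their disruption score, co-regulation permutation testing, site-level
differential methylation with recovery-reversal profiling, dual-quantifier
concordance with the consensus-DEG rule, and cross-crew unique-transcript
set logic.

# Expression model

Counts are accepted as non-negative reals because multi-mapping-aware
quantifiers emit fractional counts. When two quantifiers are available
their per-gene counts are averaged on the shared gene universe
(`average_quantifiers()`), normalized to counts-per-million
(`normalize_library_size()`), and z-scored per gene over all samples of
`log2(CPM + 1)` (`zscore_expression()`).

Two documented conventions:

* the log transform is applied before z-scoring — the scale on which
  fold-change semantics are additive and variance is roughly stabilized;
* the z-score denominator is the **sample** standard deviation (n−1).
  Consequently a single gene's squared z-scores sum to exactly n−1, which
  the co-regulation score of a singleton set inherits.

Genes with zero variance cannot be z-scored and are set aside in
`constant_genes` rather than silently dropped.

## Pathway trajectories

The trajectory of a pathway is the median z-scored expression of its member
genes at each timepoint (`pathway_trajectory()`). By default the median
pools all (member gene × subject) values at the timepoint; because it is
genuinely ambiguous whether one should first aggregate within subject, the
alternative ordering is available as `pooling = "by_subject"`. The pooled
form is the default because it is the simplest reading of "the median
z-scored expression value of genes in the pathway" per timepoint and uses
every observation symmetrically.

## Co-regulation score and permutation test

For a gene set with member z-matrix rows, let `m_s` be the mean z across
members in sample `s`. The co-regulation score is

    score = sum_s m_s^2

— large when the members move together across samples (their shared signal
survives averaging), near zero when they fluctuate independently (means
shrink by 1/k). Significance is a gene-label permutation: `n_perm` uniform
random sets of the same size are drawn from the z-scored gene universe, and

    p = (1 + #{score_perm >= score_obs}) / (n_perm + 1)

so p is never smaller than `1/(n_perm+1)`. Restricting the null to the
detected universe avoids size and detectability bias. Benjamini–Hochberg
adjustment is applied across tested pathways; pathways whose intersection
with the universe falls outside `[min_size, max_size]` are skipped and
reported, not silently ignored. The implementation is checked in the test
suite against `fgsea::geseca` as an independent route on the same score
family.

## The dz disruption statistic

Per pathway, an ordinary least-squares line is fitted to the three
pre-flight median z-scores as a time series (days −92, −44, −3), the line
is extrapolated to the return day (+1), and

    dz = z_observed(R+1) − z_predicted(R+1)

Pathways are ranked by the *signed* dz from highest (most disrupted by
flight) to lowest (continuing a pre-flight trend); ranking by magnitude is
available via `rank_by_dz(..., absolute = TRUE)` for questions where the
direction of disruption is irrelevant. dz is exactly shift-invariant and
scale-equivariant (`dz(a·z+b) = a·dz(z)`), which the suite verifies over
random trajectories, and the OLS fit is checked against an independent
normal-equation solve. The regression is unweighted: with three points and
no stated replicate variances there is nothing to weight by. Any observed
day can be scored against the pre-flight fit (`return_day` argument), which
is how "returning to baseline in recovery" claims can be quantified.

Only pathways passing the co-regulation size filter are scored by default;
restricting to significantly co-regulated pathways (adjusted p < 0.05) is a
caller-side subset.

## Differential expression and the consensus rule

The package does not reimplement NB-GLM engines. For self-contained runs it
provides `simple_de()`: log2 fold change as the mean difference of
`log2(CPM+1)`, a paired t-test on subject-blocked differences when every
subject contributes one sample to each group, otherwise Welch's t-test, and
BH adjustment. When two pipelines are compared (`concordance()`), the
consensus-DEG rule applies: a gene is differentially expressed only when
both pipelines call it significant at FDR < 0.05. Concordance is summarized
by per-sample Pearson correlation of `log2(count+1)` on the shared gene
universe (median across samples) and the correlation of log2 fold changes.
The shared-gene intersection is used rather than the union, since imputing
zeros for genes one quantifier never reported would manufacture
disagreement.

# Methylation model

Site tables carry transcript-relative 0-based positions and per-sample
(coverage, modified reads) pairs. Sites are filtered to a minimum coverage
(default 20×, read as ≥ 20) in **every** sample entering a contrast.

Differential methylation offers two engines:

* **pooled** — reads are summed within each group and a two-sided Fisher's
  exact test is applied to the 2×2 (modified/unmodified × group) table.
  The p-value is computed directly from the hypergeometric distribution
  and the test suite verifies exact agreement with `stats::fisher.test`
  on random tables;
* **logistic** — a per-sample binomial logistic regression on the group
  indicator with a likelihood-ratio p, which respects between-sample
  variation instead of pooling it away. It is the default whenever both
  groups have at least two samples.

Multiple testing uses Benjamini–Hochberg q-values. The site-caller
ecosystem's default q-value method (SLIM) relies on unpublished tuning
parameters; BH is standard, conservative, and consistent with the FDR
convention used on the expression side. Significance is `q < 0.01`.

Profiles follow the mission narrative: the flight profile FP1 contrasts R+1
against all three pre-flight draws; recovery profiles RP1/RP2 contrast R+45
and R+82 against R+1. `reversal_analysis()` reports sites hypermethylated at
return that significantly *decrease* in a recovery profile (and
symmetrically hypo → increase), with genes de-duplicated. Pathway
methylation density is significant sites per detected pathway gene, and
`density_expression_correlation()` relates it to expressional variability
(Pearson and Spearman, with the degenerate constant-vector case reported as
NA rather than an error).

# Transcript catalog logic

Catalogs are GffCompare-style: transfrag, locus, reference match, class
code, and per-sample presence. Samples failing the average-read-length QC
rule (default < 400 bp, the rule that excludes a 279 bp outlier) are removed
first. Presence at a timepoint requires **cross-crew consensus**: at least
one retained sample of every retained subject. Uniqueness within a window of
timepoints is asymmetric by design: consensus presence at the focal
timepoint, and absence from *every* retained sample at every other window
timepoint. The asymmetry maximizes specificity — a transcript seen even once
elsewhere is not unique. Uniqueness is window-relative; the return day
legitimately has different unique sets in the pre-flight+return window than
in the return+recovery window. A `min_subjects` relaxation and a
`drop_timepoint_on_exclusion` flag (discard a whole draw after one QC
failure, the stricter historical behavior) are provided.

# The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known truth without any sequencing download. It emulates:

* **counts** — negative-binomial per gene/sample; log2-scale mean = per-gene
  baseline (normal, mean 6, SD 1.5 log2 units ≈ CPM-scale spread of whole
  blood), + per-subject random effect (SD 0.2 log2 units, non-trivial
  inter-astronaut variability), + planted pathway effects. Disrupted
  pathways add their shift only at R+1; trending pathways add slope×day
  through pre-flight, continue the trend at R+1, then decay linearly to
  baseline by R+194 (the functional form of recovery is unspecified in any
  source; linear is the simplest testable choice). Effects are additive on
  the log2 scale so they compose with fold-change semantics. Note that an
  effect of 1 log2 unit corresponds to roughly 1.5–2 z-score units at the
  default dispersion of 10 — the z-scale size of a planted effect depends on
  the noise level, and tests that quote effect sizes state them on the
  generator's log2 scale.
* **dual quantifiers** — a caricature of multi-mapping read attribution:
  outside homolog groups both outputs equal the input up to small
  multiplicative noise; inside a group one quantifier concentrates the
  per-sample group total on a winner while the other splits it
  proportionally. Group totals are conserved exactly, which pins down the
  accounting.
* **methylation** — NB coverage, binomial modified reads; baseline rates
  Beta(2, 8) across sites (mean ≈ 0.2); planted sites shift by Δ/100 at
  R+1, keep the shift through recovery unless flagged as reversal sites,
  which return to baseline at the recovery draws. True sites carry DRACH
  5-mers; a fraction of null sites carries non-DRACH decoys.
* **catalogs** — shared transcripts with Bernoulli dropout plus planted
  unique transcripts present in all subjects at one focal timepoint and
  absent everywhere else.

What the generator does **not** emulate: read-level error structure,
coverage biases along transcripts (3′ enrichment), correlated dropout,
isoform-level quantification ambiguity beyond the homolog caricature,
overdispersion of methylation rates across samples within a condition, and
any real biological pathway covariance. Passing tests therefore demonstrate
the *statistical machinery* is correct and calibrated under its stated
model, not that the model captures every property of mission data.

Every generator is a pure function of (parameters, seed); identical seeds
give byte-identical outputs, which the end-to-end pipeline inherits.

# Numerical choices and degenerate inputs

* z-scores: zero-variance genes are segregated, never divided by zero.
* OLS: closed-form normal equations; collinear (exact-line) input yields
  zero residuals and dz = 0 to machine precision.
* dz ties are broken lexicographically by pathway name so ranks are total
  and reproducible.
* Fisher p-values use the standard `(1 + 1e-7)` relative guard when summing
  point probabilities, avoiding floating-point tie artifacts.
* Degenerate t-tests (zero variance) return p = 1 when the difference is
  also zero, p = 0 otherwise, rather than NaN.
* Permutation p-values are lower-bounded by `1/(n_perm+1)` by construction.
* All writers serialize counts at 17 significant digits so write→read
  round-trips are exact.

# Problem sizes

The shipped tests and the acceptance script run simulated studies of
roughly 400–4000 genes, 20–500 pathways, 100–500 permutations, 120–400
methylation sites and ≤ 100-transcript catalogs — sizes chosen so the whole
suite completes in well under a minute per stage while leaving planted
effects clearly resolvable above the simulation noise. The statistics are
size-agnostic; a full MSigDb C2 run (6336 pathways) only scales the
permutation loop linearly.

# Known limitations

* The co-regulation null assumes exchangeability of genes within the
  detected universe; strong co-expression blocks in real data make the
  permutation test anti-conservative relative to a subject-level
  resampling, which a 4-subject design cannot support.
* dz has no uncertainty interval: with three pre-flight points the residual
  degrees of freedom are one, so any interval would be decorative.
* The logistic engine does not model extra-binomial dispersion; with many
  replicates per group a beta-binomial would be preferable.
* The pipeline's simple DE test is not a substitute for NB-GLM engines on
  real data; it exists to exercise the consensus rule and concordance
  machinery self-containedly.
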