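---
title: "Models and methods behind MMCarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind MMCarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MMCarray)
```

MMCarray packages the statistical workflow for profiling rare,
laser-microdissected plant cell types — exemplified by the *Arabidopsis*
megaspore mother cell (MMC) and its surrounding nucellus — on short-oligo
expression arrays. This vignette explains the models, the defaults and why
they are what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices a reader would otherwise have to dig out
of the code.

## Probe re-annotation and the negative-probe pool

Probes are 25-mers designed against an older genome annotation, so the
first step is to re-map them: `mapProbes()` finds every target window
within a maximum number of substitutions (no indels — the contract is exact
Hamming distance, which is also what makes the search testable against a
brute-force scan). The search splits each probe into `maxMismatches + 1`
contiguous exact seeds; by pigeonhole, any window within the cap contains
at least one seed verbatim. Seeds are located with a dictionary scan
(Aho–Corasick via Biostrings) and candidate windows verified by direct
character comparison. Transcript targets are searched sense-strand only
(probes are designed against mRNA); genomic targets on both strands.
Coordinates are 0-based half-open throughout. Letters outside A/C/G/T
mismatch everything, with a warning.

`buildProbesetAnnotation()` removes probes with perfect hits to more than
one gene (cross-hybridizing probes corrupt probeset summaries), then drops
probesets left with fewer than `minProbes` probes. `minProbes` defaults to
1: a probeset disappears only when all of its probes were removed; the
threshold is exposed because reasonable pipelines differ here.

`selectNegativeProbes()` keeps probes that are (i) unused by any retained
probeset and (ii) have no hit at two or fewer mismatches. Probes with *no*
hit at all at the search cap are included — they are the cleanest
background measures — and flagged with `NA` provenance, since one could
argue either way about probes the search simply never scored.

## Summarization

**RMA.** Per array, the observed intensity is modelled as `O = S + B` with
signal `S ~ Exp(alpha)` truncated at zero and background
`B ~ N(mu, sigma^2)`; each value is replaced by `E[S | O = o]`. The
parameters are heuristic: `mu` is the kernel-density mode of the
sub-median data (localized on the log scale first — raw arrays are so
right-skewed that a density grid over the full range is coarser than the
background bulk), `sigma` the half-normal spread below the mode times
`sqrt(2)`, `alpha` the reciprocal mean exceedance above it. All three can
be injected, which is how the tests pin the transform against numerical
quadrature. Quantile normalization equalizes array distributions (ties get
the mean of their rank means; the step is idempotent). Summarization is
Tukey median polish per probeset on log2 data, rows (probes) swept first,
tolerance 0.01 on the largest sweep median, at most 10 full sweeps —
conventional RMA settings, fixed and documented rather than tunable.
Probeset expression is `overall + arrayEffect`.

**MBEI.** The model-based index fits `PM_ja = phi_j * theta_a + error` per
probeset by alternating least squares under `sum(phi_j^2) = J` (the scale
must be pinned somewhere; this puts it on the probe affinities). PM-only,
because the data model has no mismatch probes. After convergence
(relative change `1e-10`, at most 200 iterations; non-convergence warns
and keeps the last iterate), probes whose largest standardized residual
exceeds 3 are dropped once and the model refitted — a single-pass version
of the original iterative outlier handling. Arrays are quantile-normalized
before the fit; the original software's rank-invariant normalization is a
deliberate non-goal, and the output carries the `"mbei"` method tag so the
provenance is visible downstream.

## Detection calls from a resampled negative-probeset null

Negative probes carry background only, so pseudo-probesets resampled from
them — 2,000 sets of 11 per repeat, probes unique within a set — and
summarized through the *identical* RMA path (one shared background/
normalization pass; `normalizedProbeMatrix()` exists precisely so real and
pseudo probesets cannot drift apart) give each array an empirical null.
The detection p-value of a probeset with signal `x` on array `a` is

    p = (#{null_a >= x} + 1) / (nSets + 1)

— upper tail, add-one smoothed so `p` is never 0 — averaged arithmetically
over 20 independent resampling repeats, which cuts the resampling noise by
roughly `sqrt(20)`. A probeset is present on an array when `p <= 0.02`
(the comparison is inclusive; the threshold itself is the quantity quoted
with the method). Group calls: **P** when present on at least
`ceiling(3/4 * R)` of `R` replicates, otherwise **M** at
`ceiling(2/4 * R)`, otherwise **A**. P and M are disjoint — "marginal"
means *only* marginal — which matches how marginal counts are reported as
"additional" genes. The fractions generalize to other replicate counts by
ceiling.

`detectionCalibration()` measures the operating characteristic of this
machinery: with a 1,574-probe standard-normal pool, 2,000 sets of 11, 20
repeats and 10,000 test probesets drawn from the same background, the
present-call rate at `p <= 0.02` is 0.02 up to Monte-Carlo error. Two
error sources matter: the binomial error of 10,000 test probesets
(SE 0.0014) and the sampling error of the finite pool's upper tail, which
is the larger one (across reseeds the rate has SD ≈ 0.004). The second is
intrinsic to the method — a real array has one fixed negative-probe
complement — and is why calibration is judged within Monte-Carlo error
rather than exactly.

## Enrichment analysis

The per-gene model is a cell-means fit (one mean per tissue/cell type,
residual variance pooled across groups). Variances are moderated with the
standard scaled-inverse-chi-square empirical-Bayes prior: hyperparameters
`(d0, s0^2)` solve the moment equations of `log s^2` (digamma/trigamma
matching); the trigamma inverse is computed by bisection to relative
tolerance `1e-8`, which is this package's own numerical choice. When the
observed `log s^2` spread does not exceed what the chi-square alone
implies, `d0 = Inf` (full shrinkage) with a warning. Moderated t per
contrast and a moderated one-way F use `d0 + df` denominator degrees of
freedom. The implementation is tested for exact agreement against an
independent reference empirical-Bayes implementation on a heteroskedastic
fixture.

Two selection rules are provided. The *atlas* rule declares a gene
enriched in the target when the BH-adjusted p-value is below 0.01 **and**
the log fold change is positive in *every* contrast of target vs. other
tissue — positivity is made explicit because "enriched" means
upregulated, not merely different. The *gametophyte* rule gates on the
moderated F at FDR < 0.05 first, then requires adjusted p < 0.05 with
positive log fold change in all contrasts. The atlas analysis is run on
MBEI expression and the cell-type comparison on RMA expression in the
motivating workflow, but both functions accept either — the split is a
workflow convention, not a constraint. Variance is pooled across all
groups in one linear model rather than per pair; with 70-odd tissue
groups a single pooled fit is both the convention and the stabler choice.
`prefilterByDetection()` implements the detection-evidence prefilter
(present on at least 3 arrays of the comparison) used before the
cell-type comparison.

## Gene-set and GO enrichment

Family tests are two-sided Fisher exact tests of each family against the
whole array-genome (two-sided because depletion is as interpretable as
enrichment for families); GO term tests are one-sided (over-representation
is the question). The two-sided p-value is the sum of point probabilities
not exceeding the observed one, with `1e-7` relative slack for floating
point ties. GO annotations are propagated by the true-path rule (set
union, so DAG diamonds do not double-count); cycles are an error naming
the offending terms. Three scorers: `classic` tests each term in
isolation; `elim` processes children before parents and removes the genes
of any term with `p < 0.01` from all its ancestors before testing them;
`weight` compares each node with its children and down-weights the genes
of the locally less significant relatives by the ratio of p-values before
rescoring (weighted counts are rounded and scored hypergeometrically).
The published description of the weight scheme leaves implementation
freedom; this package's variant is pinned by a three-term fixture in the
test suite, and satisfies the structural guarantees that matter: leaves
(and siblings sharing no genes) score exactly as `classic`, and
decorrelation can only remove evidence from ancestors, never add it.
`Expected` is always `annotated * |sig| / |universe|`, exactly. Raw
p-values are kept; a display column truncates below `1e-30`.

## Clustering

Complete-linkage agglomeration is implemented directly (O(n^3)) so the
tie-break can be deterministic: among minimal-distance pairs, merge the
one whose smallest original leaf indices are lexicographically least. The
result is a standard `hclust` object; complete linkage guarantees
monotone heights. Row scaling for heatmaps subtracts the row mean and
divides by the *population* SD (divisor n) — display-only, hence the
simpler estimator, and stated so the z-values are reproducible. Sample
clustering runs on log2 expression of genes above a variance floor of
`1e-12` (only to drop exactly-constant rows; the atlas figure convention
does not state a gene filter, so none is imposed). The heatmap's testable
artifact is the reordered, scaled TSV; the raster image is a convenience.

## Transmission genetics

`TE = 100 * n_het / n_wt` (100% under Mendelian segregation);
`X^2 = sum (O - E)^2 / E` against the 1:1 expectation without continuity
correction, called significant above 3.85 — both conventions match the
worked cross-table arithmetic this module is tested against. Display
rounding is half-away-from-zero to one decimal; raw values are always
returned. Phenotype fractions attach Wilson 95% intervals. Relative
fluorescence divides each nucleus's intensity sum by the within-ovule
minimum, making the dimmest nucleus exactly 1 and the measure
scale-invariant.

## The synthetic-data generator

`generateSequences()` + `simulateIntensities()` emulate, with known ground
truth: per-probe multiplicative affinities (log2-normal, SD 0.5,
array-invariant — matching median polish's additive model on the log
scale); additive Gaussian optical background (`N(6, 1)` on log2 scale);
an exponential expression signal added on the log2 scale for expressed
gene/tissue pairs; a tissue atlas with per-tissue expression patterns
(each non-planted gene expressed in a tissue with probability 0.7) and
planted tissue-enriched genes of known log2 effect; orphan probes that
carry background only, verified by a mismatch scan before emission
(rejection sampling, retry cap 1,000); deliberate multi-mapping probes
spliced into a second gene; and binomial progeny counts under a reduced
transmission probability (`p/(1+p)` heterozygous).

Parameter rationale, chosen once:

* `signalRate = 0.5` — expressed genes average 2 log2 units (4-fold) above
  background. Because the exponential lives on the log2 scale, the raw
  intensity tail is Pareto; a mean of 2 keeps essentially the whole array
  inside the 6–16 log2 window of real scanners. Heavier choices give the
  raw scale an infinite-mean tail whose top quantiles are single probes
  wide at desk scale, which is neither realistic nor numerically kind to
  quantile normalization.
* The expression level is drawn *once per gene* and shared across the
  tissues where the gene is on; tissues differ through their on/off
  pattern and the planted effects. Drawing levels per tissue would make
  every gene differentially expressed everywhere and no enrichment rule
  could be calibrated against it.
* Planted genes get the median baseline level rather than a random draw,
  so the planted effect *is* their tissue contrast — "known effect size"
  in a testable sense.
* Probe length 25 nt and 11 probes per probeset follow the array
  convention; both are configurable.
* Intensities are built on the log2 scale and exponentiated, so RMA's
  raw-scale convolution assumption holds only approximately. This is
  intentional model-mismatch stress: background correction therefore
  slightly inflates contrasts of weakly expressed genes (the low side of
  `log2(O - mu)` expands), which is also the behaviour seen on real
  arrays near background.

What the generator does **not** emulate: spatial optical artifacts, batch
or scan-date effects, mismatch-probe pairs, probe-sequence (GC) affinity
structure, cross-hybridization signal on multi-mapping probes, or
saturation. Passing tests therefore demonstrate correctness of the
statistical machinery under a clean generative model, not robustness to
every failure mode of real arrays.

## Problem sizes used by the test suite

Tests run the full pipeline on an 8-tissue × 4-replicate atlas of 500
genes (11 probes each, 200 negative probes, 20 planted enriched genes at
+2 to +4 log2) for the recovery checks; detection calibration uses the
full 1,574 / 2,000 × 11 / 20-repeat / 10,000-probeset experiment; the
replicate-clustering check runs ten independent 500-gene atlases; oracle
equivalences (mapping, Fisher, BH, median polish, dendrograms, detection
p-values) run on small fixtures where brute force is exact. These sizes
were chosen so the whole suite completes in a couple of minutes while the
stochastic checks still have usable Monte-Carlo resolution.

## Known limitations

* The mismatch search is substitution-only by contract; a probe
  overlapping an indel in the target will not be found.
* The negative-probe rule trusts the search cap: probes with best hits at
  3–5 mismatches are "background" even though faint cross-hybridization
  can occur in reality.
* MBEI's single-pass outlier handling is cruder than the original
  iterative scheme; with very few probes it may keep an outlier rather
  than drop below one probe.
* The weight GO scorer is a pinned variant, not a byte-for-byte
  re-implementation of any particular released version.
* Quantile normalization at desk scale (hundreds of genes) distorts
  contrasts of genes in the sparse extreme tail; at realistic array sizes
  (tens of thousands of probesets) the effect is negligible.
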