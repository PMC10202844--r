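---
title: "Models and methods behind txsplice"
author: "txsplice authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind txsplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

txsplice analyses transcript-level RNA-seq counts from two-group
longitudinal designs in which the biology suggests that group differences
peak mid-course and vanish at the endpoints — the motivating setting is a
maternal-nutrient-reduction (MNR) versus control comparison of fetal liver
across gestational days 90, 120, 140 and 165 (term ≈ 185 dG), with 8 + 8
samples per group at the endpoints and 6 + 6 at the middle timepoints and
equal sexes throughout (`paperDesign()`, 56 samples). Three stages share
one count container:

1. differential expression with observation-level precision weights and a
   quadratic group×time interaction,
2. a splice-variant diversity statistic built from per-sample
   expressed-isoform counts, and
3. MCODE molecular-complex detection on a user-supplied gene-interaction
   edge list.

# The expression model

Counts are filtered by the rule *maximum count across all samples ≥ 15*;
anything below is too sparse to inform the mean–variance trend. Filtered
counts are converted to `log2 CPM` with the usual half-count offset,
`log2((c + 0.5)/(N + 1)·1e6)`, using plain library-size normalisation
(column sums). Scaling-factor normalisation is deliberately not applied:
the stage is defined on "normalized read counts" in the plain CPM sense,
and the simulator's library-size variation is mild.

Each transcript is fit by least squares on the seven-column design

```
[intercept, sexM, t, t², MNR, MNR·t, MNR·t²],   t = (dG − 127.5)/37.5
```

Raw gestational day and its square are nearly collinear over 90–165 dG, so
time is centred and scaled to `[−1, 1]`. This affine re-encoding changes
coefficient values but not the significance of the interaction contrasts in
combination with the other model terms; the mapping is recorded in every
output header. Sex and group are 0/1 with reference levels F and CON.

The mean–variance trend is estimated exactly in the voom style: lowess of
`sqrt(residual sd)` against average log2 count (span 0.5, configurable),
linear interpolation, each observation's fitted log2 count mapped through
the curve, and the precision weight taken as the predicted fourth-power
reciprocal. Predictions are clipped to the fitted range at the extremes so
weights stay positive and finite.

Weighted least squares then gives per-transcript coefficients, residual
variances `s²` on `d = n − p` degrees of freedom, and unscaled variances
from `(XᵀWX)⁻¹`. Residual variances are moderated empirically-Bayes style:
`log s²` is moment-matched to a scaled F distribution through
digamma/trigamma equations (the trigamma inverse solved by Newton
iteration), yielding a prior `(d₀, s₀²)`; the moderated variance is the
usual weighted combination and moderated t statistics gain `d₀` degrees of
freedom. When all variances coincide the prior degrees of freedom are
flagged infinite; zero-variance transcripts are floored to the smallest
positive variance and flagged. The unit suite cross-checks this whole stage
against limma's voom/lmFit/eBayes route, which agrees to printed precision;
the package's own implementation is what runs.

Three contrasts are tested — the MNR main effect (the group difference at
the centre of the time axis), MNR·t, and MNR·t² — each with its own
Benjamini–Hochberg adjustment. After adjustment, transcripts sharing a gene
symbol collapse to the most significant one (ties by larger |t|, then
transcript id). Genes reach the *primary* set at FDR < 0.1 in any contrast
and the *network* set at unadjusted p < 0.001; the two rules are applied
independently, mirroring the admission logic the network stage expects.

# The splice-variant diversity statistic

For every gene and sample the diversity outcome is the number of distinct
transcripts with at least one read (`presenceThreshold = 1`,
configurable). Counting uses the *unfiltered* matrix: the low-abundance
isoforms removed by the expression filter are exactly the plausible
carriers of a diversity effect. Per timepoint, each gene's counts are
regressed on group with sex as covariate by a log-link Poisson GLM (IRLS,
tolerance 1e−8, 50 iterations); the effect is the log rate ratio MNR/CON
with its Wald standard error. Estimates that fail to converge or run
unbounded (a group with all-zero counts) are excluded from downstream
combination. Per-timepoint gene lists carry their own BH FDR with a
default admission of FDR < 0.05.

Effects at the configured meta timepoints (default 120 and 140 dG, the
window where the expression differences peak) are combined per gene by
fixed-effect inverse-variance meta-analysis — with only two studies a
random-effects model has nothing to estimate — giving a meta Z and p, again
BH-adjusted. A gene failing one meta timepoint is combined on the remaining
one. The global summary reports the mean, moment skewness
`g₁ = m₃/m₂^{3/2}`, and a two-sided one-sample t-test of the meta Z-scores
against zero, on all genes and on the subset with unadjusted p < 0.05.
Two-sided Wald tests are used throughout; single-isoform genes are retained
(their counts are 0/1-valued and carry little information, but excluding
them is a config choice, not a default).

## Calibration caveats, measured

Two properties of this statistic deserve emphasis; both are inherited from
the method's definition, not from implementation choices, and both are
visible in the package's own simulation tests:

* **Per-gene Poisson p-values are conservative.** The outcome is a sum of
  presence indicators — a Poisson-binomial variable whose variance is
  strictly below its mean unless every presence probability is near zero.
  A Poisson model therefore overstates the variance and the Wald p-values
  pile up towards 1 under the null. FDR control survives (it only becomes
  more conservative), but the per-gene p-values are not uniform and a
  calibration test that demands uniformity will fail for any realistic
  isoform-abundance distribution.
* **The global t-test is anti-conservative under depth variation.** The
  diversity regression adjusts for sex only; sequencing depth enters no
  offset. A sample with more reads expresses more isoforms of *every*
  gene, so meta Z-scores are positively correlated across genes, and the
  one-sample t-test — which assumes independent observations — overstates
  the evidence. With the simulator's log-normal(0, 0.1) library factors
  the measured type-I error at α = 0.05 is ≈ 0.25; with library variation
  removed it returns to 0.05 exactly. Global-shift p-values should
  therefore be read as descriptive strength-of-skew summaries, not
  calibrated error rates.

# MCODE complex detection

The interaction graph is consumed as an edge list (e.g. a STRING export);
confidence scores may filter edges but never weight the topology, matching
the algorithm's defaults. Vertex weight is the core index `k` of the
highest k-core of the vertex's closed neighbourhood times that core's
density. Complexes grow from the highest-weighted unassigned seed over
neighbours within the vertex-weight percentage (`vwp = 0.2`), each vertex
joining at most one kept complex; the haircut (on by default) prunes each
complex to its 2-core; fluff is omitted (off in the published defaults).
Scores are `density × n`. Admission requires score strictly greater than 4,
at least 7 members ("more than six nodes"), and one member gene at
FDR < 0.1 in the DE results. All tie-breaking is lexicographic on vertex
names, so results are order-independent and deterministic.

# The synthetic-data generator

`simulateCounts()` emulates the study conditions the pipeline assumes:

* the 56-sample reference design above (any design data.frame is
  accepted);
* genes with `1 + Poisson(3)` isoforms (mean ≈ 4); a gene-level log2
  abundance `N(5, 2)` split across isoforms by flat-Dirichlet proportions,
  so most minor isoforms sit near the presence boundary — mirroring real
  transcript-level quantifications, where the large majority of annotated
  transcripts fail a max-count filter;
* negative-binomial counts (dispersion 0.1) so the weighting stage has a
  real mean–variance trend to estimate, with log-normal(0, 0.1)
  library-size factors to exercise normalisation;
* a fraction (default 10%) of genes carrying the quadratic group effect
  `deEffect · −(dG−90)(dG−165)/1406.25` on the log2 scale — zero at 90 and
  165 dG, peaking (default 1 log2 unit) at 127.5 dG;
* a disjoint fraction (default 10%) of splice-affected genes, where extra
  low-abundance isoforms are switched on only in MNR samples at the
  affected timepoints (default 120/140 dG), calibrated through the
  negative-binomial zero-probability so the *expected expressed-isoform
  count* rises by exactly `exp(spliceEffect)` (default effect 0.5) there
  and is untouched elsewhere. Injecting diversity by isoform switching
  rather than redistributing a gene total keeps gene-level expression and
  diversity effects orthogonal, which is what the presence-count statistic
  measures;
* a small additive sex effect (0.2 log2 units) so the sex covariate is
  non-trivial;
* one master seed with deterministically derived child seeds per stage, so
  a spec snapshot regenerates a fixture byte-identically.

Defaults of 500 genes (≈ 2,000 transcripts) keep every simulation-based
test and the acceptance script within minutes on one core; calibration
checks scale `nGenes` up or down per test and say so in the test code.

What the generator does *not* emulate: exon structure and junction-level
sharing between isoforms, mapping ambiguity between paralogs,
quantification uncertainty from the upstream EM step, batch structure, and
outlier samples. Passing tests therefore demonstrate the statistical
machinery under the stated model, not robustness to those real-data
complications.

# Numerical and design choices

* Lowess span 0.5 for the mean–variance trend; weights clipped at the
  trend's range ends.
* Singular per-transcript systems are flagged and excluded rather than
  pseudo-inverted; zero residual variances are floored to the smallest
  positive observed value.
* The trigamma inverse uses Newton steps from `0.5 + 1/y`, converging to
  relative 1e−8 in a handful of iterations.
* Poisson fits reporting |β| > 20 or SE > 100 are treated as unbounded
  (separation) and dropped from the meta-combination.
* "More than six nodes" is read as n ≥ 7; MCODE score comparisons are
  strict (> 4).
* FDR is computed within each contrast and within each timepoint
  separately; deduplication happens after FDR.
* All result writers emit TSV with a `#` header recording the
  configuration snapshot, time encoding and reference levels.

# Known limitations

Beyond the calibration caveats above: coefficient magnitudes depend on the
time encoding and are not comparable across different centrings (the
encoding is recorded in output headers); the moderated prior is global, not
intensity-trended; the network stage cannot reproduce any particular
published cluster without the exact interaction-database export that
produced it, and no such reproduction is attempted.
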