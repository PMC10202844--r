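# txsplice

Transcript-level RNA-seq analysis for two-group longitudinal designs in
which expression differences are expected to peak mid-course and disappear
at the endpoints — e.g. a maternal-nutrient-reduction (MNR) versus control
comparison of fetal liver sampled at gestational days 90, 120, 140 and
165. The package is aimed at analysts who have a transcript × sample count
matrix (with a transcript→gene mapping), per-sample covariates, and
optionally a gene-interaction edge list, and who want three linked
analyses with one reproducible driver:

1. **Differential expression with a quadratic time interaction.** After
   filtering transcripts whose maximum count never reaches 15, counts are
   modelled on the design
   `[1, sex, t, t², group, group·t, group·t²]` with
   `t = (dG − 127.5)/37.5`, using observation-level precision weights from
   a fitted mean–variance trend (voom-style), weighted least squares, and
   empirical-Bayes variance moderation
   (`s̃² = (d₀s₀² + d s²)/(d₀ + d)`, prior by digamma/trigamma moment
   matching). The contrasts `group`, `group·t` and `group·t²` are each
   tested with moderated t statistics and Benjamini–Hochberg FDR;
   transcripts collapse to one row per gene symbol afterwards.
2. **Splice-variant diversity.** Per gene and sample, the number of
   distinct isoforms with ≥ 1 read (on the *unfiltered* matrix) is the
   outcome of a per-timepoint Poisson regression on group adjusting for
   sex; effects at 120 and 140 dG are combined per gene by fixed-effect
   inverse-variance meta-analysis (`Z = β̂/SE`), and a global shift test
   reports the mean, skewness and one-sample t-test of all meta Z-scores.
3. **MCODE network clustering.** Molecular-complex detection on a supplied
   edge list (k-core-based vertex weighting, seeded expansion at vertex
   weight percentage 0.2, haircut), with complexes admitted when score > 4,
   nodes ≥ 7, and at least one member gene at DE FDR < 0.1.

A seeded negative-binomial simulator (`simulateCounts()`) generates data
with exactly this structure — including the reference 56-sample design and
injected quadratic-expression and isoform-diversity effects with a truth
table — so the whole pipeline is testable without external data. See the
vignette `vignettes/txsplice-methods.Rmd` for models, assumptions and
measured calibration caveats.

## Worked example

```r
library(txsplice)

sim <- simulateCounts(simulationSpec(seed = 42))   # 500 genes, 56 samples
sim$experiment
#> TranscriptExperiment: 2123 transcripts x 56 samples
#>   genes: 500
#>   samples per group x gestational day:
#>       90 120 140 165
#>   CON  8   6   6   8
#>   MNR  8   6   6   8

res <- runAll(sim$experiment, "results_run", config = pipelineConfig())
res$de$result
#> DEResult over 1017 transcripts
#>   prior df d0 = 117.1, prior variance s0^2 = 0.9786
#>   MNR     : 107 transcripts at FDR < 0.1
#>   MNR.t   : 0 transcripts at FDR < 0.1
#>   MNR.t2  : 65 transcripts at FDR < 0.1
res$splice
#> SpliceMetaResult: 500 genes meta-analysed over 4 timepoints
#>   global shift: mean Z = 0.287, skewness = 2.182, p = 6.93e-15
```

Reading the output: the injected group effect peaks at mid-gestation, so
it loads on the `MNR` main effect (the group difference at the centre of
the time axis) and on the quadratic interaction `MNR.t2`, while the linear
interaction stays empty — the signature pattern this design detects. The
positive mean meta Z and right skew reflect the simulated gain of expressed
isoforms in the MNR group at 120/140 dG. Per-stage tables are in
`res$de$deduped`, `res$de$candidates`, `spliceMeta(res$splice)`, and TSV
copies (with config headers) under `results_run/` together with a
checksummed run manifest.

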