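---
title: "Methods: coordinated BRCA1/2 and HR gene expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coordinated BRCA1/2 and HR gene expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrcoreg)
```

## Scope and data model

`hrcoreg` implements a complete analysis chain for a tumor expression-panel
study asking whether *BRCA1/2* mRNA levels are co-regulated with other
homologous-recombination (HR) genes, and whether a droplet digital PCR
(ddPCR) assay can replace panel counting for targeted *BRCA1/2*
quantitation in FFPE material.  The cohort shape it is built around is 11
normal fallopian-tube samples and 38 ovarian tumors profiled on a
DNA-damage-and-repair panel of 180 endogenous probes, 12 housekeeping
probes, 6 positive and 8 negative spike-in controls.

All panel data live in a `count_matrix`: a genes-by-samples matrix plus a
per-gene annotation (`probe_class`, `pathway`).  Counts can be read from
TSV/CSV tables or assembled from plain-text RCC lane exports
(`read_rcc()`).

## Synthetic studies: what is emulated, and what is not

`simulate_nanostring_study()` draws Poisson counts with log-normal means

```
mu[g, s] = base[g] * E[s] * L[s] * upshift[g, s] * exp(latent_sd * f[s] * 1{g in module}) * exp(noise)
```

plus a common ambient background (`background_mean`, default 10 counts,
also the negative-control mean).  `E[s]` is a per-lane binding-efficiency
factor (log-SD `lane_sd = 0.15`, shared by every probe and corrected by
the positive controls), `L[s]` a per-lane RNA input factor (log-SD
`input_sd = 0.25`, endogenous and housekeeping probes only, corrected by
the housekeeping genes).  Positive controls follow a fixed 4-fold
titration series; two extra lanes re-run the first lane of each group as
technical replicates, i.e. independent Poisson redraws of the same lane
means.

Two parameters carry the scientific structure:

* `noise_sd` (default **0.25**, log scale) — per-gene biological
  dispersion.  Normal-tissue counts of roughly 185 ± 45 and 86 ± 29
  imply a coefficient of variation of 0.24–0.34; removing the Poisson
  component leaves a biological log-SD of about 0.23–0.32, and 0.25 is
  taken as the representative value.
* `latent_sd` (default **0.306**) — the SD of the per-sample latent
  factor shared by the 14 HR-module genes (*BRCA1*, *BRCA2* and 12
  other HR genes).  In a one-factor log-normal model the pairwise
  correlation between module genes is
  `latent_sd^2 / (latent_sd^2 + noise_sd^2)`; the default puts it at
  0.6, the regime of the pooled Spearman coefficients observed between
  *BRCA1/2* and the upregulated HR genes (~0.59–0.69).

`tumor_upshift` (default 2) multiplies the tumor-group means of the
designated upregulated genes (default: the 46 endogenous genes of the
packaged differential-expression table).  The generator does **not**
emulate FFPE degradation kinetics, probe-level sequence effects,
fluorescence imaging, or tumor purity gradients; passing tests therefore
demonstrate the statistical machinery under the assumed count model, not
robustness to those artifacts.  Note that on *raw* counts the shared lane
factors induce a baseline correlation between all genes; null-structure
statements (e.g. "no latent factor implies vanishing module correlation")
hold on normalized counts.

`simulate_droplet_well()` makes each droplet independently positive with
probability `1 - exp(-c * V_d)`; well sizes default to the observed range
of 5,549–19,264 read droplets.  `simulate_transcript_fixtures()` builds
spliced transcripts from stop-free codons with stops placed exactly at
the decision boundaries of the NMD rules.

Every generator takes an explicit seed and uses a private RNG stream;
the caller's `.Random.seed` is untouched.

## Normalization chain

`normalize_counts()` applies, in order: background adjustment
(per-sample mean of the negative controls subtracted from
endogenous/housekeeping counts, clamped at zero), within-sample
positive-control scaling (per-sample geometric mean of the positive
controls, scaled to their grand arithmetic mean), across-sample
housekeeping normalization (per-sample housekeeping mean scaled to the
grand mean — afterwards the housekeeping means are equal by
construction), probe exclusion, and replicate averaging.

Choices made where the procedure is underdetermined:

* Background statistic: plain mean of negatives (the nSolver default);
  `mean + k*SD` thresholding is available via `background_stat`.
* Positive-control pooling: geometric means per sample, arithmetic
  grand mean of those — the standard nSolver convention.
* Scale factors outside [0.3, 3] **flag** the sample rather than drop
  it; what to do with a flagged lane is a cohort-level decision left to
  the caller.
* Replicate averaging runs after normalization and accepts groups of
  any size ≥ 2.
* Normalized values stay fractional (no re-rounding): the downstream
  test is rank-based, and rounding could only create ties.

The standard 12-gene TagSet exclusion list (`tagset_exclusions()`)
reduces the 180 endogenous probes to 168 analyzed genes.

## Differential expression

For each tested gene the values of all samples are pooled and
rank-transformed (average ties); Welch's unequal-variance t statistic is
computed on the two groups' rank subsets with Welch–Satterthwaite
degrees of freedom and a two-tailed Student-t p-value, then
Bonferroni-corrected.  By default both endogenous and housekeeping
probes are tested and the multiplier is the number of genes tested
(housekeeping genes can themselves shift between groups, and the printed
gene lists include housekeeping hits); the multiplier is configurable
for the stricter 168-gene convention.  The fold change is
`log2(mean_tumor / mean_normal)` of normalized values; a median-ratio
variant was considered and rejected as the ratio of group means is the
only definition the panel's figure scales support.

**Known limitation.**  The Student-t reference for ranks is approximate.
At 11 vs 38 samples it is accurate at conventional thresholds (the raw
p-value tail at 0.05 is within a few per mil of nominal) but
anti-conservative deep in the tail relevant to Bonferroni correction:
the per-gene tail probability at nominal 2.6e-4 is roughly 1e-3, so the
family-wise error of "Bonferroni-corrected p < 0.05" is about 0.10
rather than 0.05 under the null.  This is a property of the rank-t
approximation itself (the implementation agrees with `stats::t.test` to
1e-12); an exact permutation reference would remove it but is not part
of the procedure implemented here.

## Clustering

`cluster_expression()` reproduces the heatmap computation: rows scaled
to mean 0 / SD 1 (sample SD; zero-variance rows dropped with a
warning), then complete-linkage clustering of genes and samples on
`1 - Spearman's rho` distances (`stats::hclust`).  Gene-axis Spearman
distances are invariant to the row scaling; this is asserted by a test.
Under the default study conditions the two-cluster cut of the sample
dendrogram separates tumors from normals with high aggregate purity,
but complete linkage occasionally splits the heterogeneous tumor group
before detaching the tight fallopian-tube block (the three-cluster cut
is then pure); separation is therefore assessed as an ensemble average
over seeds.

## The co-regulation statistic

For an anchor gene (e.g. *BRCA1*) and a target set (the 12 other
upregulated HR genes), `pooled_rho()` computes per-target Spearman
correlations across tumors, transforms each with Fisher's Z
(`atanh`), averages on the z scale and back-transforms with `tanh`.
`permutation_null()` redraws the target set `m` times (default 10,000)
as random size-`k` subsets of the upregulated-gene pool, pooling the
same way within each draw (the per-draw pooling convention is assumed
Fisher-Z for consistency with the observed statistic).  Subsets are
drawn without replacement; the anchor is always excluded from the pool,
while the other *BRCA* gene and the targets remain in it.
`empirical_p()` is `(n + 1) / (m + 1)` with `n` the number of draws at
least as high as the observed value (ties count, comparison is exact
floating `>=`).  Perfect correlations are clamped to ±(1 − 1e−12)
before `atanh`, with a warning.

`median_split()` supports the descriptive high/low grouping; ties at
the median go to the low group by default (`ties = "high"` implements
the opposite convention, which some displays use).

Because the anchor-target correlations do not depend on the drawn
subset, the per-gene coefficients are computed once and each null draw
averages a sampled subset of z values — `m = 10,000` draws cost
milliseconds, so the default matches the full iteration count.

## NMD rule classification

Coordinates are 1-based and fully closed on the spliced transcript;
distances are counted in nucleotides from the **first** nucleotide of
the stop codon, with the last exon–exon junction located at the last
nucleotide of the penultimate exon.  A premature termination codon
(PTC) is predicted to elicit nonsense-mediated decay when all three
hold:

1. the PTC lies upstream of the last junction by more than the
   junction threshold (default **50 nt** — the permissive end of the
   quoted 50–54 nt range; configurable up to 55);
2. the transcript has more than two exons;
3. the PTC lies more than **200 nt** downstream of the start codon.

For frameshifts, `locate_ptc()` applies the indel to the spliced
sequence (the containing exon's length changes, so downstream junctions
shift consistently) and scans the shifted frame for the first stop
codon; a transcript with no stop before its end is flagged `nonstop`.
Nonsense variants place the PTC at the variant position; missense and
in-frame exon-skip variants (including the founder exon-3 skip class)
yield `not_applicable`.  Refinements of the cited rule set beyond these
three conditions (long last exons, start-proximal escape) are
deliberately not implemented: only the stated rules are applied.

## ddPCR quantitation

`estimate_concentration()` inverts the Poisson occupancy:
`lambda = -ln(negatives/total)` copies per droplet and
`c = lambda / V_d` copies/µL.  The droplet volume is an explicit
parameter recorded in every output: the package's reporting convention
is **0.001 µL** (1 nL), the value forced by the stated equivalence
"0.05 CPD = 50 copies/µL"; the QX200 instrument constant 0.00085 µL can
be passed instead.  The 95% CI uses the delta method,
`SE(lambda) = sqrt(phat / ((1 - phat) N))`.  Zero-positive wells report
`c = 0` with a rule-of-three upper limit; saturated wells substitute
0.5 pseudo-negatives to give a finite flagged lower-bound estimate.

`normalized_ratio()` propagates the CI on the log scale treating the
two channels as independent; duplex channels in fact share droplets,
and at low occupancy the induced (negative) covariance is negligible,
making the interval slightly conservative.  `loading_mass()` implements
the two-assay input-equalization scheme (30 ng first load, second load
scaled to bring the reference gene to 0.05 CPD; masses above 100 ng are
flagged as exceeding a practical well load).  `no_rt_check()` fails a
no-reverse-transcriptase control above 0.2 copies/µL, just above the
highest value seen in accepted runs (0.16 copies/µL).
`concordance()` reports Spearman and Pearson correlations between
platforms and flags samples whose cross-platform rank difference
exceeds a quarter of the cohort size — the numeric discordance
criterion is a free parameter with no published value, so the default
is deliberately loose enough to flag only clear outliers.  When one
gene is covered by several amplicon assays, `select_assay()` applies
the max-median reporting rule (FFPE fragmentation depresses some
amplicons; the highest-reading assay is closest to the truth).

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to make the Monte-Carlo error
small relative to the tested margins: 1,000 simulated wells for
estimator bias (tolerance 2%), 2,000 wells across occupancies
0.01–1.5 CPD for CI coverage (93–97% pooled), 500 null studies at
`m = 200` draws for permutation-test calibration (fraction of
`P <= 0.05` within [0.02, 0.09]), 100 studies at `m = 1000` for power
(≥ 90% detection at the 0.6-correlation regime), 20 studies for
clustering separation, and 1,000 random instances for the
Welch-on-ranks oracle comparison at 1e-12.

## Reproducibility

Every stochastic function takes an explicit integer seed; fixed seed
means byte-identical output.  `scripts/acceptance.R` (repository root)
recomputes the package's headline worked-example quantity — the
occupancy-to-concentration conversion at 0.05 CPD — from scratch
against the installed package and writes it as JSON.
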