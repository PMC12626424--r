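---
title: "Methods: microexon program calling and zebrafish phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microexon program calling and zebrafish phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mexphen)
```

`mexphen` implements four analysis stages around the biology of neural
microexons — 3–27 nt alternative exons with sharply neural-restricted
inclusion, driven by the eMIC domain of the Srrm3/Srrm4 regulators — and the
behavioral and transcriptomic phenotyping of zebrafish lines in which
individual microexons or their regulators are deleted. This vignette
documents the models, the parameters that matter, the synthetic data the
tests rely on, and the numerical choices made where the design was open.

## Tissue-enriched exon calling

The unit of data is a PSI (percent spliced-in) matrix over events × samples,
each cell carrying a coverage-quality code (`N`, `VLOW`, `LOW`, `OK`,
`SOUND`). A cell participates only if its code is at least `min_quality`
(default `VLOW`; `N` is always insufficient, and a PSI value whose code is
`N` is treated as missing). Samples map to tissue groups; a group is valid
for an event when it has at least `min_rep = 1` covered samples, and the
event is eligible when at least `n_groups = 5` groups are valid.

Two thresholds define a call for target group \(T\):

- \(\Delta \mathrm{PSI}_{target}\): the target-group mean minus the
  **unweighted mean of the other group means** (each tissue counts once,
  regardless of how many samples it has); `min_dpsi = 15` PSI units.
- \(\Delta \mathrm{PSI}_{global}\): the target mean minus the mean over all
  **pooled** other covered samples; `min_dpsi_glob = 25`.

Groups listed in the config's `excluded` column for the target are removed
from *both* the eligibility count and the comparison means; this mirrors the
practice of dropping tissues with known partial overlap of microexon
inclusion (e.g. endocrine pancreas when calling neural events) so that
shared inclusion does not dilute the contrast. Because the program of
interest is *enrichment*, calls additionally require
\(\Delta \mathrm{PSI}_{target} > 0\) by default (`require_positive`); the
thresholds themselves are applied to absolute values, so depletion screens
can be run by turning the flag off. Ties between the target and an excluded
group cannot arise because excluded groups never enter the comparison.

Downstream classifiers are deliberately minimal: length classes cut at
27/51 nt (lengths below 3 nt are rejected as outside the defined microexon
range); the regulator response takes the **lowest** ΔPSI across the
available mutant-vs-control comparisons and labels the exon affected when it
is below −15; regulatory conservation requires an exon ortholog, coverage in
the target species, and a neural ΔPSI ≥ 15 there. Association between
length class and regulation uses the exact two-sided Fisher test
(`stats::fisher.test`), with the odds ratio reported as the sample
cross-product \(ad/bc\) (∞ when \(bc = 0\)) rather than the conditional MLE,
since the cross-product is what the contingency summaries quote.

Missing-value imputation (`impute_psi_for_plotting`) exists for heatmap
display only and never enters the calling path.

## Larval activity phenotyping

The protocol timeline is fixed: 5 min habituation, 25 min baseline, dark
blocks at [30,40), [50,60), [70,80) min and light blocks at [40,50),
[60,70) min, 10 min re-habituation, then 30 taps at 1 Hz. Minutes are
half-open, with second 0 of the recording as minute 0.

Numerical conventions:

- Interval means average activity per minute first, then across minutes, so
  they are invariant to reshuffling seconds within a minute; missing minutes
  raise a QC flag and the mean uses the available minutes.
- Transition responses difference the first minute after and the last
  minute before each switch and average across same-type transitions (three
  LD, two DL).
- The per-tap response is the single 1 s bin starting at the tap — taps are
  1 s apart, so windows tile exactly — and "responding" means strictly
  positive activity in that bin. Larvae with zero response to all of the
  first three taps are flagged low responders and excluded from statistics.
- Thigmotaxis is the **median** across moving minutes (zone activity > 0)
  of the per-minute periphery share of total distance moved (TDM), per
  condition (baseline/dark/light). Larvae whose per-minute activity and TDM
  correlate at Pearson r < 0.9 are flagged as tracking mismatches. The
  low-movement rule is interpreted as *fewer than 3 minutes of movement in
  a condition excludes the larva for that condition* — the printed rule
  ("activity = 0 for < 3 min") is ambiguous between too little movement and
  too little immobility, and only the first reading describes larvae whose
  thigmotaxis would rest on almost no data.
- Trials keep only clutches with ≥ 3 larvae per genotype after larva-level
  exclusions.

Cross-replicate genotype comparisons use the subsampled permutation test:
each of `n_perm = 100` permutations draws 10 observations per genotype
(without replacement when the group allows it) and runs a two-sided Wilcoxon
rank-sum test; the **median** of the permutation p-values is reported. When
groups are larger than the subsample this median concentrates and the test
is deliberately conservative at nominal levels; at the design size of 10
observations per genotype it reduces to the exact Wilcoxon test and is
calibrated, which is what the test suite verifies. Percent change versus WT
divides by the WT median, substituting a caller-provided category floor when
that median is zero (zero floors are an error, never silently accepted).

## Pair trajectory metrics

Positions are tracked at 30 fps in a circular arena. Gaps of at most 5
frames are linearly interpolated; longer gaps stay missing and drop out of
every frame-wise denominator. Velocities use central differences and
accelerations second differences on positions smoothed with a Gaussian
kernel of σ = 1 frame (σ = 0 disables smoothing; the closed-form tests run
unsmoothed). The acceleration is decomposed along the unit velocity into
tangential and normal components, reported as absolute values. Frames with
speed below 0.1 cm/s have no defined heading — the paper states no
threshold, so a value well below swim speeds was fixed once — and are
excluded from ratio-in-front and polarization denominators.

"In front" is the half-plane test sign(û · (other − focal)) > 0; no cone
angle is stated by the metric's name, and the half-plane makes the isotropic
null exactly 0.5. Polarization for a pair uses the standard order parameter
|mean of the two unit velocities| (1 aligned, 0 antiparallel, √2/2
orthogonal); the general-N formula specializes to this for N = 2. The
periphery is the ring from 0.8·R to the wall, inclusive at the boundary;
radial distances are clamped at R to absorb tracking jitter, and
time-in-periphery is emitted both as raw frames and as a fraction.

The comparison scheme avoids double counting: homotypic pairs (Het-Het,
Del-Del) contribute the two-fish average of each individual metric as one
observation ("S" comparisons); within heterotypic pairs each fish
contributes its own value by genotype ("D"). Ratio-in-front is kept per fish
in both schemes, since averaging the two sides of an asymmetric pair would
cancel exactly the leadership signal. Pair metrics compare Het-Het vs
Het-Del ("HM") and Het-Het vs Del-Del ("HD"). All comparisons are unpaired
two-sided Wilcoxon rank-sum tests; a paired design for within-pair contrasts
would also be defensible but is not what rank-sum reporting implies.

## Transcriptomic compensation

Counts (optionally passed through the identity degradation-correction hook;
transcript-degradation normalization itself is out of scope) are normalized
with median-of-ratios size factors and stabilized as
\(\log_2(c/s_j + 1)\). This is a log-scale approximation of a
variance-stabilizing transform: every downstream statistic uses only
monotone differences of stabilized values, for which the exact transform
choice is immaterial. A fixed reference profile can be supplied to make the
transform exactly equivariant to per-sample scaling.

Batch adjustment is fitted on WT samples only: per-gene batch-mean
deviations from the WT grand mean are shrunk toward zero by an
empirical-Bayes factor \(1 - \sigma^2_{noise}/\overline{d^2}\) estimated
from the across-gene **mean square** of deviations (a variance would be
blind to a constant batch offset) and subtracted from *all* samples of the
batch — genotype effects therefore survive even when confounded with batch.

Per-line differences are mean(Del) − mean(WT) per gene. Host genes and
paralogs are flagged when their difference falls in the outer deciles
(≤ 10th or ≥ 90th percentile) of the line's distribution. The cross-line
score Σ|Δ| ranks genes with coordinated changes first and feeds a
**positive** preranked GSEA (only positive running-sum deviations are
scored, appropriate for a ranking of magnitudes).

The GSEA engine is the weighted Kolmogorov–Smirnov running sum with hit
increments \(|s|^p/\sum_{hits}|s|^p\) (default p = 1) and miss decrements
\(1/(N - N_{hit})\) — the field-standard convention, under which a top-k set
attains ES = 1 with weight 0; the test suite cross-checks the statistic
against an independent implementation and against brute-force prefix
recomputation. The null permutes gene labels (a preranked design has no
sample-level exchangeability to exploit); NES divides ES by the mean |ES| of
same-sign null draws, and p-values use the same-sign null tail with the
add-one correction, making them slightly conservative but never
anti-conservative. Rankings break ties by gene identifier so results are
reproducible; the universe is the ranked gene list, sets are intersected
with it and bounded to sizes 5–2000 by default.

Enriched terms (BH-adjusted p < 0.01) are clustered by complete-linkage on
the Jaccard distance 1 − |A∩B|/|A∪B| with the tree cut at 0.9, so any two
terms placed together share more than 10% of genes with every other member
under the complete-linkage criterion. Clusters survive only with at least
one member at p < 0.001, are named after their most significant member, and
export the union of member genes, which is then scored per line by
two-sided GSEA on the **signed** per-line differences (both directions are
biologically meaningful for compensation), starred at adjusted p < 0.01.

## Synthetic data: what it emulates and what it does not

The generators define the study conditions for all tests:

- `gen_psi_table`: 6 tissue groups × 3 samples by default; events are
  neural-enriched (base PSI uniform on [5,55] plus a planted `dpsi_effect`,
  default 40 PSI — the scale of a strong neural microexon), null, or
  low-coverage (covered in only 2 groups); per-cell Gaussian PSI noise of
  2 PSI, quality codes dropped to `N` with probability `coverage_dropout`.
- `gen_activity_experiment`: zero-inflated gamma activity per second (30%
  immobile seconds; gamma noise matches the non-negative, right-skewed
  support of %Δpixel data, for which no noise model is published), light
  level 10 %Δpixels, dark gap +5, tap amplitude 20 decaying geometrically
  (0.85/tap by default). Genotype effects enter as multipliers on baseline
  level, transition gap, and tap decay. Zone distances are proportional to
  activity with 2% noise (so tracking QC passes by construction) and a
  periphery bias of 0.65.
- `gen_pair_trajectories`: fixed-step integration at Δt = 1/fps of a
  correlated random walk (Ornstein–Uhlenbeck-style heading noise, 3 cm/s)
  in a 21 cm-radius arena; the follower's heading relaxes toward the
  leader's position at rate `follow_gain`; wall contact projects onto the
  boundary and reverses the heading. This is the simplest model with a
  thigmotaxis-free null and a tunable leadership asymmetry.
- `gen_expression_counts`: negative-binomial counts (dispersion 0.1) over a
  log2-uniform expression landscape, a planted ~50-gene pathway shifted by
  `pathway_shift` log2 units in half the lines (alternating sign), and
  injectable host/paralog shifts; two batches assigned alternately.

Every generator draws from one RNG stream per entity (event, larva, fish,
gene) derived from the master seed, so identical configurations are
byte-identical and generating more entities never changes earlier ones.

What passing tests on these data do **not** show: real inclusion tables
have correlated coverage across samples and events; real larvae habituate
within blocks and differ in baseline between individuals; real fish
biomechanics (burst-and-glide swimming, wall-following) are absent, so the
generator cannot validate thigmotaxis *effects*, only the metric
arithmetic; and real RNA-seq carries library-preparation structure beyond a
single batch offset. The suite therefore validates the estimators and their
calibration, not organism-level effect sizes, which require fish.

## Problem sizes

The test suite and acceptance script run at deliberately small scale: PSI
tables of 15–50 events, trajectories of 3,000–6,000 frames, count matrices
of 300–500 genes, 60–200 replicate simulations for calibration checks, and
200–1000 permutations per GSEA. These sizes were chosen once as the
smallest at which each statistical property is clearly resolvable; all
operations scale linearly or near-linearly in events × samples, frames, or
genes × permutations.

## Known limitations

- The exact variance-stabilizing transform and NES normalization of the
  referenced toolchain are package-defined; the approximations here are
  documented above and affect no rank-based downstream statistic.
- The subsampled permutation median-p test is conservative when group sizes
  exceed the subsample; this is a property of the published procedure, not
  an implementation artifact.
- Significance stars follow the reading `*` 0.001 ≤ p < 0.01, `**`
  0.0001 ≤ p < 0.001, `***` p < 0.0001; published star legends print the
  interval bounds in inverted order, and this is the only monotone reading.
- No multiple-testing correction is applied across behavioral features by
  default (nominal p-values are reported, as in the source analyses); a
  global BH switch is available via `bh_adjust`.
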