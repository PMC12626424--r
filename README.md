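# mexphen

Microexon splicing programs and zebrafish behavioral phenotyping.

Neural microexons — alternatively spliced exons of 3–27 nt with sharply
neural-enriched inclusion — are controlled by the Srrm3/Srrm4 regulators and
are misregulated in autism. `mexphen` implements the quantitative analysis
chain used to characterize this program in zebrafish and to phenotype
microexon deletion lines, for researchers who work with inclusion tables
(PSI matrices), larval activity exports, tracked fish-pair trajectories and
RNA-seq count matrices:

- **`splicing_program`** — calls tissue-enriched exons from a PSI matrix
  with per-cell coverage-quality codes. An event is called for target tissue
  *T* when |ΔPSI_target| = |mean_T − mean of other tissue-group means| ≥ 15,
  |ΔPSI_global| = |mean_T − pooled other-sample mean| ≥ 25, and the event
  has a valid average PSI in ≥ 5 tissue groups (≥ 1 sample of quality VLOW
  or better per group). Length classes (3–27 / 28–51 / > 51 nt), regulator
  response (lowest ΔPSI across mutant comparisons < −15 ⇒ affected),
  cross-species regulatory conservation (ortholog ΔPSI ≥ 15), and two-sided
  Fisher tests on length-class contingencies.
- **`larval_activity`** — per-larva statistics over an 80-minute light/dark
  protocol plus a 30-tap startle block: baseline/dark/light interval means
  (minute means first), LD/DL transition responses (first minute after minus
  last minute before each switch), tap habituation (Act1 − mean of taps 3–5
  and 21–30, low-responder exclusion), thigmotaxis (median per-minute
  periphery share of distance moved over moving minutes, with tracking-
  correlation and low-movement QC), and the subsampled permutation
  median-p genotype test (100 permutations of 10 observations per genotype).
- **`social_behavior`** — the nine trajectory metrics for a fish pair:
  speed, absolute normal/tangential acceleration, distance traveled, time in
  the periphery (ring from 0.8·R to the wall), normalized distance to
  origin, ratio-in-front (leadership: the fraction of frames with the other
  fish in the focal fish's frontal half-plane), pair polarization
  |(û₁+û₂)/2| and neighbor distance; plus the homotypic (S) / heterotypic
  (D) / pair-type (HM, HD) Wilcoxon comparison scheme.
- **`transcriptome_compensation`** — per-line Del−WT differences on a
  variance-stabilized scale (median-of-ratios size factors), WT-fitted
  empirical-Bayes batch adjustment, host-gene/paralog decile flags, the
  cross-line joint ranking Σ|Δ|, preranked permutation GSEA (weighted KS
  running sum, sign-matched NES, positive-only mode) and complete-linkage
  Jaccard clustering of enriched GO terms cut at 0.9.
- **`synthetic_data`** — seeded generators for all four input types with
  planted ground truth, so every stage is testable without any download.
- **`stats_core`** — bootstrap-Wilcoxon median p (10,000 × 50 per group),
  exact rank-sum wrapper, BH adjustment, rank-based two-founder ANOVA.

## Worked example

```r
library(mexphen)

cfg  <- sim_config(seed = 2025, n_events = 50, dpsi_effect = 40)
sim  <- gen_psi_table(cfg)
calls <- call_tissue_enriched(sim$table, sim$config_table,
                              calling_params(), "Neural")
head(calls[calls$called, ], 3)
#>  event_id length_class dpsi_target dpsi_global n_valid_groups called
#>    EV0004    mid_28_51    38.13607    38.13607              6   TRUE
#>    EV0005    long_gt51    38.34347    38.41680              6   TRUE
#>    EV0016    long_gt51    41.22974    41.17176              6   TRUE
sum(calls$called)
#> 13   # exactly the planted neural-enriched events
```

All 13 planted events (and nothing else) are recovered: with a 40-PSI
planted enrichment both ΔPSI thresholds clear comfortably. The published
regulated-vs-length contingency (191/243 regulated microexons vs 122/317
long exons):

```r
length_class_association(matrix(c(191, 52, 122, 195), 2, byrow = TRUE))
#> odds ratio 5.9, p = 8.36e-22
```

A synthetic pair with strong following (fish 2 follows fish 1):

```r
pm <- pair_metrics(gen_pair_trajectories(
  sim_config(seed = 11, follow_gain = 3, n_frames = 6000)))
pm[, c("genotype", "speed", "ratio_in_front", "polarization",
       "neighbor_distance")]
#>  genotype speed ratio_in_front polarization neighbor_distance
#>       Het 2.918          0.100        0.921             1.744
#>       Del 2.913          0.931        0.921             1.744
```

The leader (Het, fish 1) has the other fish in front only 10% of the time —
low ratio-in-front means high leadership — while the follower sees its
partner ahead 93% of the time; the pair is tightly aligned (polarization
0.92) and close (median 1.7 cm).

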