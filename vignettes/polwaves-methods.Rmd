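---
title: "Calling Pol II waves and elongation rates from PRO-seq time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling Pol II waves and elongation rates from PRO-seq time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polwaves)
```

## The scientific setting

Precision run-on sequencing (PRO-seq) maps the 3' end of nascent RNA —
the last base incorporated by an engaged RNA polymerase II — at
single-base resolution, so a PRO-seq track is a genome-wide snapshot of
where polymerases sit. When a transcription kinase is inhibited within
seconds-to-minutes (an analog-sensitive kinase plus a bulky ATP analog),
repeated snapshots form a time course in which polymerase redistributions
reveal elongation kinetics directly.

`polwaves` implements the analysis for the situation where inhibition
splits engaged polymerases into two kinematic populations at a
promoter-proximal checkpoint:

* polymerases upstream of the checkpoint continue, but at a severely
  reduced rate `v_slow`, forming an **advancing wave** of elevated
  density spreading from the TSS;
* polymerases already past the checkpoint keep a fast rate `v_fast` and
  run ahead, leaving behind a transiently **cleared zone** whose
  downstream edge is the rear of the fast (clearing) population.

Per-gene wave positions over time are turned into elongation rates by
linear regression of distance on time: the advancing slope estimates
`v_slow` and the clearing slope `v_fast`.

## The synthetic-data generator

Every stage of the pipeline is testable against a simulator with known
ground truth. The generator uses conveyor-belt kinematics: with constant
initiation rate `r` and speed `v`, steady-state polymerase density is
`rho = r / v`. At time `t` minutes after inhibition the expected density
along a gene of length `L`, measured from the TSS, is piecewise:

| segment (bp from TSS)                       | density                     |
|---------------------------------------------|-----------------------------|
| `[0, v_slow t)`                              | `init * v_ref / v_slow`     |
| `[v_slow t, ckpt + v_slow t)`                | `init`                      |
| `[ckpt + v_slow t, ckpt + v_fast t)`         | background only (cleared)   |
| `[ckpt + v_fast t, L)`                       | `init`                      |

plus an additive promoter-proximal pause peak
(`pause_peak_height * init` over `pause_peak_width` bp), an exponential
termination decay past the CPS with e-folding length
`termination_decay_bp`, and a uniform intergenic background. Counts are
Poisson draws per base (an optional negative-binomial mode with
dispersion `nb_dispersion` exercises the differential test under
overdispersion). At `t = 0` the profile reduces exactly to the untreated
steady state, so the 0-minute sample is the untreated reference.

Default parameter choices, made once:

* `v_slow = 400`, `v_fast = 1200` bp/min — the scale of a severely
  slowed 5' population against a several-fold faster downstream
  population.
* `v_ref = 2000` bp/min — the pre-inhibition effective rate entering the
  density elevation `v_ref / v_slow`. No fission-yeast measurement
  exists for this quantity; the value adopts the ~2 kb/min budding-yeast
  scale and is an explicit assumption of the generator, not a measured
  input.
* `checkpoint_distance = 500` bp — promoter-proximal, downstream of the
  pause peak.
* `initiation_density = 0.5` reads/bp and `background_density = 0.04`
  reads/bp — a clearly active gene body over an intergenic floor on the
  scale seen in combined untreated libraries.
* `front_offset = 0` — the advancing wave starts at the TSS at `t = 0`.
* gene lengths are drawn from a log-normal with median ~1.8 kb truncated
  to `gene_length_range`, the length scale of fission-yeast
  transcription units; at least 10% of genes are at least 6 kb so
  long-gene analyses are always exercisable. This skewed distribution is
  what makes the region-level signatures emerge: at 5 minutes the
  cleared zone spans roughly 2.5–6.5 kb from the TSS, so late-gene-body
  losses concentrate in the *longest* genes only when most genes are
  shorter than that window.
* two biological replicates per timepoint, each with `1e5` spike-in
  mapped reads (normalization factor 1), Poisson noise.

What the generator does **not** emulate: sequence content (no reads, no
mappability structure), batch effects, transcript isoforms or
bidirectional promoters, pause-site heterogeneity, and gradual (rather
than instantaneous) kinase inhibition. Passing the recovery tests
therefore demonstrates correctness of the algorithms under the stated
kinematic model, not performance on any particular experimental
dataset.

```{r simulate}
cfg <- simulation_config(n_genes = 10, gene_length_range = c(6000, 8000),
                         n_chromosomes = 1, chrom_length = 120000, seed = 7)
genome <- make_toy_genome(cfg)
sim <- simulate_inhibition_timecourse(cfg, genome)
head(sim$ground_truth, 4)
```

## Track input and normalization

Tracks are strand-specific single-base 3'-end counts read from bedGraph
pairs (0-based half-open; minus-strand values accepted as positive or
negative magnitudes and stored as magnitudes). Each library carries its
spike-in mapped read count and is scaled by the normalization factor
`spike reads / 1e5`; replicate libraries are combined by summing raw
counts and spike reads, which is equivalent to pooling the raw data.
Gene-relative coordinates follow one convention everywhere: `+n` means
`n` bases downstream of the anchor (TSS or CPS) along the gene's strand,
with half-open intervals at the downstream edge.

## Gene-set construction

Three filters reproduce the gene-set logic:

1. **Observed TSS.** The TSS is re-annotated to the position of maximum
   background-subtracted PRO-cap 5'-end signal within ±250 bp of the
   existing annotation. The selected base must exceed background by more
   than 4 reads after library-size scaling (strict inequality). The
   PRO-cap background is estimated from the same intergenic region set
   as the activity filter, scaled to the PRO-cap library — the one
   background concept, consistently library-scaled. Argmax ties break
   toward the position nearest the original annotation, then upstream
   (least-change principle).
2. **Activity.** A gene is active when its body count `k` over length
   `L` is improbable under the intergenic background: upper-tail Poisson
   `P(X >= k)` with mean `lambda L`, significant at `p < 0.01`. The body
   here is observed TSS through CPS, promoter included (the test asks
   whether the unit is transcribed at all; the bound is configurable).
   `lambda` is raw reads per bp in intergenic regions; the auto-derived
   region set excludes 500 bp upstream and 2 kb downstream of every gene
   (the larger CPS-side buffer keeps post-CPS termination zones out of
   the background).
3. **Read-through.** Genes keep only if the early gene body
   (+250..+550) strictly exceeds the immediate upstream window (−300 to
   the observed TSS) in normalized signal; equality fails, treating
   ambiguous promoters as read-through suspects.

## Pausing, profiles and region-level changes

The pausing index is promoter density (TSS..+100) over body density
(+100..CPS). The body bound is the non-overlapping complement of the
promoter window; the paper-facing definition leaves the body bounds
open, so they are exposed as arguments. Quartiles are rank-based with
deterministic id-based tie-breaks; condition comparisons use empirical
CDFs of log10 PI plus a two-sample Kolmogorov-Smirnov statistic (the
CDF display does not name a test; KS is the natural functional
comparison and is reported as such).

Composite profiles average normalized signal within bins first, then
unweighted across genes. Fold-change matrices use 10-bp bins over
−250..+4000 from the TSS with epsilon-stabilized ratios
(`log2((t + 0.5) / (u + 0.5))` per bin); bins past a gene's CPS are NA,
and rows are ordered by gene length.

The post-CPS termination zone is summarized on genes with at least the
analysis window of clearance to the next annotated gene: the zone width
is the distance from the CPS at which the CPS-anchored composite first
falls below a fraction `f = 0.25` of its CPS-proximal level (first bin).
The width and window are exposed because no printed definition exists
for this summary; with an exponential decay of scale `tau` and no
background the crossing sits at `tau ln 4`.

Region-level changes use raw strand-aware counts in promoter
(TSS..+100), early body (+150..+450) and late body (CPS−300..CPS) for
genes of at least 800 nt, with spike-in size factors. The test is a
negative-binomial Wald test written for this package — a documented
stand-in for the conventional DESeq2 analysis, aiming for directional
and threshold agreement rather than numerical parity (DESeq2 serves as
an independent cross-check in the test suite). Dispersion is estimated
by method of moments per gene-region unit, clipped to within 8-fold of
a fitted mean-dispersion trend `alpha(m) = a0 + a1/m` and shrunk toward
the trend in log space with weight 0.8; with single replicates the
trend is used outright, which mirrors the reduced power such contrasts
have. The shrink weight was set by simulating the null (5000 NB units,
3 vs 3, true dispersion 0.05) and choosing the default whose raw
type-I error at `p < 0.01` matches the nominal level. Fold changes are
raw maximum-likelihood estimates (no shrinkage): threshold calls, not
effect-size ranking, are the output. Benjamini-Hochberg correction at
adjusted `p < 0.01` defines up/down/ns calls.

## Wave calling

Wave positions come from treated-minus-untreated normalized signal in
50-bp windows along each gene, decoded with three-state left-to-right
hidden Markov models (no backward transitions, no state skipping,
initial state 1). Baum-Welch runs to a log-likelihood tolerance of 1e-6
(at most 200 iterations); decoding is Viterbi with ties broken toward
the earliest state transition, which yields conservative (shorter) wave
distances. Because the constrained topology makes every legal path
monotone, a decoded path is fully described by its two transition
times, and an exhaustive path-enumeration oracle verifies the decoder
exactly in the tests.

**Advancing variant** (genes > 4 kb, all timepoints to 5 min): windows
extend 500 bp upstream of the TSS; state 1 is normal, initialized from
the upstream windows; states 2 and 3 are gamma, initialized by
splitting the gene at the per-timepoint approximate wave distance
(0.5 min = 1 kb, 1 min = 1.5 kb, 2.5 min = 2.5 kb, 5 min = 3.5 kb). The
wave front is the distance from the TSS to the downstream edge of the
last state-2 window. Windowed differences are rectified at zero before
fitting: the advancing wave is a signal-*gain* feature, and the cleared
zone left by the fast population is a signal-*loss* feature belonging
to the other model — without rectification the maximum-likelihood
segmentation locks onto the cleared zone's boundaries whenever a long
quiet 3' plateau follows it.

**Clearing variant** (genes > 6 kb, timepoints to 2.5 min — the
cleared zone is fleeting and has usually merged with the gene end by
5 min): all three states are gamma; state 1 is initialized from the
first 1000 nt downstream of the TSS (inside the advancing wave), state
3 from beyond the per-timepoint approximate clearing start (0.5 min =
3 kb, 1 min = 4 kb, 2.5 min = 5.5 kb). The clearing-wave start is the
state-2/state-3 boundary — the downstream edge of the depleted region
between the two waves. Standardized window values are clamped at
|z| <= 5 (`tsmooth`) before fitting, restricting the leverage of
outlying windows.

Numerical choices shared by both variants:

* gamma emissions require positive support; windowed values are
  affinely shifted by the per-gene minimum minus a small margin
  (5% of the SD), recorded and invertible;
* emission variances are floored at `(0.02 * signal range)^2` — a
  near-constant run of windows can otherwise capture a state as a
  delta spike and dominate the likelihood (the floor enters the gamma
  M-step as a boundary-constrained maximization, so EM ascent is
  preserved, and the gamma M-step itself is the exact weighted MLE via
  Newton iteration on the shape);
* Baum-Welch is restarted from init-distance multipliers
  {1, 0.5, 0.75, 1.25} and the best final likelihood wins — EM is a
  local optimizer and the printed initialization distances are
  approximate by construction;
* a call passes quality control only if EM converged, a state-2
  segment exists, and the Kullback-Leibler divergence between the
  fitted state-2 and state-3 emissions exceeds 1 (closed forms for
  normal/normal and gamma/gamma; quadrature otherwise). The KL > 1
  rule is stated for the clearing variant; the same gate is applied to
  the advancing variant as the single principled criterion available.

Per gene, a wave series is retained only if a quality-passing call
exists at every timepoint of the grid and the distances never recede
toward the TSS.

## Rates

The headline rate is the pooled ordinary-least-squares slope of call
distance (bp) on time (min) over all retained gene × timepoint points,
intercept included: forcing the line through the origin would bias the
slope whenever a fixed offset exists (the clearing distance, for
instance, carries the checkpoint offset by construction), and a toggle
is provided. Uncertainty is reported two ways, as in the source
analysis: a bootstrap in which 10% of called genes are resampled with
replacement 1000 times and the pooled slope refit, and a conservative
gene-by-gene distribution of per-gene slopes. Rate comparisons report
the per-gene Welch t test and, when bootstrap distributions are
available, the two-sided percentile of zero in the bootstrap difference
distribution — the underlying analysis does not print which procedure
backed its significance statement, so both are given.

```{r waves}
combined <- lapply(sim$tracks, combine_tracks)
adv <- call_waves(combined[setdiff(names(combined), "0")], combined[["0"]],
                  genome$genes, "advancing")
series <- filter_wave_series(adv)
fit_rate(series$calls)
```

## Problem sizes and what the tests show

The package's own verification runs at desk scale: cohorts of 10-50
genes on 0.1-0.6 Mb toy genomes, 2 replicates, five timepoints, with
the acceptance analysis using 40 genes of 6-8 kb. At these sizes the
full suite (including exhaustive decoder enumeration on 400 random
instances and a 5000-unit null calibration of the differential test)
completes in a few minutes. Recovery under the default noise model is
essentially exact for the advancing rate and within a few percent for
the clearing rate; this validates the estimators under the generator's
assumptions — instantaneous inhibition, sharp kinematic boundaries,
Poisson counts — and real data, with blurred fronts and biological
heterogeneity, will be harder.

## Known limitations

* The two-population model assumes a single checkpoint distance shared
  by all genes and instantaneous inhibition; graded or gene-specific
  checkpoints would blur both waves.
* The advancing-variant rectification discards signal-loss information
  by design; a gene whose only inhibition response is loss (no slow
  wave) yields no advancing call, by intention.
* The NB Wald stand-in does not reproduce DESeq2 numerically (no
  Cox-Reid adjustment, no LFC shrinkage, simplified dispersion
  moderation); agreement is directional at the call threshold.
* Single-replicate contrasts fall back to trend-only dispersions and
  have reduced power.
* bigWig input is not implemented; bedGraph (and BED6/GFF3 for genes)
  is the interchange format.
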