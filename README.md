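# polwaves

Advancing- and clearing-wave analysis of RNA polymerase II from
spike-in-normalized PRO-seq time courses.

## The problem

PRO-seq maps the 3' end of nascent RNA — the position of every engaged
Pol II — at single-base resolution. When a transcription kinase is
inhibited within a minute (analog-sensitive kinase + bulky ATP analog),
a time course of PRO-seq snapshots shows polymerase redistributions that
directly encode elongation kinetics. In fission yeast, inhibiting the
Spt5-phosphorylating kinase splits engaged Pol II into two populations
at a promoter-proximal checkpoint:

* an **advancing wave**: polymerases upstream of the checkpoint continue
  with a severely reduced rate `v_slow`, piling up into a front of
  elevated density that spreads from the TSS;
* a **clearing wave**: polymerases already past the checkpoint keep a
  fast rate `v_fast` and run ahead, leaving a transient zone of depleted
  signal behind them.

`polwaves` is for analysts who have such time courses as strand-specific
single-base 3'-end coverage (bedGraph) with spike-in normalization
counts, and want per-gene wave positions and population elongation rates
with uncertainty.

## The method in brief

For each gene and timepoint, treated-minus-untreated normalized signal
in 50-bp windows is decoded with a three-state left-to-right hidden
Markov model (Baum-Welch + Viterbi; state 1 upstream/5' context, state 2
the wave, state 3 downstream). The advancing-wave front is the end of
state 2; the clearing-wave start is the state-2/3 boundary of an
all-gamma variant. A call passes quality control when EM converged and
the Kullback-Leibler divergence between the state-2 and state-3
emissions exceeds 1; a gene is kept when every timepoint passes and the
distances never recede toward the TSS. The elongation rate is the pooled
OLS slope of distance (bp) on time (min):

```
distance_g(t) = a + v * t + e,    v = elongation rate (bp/min)
```

with a 10% x 1000 bootstrap over genes and a per-gene slope distribution
for uncertainty. Upstream of wave calling, the package re-annotates TSSs
from PRO-cap 5'-end signal, filters genes for activity against an
intergenic Poisson background (`P(X >= k)` at `p < 0.01`) and for
freedom from upstream read-through, computes pausing indices
(TSS..+100 over +100..CPS), composite profiles, log2 fold-change
matrices, post-CPS termination metrics, and treated-vs-untreated
negative-binomial Wald tests on promoter/early/late gene regions with
spike-in size factors (`spike reads / 1e5`) and Benjamini-Hochberg
correction. A kinematic simulator generates complete synthetic data sets
with known ground truth; see the methods vignette
(`vignettes/polwaves-methods.Rmd`) for the model and all defaults.

## Worked example

Simulate a 10-gene cohort of long genes under the two-population model
(`v_slow = 400`, `v_fast = 1200` bp/min), call both waves, and estimate
the rates:

```r
library(polwaves)

cfg <- simulation_config(n_genes = 10, gene_length_range = c(6000, 8000),
                         n_chromosomes = 1, chrom_length = 120000, seed = 7)
genome <- make_toy_genome(cfg)
sim <- simulate_inhibition_timecourse(cfg, genome)
combined <- lapply(sim$tracks, combine_tracks)   # pool replicates
treated <- combined[setdiff(names(combined), "0")]

adv <- call_waves(treated, combined[["0"]], genome$genes, "advancing")
series <- filter_wave_series(adv)
head(series$calls[, c("gene_id", "timepoint", "distance_bp", "kl", "pass")], 4)
#>   gene_id timepoint distance_bp       kl pass
#> 1    g001       0.5         200 42.01990 TRUE
#> 2    g002       0.5         200 38.60691 TRUE
#> 3    g003       0.5         200 42.55632 TRUE
#> 4    g004       0.5         200 50.41275 TRUE

fit_rate(series$calls)
#> RateEstimate: 400.0 bp/min (intercept 0 bp, r2 1.000, 10 genes, 40 points)

clr <- call_waves(treated, combined[["0"]], genome$genes, "clearing")
cest <- fit_rate(filter_wave_series(clr)$calls)
cest
#> RateEstimate: 1192.3 bp/min (intercept 517 bp, r2 0.999, 10 genes, 30 points)

cmp <- compare_rates(fit_rate(series$calls), cest)
sprintf("difference = %.0f bp/min, Welch p = %.2e", cmp$difference, cmp$welch_p)
#> "difference = 792 bp/min, Welch p = 3.89e-15"
```

The advancing calls sit on the kinematic truth (`v_slow * t`; 200 bp at
30 s), the pooled advancing slope recovers 400 bp/min, and the clearing
slope recovers ~1200 bp/min with an intercept near the 500-bp checkpoint
— the clearing distance is `checkpoint + v_fast * t` by construction.
For file-based workflows, `run_pipeline("all", config, outdir)` executes
simulate → filter → metrics → diff → waves → rates against bedGraph/BED
artifacts on disk with per-stage manifests, and
`inst/scripts/polwaves.R` wraps it for the shell.

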