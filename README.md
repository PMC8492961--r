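# elongatr

Stochastic modeling of early RNA polymerase II (RNAPII) elongation and
analysis of NET-seq/TEF-seq/MNase-seq-derived signal tracks, for
researchers studying transcription elongation through chromatin in yeast
and other organisms with phased gene-body nucleosomes.

NET-seq reports the position of the RNA 3′ end in the RNAPII active site
at single-nucleotide resolution, capturing moving, stalled and backtracked
polymerases alike. `elongatr` turns the *shape* of a gene's NET-seq
profile into interpretable elongation dynamics:

* **Simulator** — a discrete-time exclusion process on a population of
  identical 1,000-nt genes: initiation (blocked while position 1 is
  occluded by a 40-nt polymerase footprint), Poisson elongation hops,
  stalling, backtracking, resumption, collisions (a truncated hop stalls
  the upstream polymerase and terminates a stalled downstream one), early
  termination at a Poisson-placed site, and two kinetic windows with
  independent rates. Steady state is reached over 8,000 steps of
  dt = 0.005 min. The stepping kernel is compiled (Rcpp).
* **Fitting** — Latin-hypercube parameter sweeps; profiles binned to
  10 nt over the first kilobase and normalised to sum 1; goodness of fit
  by the Kolmogorov–Smirnov statistic max |ΔCDF|; per-gene metrics from
  the k best-fitting sets: initiation/elongation ratio, moving ratio in
  windows 1 and 2 (moving ÷ stalled+backtracked), window-1 size, mean
  early-termination site, and processivity (% reaching 1,000 nt).
  Conditions are compared per gene by paired Cohen's d
  (mean difference ÷ sd of differences) with paired t-tests.
* **Track processing** — no-tag background correction
  `flag − r·notag` with `r` estimated from 10-nt bins of a
  high-background RNAPIII locus; spike-in calibration by the
  median-of-ratios estimator; trimmed-mean metagenes with the standard
  gene filters (length, negative values, TSS-annotation sanity).
* **Chromatin** — nucleosome dyad labeling (−1, +1…), NDR length and
  dyad spacing with replicate-level median tests; TEF/RNAPII ratio
  metagenes around dyads; a one-tailed paired flank test
  (−60..−10 vs +10..+60 nt from the dyad); per-gene shape (z-score)
  normalisation; expression-group spacing curves.
* **Synthetic data** — a generator that emits annotation, NET/TEF/no-tag
  tracks, spike-in counts and replicated dyad calls with every generating
  value recorded, so all of the above can be validated against known
  truth.

## Worked example

Simulate a transcription regime and inspect its measured metrics:

```r
library(elongatr)

p <- model_params(initiation_rate = 1, elongation_rate = 2)
r <- simulate_population(p, population_size = 2000, seed = 1)
r
#> <sim_result> population 2000, gene 1000 nt
#> # A tibble: 1 × 3
#>   moving_ratio_w1 moving_ratio_w2 processivity
#>             <dbl>           <dbl>        <dbl>
#> 1           0.813            2.29         77.1
```

Under the default regime, fewer polymerases are in the moving state in
window 1 than beyond it (moving ratios 0.81 vs 2.29 — early elongation is
where stalling concentrates), and 77% of initiated polymerases reach
1,000 nt.

Paired effect size between two per-gene metric vectors:

```r
cohens_d_paired(c(1, 2, 3, 4), c(2, 2, 5, 5))
#> $d
#> [1] 1.224745
#> $magnitude
#> [1] "large"
#> $p_value
#> [1] 0.09172111
#> $n
#> [1] 4
```

End to end on synthetic data with known truth:

```r
d <- generate_dataset(synthetic_spec(n_genes = 30, depth = 2000, seed = 42))
corrected <- notag_correct(d$tracks$net, d$tracks$notag, window = d$scr1)
genes <- filter_genes_for_metagene(corrected, d$annotation)
nrow(genes)
#> [1] 21
fl <- flank_asymmetry_test(d$tracks$tef, d$tracks$net, d$annotation,
                           d$dyads, "+2")
signif(fl$p_value, 3)
#> [1] 0.00218
```

The generator plants a dyad-locked TEF/RNAPII oscillation (amplitude
0.2), and the flank test detects the resulting upstream-vs-downstream
asymmetry at the +2 nucleosome across 30 genes.

The full pipeline — synthesis, normalisation, metagenes, sweep + fit,
effect sizes, nucleosome statistics — runs as
`run_pipeline(default_config(), "out_dir")`, or from a shell via
`inst/scripts/elongatr-pipeline.R`.

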