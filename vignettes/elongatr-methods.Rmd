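---
title: "Modeling early RNAPII elongation and analysing NET-seq profiles with elongatr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling early RNAPII elongation and analysing NET-seq profiles with elongatr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elongatr)
```

# The scientific problem

NET-seq maps the RNA 3′ end held in the RNA polymerase II (RNAPII) active
site at single-nucleotide resolution, so a gene's NET-seq profile is a
snapshot of where engaged polymerases sit — moving, stalled, or backtracked
alike. The shape of that profile over the first kilobase of a gene encodes
the underlying elongation dynamics: how often polymerases initiate, how
fast they move, where and how often they stall or backtrack, and how many
terminate early. `elongatr` provides

1. a stochastic, discrete-time exclusion-process simulator of RNAPII
   transcription over a 1,000-nt synthetic gene;
2. a Latin-hypercube sweep plus Kolmogorov–Smirnov (KS) fitting machinery
   that matches simulated steady-state occupancy to per-gene NET-seq
   profiles and summarises each gene by six interpretable metrics;
3. the accompanying sequencing-track computations: no-tag background
   correction anchored on a high-background RNAPIII locus, spike-in
   median-of-ratios calibration, trimmed-mean metagenes, nucleosome-dyad
   anchored TEF/RNAPII ratio profiles with a one-tailed flank test, and
   nucleosome position/NDR/spacing statistics;
4. a ground-truth synthetic-data generator so every analysis can be
   validated end to end.

# The transcription model

A population of identical 1,000-nt genes is simulated in time steps of
`dt = 0.005` min for 40 min (8,000 steps), long enough for occupancy to
reach steady state. Each engaged polymerase has a 1-based active-site
position, a state (MOVING, STALLED, BACKTRACKED), and a footprint of 40 nt
that no other active site may approach (exclusion). Two kinetic windows
split the gene at `window1_end`; stalling, backtracking and resumption
rates may differ between them, reflecting the distinct regulation of early
versus later elongation.

Per step, polymerases are updated most-downstream first, so nobody moves
into space vacated upstream within the same step (the standard sweep for
exclusion processes). Transitions are mutually exclusive per step, with
per-step probabilities `rate * dt`; an error is raised if any such
probability exceeds 1, which keeps the discretisation honest:

* **MOVING** — stalls with probability `stall_rate * dt`; otherwise hops
  `n ~ Poisson(elongation_rate * 1000 * dt)` nt. The Poisson hop allows
  kb-per-minute speeds (mean hop 10 nt per step at 2 kb/min) while staying
  stochastic. A hop is truncated so the polymerase stays ≥ 40 nt behind
  its downstream neighbour; a truncated hop is a *collision*.
* **STALLED** — backtracks with probability `backtrack_rate * dt`, else
  resumes with probability `resume_stall * dt`.
* **BACKTRACKED** — resumes with probability `resume_backtrack * dt`.
  Backtracked polymerases do not change position: NET-seq reports the RNA
  3′ end, and no backtrack displacement is modelled.

Collisions resolve by the state of the downstream partner: the upstream
polymerase always stalls; a stalled downstream polymerase is terminated
and removed; moving or backtracked downstream polymerases are unchanged.

Initiation places a MOVING polymerase at position 1 with probability
`min(initiation_rate * dt, 1)` per gene per step unless position 1 is
occluded (an active site within 40 nt). With probability
`early_term_prob` the newcomer is assigned an early-termination site drawn
from `Poisson(early_term_mean)` (redrawn while 0 or beyond the gene);
reaching that site removes it. Reaching position 1,000 removes it as
*completed*. Occlusion and collision are deliberately distinct: occlusion
blocks initiation and truncates hops, while the resolution rules above
apply only when a hop is actually truncated.

Two modelling choices were genuinely open and are worth stating. First,
whether *every* polymerase is subject to early termination: a universal
Poisson-placed termination site would drive processivity to ~0, so the
fraction-of-polymerases parameter `early_term_prob` is this package's
resolution. Second, whether the "moving ratio" is a final-snapshot or
time-averaged quantity: the final snapshot is the default, matching the
occupancy output convention, with `moving_ratio = "time_averaged"`
(second half of the run) available.

The output of `simulate_population()` is the final-snapshot occupancy
(summed active-site positions across the population), per-gene event
tallies obeying the conservation law
`initiated = engaged + completed + early_terminated + collision_terminated`,
and the measured metrics: moving ratio per window (MOVING over
STALLED + BACKTRACKED) and processivity (completed/initiated, %).

```{r sim-example, eval = FALSE}
p <- model_params(initiation_rate = 1, elongation_rate = 2)
r <- simulate_population(p, population_size = 2000, seed = 1)
r$metrics
plot_occupancy(r)
```

The stepping kernel is compiled (Rcpp): a 500-member, 8,000-step run with
per-step invariant assertions takes about a second on one core.

# Fitting profiles and the six metrics

Experimental and simulated profiles are compared on a common footing: the
first 1,000 nt from the TSS, summed into 10-nt bins, each bin divided by
the total so the vector sums to one. The goodness of fit is the KS
statistic — the maximum absolute difference between the two binned CDFs —
implemented directly (it is the method's core primitive) and checked in
the tests against a brute-force CDF scan.

`lhs_sample()` draws parameter sets by Latin-hypercube sampling so each
dimension is stratified into equal-probability bins;
`default_parameter_ranges()` ships plausible sweep bounds (initiation
0.1–10 min⁻¹, elongation 0.5–4 kb·min⁻¹, window-1 end 50–500 nt,
stall/backtrack/resume rates 0–20 min⁻¹, early-termination mean 50–800 nt
and probability 0–0.5), every one overridable — the sweep mechanics, not
the exact bounds, are the substance. `simulate_library()` simulates each
set and stores its binned profile plus measured metrics; `fit_gene()`
ranks the library by KS distance and averages the `k_best` best-fitting
sets into six per-gene metrics:

1. initiation-to-elongation ratio (`initiation_rate / elongation_rate`,
   in min⁻¹ per kb·min⁻¹);
2. moving ratio in window 1;
3. window-1 size (`window1_end`);
4. mean early-termination location;
5. moving ratio in window 2;
6. processivity (% reaching 1,000 nt).

The headline convention is `k_best = 1` for displaying best fits and
`k_best = 100` for metric comparisons; with desk-scale libraries
(hundreds of sets rather than 150,000) a proportionally smaller `k_best`
(10–25) avoids averaging over poorly fitting sets, and the choice is
exposed as an argument. The aggregator is the mean over sets with a
defined value — a set's moving ratio is undefined (NaN) when its final
snapshot has no stalled or backtracked polymerase in a window — and can
be replaced (e.g. by `median`).

The early occupancy peak near the TSS produced by the simulator sits in a
region NET-seq does not detect reliably; fitting nevertheless uses all
100 bins, and a bin mask can be applied by the caller by zeroing bins
before `gene_profile()`.

Genes enter fitting through the two-stage filter of
`select_genes_for_fitting()`: longer than 1,000 nt, then first-kilobase
totals strictly greater than the mean over the initially selected genes.

Condition pairs are compared gene-by-gene with a paired Cohen's d
(`cohens_d_paired()`): the mean of the per-gene differences divided by
the standard deviation of the differences, positive meaning an increase
in the second condition, with the conventional |d| labels (0.2/0.5/0.8 =
small/medium/large) and a two-sided paired t-test p-value. Raw p-values
are reported; none of the implemented operations calls for
multiple-testing correction.

# Track processing

Tracks are tibbles of strand-resolved, 3′-end-assigned single-nucleotide
counts; bedGraph (one file per strand) and BED are read and written via
`rtracklayer`. Internally, windows are extracted transcription-oriented
with the `+1` convention: +1 is the TSS nt, 0 the nt just upstream. Dyad
anchored windows use 0 = dyad. The printed background-locus interval
(chrV:442,007–442,458) is treated as 1-based inclusive.

**No-tag correction.** The background ratio `r` is the mean over the
10-nt bins of the high-background locus of the per-bin tagged/no-tag
count ratio, skipping bins with zero no-tag counts; the corrected track
is `flag − r · notag`, elementwise. Corrected values can go negative;
the metagene gene filter discards genes with any negative value in the
plotted window (the filter exists to protect metagenes, so it examines
the plotted window rather than the whole genome).

**Spike-in calibration.** `spikein_size_factors()` implements the
median-of-ratios estimator directly on the spike-in species' counts
(per-gene geometric mean across samples as reference; per-sample factor =
median count/reference over genes with full nonzero rows); experimental
tracks are divided by their sample's factor. The tests cross-check the
implementation against DESeq2's estimator on random tables.

**Metagenes.** After the three gene filters (protein-coding and > 750 nt;
no negative corrected values in the window; genes with upstream
(−150..0) counts more than 1.5× downstream (+1..+150) counts discarded
as likely TSS mis-annotations), the per-position mean across genes is
computed excluding the top and bottom 1% of per-gene values at that
position — `ceiling(0.01 · n)` genes per tail — and then averaged into
10-nt bins. Whether the 1% trim is per position, per gene or global is
underdetermined; per-position trimming is the default because the trim is
applied while forming the per-position mean, and a `trim_mode = "global"`
alternative is provided.

# Dyad-anchored analyses

Dyads are labeled per gene and replicate: +1 is the first dyad at or
downstream of the TSS (with a configurable upstream tolerance, default
0 nt), −1 the last upstream. `nucleosome_positions()` reports
TSS-relative dyad positions, NDR length (distance between the −1 and +1
dyads) and adjacent-dyad spacings; condition comparisons take
per-replicate medians across genes and test them with a paired two-sided
t-test across replicates. `ratio_metagene()` divides the TEF-seq metagene
by the NET-seq metagene around per-gene anchor dyads, masking bins with
zero NET signal. `flank_asymmetry_test()` compares, per gene, the
TEF/RNAPII ratio over −60..−10 nt versus +10..+60 nt from the dyad
(closed intervals, transcription-oriented; the ±10-nt core is excluded)
with a one-tailed paired t-test of upstream < downstream; the per-gene
flank value is the ratio of flank sums, which weights positions by
coverage and avoids dividing by empty bins. `shape_normalize_gene()`
z-scores a profile using the population standard deviation.
`mnase_gene_filter()` keeps protein-coding genes ≥ 600 nt with the
required number of dyads in +1..+600 in *every* replicate; because
"4 peaks" could mean exactly or at least 4, both modes exist
(`at_least` is the default). `expression_group_spacing()` bins genes
into equal-size quantile groups (8 by default) by NET-seq density over
the first 500 nt and reports median density and median/sd spacing per
group; the same mechanics serve the fixed-size grouping by +1-nucleosome
location.

# The synthetic-data generator

`generate_dataset()` produces every input the pipeline consumes, with
truth recorded. Its defaults are the study conditions of the package's
validation suite, chosen once:

* 200 genes (tests use fewer where stated), lengths uniform 1,100–1,500 nt
  so the 1,000-nt fitting filter and the 750/600-nt analysis filters all
  bite; alternating strands; 500-nt intergenic gaps on one synthetic
  chromosome.
* Per-gene NET expectation = the simulator's occupancy shape (extended
  flat past 1,000 nt at the level of its last 100 nt) × sequencing depth ×
  a lognormal per-gene expression factor (sdlog 0.75, mean 1), then
  Poisson sampled. The default depth is ~50 reads per gene for
  fitting-noise studies; track-level analyses (metagenes, flank tests)
  use ~2,000 reads per gene, the coverage scale of filtered deeply
  sequenced libraries.
* TEF expectation = NET expectation × `1 + A sin(2π (x − d₊₁)/spacing)`
  with amplitude A = 0.2 locked to the +1 dyad, so the TEF/NET ratio
  oscillates with nucleosome periodicity; `A = 0` is an exactly symmetric
  null. Amplitudes ≥ 1 are rejected (negative expectations).
* Background is additive Poisson shared in expectation between tagged and
  no-tag samples — so the printed correction formula is exactly the right
  estimator — at a low genome-wide rate (0.001/nt/strand) plus an
  SCR1-like hot locus (5/nt); real no-tag IPs concentrate their signal at
  a few sticky loci, and a genome-wide-dense background would make the
  any-negative-value gene filter reject everything. The no-tag library is
  scaled by 0.7, so the true correction ratio is `spike_factor / 0.7`.
* Spike-in species: 50 genes with mean counts 100× a uniform(0.5, 2)
  factor, scaled per sample by the declared spike factors.
* Nucleosomes: +1 dyad at +60, NDR 170 nt (−1 at −110), spacing 165 nt,
  six gene-body nucleosomes, three replicates of dyad calls with 4-nt
  Gaussian jitter. A mutant's `spacing_delta` widens every spacing from
  +1→+2 onward, leaving the NDR untouched.

`make_condition_pair()` shares the genome layout, expression factors and
spike-in species between conditions so that WT/mutant differences are
exactly the declared deltas. `synthetic_flank_data()` is a deliberately
minimal fixture (isolated single-dyad genes, flat Poisson rates) for
Monte-Carlo size/power studies of the flank test, where the full
generator would be needlessly heavy.

What the generator does *not* emulate: sequence-dependent pausing,
mappability artefacts, replicate-level biological variability beyond
dyad jitter, 3′-end/termination-zone structure, and read-level
processing. Passing tests therefore show the computations are correct
and well calibrated on data that match the model's assumptions, not that
the model captures every feature of real libraries.

# Validation scale and numerical choices

The validation suite runs the sweep at desk scale: a 256-set library at
population 500 with the time-averaged steady-state estimator (which
substitutes for a much larger population at no extra cost) and truth
profiles at population 2,000, versus 150,000 × 100,000 at full scale;
the package reaches the latter by changing two arguments. KS distances are exact to machine precision;
parameter recovery at ~50 reads per gene is assessed by rank (Spearman)
rather than absolute error, since sparse profiles identify the metrics
only up to monotone distortion. Degenerate inputs are handled
explicitly: zero-total profiles refuse to normalise; zero-sd profiles
are excluded from shape normalisation; a zero no-tag locus makes the
correction ratio undefined and is an error; paired differences with zero
variance and nonzero mean signal a degenerate effect-size input.

# The pipeline

`run_pipeline(default_config(), out_dir)` chains the stages on a
generated WT/mutant pair — synthesis, correction and calibration,
metagenes, sweep + fit + metric extraction, paired effect sizes, and
nucleosome statistics — writing TSV tables and a provenance manifest
(package version, seed, config hash). Every printed constant of the
analysis (footprint 40 nt, dt 0.005 min, 40 min, the 750/600-nt and
1.5×/1% filters, flank windows, background-locus coordinates) surfaces
as a named, defaulted key of `default_config()`. Stage toggles fail fast
with classed errors (`elongatr_config_error` vs `elongatr_data_error`)
so a thin script wrapper can map them to distinct exit codes
(`inst/scripts/elongatr-pipeline.R`).

# Known limitations

* The simulator has no promoter-proximal pausing regulation, no explicit
  nucleosomes (their effect is absorbed into window-specific rates), and
  no 3′-end processing; polymerases simply leave at 1,000 nt.
* KS ranking is the only model-selection criterion; there is no
  gradient-based or Bayesian inference, and flat regions of the KS
  landscape limit identifiability at low coverage.
* The moving ratio from a single final snapshot is itself a Monte-Carlo
  estimate; small populations make it noisy (use larger populations or
  the time-averaged option).
* Identifiability at very low coverage is bias-limited, not just
  noise-limited: at ~50 reads per gene, Poisson noise changes *which*
  library shapes look close in KS distance, so the recovered moving
  ratio rank-correlates with truth at ρ ≈ 0.7 and averaging more noisy
  genes per regime stops helping beyond a handful — deeper profiles, a
  denser library, or narrower sweep ranges are needed to do better. With
  noiseless profiles the generating parameter set is recovered at rank 1.
* Exactly/at-least ambiguity in the phasing filter and the per-position
  trim interpretation are resolved by documented defaults with
  alternatives exposed.
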