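# spikecollide

Collision-aware benchmarking of spike sorting, self-contained in R.

Spike sorters turn multichannel extracellular voltage traces into
single-neuron spike trains. Their characteristic failure is the **spike
collision**: two neurons firing within ~2 ms of each other superpose their
waveforms, and whether a sorter recovers both spikes depends on the time lag
between them and on the cosine similarity of the two units' templates.
`spikecollide` provides everything needed to quantify this failure mode
without any external sorter:

* a **simulator** — a 32-channel, 3-column hexagonal probe (18/22 µm pitch),
  parametric spatiotemporal templates with dendritic return currents (so the
  template-similarity axis spans negative to near-parallel values),
  independent or pairwise-correlated Poisson spike trains built by a
  mother-process construction with Gaussian jitter, 4 ms refractory pruning
  with rate compensation, and chunked trace assembly with amplitude
  modulation and additive 5 µV Gaussian noise;
* the **ground-truth comparison machinery** — agreement scores
  `n_match / (n_gt + n_sorted − n_match)` under a 0.4 ms one-to-one matching
  window, Hungarian assignment, per-spike TP/FP/FN labels, per-unit
  accuracy = TP/(TP+FP+FN), precision = TP/(TP+FP), recall = TP/(TP+FN), and
  the well-detected / false-positive / redundant / overmerged unit classes;
* **collision metrics** — synchronous-event detection (±2 ms), collision
  recall in 11 lag bins spanning [−2, 2] ms, pooling by template-similarity
  bins, recall-vs-similarity curves, and lag-wise relative errors of
  cross-correlograms for matched unit pairs;
* **reference sorters** — an oracle, a configurable degraded oracle (deletion
  probability per collision lag and similarity, jitter, spurious spikes), and
  a greedy template-matching sorter with iterative peeling (C++ core), so the
  whole pipeline runs end to end;
* a **benchmark grid runner** over the 3 rates × 3 correlations × n replicates
  design with fully derived seeds and aggregate reports.

## A worked example

Simulate one minute of ground truth at the 20 % correlation level, sort it
with the built-in greedy template matcher, and ask how collision recall
depends on lag and template similarity:

```r
library(spikecollide)

probe     <- make_probe()                                   # 32 ch, 3 columns
templates <- synthesize_templates(probe, n_units = 20, seed = 3)
gt        <- generate_correlated(20, rate = 5, correlation = 0.2,
                                 duration = 60, seed = 2)
rec       <- assemble_recording(templates, gt, noise_sd = 5, seed = 7)

sorted <- greedy_tm_sorter(rec, templates)
cmp    <- compare_sortings(gt, sorted)
glance(cmp)
#> # A tibble: 1 × 11
#>   n_gt_units n_sorted_units n_matched accuracy precision recall n_well_detected
#>        <int>          <int>     <int>    <dbl>     <dbl>  <dbl>           <int>
#> 1         20             20        20    0.863     0.920  0.931              18
```

All 20 units are matched and 18 are "well detected" (accuracy ≥ 0.8); the
sorter recovers ~93 % of spikes overall. The collision-resolved view shows
where the missing spikes live:

```r
events   <- find_synchronous_events(gt)              # ±2 ms spike pairs
profile  <- collision_recall_by_lag(events, cmp)     # 11 bins over [-2, 2] ms
sim      <- cosine_similarity(templates)
pooled   <- pool_profiles_by_similarity(profile, sim)
autoplot(pooled)                                     # recall vs lag, by similarity

collision_recall_by_similarity(profile, sim)
#> # A tibble: 7 × 7
#>   sim_lo sim_hi n_pairs n_events n_spikes  n_tp recall
#>    <dbl>  <dbl>   <int>    <int>    <int> <int>  <dbl>
#> 1   -0.4   -0.2       1        8       16     8  0.5
#> 2   -0.2    0        14      247      494   389  0.787
#> 3    0      0.2      31      518     1036   747  0.721
#> 4    0.2    0.4      30      509     1018   773  0.759
#> 5    0.4    0.6      25      433      866   652  0.753
#> 6    0.6    0.8      44      733     1466  1081  0.737
#> 7    0.8    1        45      735     1470  1011  0.688
```

Recall integrated over the ±2 ms lag range is lowest for anti-parallel
pairs (similarity < −0.2, where a collision cancels part of the detectable
negative peak) and for near-parallel pairs (similarity > 0.8, where the
matcher cannot tell the templates apart); the central lag bins show the
effect much more sharply. `correlogram_relative_error()` translates these
misses into the error a user would see in estimated cross-correlograms.

The full condition grid (rates 5/10/15 Hz × correlations 0/10/20 %) runs
with one call and aggregates across conditions:

```r
cfg <- bench_config(paper_scale = TRUE)   # 30-min recordings, 5 replicates, 45 runs
nrow(run_grid(cfg, "oracle", dry_run = TRUE))
#> [1] 45
```

A thin command-line front end over the same functions ships in
`inst/cli/spikecollide.R` (subcommands `simulate`, `sort`, `compare`,
`collision`, `correlogram`, `grid`, `report`).

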