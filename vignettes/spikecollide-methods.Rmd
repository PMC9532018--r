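---
title: "Benchmarking spike collision resolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking spike collision resolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Spike sorters reconstruct single-neuron spike trains from multichannel
extracellular recordings. Their hardest failure mode is the *spike
collision*: two neurons firing within a couple of milliseconds of each other
produce overlapping waveforms in the traces, and whether a sorter untangles
them depends on the time lag between the two spikes and on how similar the
two units' templates are. **spikecollide** is a self-contained benchmark for
exactly this failure mode: it simulates recordings with controlled firing
rates and pairwise spike-train correlations, compares any sorting output
against exhaustive ground truth, and reports collision-resolved metrics.
This vignette documents the models, the parameters that matter, and the
design decisions behind them.

## The simulation

### Probe and templates

`make_probe()` builds a multi-column probe with hexagonal staggering; the
default is 32 channels in 3 columns with 18 µm x-pitch and 22 µm y-pitch, a
common poly-3 commercial layout.

`synthesize_templates()` generates per-unit spatiotemporal templates
parametrically rather than from biophysical cable models. Each unit is a
point source at position $(x, y, z)$ near the probe plane with waveform

$$W(t, c) = a_{\mathrm{main}}(c)\,k(t) \;-\; a_{\mathrm{ret}}(c)\,k(t - \delta),$$

where $k(t)$ is a difference of two Gaussians — a sharp negative spike lobe
(σ = 0.2 ms) followed by a slower positive after-wave (σ = 0.6 ms),
normalized to a unit negative peak — and amplitudes decay with distance $d$
from the source as $a(d) = A/(1 + (d/\lambda)^2)$ with λ = 30 µm. The second
term is a polarity-inverted "return current" source displaced 40–90 µm along
a random in-plane axis at 40–80 % of the soma amplitude. Channels nearer
that source than the soma see a predominantly *positive* deflection, which
is what makes strongly negative template similarities reachable — without it
no pair of templates could be anti-parallel, and the negative part of the
similarity axis (where all sorters struggle, because a collision partially
cancels the detectable negative peak) could not be studied.

Peak amplitudes are drawn uniformly in [30, 200] µV at the unit's
perpendicular distance (z ∈ [10, 60] µm); placements whose realized
peak-channel amplitude falls below 30 µV are redrawn (up to 100 attempts),
so every unit is in principle detectable. The whole placement is resampled
(deterministically under the seed) until the pairwise cosine similarities
span at least [−0.2, 0.8], because the collision analysis needs a populated
similarity axis; with 20 units this succeeds on the first draw for most
seeds.

Template similarity is the cosine between the channel-concatenated
flattened templates (`cosine_similarity()`), bounded in [−1, 1];
`template_barycenter()` estimates unit positions as peak-amplitude-weighted
channel positions.

### Spike trains

`generate_independent()` draws homogeneous Poisson trains. Refractory
violations are pruned by a sequential scan that always keeps the earlier
spike (`prune_refractory()`, default 4 ms). Pruning alone undershoots the
nominal rate by roughly `rate × refractory` (2–6 % at 5–15 Hz), so the
generator tops trains up with fresh Poisson spikes and re-prunes, up to five
rounds, until the empirical rate is within 1 % of nominal. We treat the
configured rates as the operative levels; the acceptance checks require the
realized 30-minute rates to sit within 2 % of nominal.

`generate_correlated()` implements a mixture ("mother") process: a shared
Poisson mother process runs at the nominal rate $r$; each unit copies each
mother spike with probability $c$ (the correlation level), jitters the copy
with a zero-mean Gaussian, and adds an independent Poisson component at
$r(1-c)$, so the marginal rate stays $r$ while any pair shares a fraction
$\approx c^2$ of coincident spikes. The Gaussian jitter gives the
cross-correlogram a Gaussian-shaped central excess. The jitter SD defaults
to 0.5 ms: ±4 SD of the pairwise lag distribution (SD √2 × 0.5 ≈ 0.7 ms)
then falls almost entirely inside the ±2 ms collision window, which is the
regime the benchmark is about. It is exposed as a parameter because it is a
modelling choice, not a measured quantity.

Seeding is hierarchical: one master seed; per-unit and per-component child
seeds derived by a fixed affine rule (`master`, stream index), so train sets
are reproducible bit-for-bit and units are independent streams.

### Recordings

`assemble_recording()` pastes each spike's template into the traces at the
nearest sample (the template's negative peak defines the spike time), scaled
by an i.i.d. amplitude factor (Gaussian, mean 1, SD 0.05, truncated to
[0.7, 1.3] — "slight" physiological variability), and adds i.i.d. Gaussian
noise (default 5 µV) per sample and channel. Sub-sample alignment is
deliberately omitted: at 32 kHz one sample is 0.031 ms, an order of
magnitude below both the 0.4 ms matching window and the 0.36 ms collision
lag bins.

Traces are never materialized whole: a 30-minute, 32-channel recording at
32 kHz is ≈ 7.4 GB as float64. The `recording` object stores generation
parameters and draws any sample range on demand, with noise seeded per 10-s
chunk and amplitude factors per spike, so chunked access is deterministic
and order-independent. File export streams float32, channel-interleaved,
with a JSON sidecar; write–read–write round trips are bit-exact.

## Ground-truth comparison

`compare_sortings()` follows the standard ground-truth comparison recipe:

1. **Agreement scores.** For ground-truth unit $i$ and sorted unit $j$,
   $\mathrm{score}_{ij} = n_{\mathrm{match}} / (n_i^{gt} + n_j^{sorted} -
   n_{\mathrm{match}})$, where $n_\mathrm{match}$ counts one-to-one matched
   spikes within 0.4 ms (inclusive). We enforce a *maximum one-to-one*
   matching (greedy two-pointer on the sorted trains, provably maximal for
   window compatibility on a line and cross-checked against brute-force
   bipartite search): this is the conservative reading that keeps scores ≤ 1.
   The window is applied in milliseconds, not samples, so comparisons are
   sampling-rate independent. A 1 ps slop keeps the inclusive boundary
   robust to floating-point spike times.
2. **Hungarian assignment** maximizes the total agreement score over
   one-to-one pairings (an augmenting-path Kuhn–Munkres solver, verified
   against permutation search up to 6×6); zero-score assignments are
   discarded, and no further score threshold is applied — quality is handled
   by the classification rules below.
3. **Per-spike labels** for each matched pair: matched spikes are TP on both
   sides, unmatched sorted spikes FP, unmatched ground-truth spikes FN, so
   TP + FN = n_gt and TP + FP = n_sorted exactly.
4. **Unit metrics**: accuracy = TP/(TP+FP+FN), precision = TP/(TP+FP),
   recall = TP/(TP+FN); global values are unweighted means over ground-truth
   units (unmatched units contribute zeros).
5. **Classes**: *well detected* (matched, accuracy ≥ 0.8, inclusive),
   *overmerged* (score ≥ 0.2 with more than one ground-truth unit),
   *redundant* (not the assigned match but score ≥ 0.2), *false positive*
   (unassigned, best score < 0.2), *other* (e.g., matched below 0.8). The
   rules are applied in that order to keep classes mutually exclusive; the
   "other" class catches matched-but-poor units that the four named classes
   leave undefined.

## Collision metrics

`find_synchronous_events()` flags every cross-unit spike pair within 2 ms
(inclusive). `collision_recall_by_lag()` bins events into 11 equal bins
spanning [−2, 2] ms (bin width 4/11 ≈ 0.36 ms) and computes, per bin, the
fraction of collided ground-truth spikes labeled TP. Both spikes of an event
contribute at the event's signed lag (orientation: `unit_i < unit_j`,
lag = t_j − t_i); a spike in k events counts k times, because the unit of
analysis is the event. Empty bins report `NA`, never a silent 0.

`pool_profiles_by_similarity()` averages per-pair profiles within
similarity bins (default edges −0.4 to 1.0 in steps of 0.2), weighting by
event count; `collision_recall_by_similarity()` additionally integrates
over the 11 lag bins. Lag-symmetrized curves (`symmetrize_profile()`)
average the ±l bins, since the sign of the lag is an arbitrary orientation
convention.

`correlogram_relative_error()` compares cross-correlograms of matched unit
pairs: for each ground-truth pair above a similarity threshold (default
0.5), the per-lag error is |ccg_gt − ccg_sorted| normalized by the *mean*
ground-truth count over the window — a per-bin normalization would explode
on near-empty bins — averaged over pairs. CCG settings default to ±10 ms
windows with 0.5 ms bins: wide enough for a stable baseline, fine enough to
resolve the ±2 ms collision region. Correlogram bins are left-open,
right-closed; the reverse orientation (j, i) is defined as the exact
lag-mirror of (i, j), which fixes the behaviour of differences that fall
exactly on a bin edge.

## Reference sorters

Because running third-party sorters is out of scope, three built-in sorters
make the benchmark executable end to end:

* `oracle_sorter()` returns the ground truth; it anchors all boundary
  behaviour (all metrics 1, collision recall 1, CCG error 0).
* `degraded_oracle()` corrupts the ground truth under a `degradation_model`:
  each *collided* spike is deleted with probability `p_drop`, evaluated at
  the spike's minimum-|lag| event (and optionally the pair similarity);
  survivors can be jittered and spurious spikes injected. Each collided
  spike receives exactly one Bernoulli draw, so a constant `p_drop` yields
  an expected collision recall of exactly 1 − p in every bin. For
  lag-dependent p the physics intrudes: a deleted spike is missing for
  *all* of its events, so bins outside a deletion zone are still depressed
  by spikes that also had an event inside it. The exact model-implied
  expectation per bin is the mean survival probability of the spikes
  observed there; `degraded_oracle()` attaches the realized per-spike
  probabilities (attribute `deletion_probs`) so analyses and tests can
  compute it, and the parameter-recovery tests check the measured profile
  against that expectation with cluster-robust standard errors (a spike's
  observations across events are correlated, so plain binomial errors would
  be anti-conservative).
* `greedy_tm_sorter()` is a minimal greedy template-matching sorter given
  the *true* templates (no clustering stage — deliberately, so the benchmark
  isolates the matching step where collision resolution happens). Per 10-s
  chunk it repeatedly: detects candidate times where any channel crosses
  −5 × noise SD (noise estimated per channel via MAD/0.6745) at a local
  minimum, thinning detections within 0.5 ms to the deepest sample; fits
  every template at every candidate over ±2 samples of peak offset by least
  squares with the amplitude clamped to [0.7, 1.3] (mirroring the
  generator's modulation bounds); greedily accepts the largest reductions in
  residual squared norm, subtracts, and repeats for up to 12 passes so that
  overlapping spikes surface once their partner is peeled away. A per-unit
  refractory rule (default 3 ms) forbids fitting a unit twice at the same
  site; without it the peel loop tends to re-explain a collision residual
  with the unit just subtracted instead of extracting the partner spike.
  The candidate evaluation and subtraction loop is implemented in C++ —
  this is the compute-bound core of any template-matching sorter.

## The benchmark grid

`bench_config()` + `run_grid()` run the 3 × 3 condition grid (rates 5, 10,
15 Hz × correlations 0, 10, 20 %). Within a condition, replicates share the
spike trains and redraw templates and unit positions (the spike-train seed
depends on the condition, the template seed on the replicate): variance
across replicates then reflects template geometry, and the replicates
populate the similarity axis. The full-scale profile (`paper_scale = TRUE`)
is 30-minute recordings with 5 replicates per condition — 45 runs; the
default desk profile is 300 s with 2 replicates, which preserves every
qualitative behaviour at ~1/15 of the compute. `aggregate_report()` averages
collision-recall and CCG-error curves over runs and reports the spread as
the sample SD (n − 1).

Test and acceptance problem sizes follow the same logic: distributional
checks run on 30-minute *spike trains* (cheap), trace-level checks on 10 s
to 300 s of recording, and the five-replicate sorter experiment on 300-s
recordings at the 20 % correlation level.

## Interpreting the built-in sorter's collision curves

With the greedy matcher, pooled central-bin collision recall is compared
between near-orthogonal pairs (|cosine| < 0.2) and near-parallel pairs
(cosine > 0.8). The low band is defined by |similarity|, not signed
similarity: anti-parallel pairs are a separate regime — a collision there
*cancels* part of the detectable negative peak, which degrades every
detector — and mixing them into the "easy" band would conflate two opposite
effects. The comparison is made per replicate and decided by majority vote
over five replicates, because with ~1–3 pairs above 0.8 per template draw
the per-replicate recall estimates are noisy.

## What the synthetic data does and does not emulate

The generator reproduces the features the collision metrics are sensitive
to: realistic template geometry and amplitude decay over a hexagonal probe,
a populated cosine-similarity axis including negative values, controlled
rates and pairwise correlations with Gaussian CCG profiles, refractory
spike trains, amplitude variability and additive white noise. It does not
emulate biophysical waveform diversity across cell types, bursting or
rate inhomogeneity, correlated or colored noise, electrode drift, or
sub-sample spike alignment. Consequently, green tests here certify the
*metrics machinery* and the qualitative collision phenomenology — not that
any particular sorter would achieve the same numbers on tissue data, where
templates drift and noise is structured.

## Numerical choices and degenerate inputs

* Windows and bins are specified in milliseconds and applied in seconds
  with a 1 ps slop at inclusive boundaries (floating-point robustness).
* Refractory pruning keeps the earlier spike; ties and runs are handled by
  the sequential-scan semantics, tested against an independent reference
  implementation.
* Zero-duration train requests return an empty set with a warning;
  `rate × refractory ≥ 1` is rejected as infeasible.
* Zero-norm templates raise an explicit error rather than propagating NaN.
* Empty-vs-empty train pairs score 0 (logged); metrics with zero
  denominators report 0 with one warning.
* Hungarian ties are broken deterministically by processing ground-truth
  units in index order.
* The sorter truncates spikes within one template length of the recording
  ends (they lack a full snippet window); the generator likewise truncates
  templates at the edges rather than erroring.

## Known limitations

* The greedy matcher fits one template at a time; simultaneous near-zero-lag
  collisions are recovered through peeling passes, not joint optimization,
  so its collision recall is a lower bound on what matching-pursuit-style
  sorters can achieve. Losses concentrate on the smaller-amplitude partner
  of a collision.
* The degraded oracle's lag-dependent deletion cannot produce arbitrary
  per-bin recall profiles, for the physical reason discussed above.
* Agreement computation is quadratic in the number of units; fine for tens
  of units, not tuned for hundreds.
* The mixture process yields homogeneous, pairwise-exchangeable
  correlations only — no cell assemblies, no negative correlations.
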