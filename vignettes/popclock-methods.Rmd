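---
title: "Methods: population clocks from rhythmic somatosensory input"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population clocks from rhythmic somatosensory input}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

popclock implements the analysis chain used to ask whether rhythmic
somatosensory input to a neural population — here modelled on primary
somatosensory cortex (S1) and dorsolateral striatum (DLS) under 3.3-Hz
forelimb stimulation — carries enough sequential and temporal structure to act
as a "population clock", and whether the timing of a stereotyped treadmill
behavior reflects that clock. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
benchmark does and does not establish.

## The synthetic recording model

Cells are inhomogeneous-Poisson units with intensity

```
rate(t) = baseline * (1 - pause(t)) + evoked kernels(t)
```

Stimulation follows trains of 5-ms stimuli: by default 50 trains of 5 stimuli
at 3.3 Hz, separated by 5–10-s uniform gaps — the rhythm of the forelimb step
cycle of a rat running at about 30 cm/s. Four evoked archetypes reproduce the
response taxonomy seen under cutaneous forelimb stimulation:

- `short_excitation` — a unit-integral difference-of-exponentials kernel
  (rise 2 ms, decay 10 ms) starting at the cell's latency;
- `excitation_pause_rebound` — the same kernel, a suppression of the baseline
  to `pause_depth` (default 0.8) starting 12 ms after the latency for 50 ms,
  and a rebound kernel at 70% gain;
- `pause_late_excitation` — suppression from the latency to 100 ms, then a
  kernel at a per-cell onset drawn in 110–240 ms;
- `pause_only` — suppression for 80 ms from the latency.

The kernel forms are a simplicity choice; only their qualitative shape is
constrained by the phenomenon. Latencies are log-normal, parameterised by the
median (default 19 ms, log-SD 0.4), matching a broad latency distribution with
a stated median. Evoked spike counts per stimulus are Poisson with mean
`gain * g_k`, where `g_k` is the cell's stimulus-index gain profile
(mean 1 across the train), and spike times are drawn from the kernel by
inverse-CDF sampling, jittered trial-to-trial by `peak_jitter_ms` (default
2 ms). Because suppression only thins the baseline (depth ≤ 1) and excitation
adds spikes, the intensity is non-negative by construction; a test asserts
this on a 1-ms grid.

Two population structures set the scientific contrast. *Stereotyped*
(S1-like): every stimulus evokes the same per-cell response; the gain profile
is exactly uniform — the concentrated limit of the Dirichlet mechanism below.
*Sequential* (DLS-like): each cell draws a preferred phase uniformly over one
inter-stimulus cycle (shifting its kernels within the cycle) and a gain
profile from a Dirichlet with weight 0.3 on every stimulus plus 6 on a
preferred stimulus, so successive stimuli recruit different subpopulations.
The generative mechanism is an invention of the package — only its
signatures (higher per-stimulus pattern similarity for stereotyped, tiled and
decodable states for sequential) are constrained; both are verified by tests.

The relative abundance of the four archetypes is not empirically constrained;
`archetype_mix` defaults to (0.40, 0.25, 0.20, 0.15) and is fully
configurable.

## Single-cell responses

Spikes are binned at 1 ms and aligned to stimuli over a −1000…+300-ms window;
half-open bins `[edge, edge + 1 ms)`. The 99% confidence limits come from the
distribution of per-bin counts in the 1-s pre-stimulus baseline: empirical
0.5/99.5 percentiles when ≥ 100 baseline bins are available, otherwise
`mean ± 2.576 SD`. A cell is responsive when at least `min_run` consecutive
bins in 5–300 ms fall outside the limits in either direction; the latency is
the left edge of the first such bin.

Two caveats are structural rather than implementational. First, the limits are
per-bin: with ~295 tested bins, a flat Poisson cell has a substantial chance
of at least one spurious crossing at `min_run = 1` (the package default,
matching the "exceeded the confidence limit by at least 1 ms" reading). The
test suite quantifies this against a brute-force simulation of the rule and
shows that `min_run = 2` restores a ≤ 5% per-cell false-positive rate; users
wanting a family-wise-controlled call should set `min_run = 2`. Second, a
suppression cannot cross a lower limit of zero: cells with near-zero baseline
are flagged `indeterminate` instead of non-responsive, and archetype labelling
of pause-type cells requires a solid baseline rate.

Latency analyses use single-stimulus blocks (stimuli every 5 s) rather than
trains: within a 3.3-Hz train, the 1-s baseline window of every stimulus after
the first contains the evoked response to its predecessors, which inflates the
limits and biases latencies. This mirrors the experimental practice of
measuring latencies with isolated stimuli.

The archetype labeller walks the signed excursion sequence: `+` →
short excitation; `+,−,+` prefix → excitation–pause–rebound; leading `−` with
a `+` starting at ≥ 100 ms → pause–late-excitation; `−` only → pause only.
Ambiguous strings resolve by first match, with a message.

## Population states, silhouette, decoding

Population vectors are per-cell rates in 50-ms non-overlapping bins over
−1…+2 s around each train onset — 60 bins per train, an identity asserted for
every configuration. One PCA basis is fitted on all trains pooled (bins ×
trains observations, cells as variables): a shared basis is required for
states from different trains to be comparable in the cluster analysis; a
per-train fit remains available behind `pooled = FALSE`. The population state
of stimulus *k* in train *t* is the trajectory point of the bin containing the
stimulus time (half-open; a stimulus on a bin edge belongs to the bin starting
there, no interpolation), giving 250 states at the defaults.

Silhouette coefficients use `SC = (d' − d)/max(d, d')` with Euclidean
distances, `d` the mean intra-cluster distance and `d'` the mean distance to
the nearest other cluster; singleton clusters yield `NA` and are excluded with
a message. Distances are evaluated in the first two components by default
(`n_components` up to the full dimension is supported — whether two or five
dimensions were used in the original analyses is not documented, so both are
exposed). The observed condition labels states by stimulus index; randomised
conditions draw uniform labels for each `k` in 3–7, 100 repeats per `k` by
default (the repeat count is a package choice), redrawing any assignment that
produces a cluster with fewer than two members.

The elapsed-time decoder splits the 50 trains into 20 training and 30
comparison trajectories, projects both onto a PCA basis fitted **on the
training trajectories only** (preventing leakage; an open design point decided
here), keeps the components explaining 90% of variance capped at 20 (a fixed
count and raw-vector features are available as options), and trains one
binary linear SVM per unordered pair of time bins — 1770 classifiers at 60
bins, with majority-vote prediction and ties resolved toward the lowest bin
index. The kernel and `C = 1` follow common usage of the one-against-one
approach; both are configurable. The per-bin score is the fraction of that
bin's comparison instances labelled correctly, and the mean accuracy averages
the 60 scores; chance for uniform guessing is 1/60.

Three surrogates destroy stimulus-locked structure while preserving gross
statistics: per-cell-per-trial uniform +1–3-s time shifts (spike counts
conserved exactly), realignment to 50 random stimulus-free 3-s windows, and
realignment to a fixed point 2 s after each train's last stimulus. Their
accuracies are statistically indistinguishable on the synthetic benchmark and
are pooled as a single surrogate group. A separate control deletes all spikes
in the 50 ms after every stimulus before decoding.

Numerical choices in the decoder: the SVM optimiser tolerance defaults to
0.05 (libsvm's default is 0.001) because majority-vote labels are insensitive
to the final digits of the decision values — accuracies agree to four decimals
at a third of the fit time; prediction reconstructs the 1770 linear weight
vectors from the support vectors and evaluates them in one matrix product,
verified to agree exactly with libsvm's own voting.

## Treadmill behavior

The trial template is the Front–Back–Front sequence on an 80-cm belt moving
at 22 cm/s: passive drift from the front (start position 5 cm) to the rear
(70 cm), a holding phase at the rear (running at belt speed), and a final
sprint (locomotor speed 52 cm/s, i.e. 30 cm/s ground progress) into the 10-cm
goal area. The closed-form entrance time is
`(70 − 5)/22 + holding + (70 − 10)/30`; the default holding mean of 2.545 s
places the expected entrance at 7.5 s — an expert animal arriving shortly
after the 7-s goal time — and, with holding SD 0.25 s plus 0.15 s
acceleration-onset noise, yields sessions in the mid-90% correct range.
Noise enters only the holding duration and acceleration onset because those
are the timing-sensitive phases of the sequence; belt physics are
deterministic, and position measurement noise defaults to zero (configurable).

Entrance detection is the first crossing *into* the goal area after the
animal has left it (trials begin inside the goal area, so the naive
first-sample rule would fire at t = 0); correctness is `entrance ≥ 7 s`, and
the session criterion is ≥ 72.5% correct over the last 40 trials. Stereotypy
aligns trajectories to entrance times and takes all pairwise Pearson
coefficients: the common pre-entrance overlap for position (trials with less
than 1 s before entrance excluded), a fixed 2.5-s pre-entrance window for
speed. The scalar index is the median of the coefficients (mean available);
the aggregation is a package choice. Speed is computed ground-referenced as
`belt speed − d(position)/dt` on the 400-ms-smoothed trace, so holding
position at the rear counts as running at 22 cm/s. Phases partition the
entrance time exactly: front-to-back until first entry into the rear zone
(rear 15 cm — the zone is not numerically specified by the phenomenon and is
configurable), holding until the last exit before entrance, sprint to the
entrance.

## Spike–behavior coupling

Execution rates divide each trial into non-overlapping 250-ms windows
(trailing partial windows dropped; windows never straddle trials), take
count/0.25, and smooth within trial with a 750-ms-SD Gaussian truncated at
±3 SD and renormalised at trial edges (edge handling is a package choice).
Spike–kinematics coupling is the per-cell Pearson correlation between the
rate series and the limb trace averaged in the same windows. Note a
resolution constraint: a 3.3-Hz limb oscillation is attenuated roughly
five-fold by 250-ms windows, so strong correlations (> 0.6) arise from the
slower covariation between firing and the limb's running-epoch displacement,
not from the cycle itself — which is why the forelimb generator oscillates
around a forward `offset` during running epochs. Rhythmicity is an
autocorrelogram (symmetric by construction, zero-lag self-pairs excluded);
the modulation frequency is 1/lag of the first qualifying local maximum after
the global trough of the smoothed positive-lag autocorrelogram, and the
modulation index `(peak − trough)/(peak + trough)` is a package-defined
summary, flagged as such in outputs.

## What the synthetic benchmark shows — and does not

Passing tests establish that the implementation recovers the generator's
parameters (latencies, phases, timing), orders decoding accuracy as
sequential > stereotyped > surrogates with the surrogate band at
chance-adjacent levels, keeps decoding above surrogate after post-stimulus
blanking, and that silhouette validation separates observed from random
cluster assignments. They do not establish anything about real recordings:
the generator has no correlated noise, no slow drifts or non-stationarity, no
cell loss, perfectly known trial structure, and Poisson variability only.
Effect sizes on real data will differ; the pipeline's comparisons, not its
absolute accuracies, are the transferable content.

## Problem sizes

Defaults follow the study conditions (50 trains, 60 bins, 20/30 splits).
Repeat-heavy stages run desk-scaled in the tests and acceptance script:
decoding curves at population sizes {10, 100, 200} with 50 repeats per size
(25 in the script), surrogates pooled over the three constructions,
silhouette validation over 100 generated populations (50 in the script) with
20 random assignments per k. The full-scale settings (10-cell size steps,
500 repeats, 100 random assignments) are plain arguments
(`population_size_curve(sizes =, n_repeats =)`, `silhouette_analysis(n_random =)`).

## Known limitations

- Suppression latencies are undetectable for cells whose baseline yields a
  zero lower limit; such cells are reported `indeterminate`.
- The per-bin 99% rule at `min_run = 1` over-calls responsiveness for weakly
  modulated cells (see above).
- The archetype rule tree resolves ambiguous excursion sequences by first
  match and does not model mixed or drifting response types.
- `no_stim_random` surrogate windows require enough stimulus-free time; very
  dense protocols can exhaust the rejection sampler, which then errors.
- The behavior generator produces the expert phenotype; learning curves
  across sessions are out of scope.
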