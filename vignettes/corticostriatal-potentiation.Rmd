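---
title: "Detecting sensory-reinforced corticostriatal potentiation from multi-unit spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sensory-reinforced corticostriatal potentiation from multi-unit spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatpot)
```

## The experimental model

`striatpot` analyses in vivo recordings in which single electrical pulses to
the motor cortex evoke multi-unit spiking in the dorsal striatum, and a
delayed whole-field light flash — made effective by disinhibiting the
superior colliculus with bicuculline — acts as a sensory reinforcer.  The
scientific question is whether, and on which recording channels, the
cortically-evoked striatal response *potentiates* after stimulation–flash
pairing, and how dopamine antagonists change that outcome.

Stimulation is delivered as jittered single-pulse trains (0.2–0.5 Hz
nominal rate, inter-stimulus intervals uniformly jittered by ±30%, e.g.
1.4–2.6 s at 0.5 Hz) grouped in blocks of 120 stimulations.  One block is
the unit of analysis: all spike counting is done on a per-block
peri-stimulus time histogram (PSTH) with 1 ms bins, aligned on stimulation
onset, spanning 500 ms of pre-stimulus spontaneous activity and the 50 ms
post-stimulus window in which cortically-evoked responses occur.
Monosynaptic response components arrive below ~12 ms; multisynaptic
components later.

Two analyses operate on these block PSTHs:

* **Evoked-response analysis** (single-electrode designs,
  `analyze_evoked()`): per block, a detection threshold equal to the mean
  plus three (population) standard deviations of the 500 pre-stimulus bin
  counts; the response peak is the maximum bin within 0–50 ms, onset and
  offset are the edges of the contiguous suprathreshold run containing the
  peak, and magnitude is the spike count over onset–offset minus the
  expected baseline count for the same bins.  Per-channel block series are
  normalized to the mean magnitude of the blocks preceding the bicuculline
  injection (100% = no change).
* **Potentiation analysis** (16-channel drug design,
  `analyze_potentiation()`): each block PSTH is first corrected by its own
  mean spontaneous rate; an average baseline response (per-bin mean and SD)
  is computed over the 8 blocks preceding bicuculline (blocks 5–12: four
  post-drug blocks plus four post-drug blocks with light pairing); a
  *potentiation peak* occurs wherever a block's corrected bin value
  strictly exceeds the baseline mean plus two SDs at that bin; a channel is
  *potentiated* when peaks at similar latencies (±2 ms) occur in at least
  five strictly consecutive post-bicuculline blocks and such peaks were
  absent pre-drug.  Latency (first bin), duration (distinct peak bins
  pooled across the supporting blocks), total magnitude (summed excess over
  all supporting peaks) and average magnitude (total/duration) quantify the
  potentiated response.

Inference uses two bespoke statistics: a randomization F test
(`randomization_f_test()`) for drug effects on baseline responding
(pre-drug blocks 1–4 vs post-drug blocks 5–12, channels treated as blocks
of a two-way layout, period labels permuted within channel, add-one p
value), and a Pearson chi-square (`proportion_chi_square()`, df = 1, no
continuity correction) on the proportions of potentiated channels between
treatment groups.  Standard tests (Mann–Whitney, Wilcoxon, Kruskal–Wallis,
repeated-measures ANOVA) are deliberately left to base R.

## The synthetic-data generator

Because no recordings ship with the package, every stage is validated
against a generative model (`simulate_experiment()`) that emulates the
protocol:

* stimulation trains from the protocol's uniform ISI jitter (the printed
  1.4–2.6 s range at 0.5 Hz is exactly the uniform ±30% band, which is why
  uniform jitter was chosen);
* homogeneous Poisson background firing per channel, 30 Hz by default
  (typical of striatal multi-unit baselines in this preparation);
* evoked responses as latency-structured components: per stimulation and
  component, a Poisson count of spikes (mean = expected spikes/stimulus ×
  active gains, so probabilities above 1 are legal for multi-unit
  channels), placed at the component latency plus Gaussian jitter,
  truncated at the stimulation time.  Defaults place a monosynaptic
  component at 8 ms and a multisynaptic one at 18 ms, either side of the
  12 ms split;
* potentiation as a multiplicative gain on potentiable components starting
  at a block boundary (the gated reinforcement epoch), ramping linearly
  over 4 blocks — potentiation in the recordings grows gradually, with
  variable per-channel onset — optionally accompanied by a new component at
  a novel latency;
* drug conditions as a multiplicative scale on all components from the
  injection block onward;
* 16-channel arrays in which a configurable subset responds and a
  sub-subset potentiates, with ground truth recorded for recovery testing.

The generator does **not** emulate refractoriness (superposed multi-unit
activity makes refractory interactions negligible), spike waveform
diversity (a single biphasic template is used, and only to exercise
threshold extraction), local field potentials, bursting, or slow
non-stationarities of anaesthetised recordings.  Passing recovery tests
therefore demonstrate that the analysis correctly inverts *this* generative
model at realistic rates and counts — they cannot certify behaviour under
artefacts (e.g. unblanked stimulation transients) absent from the model.

A block-level shortcut, `simulate_block_magnitudes()`, draws per-block
response values directly from the generator's marginal distribution
(Poisson evoked count + response-window background − scaled
baseline-window background).  It exists because statistical calibration of
the randomization F test needs hundreds of replicates; a unit test checks
its mean and dispersion against the full spike-level pipeline.

## Numerical and design choices

Several points are under-determined by the verbal description of the
method; the package resolves them as follows.

**Bins and windows.** Half-open bins `[lo, hi)`, 0-based latencies from
stimulation onset, default analysis window −500 to +100 ms.  A guard of
10⁻⁶ ms absorbs floating-point error at bin edges.  Ties at the response
peak break toward the earliest bin.

**Baseline SD.** The block threshold uses the *population* SD of the 500
baseline bin counts, because the threshold is compared against individual
bin counts of the same histogram.  With 30 Hz background and 120
stimulations, baseline bins are approximately Poisson with mean 3.6; the
right-skew of that distribution means single bins exceed mean + 3 SD in
roughly 0.4% of bins — a per-block false-detection rate near 18% across
the 50 response bins, which the normalization stage tolerates because
false "responses" carry near-zero magnitude.  A unit test checks the
pipeline's false-detection rate against an independent Poisson tail
simulation rather than a nominal Gaussian rate, which would be misleading
here.

**Per-bin dispersion floor.** The potentiation analysis estimates per-bin
SDs from only 8 baseline blocks.  Such estimates are occasionally near
zero, which would let ordinary counting noise exceed the mean + 2 SD rule
at that bin in *every* later block — a correlated false-positive mechanism,
not dilutable by consecutive-block requirements.  `detect_peaks()`
therefore floors each bin's SD at its Poisson counting noise,
`sqrt(mean raw count)`, the smallest dispersion a spike count can have.
The floor is a variance regularisation, not a change of rule; it can be
disabled (`sd_floor = FALSE`).

**The pre-drug veto.** A channel qualifies only if similar-latency peaks
were "absent" pre-drug.  Read literally — no single peak in any of 4
pre-drug blocks within ±2 ms — the veto scans 20 bin–block combinations
whose individual false-peak probability under the 2 SD rule is a few
percent, so it would veto roughly half of genuinely potentiated channels
regardless of noise model; that reading is inconsistent with the method
ever detecting the potentiation it was designed for.  The package instead
applies the method's own persistence logic to the veto: isolated
single-block exceedances are expected noise, and the veto fires when
similar-latency peaks recur in ≥ 2 distinct pre-drug blocks
(`veto_min_blocks = 2`; set 1 for the literal rule).  The veto scope
defaults to the pre-drug blocks 1–4 and can be extended to all 12
pre-bicuculline blocks (`veto_scope = "all_pre_bicuculline"`).

**Run rules.** The two printed channel criteria differ only in run length
(5 vs 7 consecutive blocks); they are implemented as one run-length rule
with threshold 5, and the call records whether the run reached 7 (`run5`
vs `run7`).  "Consecutive" means adjacent block indices; a configurable
gap allowance exists (`max_gap_blocks`) but is off by default.  When
several candidate latencies qualify, the call is made at the one with the
longest run, ties broken by total excess.

**Latency semantics.** The reported latency is the earliest bin of the
potentiated response (all supporting peaks).  Because the leading Gaussian
tail of a potentiated component is genuinely suprathreshold, this onset
estimator sits 1–2 ms below the component's *mean* latency; comparisons
against generative truth should use a ±2 ms tolerance, which is also the
default "similar latency" tolerance (two bins — wide enough for latency
jitter, narrow enough not to merge mono- and multisynaptic components).

**Normalization.** Percent-of-baseline (100 = no change) is the default
convention; percent-change is available.  Blocks without a detectable
response contribute magnitude 0.  Channels whose baseline blocks contain
no detectable response at all cannot be normalized and report `NA` rather
than an error, so multichannel datasets with silent channels analyse
cleanly.

**Randomization F test.** The two-way decomposition (period + channel)
with proportional cell frequencies admits a closed-form sum-of-squares
update in which only the period-A sum changes under within-channel label
permutation; the observed F is identical to the `anova(lm())` F for the
period term (unit-tested).  The add-one p value
`(1 + #{F* ≥ F})/(1 + n)` avoids zero p values; degenerate inputs (zero
residual variance) report the floor `1/(1 + n)` with a flag.

## Problem sizes used in the tests

The test suite and `scripts/acceptance.R` run the complete pipeline at the
protocol's stated sizes: 120 stimulations per block; 20-block 16-channel
simulations for null calibration (20 seeds, 320 channel decisions) and
recovery (gain 2.0 on the 8 ms component from the gated epoch, 20 seeds);
24-block single-channel simulations for the evoked-response dissociation
(duration grows with gain while onset latency is stable — the regime in
which this holds is a unimodal evoked response whose components overlap
into one contiguous suprathreshold run, which is how the multi-unit
responses analysed by the duration measure look; with well-separated
components the contiguous-run duration tracks only the component
containing the peak); 200 replicates × 1000 permutations for F-test
type-I calibration and 50 replicates for power at a 0.5× drug
suppression, both via the block-level marginal generator.

## Known limitations

* The classifier's operating characteristics are calibrated against the
  Poisson generative model; heavier-tailed real spike-count noise would
  raise both thresholds' false rates.
* The pre-drug veto interpretation and the SD floor are design decisions
  in territory the verbal method leaves open; both literal behaviours
  remain available through arguments.
* The evoked-response duration measure is only meaningful for responses
  forming a single contiguous suprathreshold run.
* No spike sorting is attempted: all quantities are multi-unit, and the
  analysis cannot attribute potentiation to single neurons.
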