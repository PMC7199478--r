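---
title: "Methods: characterizing movement artifacts in infant EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing movement artifacts in infant EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the processing
model and its assumptions, the parameters that matter, what the synthetic
cohort generator does and does not emulate, the numerical choices made
where the design was genuinely open, and the package's known limitations.

## The analysis problem

Naturalistic infant EEG is recorded while the infant behaves freely; rest
and motion periods are identified afterwards by frame-accurate video
coding (30 fps, so 33 ms resolution). The scientific question is *how* each
motion type distorts the EEG spectrum relative to rest: where on the scalp,
at which frequencies, and in which direction. The analysis therefore
compares, within each infant, the spectral power of EEG recorded during
isolated single motions (jaw, hand, arm, foot, leg) against resting-state
EEG, and asks at the group level where those differences are reliable.

## Annotation model and inclusion rules

Annotations are intervals on the 1/30 s frame grid. The inclusion rules are
implemented literally:

* motion events must last *strictly longer than* 250 ms — shorter bursts
  are too brief to contribute a stable spectral estimate;
* rest events must last *at least* 500 ms;
* two temporally overlapping motion events are both removed: only
  unambiguous single-motion exemplars are analyzable. Truncating to the
  non-overlapping parts was the alternative; discarding was chosen because
  motion onsets/offsets are coded to ±33 ms and truncated remnants would
  inherit that uncertainty at both ends.
* a rest event overlapping a motion event is treated as a coding
  contradiction and raises an error instead of being silently resolved.

Per-infant clean totals are aggregated per condition over *contributing*
infants only (spontaneous motion is sparse; many infants never produce a
given type), with the sample (n − 1) standard deviation.

## Preprocessing

The stage order is fixed and order matters:

1. **Bad-channel rejection.** A channel is rejected when its raw amplitude
   deviates from "the rest of the channels" by more than 100 µV for more
   than 25% of the session. The comparator is operationalized as the
   instantaneous *median of the other channels*: a robust center that the
   offending channel cannot drag toward itself (a mean comparator fails
   exactly when the artifact is largest). If more than half the channels
   fail, the recording is declared unusable.
2. **Average re-referencing** over the retained channels only — rejection
   must come first, otherwise a bad channel contaminates the reference of
   every other channel (a property asserted by a test).
3. **Segment extraction and concatenation** per condition. Sample indexing
   is 0-based with half-open `[floor(onset·fs), floor(offset·fs))`
   intervals; stated once, used everywhere.
4. **Amplitude cleaning**: manual inspection for blinks and large
   excursions is replaced by a deterministic rule — 1-s windows whose
   peak-to-peak amplitude exceeds 200 µV (post-reference) on any retained
   channel are excised. Determinism was preferred over fidelity to manual
   cleaning because reproducibility is the package's point.
5. **Epoching** into non-overlapping 1-s epochs; the trailing remainder is
   dropped. Epochs may span concatenation joins (the concatenated stream
   is treated as continuous, matching the stated procedure); a flag
   disables this for sensitivity analysis.

No filtering or detrending is applied anywhere: none is part of the
modeled procedure. Real recordings with line noise or drift would need a
prior cleaning step outside this package.

## Spectral estimation

Two spectral paths are deliberately kept separate.

**Topography path.** Per-epoch FFT power (rectangular window — no taper is
part of the modeled procedure; 1-s epochs give a native 1 Hz grid) is
z-normalized per frequency bin within each infant and condition:

$$ z(c,f) = \frac{\operatorname{mean}_e p(c,f,e) -
\operatorname{mean}_e m(f,e)}{\operatorname{sd}_e m(f,e)},\qquad
m(f,e)=\operatorname{mean}_c p(c,f,e). $$

The denominator is the sample SD over epochs *of the channel mean*. The
surrounding prose description of this normalization ("standard deviation of
all epochs and all channels") disagrees with the formula; the formula wins,
and the pooled-SD variant remains available via
`znormalize(denominator = "pooled")`. Two consequences are asserted
exactly: the channel mean of z is 0 at every bin, and z is invariant under
positive rescaling of the raw signal (µV calibration cannot matter).
Z-spectra are grand-averaged across infants per channel (missing/rejected
channels are averaged over the infants that retain them) and summarized
over infant bands — delta 1–3, theta 3–6, alpha 6–9, low beta 9–13, high
beta 13–20 Hz. Band edges are low-inclusive/high-exclusive so shared edges
belong to the upper band and the bands partition the axis; the top band
closes at the last analyzed bin (20 Hz).

**Statistics path.** The cluster test consumes raw µV²/Hz DPSS multitaper
spectra, not z-scores: the z-normalization destroys absolute power
differences between conditions, which are exactly what the test is about.
With 1-s epochs and 2 Hz smoothing half-bandwidth, the time-bandwidth
product is NW = 2 and K = ⌊2·NW − 1⌋ = 3 Slepian tapers are averaged. The
tapers are computed from the standard symmetric-tridiagonal eigenproblem
and cached per (N, NW, K). The analyzed range 0.1–20 Hz on the 1 Hz grid
keeps bins 1–20 (the 0.1 Hz bound excludes only DC).

## The cluster-based permutation test

* **Point statistic**: dependent-samples t across subjects of
  (motion − rest) per (channel, bin), df = n − 1. The cluster-forming
  threshold defaults to the two-tailed paired-t critical value at
  point-level α = 0.05 — the de-facto convention where none is stated.
  Zero-variance points get t = 0 and cannot seed clusters.
* **Connectivity**: within a bin, channels connected in the neighbor graph;
  within a channel, adjacent 1 Hz bins. Clusters must span ≥ 3 distinct
  sensors. Cluster score = mass (sum of member t values).
* **Exchange scheme**: within-subject condition exchange = independent sign
  flips of each subject's difference. For n ≤ 13 subjects all 2^n patterns
  are enumerated (exact); otherwise 10,000 Monte-Carlo cycles with the
  add-one estimator p = (1 + #{null ≥ |mass|}) / (1 + n_perm).
* **Two-tailed control**: a single null distribution of the maximum
  *absolute* cluster mass is used, and a cluster of either sign is
  significant iff p ≤ α. Tail conventions differ across toolboxes; with
  the pooled max-|mass| null, comparing at α (not α/2) is what delivers
  family-wise error ≈ α, and the empirical type-I experiment below
  confirms it.
* A structural fact worth knowing: sign-flip enumeration is mirror
  symmetric (flipping every subject negates the map), so the smallest
  achievable two-tailed exact p is 2/2^n. Five paired subjects can never
  reach α = 0.05; group comparisons here need six or more.
* **Missing data**: subjects lacking one condition are dropped from that
  comparison; a channel enters a comparison only if retained in both
  conditions for all contributing subjects (the conservative choice — the
  alternative, per-subject channel sets, would make cluster masses
  incomparable across permutations).
* **Stratified rerun**: to rule out duration-imbalance artifacts, the
  larger condition's epochs are subsampled per subject to the smaller
  count before averaging and the full test is rerun; both results are
  reported side by side.

## The montage and neighbor graph

The 32-channel extended 10-20 set (with the inferior TP9/TP10/PO9/PO10
row) is built from the idealized spherical construction: unit-sphere head,
canonical 10%/20% arc fractions, 10-10 intermediate sites as geodesic
midpoints of their four flanking sites. The full label set is an assumption
(only a handful of labels are externally constrained); it is the standard
32-electrode cap layout containing all of them. Neighborhood is thresholded
3-D chord distance. "One unit distance" between neighbors is meaningless
without a coordinate scale, so the threshold was calibrated once, on this
montage, to the stated target density of 6–7 neighbors per sensor: the
mean degree is flat at 6.19 for thresholds in [0.69, 0.76], and the stored
default 0.72 sits mid-plateau. Calibrated mode verifies the density (and
graph connectivity) and errors otherwise, naming the achieved degree.

## The synthetic cohort generator

The generator's job is to produce data with the statistical structure the
analysis assumes, with known ground truth. Defaults emulate the study
conditions: 12 infants, 500 Hz, 274–448 s recordings, ~15% incidental
rest, five motion types with per-infant presence probabilities
(jaw 0.5, hand 0.67, arm 0.83, foot 0.33, leg 0.83 — chosen to reproduce
the observed 4–10 contributors out of 12) and truncated log-normal event
durations (right-skewed, with foot given sdlog = 1 to allow the occasional
very long event that dominates a small-sample SD).

Per channel the background is unit-RMS 1/f noise (spectral shaping of
white noise, exponent 1, scaled to 15 µV RMS) plus band-limited bumps:
posterior delta (2 Hz) and theta (4.5 Hz) and centro-parietal alpha
(7.5 Hz), each one a *common* source waveform whose per-channel amplitude
decays as a Gaussian of 3-D distance from its seed channels — so bump
power is spatially coherent and maximal at the seeds, as scalp
oscillations are.

Artifacts are injected per motion interval:

* the **beta increase** is realized additively — independent band-limited
  noise centered at 15 Hz whose per-channel variance is (gain_c − 1) times
  the channel's measured in-interval beta power, with
  gain_c = 1 + (β − 1)·exp(−d²/2σ²) decaying from the type's seed
  channels (frontal bilateral set for jaw, posterior parietal/occipital
  for arm), and 10 ms raised-cosine on/off ramps so interval edges do not
  click. Additive narrowband noise was chosen over time-domain gain
  modulation because its spectral footprint is exactly interpretable;
* the optional **central theta/alpha decrease** multiplicatively scales
  3–9 Hz content at central channels via frequency-domain masking of the
  interval, cross-faded at the edges. Unit gains are exact no-ops.

The bad-channel model adds a +150 µV offset to one random channel for a
contiguous 30% of the recording — enough to trip the rejection rule, as
the deposited rejected-channel patterns do.

What the generator does **not** emulate: eye movements and blinks,
heartbeat, electrode drift, line noise, biophysical volume conduction
(spatial profiles are Gaussian in sensor space, not forward-modeled), and
any coupling between motion kinematics and artifact amplitude. Passing
recovery tests on this cohort therefore shows the *pipeline* is correct
and sensitive, not that real infant artifacts are fully described by these
signatures.

Reproducibility: each infant gets an RNG substream derived from the master
seed, so cohorts are bit-identical given the seed and infants are
statistically independent; changing downstream parameters (e.g. n_perm)
never perturbs the cohort.

## Validation experiments and problem sizes

Three packaged experiments quantify the claims; the test suite and the
acceptance script run them at these sizes, chosen to make the full suite
affordable on one CPU while leaving the semantics of every stage intact:

* **Type-I error** (`estimate_fwer`): 500 null datasets of 8 subjects,
  32 channels × 20 bins, n_perm = 1000 (auto-exact: 256 enumerated
  patterns). The empirical family-wise rate must land in [0.03, 0.07];
  measured 0.064 during development.
* **Artifact recovery** (`run_artifact_recovery`): 100 seeded cohorts per
  motion type at 8 infants, 80 Hz, 70–90 s — full pipeline from raw
  synthetic signal to cluster p-values. The injected beta gain (1.15) was
  calibrated, before freezing, so the point-level paired effect at a seed
  channel and 15 Hz is ≈ 1 SD of the across-subject differences under
  exactly these cohort conditions (measured d ≈ 1.0 for both types over 8
  calibration seeds). A run counts as recovered when a significant
  positive cluster peaks in 13–17 Hz and its member channels overlap the
  injected region more than the opposite one (posterior vs frontal for
  arm; reversed for jaw). The recovery experiment equalizes event
  statistics across types and disables the optional theta/alpha
  attenuation so the two experiments differ only in injected topography.
* **Oracle equivalence**: on a fixed 5-subject dataset, Monte-Carlo
  p-values (10,000 cycles) must agree with the exhaustive 32-pattern
  enumeration within 3 Monte-Carlo standard errors.

Smaller synthetic cohorts used in unit tests (6 infants, 125 Hz, 100–140 s)
exercise the identical code paths as the full-scale defaults.

## Known limitations

* The deposited per-infant duration table is reproduced exactly; the
  original recordings are not available, so the real-data cluster
  statistics (e.g. the near-significant theta/alpha trend) are covered
  only qualitatively, by the synthetic attenuation's sign and topography.
* The rejection comparator ("the rest of the channels") and the FFT
  windowing of the topography path are assumptions where the modeled
  procedure is underspecified; both are isolated behind single functions
  and flagged here.
* Exact no-filtering fidelity means real EDF-era recordings with drift or
  mains interference need external cleaning first.
* The spatial profiles and effect sizes of injected artifacts are free
  parameters of the generator; published figures constrain their sign and
  topography but not their magnitude.
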