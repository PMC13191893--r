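---
title: "Methods: auditory phenotyping with audiphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditory phenotyping with audiphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

audiphen implements the analysis chain used to phenotype hearing across the
lifespan of a mouse model: neonatal ultrasonic vocalizations (USV), auditory
brainstem responses (ABR), cortical frequency-response areas (FRA) from
two-photon calcium imaging, ensemble decoding of tone frequency, and go/no-go
psychophysics. Because such datasets are rarely deposited, every stage has a
paired synthetic generator that produces its inputs with known ground truth;
all quantitative claims about the pipeline are made on those generators, by
the test suite and by `scripts/acceptance.R`.

This vignette documents the models, the tunable parameters, and the design
choices made where the procedure was genuinely open.

## USV detection and features

Detection operates on a short-time power spectrogram: Hann window of 512
samples (~2 ms at the 250 kHz recording rate), 75% overlap, one-sided
power-spectral-density scaling. Frames are half-open `[k*hop, k*hop + win)`
and timestamped at their centers; power integrates back to signal power up
to the windowing loss, which the tests verify against a flat-spectrum
oracle.

A frame is call-active when its energy inside the detection band (default
30–120 kHz, the mouse USV band) exceeds `median + k*MAD` of the recording's
frame energies (`k_mad = 5`). The scan is chunked in 0.5 s segments with
one-window overlap; the threshold is computed once per recording, so
chunking changes nothing except peak memory. Active runs separated by gaps
of at most 10 ms are merged (this is what keeps a two-syllable call — main
component, ~8 ms gap, punctuated second component — a single call), and
runs shorter than 5 ms are dropped. Reported boundaries are frame centers
trimmed by half a window minus half a hop, which compensates the smearing
of the short-time transform; on noiseless synthetic calls the residual
duration error is below one hop (~0.5 ms).

Per call, the peak-frequency track is the argmax of in-band power per
frame. Start (end) frequency is the mean of the track over the first (last)
3 frames; calls shorter than 3 frames use all frames and are flagged. The
3-frame window is a compromise between noise suppression and bias on
frequency-modulated calls: the expected bias is `slope x 3 hops`, which the
tests account for explicitly.

Inter-syllable intervals are the gap between a call's end and the next
call's start; gaps strictly greater than 0.5 s are inter-burst intervals
and excluded from ISI summaries. A gap of exactly 0.5 s is retained — the
convention is a strict inequality.

Call types (flat, chevron, frequency-step, composite, two-syllable) are
accepted as labels; automatic type classification is deliberately out of
scope, since in the emulated workflow types are assigned by a blinded
observer. `repertoire_counts()` cross-tabulates labels by group and runs a
chi-square test of independence without continuity correction, rejecting
when an expected cell is zero.

## FRA estimation and the resampled d' statistic

The evoked scalar is the mean activity in the 120 ms after tone onset minus
the mean in the 120 ms before, half-open windows, frames assigned by their
center times; at a 30 Hz frame rate this is 3–4 frames per window and at
least 2 are required.

The tone-driven portion of an FRA is found on the repeat-averaged grid
(8 frequencies, 4–45 kHz in half-octave steps, by 7 levels, 20–80 dB SPL):
3x3 median smoothing, then a threshold at
`baseline + max(0.2 * (peak - baseline), 2.5 * MAD)` with baseline and MAD
taken over the smoothed grid, keeping the 4-connected component that
contains the smoothed peak. The fraction-of-peak term places the boundary
for responsive cells; the MAD floor exists because in an unresponsive grid
20% of the noise peak sits inside the noise distribution itself, and
without the floor pure-noise cells grow spurious masks covering ~15% of the
grid. With it, noise masks stay at or below 10% of the grid in about 97% of
seeded runs, while noiseless tuned cells are recovered exactly. Both
constants are exposed as arguments. One special case: an isolated
single-combination responder is flattened away by the median filter, so
when smoothing removes all contrast that the raw grid carries, the
boundary is determined on the raw grid instead — a lone responsive
combination then yields exactly that one-cell mask.

Tuning quality is a resampled separation statistic: 1000 iterations, each
drawing 30 combinations with replacement from the driven portion and 30
from the undriven portion (all grid cells outside the mask), recording the
two subsample means. When the driven portion holds fewer than 50
combinations — which on the 56-cell grid is essentially always — it is
padded with random undriven draws up to 50 candidates before sampling,
diluting the driven pool and making the estimate conservative. The padded
pool is redrawn every iteration. d' is the difference of the two
iteration-mean distributions' means divided by the arithmetic average of
their SDs. If both SDs are zero with unequal means (noiseless, strongly
driven cells) the statistic is reported at a cap of 10 so that the
d' > 1.5 selection stays well defined; equal constants give 0. Sampling
with replacement is required because both portions are usually smaller than
30. The padded undriven draws are included in the driven mean, the
conservative reading of the padding rule.

Metrics on the driven portion: best frequency is the frequency with the
largest driven response summed across levels; the minimum response
threshold is the lowest level with at least one driven cell; bandwidth is
the octave span `log2(f_hi/f_lo)` of driven cells in the row 10 dB above
threshold (0 for a single frequency, undefined if that row is empty or off
the grid). Bandwidth is reported in octaves — the natural unit on a
half-octave grid; a kHz report would make the same width look broader at
high BF. Cell selection uses a strict `d' > 1.5`.

## Ensemble decoding

The feature matrix holds one row per trial at 70 dB SPL (well above
threshold) and one column per cell — all cells of the session, not only
d' > 1.5 cells. Features are the evoked scalars; when built from traces the
normalization is `(post - pre) / max(pre, 1e-3)`, the epsilon guarding
against near-zero baselines. Missing combinations are imputed with 0 and
counted in an attribute rather than dropped.

Pairwise decoding fits a linear-kernel SVM (cost 1) under stratified 5-fold
cross-validation, z-scoring each column on the training folds only;
accuracy is 1 minus the held-out misclassification rate, averaged over 100
repetitions whose fold assignments are re-randomized with `seed + r`. Only
the partitions are re-randomized between repetitions, not the trials.
Per-column standardization makes accuracy invariant to affine rescaling of
any single cell, and the procedure is invariant to column permutation;
both are tested. Pair results are summarized by octave separation
`|log2(f1/f2)|`, with the two-bin split at 1.5 octaves (a pair at exactly
1.5 falls in the small bin) and per-separation curves via arbitrary edges.
Mean accuracy is computed per session first, then across sessions.

The property tests run decoding in a deliberately lean regime — 12 tuned
cells, trial noise SD 0.8 — because realistically sized ensembles (~140
cells) decode at ceiling for every separation, where monotonicity in
separation and the broad-tuning cost are invisible. Best frequencies for
these ensembles are drawn log-uniformly from one octave below to roughly
half an octave above the tone grid, so that extreme-frequency pairs have
the same expected cell coverage as central pairs; sampling BFs only on the
grid makes large-separation pairs information-poor at their edges, an
artifact of coverage rather than of tuning width.

## Go/no-go scoring

A go trial (12 kHz target) with at least one lick in `[onset + 0.15 s,
onset + 1.2 s)` is a hit, otherwise a miss; a no-go trial (non-targets at
4, 6, 8.48, 10.09, 11.04, 11.35 kHz — 1.58 down to 0.08 octaves from the
target) with a lick in the window is a false alarm, otherwise a correct
rejection. The window is closed on the left and open on the right; licks
before the session start are ignored with a warning, and pre-window licks
leave the trial a non-response rather than excluding it.

Sensitivity is `d' = z(HR) - z(FAR)` with rates clipped to
`[1/(2N), 1 - 1/(2N)]` per condition — the standard finite-sample
correction that keeps perfect sessions finite (50/50 hits against 0/50
false alarms gives 4.653). The hit rate is shared across a session's
conditions; false-alarm rates are per non-target condition. The easy/hard
contrast compares the 4 kHz and 11.35 kHz conditions, and the hard-to-easy
ratio `d'_hard / d'_easy` is computed per session, undefined when
`d'_easy <= 0.1`.

## ABR thresholds and wave I

Repeatability at a level is the Pearson correlation between the two
split-half averaged waveforms over a 1–6 ms response window; the threshold
is the lowest level repeatable (`r >= 0.5`) at that level and every level
above it, and 100 dB is assigned when no level qualifies. The correlation
criterion operationalizes what is in practice a human judgement of
"repeatable"; both the criterion and the window are configurable, and flat
(zero-variance) waveforms count as not repeatable. Enforcing monotonicity
means a level that is repeatable below a non-repeatable one does not set
the threshold.

Wave-I amplitude is the waveform maximum inside a 1.0–2.5 ms latency
window minus the minimum over the 1 ms that follows the peak. On noisy
averages an optional moving-average smoothing (~0.15 ms) precedes
peak-picking so the measurement does not lock onto a noise ripple; the
measurement is exactly linear in the waveform.

## Statistical reporting

`run_comparison()` is a thin contract over standard routines: factorial
ANOVA with interaction (Type III sums of squares under sum-to-zero
contrasts — appropriate for the unbalanced group sizes of animal cohorts,
and identical to the textbook decomposition when balanced), Welch t,
two-sample Kolmogorov–Smirnov, and chi-square without continuity
correction. Cohen's d uses the pooled SD; Bonferroni multiplies p by the
family size and caps at 1. Empty factorial cells are rejected with a
diagnostic rather than silently dropped. The analysis unit (calls, cells,
sessions, or animals) is whatever the input table's rows are; the module
does not aggregate for you.

## Synthetic generators

Every generator is a pure function of its spec and one integer seed (no
global RNG state leaks), and each output row is described exactly once in
a returned truth table.

* **USV**: calls are rendered as linear FM chirps with 1 ms cosine ramps —
  chevron as a rise-then-fall pair of chirps peaking at the midpoint,
  frequency-step as an abrupt switch between two stable bands, composite
  as two simultaneous independent components, two-syllable as the main
  syllable plus a short flat component after an 8 ms gap — in additive
  white Gaussian noise, written as 16-bit PCM WAV at 250 kHz with
  amplitudes at or below 0.5 full scale. Call frequencies are constrained
  to 10–120 kHz and the sampling rate must satisfy Nyquist for every
  component. Real recordings have colored noise floors, reverberation,
  amplitude modulation and harmonics; none are modeled, so detection
  scores here bound performance from above.
* **FRA trials**: a tuned cell's trial response is
  `gain * G(log2(f/BF); width) * S(level) + N(0, noise_sd)` with G a
  unit-peak Gaussian in octaves and S a piecewise-linear ramp from 0 at
  threshold - 10 dB to 1 at threshold + 20 dB (the growth law is a modeling
  choice; nothing in the emulated protocol constrains it). Untuned cells
  are pure noise. Defaults — gain 1, noise SD 0.3, widths ~0.5 octaves,
  thresholds 30–50 dB — give single-trial SNR comparable to clearly
  responsive dF/F cells. 15 repeats per combination, as in the standard
  protocol.
* **Behavior**: each non-target condition has generative sensitivity
  `d(u) = asymptote * (1 - exp(-slope * u))` of its octave distance u from
  the target (defaults: asymptote 4.5, slope 2.2/octave — near-ceiling on
  the easiest condition, moderate on the hardest). Lick probabilities
  follow equal-variance signal detection with the criterion midway between
  the distributions, mixed with a 2% lapse and 5% guess rate; responses
  place one lognormal-latency lick inside the scoring window. Hit/false
  alarm rates match these probabilities within binomial 99% intervals at
  n = 1000, which the suite checks.
* **ABR**: a fixed five-wave difference-of-Gaussians template (peaks at
  1.5/2.5/3.5/4.7/5.8 ms), normalized to unit wave-I peak-to-trough and
  scaled by `slope * max(level - threshold, 2.5)` µV at and above
  threshold, zero below; the 2.5 dB floor makes the response at threshold
  itself just detectable, so a clean series recovers its generative
  threshold exactly rather than one step late. Split-half averages receive
  independent Gaussian noise. Latency shifts with level and across-subject
  template variation are not modeled.

## Problem sizes and numerical conventions

The test suite and acceptance script use: 100-call recordings at 20 dB SNR
for detection; 300-cell mixed populations (50% tuned) with 1000-iteration
d' for the selection filter; 12-cell/noise-0.8 ensembles, 5 seeds, 5–10
CV repetitions for the decoding curves; 20 seeded sessions at 200
trials/condition for behavioral recovery; 10–20 seeded series for ABR;
1000 null simulations at n = 6 per factorial cell for type-I calibration.
These sizes keep the full chain runnable on a laptop in about a minute
while leaving every statistical check comfortably powered.

Degenerate inputs are handled explicitly rather than by NaN propagation:
empty driven masks give undefined d' and metrics; all-constant cells are
flagged; zero-variance d' is capped; empty separation bins are reported as
NA; missing behavioral conditions leave their contrast undefined; the
hard-to-easy ratio guards against a near-zero denominator.

## Limitations

The generators provide statistical structure sufficient to test the
analysis code, not biophysical realism: no cochlear mechanics, no
adaptation or noise correlations between cells, no learning dynamics
within behavioral sessions, no call-type syntax. Passing tests therefore
certify the estimators — detection, masking, resampling, decoding,
scoring, thresholding — not any claim about real mice. Where a published
number is self-contained (octave distances, d' worked examples, repertoire
totals), the acceptance script reproduces it exactly; group-difference
statistics from undeposited animal data are out of reach by construction
and are not imitated.
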