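---
title: "Quantifying developing-hippocampus network activity with neophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying developing-hippocampus network activity with neophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neophys)
```

## What the package computes

Before eye opening, the rodent hippocampus is not continuously active:
CA1 alternates between silence and brief network-wide events — giant
depolarizing potentials (GDPs) in slices, early sharp waves (eSPWs) and
theta–beta oscillatory bursts in vivo. Studies that manipulate this
activity (pharmacologically or chemogenetically) quantify it through a
small set of bespoke procedures: ΔF/F0 calcium-transient rasters and a
coactivation rule for GDPs; passive and active membrane features from
current-clamp sweeps; miniature and evoked EPSC statistics with a
failure-based amplitude correction; and LFP band power normalized to the
electrode's technical noise, plus amplitude/band-power event detectors.
`neophys` implements each of those procedures as a tested, reusable
function, together with synthetic-data generators that plant
machine-readable ground truth for all four modalities, so every stage of
the pipeline can be validated without access to recordings.

## Calcium module

**Baseline and ΔF/F0.** The baseline `F0(t)` is the raw fluorescence
oversmoothed with a second-order Savitzky–Golay filter, window 1,500
frames (~30 s at typical acousto-optic frame rates of 40–62 Hz; even
window lengths are adjusted down to the next odd integer, 1,499). A
window that long averages over every transient (~1 s decay) while
following slow drifts of indicator brightness. Because a second-order
filter reproduces polynomials up to degree 2 exactly, constant and
linearly drifting baselines give ΔF/F0 ≡ 0, and the filter output at any
interior frame equals an independent quadratic least-squares fit over
the centered window — the package's tests verify this to 1e-9 relative.
Masked frames (z-drift epochs) are linearly interpolated before
smoothing and returned as missing; they never enter counts or durations.

**Transient onsets.** The onset detector is deliberately simple (the
upstream literature uses a separately published reconstruction
algorithm whose internals are not this package's concern): the ΔF/F0
trace is lightly smoothed (second-order SG, 5 frames), and an onset is
the first frame of each suprathreshold excursion, with the per-cell
threshold `max(5 × σ̂, 0.05)` in ΔF/F units. The noise scale σ̂ is the
median absolute deviation of the first difference divided by √2 — a
robust estimator that ignores the sparse transients — computed on the
*raw* trace, because after smoothing the first difference is strongly
anticorrelated and the estimator collapses. An excursion only ends once
the trace falls below half the threshold (hysteresis); without that
release rule, noise on a decaying transient re-triggers the detector and
biases recovered rates upward by ~20% under the study conditions. Onsets
closer than 0.5 s merge into the earlier one.

**Network events (GDPs).** A transient is GDP-related if some 500-ms
interval containing it has ≥ 20% of all recorded cells active (≥ 1 onset
inside the interval; the 20% boundary is attained inclusively), and two
GDP-related transients share a GDP if they share such a qualifying
interval; chaining is transitive and overlapping chained events are
merged. The active-cell count as a function of the window start only
changes when the start passes an onset or an onset-minus-window
breakpoint, so evaluating all windows anchored at those breakpoints *is*
the exhaustive continuous search. The test suite checks this against an
independent brute-force oracle (dense candidate grid, explicit pairwise
linking, explicit transitive closure) on 100 random rasters. The 20%
denominator counts all recorded cells, including ones with masked
stretches.

## Intrinsic-excitability module

Resting membrane potential is the median of the voltage in consecutive
20-s intervals at zero holding current (medians are insensitive to the
occasional spontaneous depolarization), with test-pulse epochs excised
plus a 100-ms settle margin, and the summary is the mean of interval
medians inside a caller-chosen window. Membrane resistance comes from
the steady-state deflection of 500-ms hyperpolarizing test pulses:
`Rm = ΔV/I`, with ΔV the mean over the final 100 ms minus the mean over
the 100 ms before pulse onset. Those window lengths are a package choice
— reported neonatal membrane time constants are tens of milliseconds, so
the last 100 ms of a 500-ms pulse is within a fraction of a percent of
steady state; a pulse whose mid-point deflection differs from the final
deflection by more than 5% is flagged as not settled.

Action potentials are detected on the first derivative of Vm (central
difference × sampling rate, then second-order SG smoothing over 5
samples, in that order): an onset is the first sample at which the
smoothed derivative reaches 20 V/s (inclusive), with no re-trigger until
it falls back below threshold. Derived metrics follow the standard
definitions — AP threshold is Vm at the onset of the first spike at the
lowest spiking current; rheobase is that current; maximum mean rate is
the largest per-step count divided by the 500-ms step duration; maximum
instantaneous rate is the inverse of the minimum inter-spike interval.
Across repeated series, metrics aggregate by the mean except rheobase,
which uses the median (rheobase lives on the discrete step grid, where a
median is the natural summary). Metrics undefined for a series (no
spikes) are explicit `NA`s, never zeros.

## Synaptic module

**Minis.** Detection is a matched filter: the trace is
rolling-median-baseline corrected, sign-flipped, and cross-correlated
with a unit-peak bi-exponential template (defaults 1.5 ms rise, 6 ms
decay), normalized by the template energy so the filter output is a
per-lag least-squares amplitude estimate. Events are local maxima of
that estimate passing both an amplitude and an area criterion — the
area default is `amp_threshold × decay/2` (pA·ms), mirroring the dual
criterion of semi-automatic mini analysis whose exact values are not
published. The matched filter is what makes a 5-SD threshold quiet
(< 0.01 false positives per minute measured on noise-only synthetics)
while keeping ≥ 95% recall at SNR 8.

**Evoked trials.** The paired-pulse protocol (2 pulses, 50 ms apart, 30
trials at 10-s intervals) is classified success/failure by an explicit
rule standing in for visual classification: blank 2 ms after each
stimulus, measure the peak inward deflection in a 3–20 ms response
window relative to a 10-ms local baseline just before the pulse (for
pulse 2 this baseline removes the decay of response 1), and call success
if the peak of a 1-ms-smoothed copy of the trace exceeds `k = 3`
baseline noise SDs. Two details matter at 20-kHz sampling. First, the
smoothing: the raw maximum over a 17-ms window of wideband noise
routinely exceeds 3 SD, which would misclassify a large fraction of
failures. Second, latency awareness: after a provisional pass, the
criterion is re-evaluated in a ±1-ms window around the median latency of
the provisional successes — a human classifier knows where the response
occurs, and the narrow window restores that information. Reported raw
amplitudes are measured unsmoothed, so planted noiseless amplitudes are
returned exactly. The failure correction then subtracts the mean raw
amplitude over failure trials (pure residual artifact and noise) from
every trial of the same pulse; per-cell summaries average over all
trials by default (failures ≈ 0 after correction), with a
successes-only mean also returned.

## LFP module

**Preprocessing.** Signals are decimated to 500 Hz through zero-phase
order-6 Butterworth stages (cutoff 0.8 × target Nyquist per stage,
factors > 10 cascaded; ends are odd-reflection padded so DC offsets do
not excite filter transients — a 300-Hz tone at a 20-kHz source rate is
attenuated by > 40 dB) and baseline-corrected by subtracting a centered
1-s rolling median, which removes DC and slow drift without distorting
100-ms events.

**Spectral estimation.** Welch's PSD (6-s Hamming segments, 20%
overlap, one-sided density) and a DPSS multitaper spectrogram (1-s
windows, 3 tapers at NW = 2, 80% overlap, i.e., a sample every 0.2 s,
3–100 Hz) are implemented in the package following the textbook
definitions, since no installed library provides them; the white-noise
density and the window-count arithmetic are pinned by tests. Normalized
band power is the 8–40 Hz Welch band power of consecutive 5-min
intervals divided by the same quantity for the electrode's technical
noise reference, so 1 marks the noise floor and the measure is invariant
to amplifier gain.

**eSPW detection.** Candidates are deflections exceeding 0.05 mV
(negative polarity by default — below the sharp-wave polarity reversal —
and configurable), merged within a 200-ms refractory period. The
accompanying band-power criterion is evaluated on a statistic matched to
the event's timescale: the 15–30 Hz band-passed signal's 0.1-s RMS
envelope, robust-z-scored against a rolling 10-s median/MAD baseline. A
1-s spectrogram window dilutes a 100-ms event's band power roughly
tenfold, and on synthetic data at the design SNR of ~5 the diluted
statistic has no threshold separating planted events from pink-noise
fluctuations; the envelope statistic separates them by a wide margin,
and its default cut `z ≥ 6` sits at the measured valley between the two
populations (planted-event z median ~9–10, noise 99.9th percentile
~4.5–5). Both the statistic and the cut are exposed as parameters.

**Burst detection.** The 4–15 Hz spectrogram band power at 0.2-s steps
is thresholded at its 120-s moving median plus 5 × its 360-s moving MAD
(raw MAD, no 1.4826 factor — the recipe specifies the MAD itself), with
centered, edge-truncated windows. Supra-threshold runs separated by
≤ 200 ms merge (step-quantization artifact). Because the 1-s analysis
window smears a clearly supra-threshold burst over up to a second of
window positions, each candidate epoch's boundaries are then refined at
signal resolution: the fine-scale band power (4–15 Hz band-pass, 0.1-s
rolling mean of the squared signal — the same units as the integrated
spectrogram band power) is compared against the same threshold
interpolated to the fine time base, and the refined runs must last
≥ 600 ms. Without the refinement the duration gate is vacuous: any
detectable 0.4-s burst spends ≥ 0.6 s above threshold at coarse
resolution. The refined detector keeps the adaptive-threshold character
(false-positive rates on event-free synthetics stay below 0.1 min⁻¹ and
within a factor of two when background power doubles) while making the
600-ms criterion exact.

The default 4–15 Hz band is fixed; a per-animal data-driven band is a
caller override rather than an automatic procedure, since no derivation
rule is published.

## Synthetic-data generators

The generators' defaults are the study conditions: 8-min imaging blocks
of 20 cells with spontaneous transients at 1.4 min⁻¹ and network events
at 2 min⁻¹ co-activating ≥ 50% of cells in a 500-ms span; 20-kHz
current-clamp with a single-compartment leaky membrane updated by the
exact per-sample exponential map (so the step response equals the
closed-form RC solution to machine precision) and integrate-and-fire
spikes pasted as 2-ms raised-cosine templates with ~100 V/s peak dV/dt —
comfortably above the 20 V/s detection criterion; Poisson minis at
0.13 min⁻¹ with lognormal amplitudes (only medians are reported, so the
shape is a modeling choice); paired-pulse evoked trials with exact or
Bernoulli failure patterns; and 30-min LFP blocks of 1/f pink noise at
0.04 mV SD (planted events at SNR ≈ 5) with sharp-wave templates
(100 ms, 0.2 mV, ripple at 80% of peak — a waveform without genuine
15–30 Hz content would not be a sharp wave to either the detector or a
reader of the raw trace) and enveloped theta-beta bursts (0.8–2 s,
carrier inside 4–15 Hz) at 2.1 and 4.0 min⁻¹. Each event class draws
from its own derived seed stream, so ground truth per class is
independent and identical configs with identical seeds regenerate
bit-identical data. The evoked presets in `ca1_presets()` plant 8/30 and
92/100 failures with success amplitudes 46.5 and 21.25 pA, chosen so the
all-trials mean corrected first-pulse amplitude equals 34.1 and 1.7 pA
analytically.

What the generators do *not* emulate — and therefore what passing tests
do not certify on real data: imaging movies and motion (traces are
generated directly), kinetic diversity of synaptic events, biophysical
conductances behind spikes, state-dependent or non-Poisson event
statistics, and recording artifacts beyond a user-supplied mask. The
validation shows the procedures recover what was planted under the
stated noise models, not that the noise models exhaust reality.

## Statistics and reporting

`paired_t()` and `holm_bonferroni()` are thin validating wrappers over
the standard tests (a zero-variance difference vector is an error — the
statistic is undefined, and silently returning `p = 1` would hide a
degenerate design). `contrast_report()` implements the gated
reporting logic of a paired two-group design: an omnibus stage (linear
mixed model with random subject intercepts via lmerTest — normal
family with identity link; a gamma-family variant is a modeling choice
outside this adapter — or a reduced mode comparing per-subject
differences between groups) must be significant, including its
interaction term, before the per-group paired contrasts are computed and
Holm-adjusted. On null simulations the gate makes the family-wise error
of the reduced pipeline conservative (≤ 0.05 at 10⁴ replicates, tested).

## Problem sizes and runtime

The validation suite runs the full study geometry where it is cheap
(30-min LFP blocks, 10 × 60-min pooled mini recordings, 10-min RMP
recordings at 20 kHz) and scales down only the LFP source rate
(2 kHz or 1 kHz instead of 20 kHz where only the decimated 500-Hz signal
matters downstream; one dedicated test keeps the 20-kHz
anti-aliasing path honest) and the repetition counts of
multi-seed properties (e.g., 8 event-free LFP blocks for the
false-positive bound). The whole suite completes in about three minutes
on one CPU; `scripts/acceptance.R` in well under one.

## Known limitations

GDP chaining is quadratic in the number of related onsets per
neighborhood (fine for rasters of tens of cells and hundreds of onsets;
a segment-tree formulation would be needed for orders of magnitude
more). The eSPW detector's operating point was characterized at the
generator's SNR of ~5; lower-SNR recordings will need the exposed
`band_z_min`/`amp_threshold` revisited. The burst band refinement the
in-vivo literature alludes to ("data-driven frequency band") is a
caller decision here. The GLMM adapter covers the normal-family case;
count- or skew-distributed metrics should be transformed or handled
with a dedicated model outside the package.
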