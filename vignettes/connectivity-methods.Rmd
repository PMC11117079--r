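---
title: "Methods: connectivity and phase-amplitude coupling in neuroconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity and phase-amplitude coupling in neuroconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroconn)
```

This vignette documents the models behind the package, the defaults and
why they were chosen, the numerical edge cases, and what the synthetic
test bed does and does not establish about real recordings.

## Signal model and preprocessing

A recording is a channels-by-samples matrix at a fixed sampling rate.
Common average re-referencing (`apply_car()`) subtracts the
instantaneous cross-channel mean — the component shared by all sensors,
presumed to be reference-electrode activity. It assumes a dense,
head-covering montage; with few channels the "average" is dominated by
individual sources, so the function warns below 64 channels.
Deliberately, bad channels are *not* excluded from the average: CAR is a
pure, composable operation, and the recommended pipeline order is
cleansing first, CAR second.

`downsample()` performs pure sample selection: the output instant
`i / target_fs` is mapped to the nearest original sample. For integer
rate ratios this reduces to taking every k-th sample; for non-integer
ratios nearest-index selection avoids interpolation (which would be a
filter in disguise). Anti-aliasing is the caller's job — selection
cannot remove power above the new Nyquist frequency — so the function
measures the fraction of total power above `target_fs / 2` and warns
when it exceeds 1% of the total variance. A warning, not an error: the
user may know the spectrum better than the heuristic. The pipeline
runner offers an `antialias` flag that inserts a low-pass FIR at
`0.45 * target_fs` first.

## FIR filtering

Filters are linear-phase type-I (odd-length, symmetric) windowed-sinc
designs with a Hamming window. The tap count is the smallest odd integer
at least `3.3 * fs / transition_width` — the classical Hamming rule that
fits the full passband-to-stopband transition inside one transition
width, giving roughly −53 dB stopband ripple and <1% passband ripple.
High-pass and band-stop kernels are spectral inversions of low-pass
kernels; band-pass is the difference of two low-pass kernels, which
makes the DC gain exactly zero and the low-pass DC gain exactly one by
normalization.

Application is by FFT overlap-add: blocks of length
`nfft − n_taps + 1` with `nfft` the smallest power of two at least
`4 * n_taps` (a standard speed/memory balance: the FFT is at least
three-quarters "useful" output). The group delay of
`(n_taps − 1) / 2` samples is compensated inside the function, so output
aligns with input at equal length. Edge samples are computed against
zero-padded context and should be treated as transient-contaminated for
`(n_taps − 1) / 2` samples at each end.

Two precision modes exist. `precise` computes everything in double
precision. `fast` quantizes the input and the taps once to IEEE single
precision, computes, and quantizes the output — single-precision storage
with double arithmetic in between, which bounds the deviation from
`precise` well below the 1e−4 relative tolerance the tests assert.
The Butterworth path (`apply_iir()`) wraps `signal::butter` +
`signal::filtfilt` (forward-backward, hence zero-phase and double
attenuation), with an explicit pole-magnitude stability check.

## Spectral estimation

`cross_spectra()` uses Welch-style segmentation: 1-second Hann windows
(`nperseg = fs`) at 50% overlap, one-sided density scaling, no
detrending (a DC offset legitimately appears in the 0 Hz bin). These
defaults give 1 Hz resolution and, on a 60 s recording, ~119 segments —
standard practice for resting-state coupling estimates. Per-segment
spectra are kept because the weighted phase lag index must average the
imaginary cross-spectrum over segments *before* normalizing.

The cross-spectrum convention is `S_xy = X · conj(Y)`; a positive phase
of `C(f)` and a positive phase slope mean the first signal leads. All
directional statements (PSI, DAC) are defined against this convention.

Two numerical details matter. First, the complex product `X · conj(Y)`
is formed before any real scaling so that for `y = x` its imaginary part
is *exactly* zero in floating point — this is what makes the wPLI
zero-lag convention exact rather than approximate. Second, wPLI treats
imaginary mass at the floating-point noise floor (at or below
`1e−12 · mean |S_xy|`, e.g. the Nyquist bin of any real signal) as the
0°/180° case and returns 0 instead of a ratio of rounding errors.

## Same-frequency metrics

MSC and imaginary coherence are direct transforms of `C(f)`. PSI sums
`Im(conj(C(f)) · C(f + δf))` over the band (δf defaults to one bin) and
standardizes by a leave-one-segment-out jackknife estimate of its
standard deviation; fewer than 4 segments make the jackknife
meaningless and raise an error. The standardized value is a z-like
quantity and is reported **unclipped**: a standardized slope is not
intrinsically confined to [−1, 1], and clipping would destroy its use as
an evidence scale (|PSI| ≲ 2 under the null, as the test suite checks
across 100 null replicates).

DAC combines the three constituents into one signed, bounded score:
`sign(raw PSI) × band-mean |C|`, therefore in [−1, 1], with a
volume-conduction flag raised when band-mean `|C| ≥ 0.5` while
band-mean `|Im C| ≤ 0.05` — strong coupling at near-zero lag is exactly
the signature of one source seen by two sensors. The flag annotates, it
never zeroes the value; thresholds are arguments. The combination rule
lives in one function (`dac()`) so an alternative formulation can be
swapped in without touching its constituents.

## Phase-amplitude coupling

All CFC metrics operate on pre-filtered band signals; none filters
internally. Phase and envelope come from the FFT-constructed analytic
signal; a constant input has no definable phase and errors. The
phase-amplitude histogram uses 18 bins (20°) by default — the common
resolution for the modulation-index family; empty bins contribute 0 and
warn rather than being interpolated (deterministic and conservative).
The modulation index uses the natural logarithm; any base cancels in
the `(log N − H) / log N` ratio.

The PAC phase-locking value needs the *phase of the envelope*. An
amplitude envelope has a large DC level that carries no phase
information and would dominate the analytic signal, so the envelope is
mean-centred before its phase is taken; a constant envelope then
correctly degenerates to the error case.

### The direct modulation index

The DMI is a sinusoid-fit score: fit `A sin(φ + φ₀) + c` to the
histogram by least squares (linear in `A cos φ₀`, `A sin φ₀`, `c`, so
`A ≥ 0` automatically) and penalize non-sinusoidal residue through
`nrmse = RMSE / 0.5`. The design question is how to normalize the
histogram before fitting. Min-max rescaling to [0, 1] was considered
and rejected: it maps *any* sinusoidal histogram to full swing, so the
score saturates near 1 at every nonzero depth and amplifies noise
ripple in flat histograms — it measures sinusoidality, not coupling
strength. Instead the histogram is normalized by its mean level. Under
the generator's modulation law the fitted relative amplitude is
`(d/2) / (1 − d/2)`, strictly increasing in depth `d`, reaching 1
exactly at full depth (envelope touching zero at the opposite phase).
The score `DMI = clip(A · max(0, 1 − nrmse), 0, 1)` is then statically
bounded, 0 for flat histograms, 1 for full-depth sinusoidal coupling,
and monotone in depth — the property the test suite asserts across
depths {0, 0.25, 0.5, 0.75, 1}.

## Artifact handling

Bad-channel detection z-scores each channel's mean band power across
channels and flags `|z| > 3` (two-sided: both dead and noisy channels
deviate). z-scores use the population (n-denominator) standard
deviation, fixed for reproducibility. One consequence worth knowing:
with `n` channels a single deviant channel can reach at most
`z = √(n−1)`, so the default threshold needs comfortably more than 10
channels to be attainable — with fewer channels, lower the threshold
deliberately. Identical powers across channels (sd = 0) yield no flags
and a warning. The interactive confirmation step common in GUI tools is
replaced by a machine-readable report plus an `overrides` argument,
which keeps headless runs reproducible while preserving user authority.

Restoration replaces each bad channel by the unweighted mean of its
currently non-faulty neighbors, scheduling the channel with the most
non-faulty neighbors first and re-admitting restored channels as
donors; ties break to the lowest channel index (deterministic).
Channels with no path to good data raise an error naming them.

Outlier removal iterates: z-score the kept set (population sd), drop
everything beyond `|z| > 2`, repeat until clean, until the spread
collapses, or until the `min_keep` floor (default 20% of the input)
would be violated — then only the most extreme samples are dropped,
down to exactly the floor, and the event is reported. Detection bands
should not overlap later analysis bands; the pipeline runner logs a
warning when they do (a warning, not an error — the overlap is
sometimes intentional).

## Visualization

`topoplot()` interpolates channel values over the unit head disk with a
thin-plate radial basis expansion (exact at the electrodes, smooth
in between, affine term included, tiny ridge for conditioning) and
masks outside the head circle — extrapolation beyond the electrode hull
is smooth rather than clamped, which is the documented choice.
Significance markers encode three levels: white = survives multiple
comparison correction, grey = significant only uncorrected, black =
nonsignificant. The function computes no statistics itself; it consumes
p-values. Every render also emits a JSON marker manifest so the marker
logic is testable without pixel inspection.

## Chunked storage and pipelines

`chunk_write()` splits an array along its first axis into raw
little-endian binary files with a JSON manifest; `chunk_read()`
verifies per-chunk MD5 checksums and shape consistency before assembly.
Both sides touch one chunk at a time, so the transient buffer stays
bounded by one chunk beyond the destination — the memory-spike contract
that motivates chunking in the first place. The pipeline runner is
single-process by design; per-stage logging of parameters and shapes
into `run_report.json` makes runs auditable and reruns with the same
config and seed bit-reproducible.

## The synthetic test bed

The generators define the conditions under which everything is
validated: 250 Hz sampling and 60 s duration (typical EEG/LFP session
lengths; 1 Hz spectral resolution with ~119 Welch segments), SNR 10 for
coupled-pair and PAC fixtures (clearly detectable but far from
noise-free), 20 ms delays (a plausible cortico-cortical conduction
delay, 5 samples at 250 Hz), 6 Hz theta phase modulating a 60 Hz gamma
envelope, 32-channel recordings with a 5× amplitude (25× variance)
rogue channel, and 50 injected ±10 sd outliers per 10,000 samples.
Acceptance checks scale some of this down (5 s pairs for the bound
suite, 20 s pairs for direction recovery) to keep the suite fast; the
problem sizes are stated in the tests themselves.

Gaussian white noise and clean sinusoidal/band-limited sources are a
deliberate idealization. Real recordings have 1/f backgrounds,
nonstationarity, muscle and ocular artifacts with structure that a
z-score does not capture, and volume conduction that is partial rather
than all-or-none. Passing this test bed therefore demonstrates metric
correctness (bounds, closed forms, symmetries, direction recovery,
monotonicity in coupling strength) — not robustness to every property
of in-vivo data.

## Known limitations

* PSI needs many segments; with fewer than ~20 its jackknife sd is
  noisy and the standardized value should be read cautiously.
* The DMI formula is this package's own construction (sinusoidal fit,
  static bound, depth-monotone); other implementations of a
  "direct modulation index" may scale differently, so compare scores
  only within one implementation.
* Downsampling without prior low-pass filtering aliases; the 1% power
  warning is a heuristic, not a guarantee.
* Fast filter mode stores single precision; for signals with extreme
  dynamic range prefer `precise`.
* The topographic map is a 2-D schematic, not a source localization.
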