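# neuroconn

Functional-connectivity and phase-amplitude-coupling analysis for
multichannel neurophysiological time series (EEG, MEG, LFP) in R.

Neural populations coordinate across regions by synchronizing their
oscillations. Two kinds of coordination are covered here:

* **Same-frequency coupling (SFC)** — statistical dependence between two
  signals within one frequency band. All SFC metrics derive from the
  segment-averaged *complex coherency*

  C(f) = ⟨S_xy(f)⟩ / √(⟨S_xx(f)⟩ ⟨S_yy(f)⟩),

  whose magnitude measures coupling strength and whose argument is the
  phase lag. The package provides magnitude squared coherence
  (|C|², in [0, 1]), imaginary coherence (Im C, insensitive to zero-lag
  volume conduction), the weighted phase lag index
  (wPLI = ⟨Im S_xy⟩ / ⟨|Im S_xy|⟩, in [−1, 1]), the phase slope index
  (PSI, jackknife-standardized slope of the coherency phase across a
  band; its sign says which signal leads), and the directional absolute
  coherency (DAC = sign(PSI) · band-mean |C|, in [−1, 1], with a
  volume-conduction flag from the imaginary coherence).

* **Cross-frequency coupling (CFC)** — here phase-amplitude coupling
  (PAC): the envelope of a fast oscillation rides on the phase of a slow
  one. From the phase-amplitude histogram (mean high-band envelope per
  low-band phase bin) the package computes the modulation index
  (entropy deficit, MI = (log N − H)/log N), the direct modulation index
  (sinusoid-fit score, statically bounded to [0, 1]), the PAC
  phase-locking value, and the mean vector length.

Around the metrics sit the standard workflow pieces: common average
re-referencing and downsampling, linear-phase windowed-sinc FIR filters
applied by FFT overlap-add (fast 32-bit or precise 64-bit mode, plus a
zero-phase Butterworth wrapper), band-power bad-channel detection with
neighbor-average restoration, iterative z-score outlier removal,
significance-aware topographic maps, chunked binary array storage, a
declarative JSON pipeline runner, and seeded synthetic-signal generators
with known ground truth.

## Worked example

Detecting directed coupling between two signals where the second is a
20 ms-delayed copy of the first (8–30 Hz source, SNR 10):

```r
library(neuroconn)

pair <- gen_coupled_pair(fs = 250, duration = 60, seed = 42,
                         band = c(8, 30), delay = 0.02, snr = 10)
C <- complex_coherency(cross_spectra(pair$x, pair$y, fs = 250))
C
#> <coherency_spectrum> 126 frequency bins 0-125 Hz, 119 segments, max |C| = 0.984

dac(pair$x, pair$y, fs = 250, band = c(8, 30))
#> # A tibble: 1 × 9
#>   metric value band_lo band_hi volume_conduction mean_coh mean_imcoh mean_msc
#> 1 dac    0.977       8      30 FALSE                0.977      0.615    0.955
```

The DAC value of 0.977 says the signals cohere almost perfectly over
8–30 Hz and its positive sign says the first signal leads (drives) the
second — which is how the pair was built. The volume-conduction flag is
off because the delayed coupling leaves a large imaginary coherence.

Phase-amplitude coupling at modulation depth 0.8 (6 Hz phase, 60 Hz
amplitude):

```r
pac  <- gen_pac_signal(fs = 250, duration = 60, seed = 42, depth = 0.8)
low  <- apply_fir(pac$composite, "bandpass", c(4, 8),  2, fs = 250)
high <- apply_fir(pac$composite, "bandpass", c(50, 70), 4, fs = 250)
ph   <- analytic_phase_amp(low)$phase
amp  <- analytic_phase_amp(high)$amplitude
h    <- phase_amp_histogram(ph, amp)

modulation_index(h)$value          # 0.0372  (entropy deficit, small scale)
direct_modulation_index(h)$value   # 0.630   (depth-sensitive, ~0.8 coupling)
```

Both scores rise monotonically with the generator's modulation depth;
`autoplot(h)` shows the sinusoidal histogram the DMI fits.

## Command-line interface

A thin CLI over the same functions ships in `inst/cli/neuroconn`:

```sh
Rscript inst/cli/neuroconn simulate pair --seed 3 --out demo/
Rscript inst/cli/neuroconn sfc --metric dac --band 8:30 --fs 250 x.csv y.csv
Rscript inst/cli/neuroconn pipeline config.json
```

See `vignettes/connectivity-methods.Rmd` for the methods, parameter
choices and known limitations.
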