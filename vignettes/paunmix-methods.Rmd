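---
title: "Multispectral photoacoustic unmixing: models, parameters and design choices"
author: "paunmix authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral photoacoustic unmixing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paunmix)
```

## The problem

Multispectral laser-scanning photoacoustic microscopy (MS-LS-PAM) raster-scans
a pulsed laser over skin at several visible wavelengths and records, at every
scan position, a time-resolved acoustic signal (an *A-line*). Because the
photoacoustic amplitude scales with the local optical absorption, images
acquired at wavelengths where oxy- and deoxyhemoglobin, melanin and collagen
absorb differently can be decomposed into per-chromophore maps: vascular
oxygen saturation (sO~2~) inside vessels, and relative collagen/melanin
content in the surrounding dermis.

`paunmix` implements the analysis side of such a system for the excitation
set 532/545/558/571 nm: A-line enhancement, envelope-energy image formation,
vessel masking, region-partitioned constrained spectral unmixing, and the
functional maps. Because no raw data are publicly deposited, the package
also contains a synthetic forward simulator that replaces the microscope
(and a full acoustic wave solver) for validation.

## Image formation

Each A-line `p(t)` is background-subtracted (mean of the first
`background_window = 256` samples, i.e. the pre-arrival baseline -- the
estimator is a package choice, the record length comfortably precedes the
first acoustic arrival at the default 6 mm standoff), converted to its
envelope `|H[p](t)|` via the analytic signal, and integrated with the
trapezoidal rule:

$$\mathrm{AUC} = \int_{t_0}^{t_1} \left| H[p](t) \right| \, dt .$$

The envelope integral is used rather than the peak amplitude because it
pools signal energy over the whole detected pulse, which is more robust to
noise and consistent across wavelengths. The integration limits $t_0, t_1$
are not fixed by the model, and their choice matters more than it looks:
the detected pulse occupies only a few percent of the 40.96 µs record, so
integrating the rectified envelope over the full record accumulates a
noise pedestal of roughly $1.25\,\sigma_n$ per sample that can exceed the
signal of weak (dermal) absorbers outright and bias the unmixing toward
the spectrally flatter chromophore. The default is therefore a
signal-adaptive gate — the support of the pixel-mean envelope above 10% of
its peak, widened by four pulse widths and shared by all wavelengths (the
arrival geometry is wavelength-independent) — combined with per-A-line
subtraction of the envelope noise floor estimated over the pre-arrival
baseline window, with the AUC clipped at zero. Both corrections scale
identically across wavelengths for a given pixel, so zero-noise recovery
is unaffected; `gate = "full"` and explicit `t0_us`/`t1_us` windows remain
available.

Each wavelength's AUC image is divided by that wavelength's mean applied
pulse energy, so that image intensities reflect relative absorption rather
than source power. Per-shot compensation (dividing by each shot's recorded
energy) is available and is exact by construction in the simulator, which
records post-jitter energies.

## Vessel masking and the partition

The 545 nm image -- a hemoglobin isosbestic point, so vessel contrast is
independent of oxygenation -- is min-max normalized and filtered with a
Frangi vesselness filter (Hessian eigenvalues at Gaussian scales
$\sigma \in \{1,2,3\}$ px, blobness $\beta = 0.5$, structureness constant =
half the maximum structureness per scale). The vesselness map is min-max
normalized to $[0,1]$ and thresholded at 0.1. The scale set and the
normalization are package choices (only the threshold is externally fixed);
scales 1--3 px match vessel radii of roughly 60--180 um at the default
60 um pixel pitch.

Blood absorbs roughly a thousandfold more strongly than dermal pigments in
this band, so dermal pixels near a vessel receive a non-negligible share of
their signal from the vessel. The vessel mask is therefore dilated by a
Euclidean disc of `ceiling(160 / pitch)` pixels (rounding up so the buffer
is never narrower than 160 um, which exceeds the ~150 um contamination
range), and the grid is partitioned exactly into *vessel core*, *buffer*
and *dermis*. Hemoglobin is unmixed only in the core, collagen/melanin only
in the dermis, and buffer pixels are excluded from both models; the
disjoint-cover invariant is asserted on every call.

## Constrained unmixing

Per pixel, the energy-compensated AUC values form a vector
$b \in \mathbb{R}^4$ and the extinction matrix $A$ (4 wavelengths x 2
chromophores) comes from the packaged spectral library. Concentrations are
estimated by non-negative least squares,

$$\hat{x} = \arg\min_{x \ge 0} \lVert A x - b \rVert_2,$$

optionally with a Tikhonov penalty $\lambda^2 \lVert L x \rVert_2^2$ solved
through the augmented system $[A; \lambda L]$. `L` defaults to the
identity (ridge penalty); $\lambda$ can be fixed or selected at the corner
(maximum discrete curvature) of the L-curve of log residual norm versus log
solution seminorm over 30 log-spaced candidates spanning
$[10^{-6}, 10^2] \cdot \lVert A \rVert_2$.

Numerical choices in the corner search: a consistent (noise-free) system is
detected by a residual below $10^{-8}\lVert b \rVert$ and returns the
smallest candidate (the data term dominates everywhere, and the
log-residuals on the solver floor are numerical noise); curvature is
estimated by centered differences on the log-log curve; points whose
log-log tangent speed is below $10^{-4}$ (the flat residual plateau, where
the curvature estimate is noise-driven) are excluded; ties break toward
smaller $\lambda$. By default $\lambda$ is selected once per region class
from the median-intensity pixel's L-curve -- per-pixel selection is
available but roughly 30x slower and was not observed to change the
recovered fractions in the synthetic scenes. With $\lambda = 0$ the
regularized path dispatches to plain NNLS bit-for-bit.

Functional maps follow directly:
$\mathrm{sO_2} = 100\,\mathrm{HbO_2}/(\mathrm{HbO_2}+\mathrm{Hb})$ on
vessel pixels, and relative collagen/melanin percentages (summing to 100)
on dermal pixels. Only relative quantities are reported: with unit
calibration constants the absolute scale of $\hat{x}$ is arbitrary.
Validation uses the absolute percent error
$100\,|C_\mathrm{true}-C_\mathrm{est}|/C_\mathrm{true}$, which is undefined
(an error, not infinity) at zero true concentration.

## The spectral library

The library (`inst/extdata/spectral_library.csv`) is a **synthetic compiled
tabulation**, not a copy of any single published table. Anchors that are
externally fixed: the 532 nm absorption values (Hb 21.7360, HbO~2~ 23.499,
melanin 0.124678, collagen 0.025647 mm^-1^), the collagen/melanin
scattering columns, and the conditioning diagnostics of the two unmixing
matrices (condition numbers approximately 7.5 for HbO~2~/Hb and 41 for
collagen/melanin). The remaining entries follow standard spectral shapes --
a near-isosbestic hemoglobin crossing at 545 nm, the Hb absorption peak
near 558 nm, the HbO~2~ alpha-band rise toward 571 nm, and power-law decay
for melanin and collagen -- with the free shape parameters calibrated so
the packaged 4x2 matrices reproduce the conditioning diagnostics exactly.
Lipid (3--9 x 10^-6^ mm^-1^) and water (1--2 x 10^-4^ mm^-1^) columns are
orders of magnitude weaker; the lipid column is constructed to lie almost
exactly in the span of the other dermal columns, reproducing the severe
(>6 x 10^7^) ill-conditioning of the four-absorber non-blood matrix that
motivates excluding lipid and water from visible-band unmixing. Because
per-wavelength values away from 532 nm are not externally pinned, the
melanin column decays to 0.093 mm^-1^ at 571 nm -- the value demanded
jointly by the anchor, the power-law shape and the conditioning diagnostic.
No interpolation outside the tabulated wavelengths is offered; lookups off
the grid are errors.

`feasibility_study()` quantifies the consequence: with spectra quantized to
16-bit depth, the two-chromophore systems invert to sub-percent error while
lipid/water recovery fails outright, mirroring the 64-bit-vs-16-bit
contrast that justified the two-chromophore design.

## The forward simulator

The simulator deliberately replaces a pseudospectral acoustic solver with a
1-D depth-encoded convolution model: the detected waveform of an absorbing
layer at depth $d$ is a Gaussian-envelope sinusoid at the transducer center
frequency $f_0 = 2.25$ MHz, envelope width set by the 66% fractional
bandwidth (spectral FWHM $= 0.66 f_0$, so
$\tau = \sqrt{2\ln 2}/(\pi \cdot 0.66 f_0) \approx 252$ ns), centered at
the time of flight $d/c$ with $c = 1500$ m/s. The amplitude is
$\mu_a(\lambda) \times E(\lambda)$ with the Grueneisen coefficient and
fluence folded into a unit calibration constant -- i.e. the simulator
embodies the same "photoacoustic energy scales with absorption" assumption
the analysis inverts. Region-partitioned unmixing depends only on these
relative spectral amplitudes, not on wave-propagation fidelity, which is
what makes the desk-scale replacement faithful for validation purposes.
What the simulator does **not** emulate: acoustic scattering and
attenuation, optical fluence and its depth dependence,
chromophore-dependent Grueneisen efficiency, scan-geometry distortion and
inter-wavelength misregistration, and structured (non-Gaussian) detector
noise. Passing tests therefore demonstrate the correctness of the
inversion chain under its own model assumptions, not in vivo accuracy.

Defaults and their origins: 4096 samples per A-line at 10 ns (the digitizer
rate is a package choice; 40.96 us covers centimetre-scale standoffs),
phantom layers at a 6 mm acoustic standoff (so the pulse arrives well after
the 256-sample baseline window), four unit pulse energies with 2%
multiplicative per-shot jitter, additive Gaussian noise specified relative
to the maximum clean amplitude of the frame set (default 0.2% of full
scale: dermal absorbers sit three orders of magnitude below blood, so a
much higher floor would leave no single-shot dermal signal, contradicting
the demonstrated dermal imaging of the emulated system), and optional 16-bit
mid-rise quantization over the frame set's full scale (the recorded full
scale makes re-quantization idempotent). Mixture phantoms default to a
64 x 64 grid at 60 um pitch -- a deliberate reduction of the full
512 x 512 / 10 um validation grid to keep the end-to-end suite desk-scale;
the grid is configurable and the recovered errors are grid-size-insensitive
at zero noise. All randomness flows from one integer seed; the pipeline
derives per-stage child seeds so toggling the denoiser does not perturb the
simulation stream.

Validation scenarios fix melanin:collagen at (1:99), (5:95), (10:90) and
(20:80) -- the 1% case matching dermal physiology, the higher fractions
serving as pigment stress tests. At zero noise the full chain recovers
these compositions to ~10^-6^ percent error; the package's acceptance
bound for the maximum scenario error is 0.18%.

## The denoiser

The optional A-line enhancer is a dense autoencoder: encoder
4096 → 3072 → 1024 → 512 → 256 with ReLU activations, a learned additive
positional embedding on the 256-dimensional code, a single-head attention
gate $u = \tanh(W_a z)$, $\alpha = \mathrm{softmax}(W_s u)$,
$c = \alpha \odot z$ (softmax over the embedding elements -- after a dense
encoder there is no sequence axis left, so the gate reweights latent
features and $\alpha$ is a probability vector), and a mirrored decoder
256 → 512 → 1024 → 3072 → 4096. A decoder ending at 3072 cannot reproduce
a 4096-sample input, so the final 3072 → 4096 layer completes the mirror;
its weights are zero-initialized so the untrained network outputs the null
waveform and the first optimization steps are independent of the random
initialization of the deep stack.

Training minimizes
$\lambda_1 \lVert \hat{x}-x_\mathrm{ref} \rVert_1 + \lambda_2
\sum_s \lVert\, |\mathrm{STFT}_s(\hat{x})| - |\mathrm{STFT}_s(x_\mathrm{ref})|\,\rVert_1$
with $\lambda_1 = 0.6$, $\lambda_2 = 0.4$, Hann windows of 256/512/1024
samples (hop = window/4, per-scale terms averaged; the scale set is a
package choice). Gradients flow through the STFT magnitudes via the DFT
adjoint and are verified against finite differences in the test suite.
References are means of `n_average = 150` independent noisy realizations of
the same clean signal, emulating high-SNR averaging; training pairs sample
phantom pixels with probability proportional to signal amplitude, since an
A-line with no signal above the noise floor teaches only suppression.
Inputs are normalized per A-line by maximum absolute amplitude (the same
factor scales the reference), making optimization independent of the
arbitrary acquisition scale.

Two protocols ship. The full protocol is Adam at 1e-4, batch 32, 120
epochs, with augmentation by additive Gaussian noise (up to 2x the
estimated input noise), ±10% amplitude jitter and ±16-sample circular
shifts. The reduced desk-scale protocol (15 epochs on ~500 pairs, the
surface exercised by the tests) differs in three deliberate ways, each a
consequence of the ~200-step budget: the Adam rate is 3e-2 (with Adam the
total parameter displacement is bounded by rate x steps; at 1e-4 the
network cannot even write a unit-amplitude pulse into its weights in 225
steps -- the large constant rate proved more reliable across seeds than
warmup/decay schedules, which trade away late-stage displacement),
augmentation noise is halved, and temporal-shift augmentation is disabled
(reconstructing the 2.25 MHz carrier at randomly shifted arrival phases
through a dense bottleneck is learnable over 120 epochs, not 200 steps; a
model trained under shifts at this budget reproduces an average-phase pulse
that *lowers* output SNR). Under the reduced protocol the trained model
improves held-out A-lines at 10 dB input SNR by well over the 3 dB
acceptance margin. Training aborts with a diagnostic on a non-finite loss;
optional global gradient-norm clipping is available but off by default (at
this scale it slowed convergence without improving stability). Denoising is
strictly optional: with no model supplied the reconstruction path is
untouched.

## Problem sizes in the test suite

The suite runs the mixture validation at the 64 x 64 default, module tests
at 6--32 pixel grids with 512--1024-sample A-lines, and the denoiser
acceptance property at the full 4096-sample architecture (500 pairs, 15
epochs). These sizes are the package's reduced-scale defaults; every
reduction is configurable upward.

## Known limitations

- The spectral library away from 532 nm is a calibrated reconstruction, not
  a measured tabulation; absolute per-wavelength values at 545--571 nm
  carry the uncertainty of that construction (the conditioning diagnostics,
  which drive unmixing stability, are pinned).
- The forward model omits fluence, acoustic propagation and
  Grueneisen heterogeneity, so recovered "concentrations" are relative
  absorption shares, and collagen may be over-weighted relative to melanin
  in real tissue.
- The Frangi scale set assumes vessels of ~1--3 px radius; much wider
  vessels need wider scales.
- The denoiser's reduced protocol is tuned for the synthetic pair
  distribution; real-data use should train the full protocol on acquired
  pairs.
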