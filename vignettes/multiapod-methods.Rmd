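---
title: "Non-linear multi-apodization for high-frequency ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-linear multi-apodization for high-frequency ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiapod)
```

## The problem

In B-mode ultrasound imaging, the lateral point response of a focused
array has a main lobe, whose width sets lateral resolution, and side
lobes, which leak off-axis echoes into every image point and fill in
anechoic structures, reducing contrast-to-noise ratio (CNR).  Linear
apodization — fixed amplitude weighting across the receive aperture —
lowers side lobes at the cost of a wider main lobe.  The
minimum-selection multi-apodization scheme avoids this trade-off
non-linearly: the same received channel data are beamformed several
times with different windows, each envelope image is normalized by its
own maximum, and the final image keeps the pointwise minimum.  Near the
main-lobe peak the narrow-window image is smallest, so the combined
image inherits the narrow main lobe; in side-lobe regions whichever
window is lowest wins, so the combination inherits the lowest floor.
At 40 MHz, where side-lobe clutter is a dominant contrast limit, this
is an attractive, computationally cheap scheme.

## Window models

Three window families are synthesized from their closed forms, all
peak-normalized with symmetric weights:

* **Rectangular** (uniform): all weights one.  Narrowest main lobe
  (-6 dB spectral width 1.21 bins at N = 32; a *bin* is one sample
  spacing of the unpadded N-point DFT) and highest side lobe (-13 dB).
* **Dolph-Chebyshev**: the equiripple design.  The spectrum samples are
  the Chebyshev polynomial `T_(N-1)(beta cos(pi k / N))` with
  `beta = cosh(acosh(10^alpha)/(N-1))`; the weights are its inverse
  DFT, with a half-sample linear phase for even `N` so the window is
  symmetric.  The parameter `alpha` is the common log of the
  main-to-side-lobe ratio: every side lobe sits at exactly
  `-20 alpha` dB.  `alpha = 2.5` (the default) gives -50 dB.
* **Kaiser**: `I0(pi alpha_k sqrt(1 - x_n^2)) / I0(pi alpha_k)`, with
  the zero-order modified Bessel function evaluated by its power
  series (terms below 1e-12 of the running sum are dropped).
  `alpha_k = 2.5/pi` gives a -21 dB highest side lobe and a 1.43-bin
  main lobe, between the other two families.

A note on the Chebyshev design: an alternative construction circulating
in the literature samples the degree-`N` polynomial at `N` points with a
`(-1)^k` shift.  That construction aliases an (N+1)-point design onto
`N` samples and its first side lobes rise to -43 dB at `alpha = 2.5`;
it also yields a slightly narrower measured -6 dB width (1.84 bins
versus 1.89).  This package uses the exact equiripple synthesis, for
which the -50 dB floor is analytic.  One consequence is worth stating
plainly: for a true -50 dB equiripple design at N = 32 the -6 dB width
is forced analytically to 1.89 bins — width figures near 1.85 bins
quoted together with a -50 dB floor cannot both be exact.

Spectra are measured on a zero-padded DFT (default pad factor 64, i.e.
1/64-bin resolution, enough to quote widths to 0.01 bins), peak
normalized to 0 dB, with level crossings linearly interpolated between
samples.  The main lobe is bounded by the first local minimum on each
side of the peak — unambiguous for these windows, whose first nulls are
deep.  Minimum-combined spectra additionally expose a *harmonic* (far)
side-lobe floor, reported by `harmonic_sidelobe_level()` as the maximum
level beyond `N/8` bins: near-in transition lobes of a combined
response are set by crossings between member main lobes (the
Dolph-Chebyshev main lobe extends to about 2.2 bins at N = 32), whereas
the far floor is capped by the lowest member ripple, which is the
quantity of interest (-50 dB for the dual and tri combinations).

## The simulator

`simulate_rf()` is a point-source acoustic model of the 128-element,
40 MHz, 40 um-pitch linear array: for each of 128
scanlines a 32-element walking subaperture (truncated at the array
ends) transmits a 2-cycle sinusoid focused at 3.5 mm, and every
transmit-element/scatterer/receive-element path contributes the pulse
delayed by its round-trip travel time and scaled by spherical spreading
`1/(d_tx d_rx)`.  Sampling is at 400 MHz (10x the carrier) with
linearly interpolated fractional delays, keeping delay quantization far
below a wavelength.

Each element carries an electromechanical impulse response — a 2-cycle
Hanning-weighted sinusoid at the center frequency, applied once on
transmit and once on receive — so the round-trip pulse is the 2-cycle
excitation convolved twice with it (about 6 cycles, 150 ns).  This
band-limiting is essential, not cosmetic: with ideal broadband
elements, the beam skirts at a few tenths of a millimetre off-axis are
dominated by *time-spread* energy (channel contributions that no longer
overlap within the pulse), which no apodization window can reject.
Band-limited elements put those offsets back into the
interference-dominated regime where the window shape controls the
response, which is how real transducers behave.  With this element
model the simulated focal-target -6 dB width is about 93 um against
about 92 um for a continuous-wave two-way calculation of the same
geometry, and the -35 dB widths and side-lobe ROI ranges fall in the
expected few-hundred-micrometre / -40 to -60 dB ranges.

What the simulator does *not* model: element directivity and elevation
geometry, frequency-dependent attenuation, multiple scattering, and
the full spatial impulse response of rectangular elements.  Absolute
micrometre-level beam widths are therefore approximate (at the
few-percent level at the focus), and quantities dominated by
out-of-plane or far-off-axis energy are outside its reach (see
*Limitations*).

## Beamforming and the image pipeline

`das_beamform()` applies delay-and-sum with dynamic receive focusing at
every axial sample: receive delays from exact element-to-pixel
geometry, linear-interpolation fetches, weighting by the receive
window.  At truncated edge subapertures the window is re-synthesized at
the reduced element count rather than cropped, preserving its spectral
character.  The image then flows, in fixed order, through envelope
detection (per-scanline analytic-signal magnitude along depth,
full-length transform), self-normalization (division by the image's own
global maximum), the pixelwise-minimum comparator for dual/tri
combinations, and log compression (`20 log10`, clipped to a 60 dB
display range).  The order matters and is enforced through an explicit
`stage` field: normalization must precede the comparator so that
differently-weighted images are comparable, and the combined image goes
to log compression *without* re-normalization, so its maximum may fall
slightly below 0 dB.

## Phantoms and metrics

The **point phantom** places unit scatterers at 2.5, 3.0, 3.5, 4.0 and
4.5 mm on the image axis.  Per target, an axial-maximum lateral
projection over the target depth +/- 0.15 mm (spanning the round-trip
pulse plus margin) yields -6 dB and -35 dB full widths (linearly
interpolated, reported in micrometres) and the side-lobe level range
over strips 0.3-0.4 mm from the peak on both sides.

The **cyst phantom** embeds a 1 mm anechoic disc at 3.5 mm in a
uniform random scatterer field (lateral span of the image, axial
2-5 mm) with standard-normal amplitudes.  The density default is
4000/mm^2: the background envelope SNR (mean/sd of the linear envelope,
after dividing out the smoothed depth-gain profile so the focal gain
variation does not masquerade as speckle variance) then reaches the
Rayleigh value `sqrt(pi/(4-pi)) = 1.91`, the operational definition of
fully developed speckle.  At 1000/mm^2 the measured SNR is only about
1.68.  The SNR estimator itself was validated on an ideal correlated
Rayleigh field (it reads 1.94 +/- 0.03 there).

CNR follows the standard definition
`|S_o - S_i| / sqrt(sigma_i^2 + sigma_o^2)` on log-compressed
("brightness") pixels, with `sigma^2` the ROI variances; a zero
denominator returns `Inf` as a documented sentinel.  The ROI geometry —
unstated in most reports — is: inside, a concentric disc of 0.35 mm
radius (70 % of the cyst radius); outside, two 0.7 mm squares at the
cyst depth, offset +/- 1.2 mm laterally.

## Experiment drivers and problem sizes

`run_ipr_report()` evaluates the five methods spectrally (instant).
`run_point_experiment()` simulates the five-point phantom once and
reuses the same RF for every method, as the minimum-selection pipeline
prescribes (about a minute).  `run_cyst_experiment()` runs a seeded
ensemble (default 10 realizations) of the cyst study; at the default
density each realization simulates roughly 58,000 scatterers and takes
on the order of 1.5 minutes, so the full ensemble is a
15-to-20-minute computation.  All drivers are deterministic given their
seeds.

## Design choices that were genuinely open

* **Chebyshev construction** — exact equiripple synthesis over the
  aliased degree-N variant (above).
* **Projection statistic** — axial *maximum*, not mean: it preserves
  side-lobe peaks, which the side-lobe ROI ranges are meant to capture.
* **Window-to-subaperture mapping at edges** — re-synthesis at the
  reduced length, not cropping.
* **Transmit apodization** — uniform always; the window under test
  applies on receive only.
* **Normalization scope** — whole-image (by the global maximum), not
  per scanline; the comparator then needs no tie-breaking since equal
  values yield the same minimum.
* **Clipping** at the display floor rather than flooring to missing
  values, for parity with 60 dB display figures.
* **Numerical details** — pad factor 64; linear interpolation for all
  level crossings (the minimal assumption at that resolution); the
  Chebyshev polynomial evaluated piecewise (cos/acos inside [-1, 1],
  cosh/acosh outside) to avoid complex intermediates; the
  numerically-zero imaginary residue (< 1e-10) of the inverse DFT
  discarded.

## Limitations

Two published behaviours of this method family are *not* reproduced by
a two-dimensional broadband point-source model, and users should not
expect them from this package:

1. **Cyst CNR ordering across windows.**  In our simulations the cyst
   interior brightness is dominated by background scatterers at lateral
   offsets beyond the pulse-coherence radius `T c z / D` (about 0.6 mm
   here), where channel contributions no longer overlap in time and the
   fill level is set by incoherent energy, nearly independent of the
   receive window (the Chebyshev window's interior is in fact about
   1 dB *brighter*, exactly its noise-bandwidth penalty; the dual/tri
   minima are about 2.5 dB darker by picking minima over decorrelated
   fields).  Consequently measured CNR differences between methods are
   small and do not follow the large window-ordered spreads reported in
   narrowband or display-processed studies.  Diagnostics in our
   development showed the ordering emerges only when the element
   ring-down is stretched to an unrealistic quasi-CW regime.  The
   absolute rectangular-window CNR (about 2.3-2.6) is in the expected
   range.
2. **Exact micrometre beam widths.**  Without the authors' exact
   transducer impulse response, element geometry and sampling, widths
   match at the several-percent, not sub-micrometre, level.

Within scope, the spectral layer (window synthesis, combination,
width/side-lobe measurement) is exact to numerical precision and
cross-checked against independent brute-force oracles, and the
point-target layer reproduces the published widths and side-lobe
suppression of the dual/tri combinations.
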