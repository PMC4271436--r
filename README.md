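# multiapod

Non-linear multi-apodization beamforming for high-frequency (40 MHz)
linear-array B-mode ultrasound, in R.

High side-lobe levels fill in anechoic structures and depress the
contrast-to-noise ratio (CNR) of B-mode images.  Linear apodization
lowers side lobes but widens the main lobe, costing lateral
resolution.  The *minimum-selection* dual-/tri-apodization scheme
sidesteps the trade-off: the same received RF data are beamformed with
several windows — rectangular, Dolph-Chebyshev(α), Kaiser(α_K) — each
envelope image is normalized by its own maximum, and the output keeps
the pointwise minimum

    I(x, z) = min_k  E_k(x, z) / max E_k ,

so the combination inherits the rectangular window's narrow main lobe
(−6 dB width 1.21 bins at N = 32) *and* the tapered windows' low
side-lobe floor (−50 dB for the α = 2.5 Chebyshev design, whose side
lobes sit at exactly −20·α dB).

The package implements the full evaluation chain:

* **Windows** — closed-form synthesis (`make_rectangular()`,
  `make_dolph_chebyshev()`, `make_kaiser()`, with a series-evaluated
  `bessel_i0()`), padded-DFT spectra (`impulse_response()`), and
  measurements (`mainlobe_width()`, `highest_sidelobe()`,
  `harmonic_sidelobe_level()`).
* **Combiner** — `combine_spectra_min()` and `combine_images_min()`.
* **Simulator** — a point-source RF channel-data model of a 128-element,
  40 μm-pitch, 40 MHz array with a 32-element walking subaperture,
  2-cycle excitation, band-limited elements and a 3.5 mm transmit focus
  (`array_config()`, `simulate_rf()`), plus point and anechoic-cyst
  phantom generators.
* **Beamformer** — delay-and-sum with dynamic receive focusing
  (`das_beamform()`), envelope detection, self-normalization, log
  compression.
* **Metrics** — lateral beam projections, main-lobe widths in μm,
  side-lobe ROI levels, cyst CNR (`cnr()`) and speckle SNR.
* **Experiments** — `run_ipr_report()`, `run_point_experiment()`,
  `run_cyst_experiment()`, and a thin CLI at `inst/cli/multiapod.R`.

## Worked example

```r
library(multiapod)
run_ipr_report()
#>            method width_6db_bins highest_sidelobe_db harmonic_floor_db
#> 1     rectangular       1.205209           -13.23482         -22.70508
#> 2 dolph_chebyshev       1.894734           -50.00000         -50.00001
#> 3          kaiser       1.449131           -21.59383         -31.13283
#> 4            dual       1.205209           -13.46072         -50.00001
#> 5             tri       1.205209           -19.29159         -50.00001
```

Reading the table: the Dolph-Chebyshev window buys its −50 dB
equiripple floor with a 57 % wider main lobe; the dual combination
keeps the rectangular 1.21-bin main lobe while its far ("harmonic")
side-lobe floor drops to the Chebyshev −50 dB; adding the Kaiser member
(tri) also pulls the *first* side lobe down from −13.5 to −19.3 dB.

The imaging counterpart (a few minutes of computation):

```r
pe <- run_point_experiment()
subset(pe$report, target == 3)   # the focal (3.5 mm) target
#>    target depth_mm          method width_6db_um width_35db_um sidelobe_min_db sidelobe_max_db
#>         3      3.5     rectangular        92.68         412.1           -47.6           -40.9
#>         3      3.5 dolph_chebyshev       113.51         370.3           -67.3           -55.3
#>         3      3.5          kaiser       102.16         256.5           -56.6           -47.7
#>         3      3.5            dual        93.22         370.3           -67.3           -55.4
#>         3      3.5             tri        93.22         250.2           -69.0           -55.7
```

The dual/tri images keep the rectangular window's ~93 μm lateral
resolution while their side-lobe ROI levels (0.3–0.4 mm off the peak)
drop by roughly 15 dB.  `run_cyst_experiment()` runs the seeded
anechoic-cyst ensemble and reports per-method CNR and the background
speckle SNR (≈ 1.91, the fully developed Rayleigh value, at the default
scatterer density); see the methods vignette
(`vignettes/multiapod-methods.Rmd`) for what the cyst study can and
cannot show with a 2-D broadband simulator.

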