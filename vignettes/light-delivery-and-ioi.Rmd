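---
title: "Modeling side-firing fiber light delivery and intrinsic-imaging activation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling side-firing fiber light delivery and intrinsic-imaging activation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sidefire` models an optogenetic stimulation experiment in which a
side-firing optical fiber — a fiber whose mirror-coated 45° bevel
redirects the beam perpendicular to its axis — is implanted in deep brain
tissue (the mouse LGN in the motivating experiment) and rotated or
translated to illuminate different sub-volumes of ChR2-expressing
neurons. The package has two halves:

1. a voxel Monte-Carlo photon-transport engine that predicts the fluence
   distribution around the fiber tip, from which the activated tissue
   volume and the overlap between fiber poses are computed, and
2. a synthetic intrinsic-optical-imaging (IOI) trial generator plus the
   activation-map analysis used on the cortical readout: trial averaging,
   pre-stimulus normalization, Gaussian smoothing, pixelwise t-maps,
   activated-area and peak-amplitude quantification, and
   intensity-response fits.

# Photon transport model

## Transport scheme

Photons are launched with weight 1 from a disc source and traced with the
standard hop-drop-spin scheme in a homogeneous medium described by an
absorption coefficient $\mu_a$, scattering coefficient $\mu_s$,
Henyey-Greenstein anisotropy $g$ and refractive index $n$:

* **hop** — step lengths are drawn from the exponential free-path
  distribution, $s = -\ln u / \mu_t$ with $\mu_t = \mu_a + \mu_s$;
* **drop** — at each interaction the photon deposits
  $w\,\mu_a/\mu_t$ of its weight into the enclosing voxel (absorption
  weighting, which is unbiased and lower-variance than terminating
  photons on absorption events);
* **spin** — the polar scattering angle is drawn from the
  Henyey-Greenstein inverse CDF
  $\cos\theta = \frac{1}{2g}\left[1 + g^2 - \left(\frac{1-g^2}{1-g+2gu}\right)^2\right]$
  (isotropic, $2u-1$, for $g = 0$), the azimuth uniformly.

Photons below a weight of $10^{-4}$ enter Russian roulette (survival
probability 0.1, survivors multiplied by 10), keeping the estimator
unbiased while bounding the work per photon. Photons that leave the grid
are tallied as escaped; the tissue boundary is far from the fiber tip at
these intensities, so no internal reflection is modeled. Every photon's
ledger (deposited + escaped + roulette loss − roulette gain = launched)
is checked to $10^{-9}$ at run time, and the test suite verifies the
kernel against the Beer-Lambert law ($\mu_s = 0$), the diffusion
approximation
$\Phi(r) = e^{-\mu_{\mathrm{eff}} r}/(4\pi D r)$ at five transport mean
free paths from an isotropic source, and the first moment of the
Henyey-Greenstein sampler.

The per-voxel fluence estimator is the absorbed energy divided by
$\mu_a \times$ voxel volume $\times$ photon count. This estimator cannot
handle $\mu_a = 0$, which `run_mc()` rejects (use a tiny positive
$\mu_a$ if a conservative medium is needed).

Random numbers come from a xoshiro256** generator seeded explicitly per
run, so every simulation is bitwise reproducible from its `(config,
seed)` pair independently of R's RNG state; sweep drivers derive one
independent seed per fiber pose from the base seed.

## Source model

The fiber emits from a flat disc of the core diameter (0.2 mm default)
into a cone. The divergence half-angle inside tissue is
$\arcsin(\mathrm{NA}/n)$ — numerical aperture is conserved across the
fiber-tissue interface — about 15.7° for NA 0.37 in tissue of $n = 1.37$.
Within the cone the angular density is uniform in solid angle (a top-hat
far field, the usual approximation for a highly multimode fiber).

In side-firing mode the disc normal is perpendicular to the fiber axis,
selected by the rotation angle $\varphi$, and the disc is centered one
core radius off the axis (`surface_offset`), on the side surface where
the mirrored bevel emits. This offset matters: it is what makes a
rotation of the fiber *translate* the illuminated blob. With the disc
centered on the axis, rotating the fiber about that same axis moves the
nearby fluence field very little in a strongly scattering medium and
pose-overlap estimates roughly triple. An axial (flat-cleaved) emission
mode is also provided.

The absolute registration of $\varphi$ to anatomy varies between
implantations; $\varphi = 0$ maps to the lateral (+x) direction projected
off the insertion axis, which is itself tilted 57° from vertical in the
x-z plane by default (an oblique insertion toward the LGN in a
right-handed stereotaxic frame: x lateral, y anterior, z dorsal).

## Tissue optics and the scattering-coefficient convention

`brain_optics_473()` encodes the adopted tissue model at 473 nm:
$\mu_a = 0.48\ \mathrm{mm^{-1}}$, $g = 0.9$, $n = 1.37$, and a
scattering value of $4.37\ \mathrm{mm^{-1}}$ interpreted as the
*reduced* coefficient $\mu_s' = \mu_s(1-g)$, i.e.
$\mu_s = 43.7\ \mathrm{mm^{-1}}$. The interpretation of a quoted
scattering number is the one genuinely open choice in this model, and we
adopt the reduced reading for two reasons. Physically, brain tissue at
blue wavelengths has $\mu_s' \approx 1\!-\!5\ \mathrm{mm^{-1}}$
(transport mean free path of a fraction of a millimetre); reading
$4.37\ \mathrm{mm^{-1}}$ as an *unreduced* $\mu_s$ with $g = 0.9$ would
give $\mu_s' = 0.44\ \mathrm{mm^{-1}}$ and a transport mean free path
over 2 mm — implausibly transparent tissue. Empirically, only the
reduced reading reproduces both the published activated-volume
titration and the pose-overlap fractions that the acceptance tests
target. Both readings remain available
(`optical_properties(reduced =)`), so the alternative convention is one
flag away.

## Fluence normalization

Simulated maps are stored with *the intensity value at the source
normalized to one*: the map is divided by its maximum, which sits at the
source exit. Physical fluence is then `values * source_intensity`, with
`source_intensity` the measured light intensity at the fiber tip in
mW/mm². This matches how such simulations are used experimentally: the
map is unit-normalized and scaled by the tip intensity measured with a
power meter.

Note that the fluence at an embedded source exceeds the bare exit
intensity $I_0 = P/(\pi r^2)$, because scattered light returns through
the exit plane: the conversion factor (about 1.37 under the default
optics) is recorded as `source_fluence_per_exit`, and
`threshold_volume(..., normalization = "exit")` switches to the
exit-intensity convention if wanted.

## Activation volumes and overlap

A voxel is "activated" when its fluence exceeds the ChR2 half-maximum
firing threshold, 0.5 mW/mm² by default (0.49 mW/mm² is an equally
common convention and is accepted via the `threshold` argument). No
connected-component filtering is applied: the criterion is pure fluence.
Volume is the voxel count times the voxel volume; the simulation grid
defaults to a 2 mm cube of 10 µm voxels centered on the tip, which
resolves the 0.2 mm source, keeps discretization error well below
Monte-Carlo noise for the smallest volumes of interest
(≈ 0.005 mm³ ≈ 5000 voxels), and leaves ≥ 0.5 mm of margin around every
above-threshold voxel at the intensities studied.

"Percent overlap" between two activated voxel sets is ambiguous, so
`overlap_fraction()` reports three conventions: intersection over the
mean single volume (default — for two poses related by a rotation, whose
volumes are congruent, this coincides with intersection over the
smaller), Jaccard (intersection over union, related to the mean
convention by $j = m/(2-m)$), and intersection over the minimum. Sweep
drivers report all three.

# Synthetic intrinsic-imaging data

The generator emulates the acquisition protocol of the motivating
experiment: 20 s trials of 80 frames at 4 Hz, 8 pre-stimulus frames
(2 s), a 250 ms optogenetic stimulus starting at frame 9, and 20
stimulus plus 20 blank trials in randomized order. The ground truth is a
spatially Gaussian reflectance *decrease* (the deoxyhemoglobin-dominated
IOI response under ~630 nm light) with peak fractional amplitude of
order −2×10⁻⁴ (−0.02%), modulated in time by a gamma-variate kernel
$k(t) = (t/t_p)^{\alpha} e^{\alpha(1 - t/t_p)}$ normalized to 1 at the
peak time $t_p$ (2.5 s default) with the shape $\alpha$ solved
numerically from the requested FWHM (3 s default) — a smooth, causal,
unimodal hemodynamic response that returns toward baseline within the
~18 s post-stimulus window. Noise is i.i.d. multiplicative Gaussian per
pixel and frame.

What the generator deliberately does *not* contain: vascular structure
and pulsation, photon shot noise, slow drifts, motion, camera
nonlinearity, or hemoglobin spectroscopy. Passing recovery tests on this
synthetic data therefore demonstrates that the analysis pipeline is
correctly implemented and statistically calibrated for
independent-noise data — not that it is robust to structured in-vivo
artifacts.

The default field is 128 × 128 pixels at 0.01 mm/pixel. The pixel scale
makes areas come out in cortex-like units; the field is sized to contain
the default activation focus while keeping a full 40-trial set in a few
hundred MB of memory (a V1-scale 300 × 300 field is one protocol
argument away).

The half-maximum footprint of the truth has the closed form
$A_{1/2} = 2\pi \ln 2\, \sigma_s^2$ pixels for spatial SD $\sigma_s$,
which recovery tests use as ground truth.

# Activation-map analysis

`average_and_normalize()` averages the trials of one condition frame by
frame and divides each pixel's time course by its own pre-stimulus mean
(enforced to 1 within $10^{-12}$). `spatial_filter()` applies an
isotropic Gaussian (σ = 4 px default, truncated at 4σ with renormalized
boundary weights so constant frames are exact fixed points).
`t_map()` then runs, per pixel, a two-sided Welch t-test comparing the
pre-stimulus frames against a response window, and thresholds
$p < \alpha$ into the significant mask whose pixel count gives the
activated area.

Choices worth stating explicitly, since the underlying experimental
description leaves them open:

* **Response window.** The stimulus occupies a single frame at 4 Hz, so
  "stimulation period" cannot mean one frame if a t-test is to have
  within-window variance. The default window is the 16 frames after
  onset (0–4 s), covering the hemodynamic peak; it is configurable.
* **Filter-then-test order.** Smoothing is applied to the frames of the
  averaged, normalized stack *before* the t-test (this is the order in
  which smoothing affects the statistics); σ = 0 recovers the unfiltered
  test.
* **Test family.** Welch (unequal variance) rather than pooled, two
  sided; the samples are the frames of the trial-averaged stack. No
  multiple-testing correction by default, matching per-pixel $p<0.05$ /
  $p<0.01$ mapping practice; `correct = "BH"` enables
  Benjamini-Hochberg.
* **Blank trials** are analyzed identically as a null control but are
  not subtracted from stimulus trials.

With unfiltered null data the pipeline is calibrated: the
significant-pixel fraction at $\alpha$ matches $\alpha$ (the Welch test
at 8-vs-16 frames has empirical size ≈ 0.050). Smoothing correlates
neighboring pixels, so calibration tests run at σ = 0.

For *recovery* of the activation footprint the package measures the
half-maximum area of the response-amplitude map
(`response_footprint()`), not of the significance mask: a significance
footprint grows without bound as SNR increases and is the wrong estimand
for a fixed spatial truth. Footprint measurements use light smoothing
(σ = 2 px in the tests) — enough to suppress pixel noise in the peak
estimate, while inflating a σ_s = 12 px footprint by under 3%
(convolution maps $\sigma_s^2 \to \sigma_s^2 + \sigma_f^2$); the
pipeline's σ = 4 px default would already cost 11%.

`fit_intensity_response()` fits the two standard intensity-response
shapes by ordinary least squares — area vs intensity linearly,
peak amplitude vs intensity logarithmically (the saturating form) — and
reports $R^2$ and the overall F-test p-value via `lm()`.

# Numerical and testing choices

* Volumes and overlaps in the acceptance tests run at the study optics
  on the 10 µm grid with 10⁷ photons for the intensity titration and
  2.5×10⁶ photons per pose for overlap pairs; overlap fractions average
  over ~10⁴ boundary voxels and are stable at that budget (they change
  by well under a percentage point between 10⁶ and 2.5×10⁶ photons).
* Recovery tests run 100 generator seeds at a 64 × 64 field with
  σ_s = 12 px and SNR 5 (SNR defined as peak amplitude over the
  per-frame noise of the 20-trial average).
* The known-$R^2$ fit oracle compares the simulated $R^2$ mean over 200
  seeds against the exact expectation computed by integrating the
  noncentral-F density of the regression F-statistic.
* Degenerate inputs are rejected loudly: zero pre-stimulus means,
  windows under two frames, empty masks in `peak_amplitude()` /
  `overlap_fraction()`, $\mu_a = 0$ in the fluence estimator,
  NA ≥ n in the source builder.

# Known limitations

* Homogeneous tissue only: no atlas segmentation, no wavelength tables,
  no polarization or time-of-flight. The LGN is treated as optically
  uniform and unbounded.
* The fiber shaft is not an obstacle to photons, and the tissue surface
  does not reflect; both are reasonable at ≥ 1 mm depth but wrong near
  the craniotomy.
* The side-firing tip is an ideal disc with a top-hat cone; real beveled
  chrome mirrors have finite reflectance and a structured near field.
* The IOI generator's noise model is white; real intrinsic imaging noise
  is heavily structured by vasculature, so in-vivo performance of the
  pipeline cannot be inferred from these tests.
* Absolute anatomical registration (which $\varphi$ faces the LGN
  center, the cortical pixel scale) is experiment-specific and left as
  free parameters.
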