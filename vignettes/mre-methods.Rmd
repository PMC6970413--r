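---
title: "Shear-wave reconstruction and analysis with mrelastic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shear-wave reconstruction and analysis with mrelastic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrelastic)
```

## The measurement and the model

Magnetic resonance elastography (MRE) drives a mechanical vibration into
tissue and images the resulting shear wave with a motion-sensitizing
gradient (MSG): the tissue displacement at each pixel is encoded into the
phase of the MR signal. Acquiring the same image twice with opposite MSG
polarity and subtracting cancels every static phase contribution while
doubling the motion-encoded phase; sampling several temporal offsets across
one vibration period lets the harmonic displacement at the drive frequency
be extracted by a temporal Fourier transform.

Under local homogeneity, negligible compression-wave contribution and
time-harmonic steady state, the complex displacement field $U$ obeys the
Helmholtz equation

$$\rho\,\omega^2 U + G^*\,\nabla^2 U = 0,$$

so the complex shear modulus is recovered algebraically per pixel:

$$G^* = -\frac{\rho\,\omega^2\,U}{\nabla^2 U},\qquad \omega = 2\pi f .$$

From the ROI-averaged $G^*$ the package reports the four standard scalars:
storage modulus $G' = \mathrm{Re}(G^*)$ (elasticity), loss modulus
$G'' = \mathrm{Im}(G^*)$ (viscosity), magnitude $|G^*|$, and the loss
factor / phase angle $\varphi = \arctan(G''/G')$, a measure of fluidity.

The default acquisition geometry is a 900 Hz drive, eight temporal offsets
per period, a 128 x 128 matrix over a 25 mm field of view and a single
sagittal slice - the regime of high-frequency murine brain MRE. Density is
fixed at 1000 kg/m^3 (soft-tissue convention; elastograms scale linearly in
it).

## Processing chain

`mre_reconstruct()` runs the chain in the order the physics dictates, and
each stage records itself in the field's provenance:

1. **Phase difference** (`phase_difference`): subtract the negative-MSG
   series, rewrap to $(-\pi, \pi]$. Static background phase cancels exactly;
   motion phase doubles.
2. **Unwrapping** (`unwrap_phase`): each temporal frame is unwrapped with
   the unweighted least-squares (DCT/Poisson) method and then snapped back
   onto the $\psi + 2\pi k$ lattice (congruence). For residue-free fields
   the result equals the true phase up to one global multiple of $2\pi$ per
   frame; that constant lands in the DC bin of the next step and is
   discarded, which is why a global offset is harmless. We chose the
   least-squares solver over quality-guided region growing because it is
   fully vectorised, has no data-dependent scan order, and is exact (up to
   the global constant) on every field the simulator produces.
3. **Temporal harmonic** (`temporal_harmonic`): the first DFT coefficient
   over the period, normalised so $A\cos(\omega t + \theta) \mapsto
   A e^{i\theta}$. With the simulator's convention
   $u(x,t)=\mathrm{Re}[A e^{i(\omega t - \kappa s)}]$, a wave travelling
   along unit vector $d$ appears in the extracted complex image as
   $e^{-i\kappa(d\cdot x)}$, i.e. with spatial-frequency support in the
   half-plane $\xi\cdot d < 0$. This sign bookkeeping is what ties the
   directional filter to a physical propagation direction, and it is
   asserted against the simulator in the tests.
4. **Butterworth band-pass** (`butterworth_bandpass`): radial gain
   $H(k) = [1 - (1 + (k/k_{low})^{2n})^{-1}]\,[1 + (k/k_{high})^{2n}]^{-1}$
   with defaults $n = 3$, $k_{low} = 20$, $k_{high} = 2000$ m$^{-1}$. The
   passband brackets the ~520 m$^{-1}$ wavenumber of a 3 kPa medium at
   900 Hz with a decade of margin on both sides; all three values are
   exposed. The filter runs on an even-reflected (doubled) domain so the
   periodic-FFT wrap-around jump of a decaying wave does not ring into the
   image; for a radially symmetric gain this extension is exact for
   travelling waves.
5. **Directional filter** (`directional_filter`): retains the spectral
   half-plane of waves propagating in the chosen direction with a
   raised-cosine transition (default width 100 m$^{-1}$), suppressing
   counter-propagating (reflected) waves. Row 1 is the top of the image;
   `"bottom_to_top"` means decreasing row index. This filter deliberately
   does *not* use the reflected-domain trick: an even extension contains a
   mirrored, counter-propagating copy of the wave, and removing it breaks
   the exact pass-through of travelling waves. On the periodic domain a
   plane wave at a grid frequency passes, or is rejected, exactly.
6. **Helmholtz inversion** (`helmholtz_invert`): 5-point discrete
   Laplacian, pixelwise quotient. Validity masking and the stencil
   correction are described below.

## Numerical choices

**Stencil bias.** The 5-point Laplacian of $e^{iks}$ returns
$-(2 - 2\cos kh)/h^2$ instead of $-k^2$, inflating $G^*$ by
$(kh)^2/(2-2\cos kh)$ - about 3.3% at 10 pixels per wavelength.
`stencil_correction = TRUE` removes this with three fixed-point iterations
using the complex local wavenumber implied by the raw estimate. The default
is off, matching the plain inversion; the homogeneous-phantom tests show
3.1% raw error shrinking below 0.01% with the correction.

**Validity masking.** A pixel enters summaries only if (a) it is not on the
image border, (b) $|\nabla^2 U|$ is at least `mask_threshold` (default 0.1)
times the masked median - this removes wave nodes where the quotient is
0/0 - and (c) $|U|$ is at least `min_amplitude` (default 0.05) times the
in-support maximum. The amplitude floor is standard practice in MRE: at
900 Hz a lossy medium ($G'' \approx 1$ kPa) attenuates with
$e^{-\alpha s}$, $\alpha \approx 500$ m$^{-1}$, so a few millimetres from
the driver the wave falls under the noise floor, and the laplacian-median
rule alone cannot exclude such pixels because noise has a large (not small)
Laplacian. Without the floor, summaries over full-image ROIs are dominated
by noise-quotient pixels whose moduli are biased low.

**ROI summaries.** `summarize_roi()` erodes the ROI by 2 pixels (stencil
edge guard), averages complex $G^*$ over the remaining valid pixels, and
derives all four scalars from that single complex mean, keeping $|G^*|$ and
$\varphi$ mutually consistent. The alternative - averaging per-pixel
magnitudes (`mode = "magnitude"`) - is also implemented. The two modes
behave differently under artifacts: complex averaging lets phase-random
errors cancel, while magnitude averaging accumulates them as a positive
bias. This is why the benefit of the directional filter is assessed under
magnitude averaging (below).

**When the directional filter helps - and when it does not.** In a
homogeneous medium, a superposition of forward and reflected waves shares
one wavenumber, so the Helmholtz quotient is *analytically exact* on the
superposition: with complex-mean summaries, reflections barely corrupt the
result, and the filter has nothing to fix. What reflections do produce is
standing-wave nodes, where the signal vanishes and noise takes over the
quotient; under magnitude-first averaging those pixels bias $|G^*|$, and
removing the reflected component eliminates both the nodes and the
reflected-dominated zone. On a 3000+1000i Pa phantom with a 0.5 reflection
and 0.05 rad phase noise, the filter cuts the magnitude-averaged error by
a factor of ~4. Conversely, for a strongly damped one-sided wave the
filter *costs* accuracy near the driver: a one-sided decaying envelope has
genuine spectral mass in the opposing half-plane (a Lorentzian tail of
width $\alpha$), and removing it perturbs the field; the contamination
decays only geometrically from the driver edge while the signal decays
exponentially. Engage the filter when counter-propagating waves are
expected; leave `direction = NULL` for reflection-free fields.

## The synthetic generator

`simulate_wave_series()` inverts the reconstruction's forward model: plane
waves $u(x,t) = \mathrm{Re}[A e^{i(\omega t - \kappa s)}]$ with
$\kappa = \omega\sqrt{\rho/G^*}$ (principal branch, so lossy media
attenuate along propagation), an optional counter-propagating reflection,
MSG encoding with opposite sign in the two series (default gain 2 rad per
unit displacement, so the ~4 rad phase-difference amplitude exercises
wrapping; the inversion is invariant to this scale), a static low-order
polynomial background phase common to both polarities, wrapping to
$(-\pi,\pi]$ and Gaussian phase noise. Simulations whose wavelength falls
under 4 pixels in the stiffest region are rejected as aliased. All
randomness flows from the seed.

`simulate_two_region_phantom()` builds a piecewise-constant modulus map
split at a column junction, mimicking the anterior (cerebrum) / posterior
(cerebellum) division of a sagittal slice. Waves are computed per pixel
from the local modulus with the default source at the bottom edge, so each
column stays homogeneous along the propagation path; displacement/stress
continuity is *not* enforced across the interface, which is why recovery
tests exclude a 3-pixel band at the junction.

What the generator does **not** emulate: geometric spreading and mode
conversion, compression waves, spatially varying coil sensitivity, RARE
readout artifacts, motion, or anatomically realistic boundaries. Passing
recovery tests therefore demonstrates correctness of the processing chain
on fields that satisfy its model assumptions, not performance on in vivo
data.

`simulate_t1_series()` produces variable-TR saturation-recovery stacks
($S = S_0(1 - e^{-TR/T1})$, exact when noise-free), and
`simulate_cohort()` produces per-animal tables in which the whole-brain
magnitude modulus falls linearly with the clinical disability score
(default slope -300 Pa per score unit, noise 150 Pa, baseline 3.5 kPa),
the posterior region is softer and more strongly affected than the
anterior - the regional vulnerability seen in relapsing-remitting
neuroinflammation models - a fibronectin fold-change column rises as the
posterior modulus falls, and contrast-uptake metrics (delta-T1, SI%) are
drawn independently of score.

## T1 mapping

`fit_t1_map()` fits the 2-parameter saturation-recovery model per voxel by
Levenberg-Marquardt least squares, initialised from the longest-TR signal
and the log-linearised shortest-TR point; voxels failing convergence or
leaving (1, 10000) ms are flagged. A deliberate design point: with the
printed 7-TR array and Gaussian noise at SNR 50, the Cramer-Rao bound
already puts the median |T1 error| at 3.1-3.8% for T1 in 800-2500 ms - no
estimator does much better - and the tests assert efficiency relative to
that bound rather than an absolute error. The model is fit on magnitude
signal without Rician correction (the intended regime is high SNR), and
slice means in `delta_t1()` are unweighted, with
`SI% = (post - pre)/pre * 100` computed across-slice exactly as printed in
the protocols it mirrors.

## Statistics

`spearman_test()` uses midranks and, for $n \le 9$, an exact two-sided
permutation p-value obtained by enumerating all $n!$ permutations (valid
under ties, where classical null tables are not); larger samples use the
t-approximation. `pearson_test()` delegates to `stats::cor.test`.
`ddct_fold_change()` implements the Livak $2^{-\Delta\Delta C_T}$
convention with arithmetic-mean centring of control $\Delta C_T$.
`correlation_report()` runs declared variable pairs over a cohort table,
with the symptomatic-only filter defined as score > 0. Raw p-values are
reported without multiplicity correction by default (a Benjamini-Hochberg
column is available behind `adjust = TRUE`).

## Problem sizes and limitations

The test-suite and acceptance computations use the full 128 x 128 protocol
geometry for wave simulations (single reconstructions run in well under a
second), 200 voxels per T1 value for the noisy recovery grids, 100 draws
for the small-sample permutation checks and 500 replicate cohorts for the
direction-of-effect Monte Carlo.

Known limitations: 2D inversion only (no curl decomposition, no
multifrequency rheometry); the two-region phantom's interface is
discontinuous by construction; the directional filter distorts strongly
damped fields near the driver as discussed; no registration between pre-
and post-contrast T1 series (assumed aligned); and the simulator's
plane-wave fields are a favourable case for phase unwrapping compared to
in vivo data.
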