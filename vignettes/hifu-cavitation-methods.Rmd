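---
title: "Methods: focused-ultrasound fields, cavitation regions and model-stone damage analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: focused-ultrasound fields, cavitation regions and model-stone damage analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lithocav)
```

`lithocav` implements the computational chain used in laboratory-scale
studies of high-intensity focused ultrasound (HIFU) lithotripsy: it
predicts the linear acoustic field of a bowl transducer, simulates its
scattering by a model kidney stone, extracts the supra-threshold
pressure regions where cavitation clouds nucleate, converts them into
spherical-cap surface-damage coefficients, and provides the shadowgraph
image analytics (minimum intensity projection, bubble census, cloud
tracking, surface intensity profiles) that connect those predictions to
high-speed imaging. This vignette documents the models, the numerical
choices, and what the synthetic-data tests do and do not demonstrate.

## The acoustic source model

The source is a single-element concave spherical-cap (bowl) transducer
described by its carrier frequency (250 kHz in the reference
configuration), geometric focus $f$ (the radius of curvature, 67 mm),
aperture radius $a$, and a uniform normal surface velocity $u_0$. The
axial coordinate has its origin at the centre of the bowl rim plane and
increases along the beam; the curvature centre then sits at
$z = \sqrt{f^2 - a^2}$.

Two complementary evaluations of the same linear monochromatic model
are provided:

* `oneil_axial()` — the closed-form on-axis solution for a focused bowl
  with uniform normal velocity,
  $|p(z)| = 2\rho c u_0\, |\sin(k(R_e - z')/2)| / |1 - z'/f|$ with $z'$
  the distance from the apex and $R_e$ the rim-to-point distance. The
  removable singularity at the curvature centre is eliminated
  analytically via $R_e - z' = 2h(f - z')/(R_e + z')$ ($h$ the bowl
  depth), which yields the finite focal limit $\rho c u_0 k h$ without
  numerical cancellation.
* `rayleigh_field()` — the off-axis Rayleigh surface integral
  $p = \tfrac{i\rho c k u_0}{2\pi}\int_S e^{-(\alpha + ik)R}/R\,
  \mathrm{d}S$ over the cap, using Gauss–Legendre quadrature along the
  cap polar angle (64 nodes per wavelength of cap arc by default) and
  uniform azimuthal sampling (spectrally accurate for the periodic
  integrand; 256 samples by default). The on-axis column agrees with
  the closed form to about $10^{-5}$ relative, far inside the 1%
  contract, and an independently coded midpoint-rule oracle confirms
  the closed form in the test suite.

Attenuation follows the power law $\alpha_0 f^y$ (dB/(MHz)$^y$/cm, the
convention of water/tissue attenuation tables) evaluated at the carrier
and applied as a single-frequency exponential decay — per ray inside the
Rayleigh integral, over the apex distance in the closed form. At
250 kHz in water this is a $10^{-4}$-level correction; the distinction
between the two path conventions is far below the quadrature tolerance.

### Focal geometry and normalization

`physical_focus()` locates the acoustic focus $\gamma_f$ as the argmax
of the axial amplitude with three-point quadratic interpolation. The
textbook closed-form estimate $\beta[1 + 2\beta^2/(1+2\beta)]^{-1}$
with $\beta = f\lambda/a$ is exposed as `focal_shift_estimate()` but is
advisory only: taken literally it is dimensionally inconsistent, and
the computed argmax is authoritative (the physical focus is *defined*
as the pressure maximum).

`focal_geometry_fit()` measures the focal ellipsoid on pressure
amplitude (not intensity): the lateral full width at half maximum
$\ell_1$ in the plane $z = \gamma_f$ and the axial FWHM $\ell_2$ along
the axis, with half-maximum crossings located by linear interpolation.
The dimensionless fit coefficients are
$\alpha_k = \ell_k / (\lambda\,(f/2a)^k)$. For the reference
configuration the aperture radius is not independently specified; the
package default $a = 32$ mm gives an
F-number of about 1.05, typical of bowls of this focal length, and
yields $\alpha_1 = 1.261$ and $\alpha_2 = 7.90$ on the default grid —
within a few percent of the reference values 1.26 and 8.24. Because
$\alpha_2$ scales with the assumed aperture through $(f/2a)^2$, a ±10%
agreement band is the appropriate reading of those constants. The fit
is performed on the Rayleigh-integral field; whether the original
constants were fitted on an equivalent analytic field or a discrete
simulation is unknown, which is a second reason not to over-interpret
agreement beyond a few percent.

`normalize_field()` applies the dimensionless change of variables
$z^* = z/\gamma_f$, $r^* = r/\ell_1$, $p^* = p/\max p$, and flags the
result so that accidental double normalization is rejected.

## Time-domain scattering by a model stone

`simulate_linear_field()` integrates the first-order linear acoustics
equations (pressure–velocity form) on a staggered grid in axisymmetric
cylindrical coordinates. Design choices:

* **Spatial differences are 4th-order** staggered stencils
  ($9/8, -1/24$). At the default 8 points per wavelength a 2nd-order
  scheme has ~2.5% phase-velocity error, which visibly distorts the
  focal interference structure; the 4th-order stencils bring the
  homogeneous-medium axial profile within 5% of the closed form over
  the focal lobe without refining the grid. Across the symmetry axis,
  ghost cells use the even symmetry of $p$ and of $r u_r$.
* **Absorption** is applied as a per-cell damping factor
  $\exp(-2 c \alpha\, \mathrm{d}t)$ with $\alpha$ the power-law
  coefficient evaluated at the carrier — exact for monochromatic drive,
  which is the only regime the solver is used in. A 1-D plane-wave run
  reproduces the prescribed decay to 0.3%.
* **The stone** enters as an impedance jump: density and sound-speed
  maps multiplied inside the stone mask. The reference stone is often
  summarized by a single factor of 6.5 applied to both density and
  sound speed, which taken literally would give an impedance ratio of
  42; the physically meaningful quantity is the impedance ratio of 6.5
  computed from gypsum-phantom properties, so the package splits it
  as a sound-speed ratio of 2.77
  (plaster/water) times a density ratio of 2.346, both configurable.
  The hemisphere is oriented with its spherical face toward the source.
* **Boundaries** are absorbing sponge layers (cubic taper, 16 cells) in
  place of tank walls; the analyses concern the focal region, not
  reverberation. A `walls` flag restores rigid walls. Plane-source runs
  damp only the axial edges so the duct mode stays planar.
* **Steady state**: the drive ramps over 3 cycles and runs 40 cycles by
  default; the per-pixel amplitude is the half peak-to-peak over the
  last two cycles, and the run errors out unless the relative L2 change
  between the last two per-cycle amplitude maps is below 2%.
* The source is a sinusoidal pressure term painted on the bowl arc with
  sub-cell hat weights (reducing staircase artifacts). Absolute source
  calibration is not attempted: every validation and downstream use is
  on normalized fields, and the solver is verified to be linear in the
  source amplitude to 0.1%.

Default grid: 8 points per wavelength (0.75 mm at 250 kHz), domain
80 mm (r) × 120 mm (z), CFL 0.3 — a desk-scale run of a few seconds.

## Cavitation regions and damage coefficients

A cavitation threshold $p_c^*$ — the fraction of the peak dimensionless
pressure above which clouds nucleate — is an experiment-specific,
required input; 0.46 is the value inferred at 250 kHz from stone-free
cloud-trajectory envelopes and is the package default, applied as a
strict inequality $p^* > p_c^*$.

`label_regions()` labels the supra-threshold mask by orthogonal
connectivity: the component touching the stone within one cell is
$\Pi_1$ (the full attached component, not only its surface lobe),
detached components on the source side are $\Pi_2, \Pi_{2,2}, \dots$
ordered by distance. With the hemisphere at the focus, the standing
wave formed by the reflected beam produces the expected layered
structure: several detached antinodal lobes below one attached region.

`cap_angle_of_region()` projects each $\Pi_1$ pixel along the local
surface normal — for a sphere, centrally toward the centre — and takes
the largest polar angle $\theta_p$ (measured from the source-facing
pole). The damage coefficient is the cap area normalized by the exposed
proximal area: $A^* = A/A_0 = 4(1 - \cos\theta)$, identical in form for
the numerically predicted cap ($\theta_p$), the bubble-layer cap
($\theta_b$) and the fragment cap ($\theta_d$).

`optimal_distance()` scans proximal-surface positions
$z \in [\gamma_f, \gamma_f + \ell_2/2]$, evaluating the reflected
surface pressure $p_r(z) = 2 p_i(z) I_2/(I_1+I_2)$, and returns the
largest $z$ with $p_r \ge p_c$. The reference closed form states its
two cases on the incident pressure ($z^+ = \gamma_f$ if
$p_i(\gamma_f) = p_c$; $z^+ = \gamma_f + \ell_2/2$ if
$p_i(\gamma_f + \ell_2/2) \ge p_c$) while the accompanying discussion
conditions the optimum on $p_r$. These are not mutually consistent when
$I_2 > I_1$: if $p_i(\gamma_f)$ only just reaches $p_c$, the reflected
pressure still exceeds $p_c$ beyond the focus. The package resolves
this by letting the closed-form cases take precedence for the returned
$z^+$ (equality tested at 1% relative tolerance, since exact equality
is measure-zero) and using the $p_r$ scan for the intermediate regime;
the bound $\gamma_f \le z^+ \le \gamma_f + \ell_2/2$ holds in all
regimes.

## Shadowgraph analytics

Frames follow the camera convention (row 1 = top); the beam travels
upward, so physical $z$ increases with decreasing row index — stated
here because it is the classic source of sign errors in rise speeds.

* `minip()` — minimum intensity projection,
  $I_r(i,j) = \min_f I(i,j)$: compiles dark transients (bubbles,
  falling fragments) from a sequence into one image.
* `detect_bubbles()` — Otsu threshold (shadowgraphy reports rarely state
  a segmentation criterion; inter-class variance
  maximization is the standard neutral choice), hole filling, and
  watershed splitting on the distance map to separate touching bubbles.
  A guard rejects frames whose Otsu split lies inside the background
  mode (median-to-threshold contrast < 0.1), which otherwise segments
  pure noise. Blobs with circularity $4\pi A/P^2 \ge 0.85$ are flagged
  *individual*; reported individual fractions (75%/60% early/late) come
  with no stated criterion, so this cut is a documented default, not a
  reconstruction. Equivalent-circle diameters come from blob areas.
* `number_density()` — individual count per interrogation volume
  (field-of-view area × depth of field). The depth of field is a
  required input and never defaulted: the interrogation volume behind
  the reference density $n \approx 33\ \mathrm{mm^{-3}}$ is not
  specified.
* `track_clouds()` — coarse threshold + disc dilation fuses each
  cloud's bubbles into one blob; linking is by mask overlap with the
  previous frame (robust through merges), falling back to
  nearest-neighbour linking gated at 3× the median per-frame
  displacement. When two tracks land on one component, the parents
  terminate and a child records the lineage. `rise_speed()` is the
  least-squares slope of $z(t)$ (the rise is constant-speed), and
  `dimensionless_speed()` divides by the mean stone-free rise speed,
  rounded to 2 decimals to match the presentation convention of cloud
  velocity tables.
* `surface_intensity_profile()` samples the image by bilinear
  interpolation along an arc offset from the stone silhouette,
  averages the two azimuthal sides, and normalizes to [0, 1] by the
  arc min/max; `cap_angle_from_profile()` reads the cap edge as the
  largest angle with $I^*$ below a dip threshold (default 0.5).

## The synthetic scene generator

`scene_spec()` fixes the study conditions the generators emulate:

* bubble sizes from a lognormal mixture with medians 150 µm and 50 µm
  ($\sigma_{\log} = 0.25$) — the reference distributions give only peak
  locations and skew direction, so a lognormal mixture is the standard
  minimal choice with those features; weights (1, 0) reproduce the
  early unimodal law, mixed weights the later bimodal one;
* a target number density of 33 mm⁻³ (Poisson-drawn counts over the
  interrogation volume), pixel scale 8 µm, depth of field 0.1 mm;
* cloud rise speeds of 1–1.5 m/s at frame rates of 30–100 kHz, with
  rigid bubble-cluster clouds and a declarative merge schedule;
* a stone silhouette with a bubble layer over the polar cap
  $[0, \theta_b]$ and fragment plumes seeded evenly over
  $[-\theta_d, \theta_d]$, ejected along the local surface normal with
  a weak, growing downward drift.

The optics model is deliberately simple: opaque discs with a ~1-pixel
logistic edge, a mild vertical background gradient and additive
Gaussian noise — adequate for segmentation and tracking tests, *not* a
physical shadowgraph model (no diffraction rings, no defocus blur, no
bubble oscillation). Consequently the recovery tests demonstrate that
the analysis chain is unbiased on data with the stated statistical
structure; they do not certify performance on real images, whose
failure modes (motion blur, non-uniform illumination, out-of-focus
bubbles) are outside the emulation.

All generators are bit-reproducible from (spec, seed).

## Problem sizes and test design

The default analysis sizes are chosen to resolve the physics while
keeping any run desk-scale: the focal-geometry field uses a
61 × 127-point (r, z) grid (about 7 × 10³ Rayleigh evaluations, ~80 s);
solver runs use the 8-points-per-wavelength grid above (seconds per
run); synthetic recovery suites use 256²–512²-pixel frames. The
density-recovery test runs on a 512² field of view specifically so that
per-frame truth counts (≈17–67 bubbles) keep ±1-bubble Poisson
quantization well below the 20% tolerance being tested; recovery is
always judged against the *realized* (rendered) density, not the target
parameter. Deep 2-D overlaps of projected bubbles are genuinely
unresolvable and cap the census recovery at high crowding — visible as
a ~10% undercount at 40 mm⁻³, inside the stated tolerance.

## Known limitations

* Linear acoustics only; no nonlinear propagation, no elastic (shear)
  waves inside the stone, no acoustic feedback from the bubble field.
* The solver's stone boundary is a staircase impedance jump; reflection
  accuracy is validated to ~10%, not to sub-percent.
* Bubble dynamics (Rayleigh–Plesset, Bjerknes forces, the umbrella
  cloud morphology) are out of scope; cloud kinematics in the
  generator are purely descriptive.
* $A_3^*$-type (tomography) cap angles are accepted as user-supplied
  values; no tomographic reconstruction is provided.
* The closed-form focal-shift estimate is advisory; all quantitative
  statements use computed fields.
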