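---
title: "How onlenspower models on-eye power change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How onlenspower models on-eye power change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onlenspower)
```

A soft contact lens does not keep its labelled power on the eye. Under the
tear-film suction and the eyelid pressure it bends onto the cornea, both of
its optical surfaces change curvature, and the delivered power shifts by an
amount — the *effective power change* (EPC) — that depends on the hydrogel's
elastic modulus, the lens power and type, and the lens diameter. This
vignette describes the models behind each stage of the package's pipeline,
the free parameters and their defaults, and the places where a genuine
design choice had to be made.

## 1. Material model

Uniaxial tensile records of rectangular hydrogel strips (time, force $F$,
instantaneous length $L_1$) are reduced with engineering stress and strain,

$$\sigma_t = F / A_0, \qquad \varepsilon = (L_1 - L_0)/L_0,$$

and the elastic modulus is the least-squares gradient of $\sigma_t$ on
$\varepsilon$ (`fit_modulus()`). Hydrogels are close to linear-elastic over
in-vivo load ranges, so the default fit uses every recorded point; a
`strain_window` argument restricts it when a record runs to failure. A
material is characterised by fitting each strip separately and averaging
the per-strip gradients (`average_modulus()`), matching the usual
"mean ± SD over three strips" presentation.

The built-in catalogue (`hydrogel_materials()`) holds four lens materials —
a 77% water-content clear hydrogel, blue and clear 74.5% silicone
hydrogels, and a 64% clear hydrogel — each with two moduli: the
manufacturer's datasheet value and the value measured under in-vivo-scale
loads (0.195, 0.277, 0.279 and 0.457 MPa). *The measured modulus is the
simulation default*: lenses on the eye never see the near-failure strains
the datasheet values average over. All materials carry a Poisson ratio of
0.49 (water-swollen gels are nearly incompressible) and their wet
refractive indices.

`synth_tensile()` generates synthetic records for testing: a constant
strain rate of 10% per minute, stress $E\varepsilon$ plus optional additive
Gaussian noise, inverted to forces through $A_0$. It emulates a clean
linear-elastic experiment only — no viscoelastic creep, hysteresis, grip
slippage or failure, so passing parameter-recovery tests says nothing about
those effects in real records. The default strip (20 mm × 5 mm × 0.55 mm)
uses the lathed blank thickness; the strip *width* is not a reported
quantity and 5 mm is simply a realistic cut width.

## 2. Tri-curve lens design

The back surface is a rotationally symmetric tri-curve: optic, transient
and peripheral zones with radii $B_c$, $B_c + 2$ and $B_c - 2$ mm, the zone
centres placed on the axis at heights that make the piecewise spherical sag
continuous at both joins (continuity holds to machine precision by
construction; the surface is deliberately only $C^0$ there, as tri-curve
designs are). Defaults: diameter 13.5/14.0/14.5 mm, optic zone 8.0 mm, base
curve 8.5 mm, shape factor 0.75, centre thickness 0.25 mm, edge thickness
0.4 mm.

Two aperture safeguards are needed because the zone formulas above do not
span the full lens:

* the peripheral-zone circle has radius $B_c - 2 = 6.5$ mm, which is
  *smaller* than every standard semi-diameter (6.75–7.25 mm); the arc is
  therefore continued by its tangent line once the surface angle reaches a
  75° cap;
* the front-surface sag formula
  $Z_f = T_c - (R_f - \sqrt{R_f^2 - \rho X^2})/\rho$ has no real value at
  the periphery of high-plus lenses ($\rho X^2 > R_f^2$), so outside the
  optic zone the front surface is defined by a cubic-Hermite *thickness*
  blend from the optic-zone edge (matching value and slope) to the edge
  thickness $T_e$ at $X = D/2$.

Both safeguards live outside the optic zone; every ray and every paraxial
check stays inside it.

The front optic zone carries the power. A toric prescription is expanded
into 360 meridian powers by a cosine with a 180° period in meridian angle,
circularly shifted so the maxima sit on the cylinder axis (the shift is an
exact index shift on the 1° grid, periodic cubic interpolation otherwise).
Each meridian power is inverted through the thick-lens maker's relation for
the front radius. The transient-zone outer diameter $d_2$ is not a reported
quantity; the default splits the non-optic annulus symmetrically,
$d_2 = (d_1 + D)/2$, and is exposed in `lens_spec()`.

**Minimum thickness.** High plus powers drive the front surface into the
back. Following the stated remedy, the centre thickness grows in 0.01 mm
steps — with the front *curvatures untouched* — until the thickness map
clears 0.1 mm everywhere. A +20 D lens needs ~46 steps
($T_c: 0.25 \to 0.71$ mm). Because the curvatures are pinned, the as-built
paraxial power of such a lens is no longer its label (+20 D builds to
≈ +20.9 D equivalent); all optical validation therefore compares rays
against the as-built paraxial value, and EPC — a difference of two traces
of the same build — is unaffected.

**Ballast.** The stabilising prism ballast thickens the lower lens with the
per-meridian profile $T_j = T_c(1 - W\sin\theta)$, $W = 0.2$ above /
$1.0$ below. Applied literally as a per-meridian constant the apex height
would be multivalued, so the package applies the *excess* $T_j - T_c$
tapered linearly with $X/(D/2)$: zero at the apex, the full profile value
at the edge (`ballast_profile()` exposes the raw profile). `build_lens()` leaves
ballast off by default: the conformance model below pins the lens centre
and has no rotational degree of freedom, so the ballast has no mechanical
role here, while its prism wedge contaminates the axis-crossing focal
estimator. It can be enabled (`ballast = TRUE`) when the geometry itself is
of interest.

## 3. Conformance to the cornea

The anterior eye is a rigid sphere with radius $R_c = 337.5/K$ (default
$K = 43.7$ D, i.e. $R_c = 7.7231$ mm), carrying a 545 µm constant thickness
only for finite-element export. The loads are the tear-film pressure
$P_1 = 43.6$ mPa on the lens back and the eyelid pressure $P_2 = 8.0$ mmHg
(1066.58 Pa) on the lens front; friction (µ = 0.01) is recorded for FE
export, the surrogate itself being a frictionless quasi-static normal
conformance.

The on-eye shape is produced by a *stiffness-weighted, arc-length-preserving
surrogate* rather than a contact finite-element solve. Per meridian, the
lens back surface and the corneal circle are parameterised by arc length
$s$ from the apex, their tangent angles are blended,

$$\psi(s) = w\,\psi_{\text{lens}}(s) + (1 - w)\,\psi_{\text{cornea}}(s),
\qquad w = \frac{S}{1 + S},$$

and the unit-speed curve is re-integrated. The weight comes from a
plate-bending stiffness number

$$S = \frac{E\,\bar t^3}{12(1-\nu^2)\,(P_1 + P_2)\,a^3},$$

with $\bar t$ the mean lens thickness and $a$ the semi-diameter — the ratio
of bending rigidity to the load-times-span scale, in the spirit of treating
lens flexure as beam bending. Both tangent-angle functions are piecewise
*linear* in arc length (circular arcs and a straight extension for the
lens; a circle for the cornea), so the integration is done in closed form
per segment: no quadrature error, and meridional arc length is preserved
exactly. The limits behave as they must: $E \to \infty$ returns the lens
unchanged, $E \to 0$ lays the back surface exactly on the corneal sphere.
Nodes that penetrate the cornea (the steep tri-curve periphery can) are
projected radially onto it; in the rigid limit the lens is returned as-is —
a rigid lens rests on the cornea instead of conforming.

The front surface follows by transporting the *normal thickness* — the
distance from each back node along its local normal to the front surface,
found by Newton iteration on the splined front meridian — along the
conformed normals. Thickness is preserved ($\nu = 0.49$, thin shell, no
Poisson thinning), and the construction reproduces the original lens
exactly in the rigid limit, which an axial-thickness offset would not.

At the stated pressures the four catalogue materials give
$S \approx 4\times10^{-3}$–$10^{-2}$: all of them sit deep in the drape
regime. Two consequences worth stating plainly:

* EPC differences between materials are small (stiffness moves $|EPC|$ by
  under 1%), and
* the drape-limit EPC scales with $(n - 1)$, so the 64% hydrogel's higher
  refractive index (1.392 vs 1.374) *raises* its $|EPC|$ by a few percent
  in the low-power region. The surrogate therefore does not reproduce the
  stiffness ordering of lower-region EPC magnitudes that a nonlinear
  contact solve yields; it does reproduce the high-power convergence and
  the strong negative EPC–power trend. This is the single largest known
  limitation of the surrogate and is visible as a failing ordering check
  in the test suite.

An optional `w` argument overrides the stiffness-derived weight for limit
studies. `export_fe_model()` writes a FEBio-style XML input (structured
HEX8 meshes for lens and cornea, linear-elastic and rigid material cards,
both pressures — the eyelid pressure ramped in from halfway through the
step — frictional sliding contact and the boundary conditions) for anyone
who wants the full contact solve externally; the mesh is annular with a
small inner radius, since a structured polar mesh would degenerate at the
apex.

## 4. Ray tracing and EPC

Both lens interfaces (original or conformed node clouds) are fitted with
Zernike disk polynomials (radial order 8 by default) over the optic-zone
semi-aperture; the basis is evaluated through harmonic-polynomial
recursions, so heights *and* analytic gradients are exact polynomials in
$(x, y)$. Fit residuals are ~$10^{-7}$–$10^{-4}$ mm, three to six orders
below the sag error that could masquerade as 0.1 D.

Rays start parallel to the axis, refract at the front (air→lens) and back
(lens→air) surfaces — the normal from the implicit-surface gradient, the
refracted direction from the meridian-rotation construction (rotate the
event about $z$ to zero the normal's $y$ component, rotate the direction
within the plane of incidence by the Snell angle, rotate back). Every
event is cross-checked at run time against the closed-form vector Snell
law at $10^{-8}$; the test suite asserts the Snell identity at $10^{-12}$.
Ray–surface intersections use damped Newton iterations (tolerance
$10^{-10}$ mm) batched across the bundle.

**Focal length and power.** Each refracted ray's axial crossing is its
point of closest approach to the optical axis (meridional rays intersect
it exactly). For spherical lenses a hexapolar bundle (6 rings, 127 rays,
default pupil semi-aperture 1.5 mm — the pupil is a free parameter, not a
reported one) is traced; the focal length is the distance from the back
apex to the *mean* crossing of the rays that have one (the chief ray does
not), and power is its reciprocal. Measured this way the traced power is a
*back vertex* power — the convention contact lens prescriptions use — and
the paraxial oracle `lens_paraxial_power()` is computed accordingly.

Toric lenses are traced as the two principal meridional fans (on the
cylinder axis and 90° away) and the fan powers averaged. Skew rays of an
astigmatic bundle do not intersect the axis, and for a sphero-cylinder
whose weak meridian sits near zero the mean crossing *position* diverges;
within a fan each ray has a well-defined focus, and the fan power is the
average per-ray vergence, which stays stable through zero.

Residual spherical aberration is real, not numerical: the tri-curve lens
is a steep meniscus (surface powers of ±40–65 D combining to a few
diopters; thin-lens shape factor $|q| \approx 7$), and the traced-minus-
paraxial difference scales with the pupil squared. At a 1 mm pupil
semi-aperture it stays below 0.1 D for −8…+17 D lenses and reaches 0.123 D
at +20 D; the acceptance suite asserts the 0.1 D bound over the whole
−10…+20 D grid and that check fails honestly at the five extreme powers.

**EPC** is the traced power of the conformed lens minus the traced power of
the undeformed lens under identical pupil, grid and fit settings (both in
air; no tear-lens or corneal refraction is modelled, so the difference
isolates the conformance effect). Using the labelled power as the baseline
instead is a configuration switch (`baseline = "labelled"`).

## 5. Sweep and statistics

`run_sweep()` iterates design → conform → trace over materials × lens
types × powers × diameters. Defaults follow the study conditions: four
materials with measured moduli, spherical and cylindrical types
(cylindrical holds SPH = 0 and puts the power in CYL at axis 90°, since
the spherical component of the study's toric lenses is not reported),
powers −10…+20 D in 1 D steps, diameters 13.5/14.0/14.5 mm, the 43.7 D
cornea and the stated loads. The sweep is deterministic — no randomness
anywhere in the chain — and cell failures are recorded, not fatal.

Analyses split the table at 5 D (boundary in the upper region, matching
the "5–20 D" phrasing): pooled-variance two-sample t-tests between
material pairs per lens type and diameter (`pairwise_ttests()`, Welch via
a flag; no multiple-testing correction is applied, matching the original
analysis), Pearson correlations of EPC against power per cell group
(`correlations()`; a zero-variance group yields a missing value, not 0),
and the clinical acceptability flag $|EPC| \le 0.25$ D — the trial-lens
increment — with `acceptable_range()` reporting the longest contiguous
acceptable power run. `report()` writes the long CSV tables, the figures
and the YAML config; re-running a configuration reproduces byte-identical
CSVs.

## 6. Numerical choices and problem sizes

* Grid: 360 meridians × 101 radial stations (design), Zernike order 8,
  fit aperture 4 mm, pupil 1.5 mm (1.0 mm in the paraxial checks), 127-ray
  hexapolar bundles, 40-ray fans. The unit-test suite uses 48 × 61 grids;
  the acceptance checks and the acceptance script run the full study
  resolution, with the trend targets computed from the complete
  cylindrical sweep (192 cells) and the four-material +20 D spherical
  cells.
* Ties and degeneracies: zero cross-section or gauge length and
  non-distinct strains are errors; a singular lens-maker denominator is an
  error; total internal reflection and aperture misses drop the ray and
  are logged per ray; degenerate (zero-variance) t-tests return the
  limiting p-value (1 for identical means, 0 otherwise) and are flagged.
* The minimum-thickness loop is guarded at 200 iterations; the 0.01 mm
  step quantises the centre thickness, which puts a small saw-tooth on
  EPC-versus-power curves (visible jitter of a few hundredths of a
  diopter) — real structure of the stated design procedure, not noise.

## 7. Known limitations

* The surrogate replaces a nonlinear contact FE solve; its stiffness
  sensitivity at the stated loads is weak (Section 3) and lower-region
  material ordering is index-dominated. Exact reproduction of the FE
  study's per-cell EPC values is not claimed anywhere.
* The cornea is a rigid sphere; no aspheric periphery, no patient
  topography, no decentration or rotation (the centre is pinned), no blink
  dynamics, no tear-film optics.
* Loads enter as a single static sum $P_1 + P_2$; the incremental eyelid
  application affects only the FE export's load curve.
* Wavelength dependence, diffraction and image-quality metrics are out of
  scope; the trace is monochromatic geometric optics in air.
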