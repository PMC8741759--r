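---
title: "Methods: planar Y-90 dosimetry and tumour-control modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planar Y-90 dosimetry and tumour-control modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`bat90` models intraoperative radio-ablation of the breast tumour bed with
a planar ⁹⁰Y source: a thin layer of beta-emitting microspheres in a
surgical sealant, applied to the resection cavity. This vignette documents
the models, the parameter defaults, the numerical choices, and the
limitations a user should know before trusting the numbers.

## Decay physics

⁹⁰Y is a pure β⁻ emitter with half-life 64.1 h, so λ = ln 2/64.1 ≈
0.0108 h⁻¹. The device stays in place indefinitely, so an administered
activity A yields Ñ = A/λ cumulated decays (λ per second, A in decays/s;
1 MBq ≈ 3.33 × 10¹¹ decays). The delivered-dose fraction after time t is
1 − exp(−λt): one half-life delivers 50%, nine days ≈ 90%, three weeks
essentially everything. A delivery integrating to D Gy starts at rate λD;
the 20 Gy endpoint corresponds to ≈ 0.2 Gy/h, an order of magnitude below
conventional HDR brachytherapy, which is why sublethal-damage repair enters
the survival model below.

The beta spectrum is the allowed-transition Fermi shape
N(E) ∝ p·W·(E_max − E)²·F(Z, W) with the nonrelativistic Coulomb
correction, daughter Z = 40 and endpoint 2.2801 MeV (the evaluated
nuclear-data endpoint; it is often quoted rounded as 2.26 MeV). The
resulting mean energy is 0.947 MeV, within 1% of the accepted 0.94 MeV
mean. Spectrum-sensitive checks therefore use the band 0.92–0.96 MeV
rather than a point value. A measured or evaluated spectrum can be
substituted via `beta_spectrum(energies_MeV=, density=)`; everything
downstream consumes only the tabulated inverse CDF.

## Transport model

The dose engine is a deliberately simple condensed-history scheme,
implemented in C++ for throughput:

* **Energy loss**: continuous slowing-down with the Berger–Seltzer
  collision stopping power from the material's Z/A and mean excitation
  energy I (Bragg additivity over the composition unless overridden; water
  uses the ICRU value 75 eV). No density-effect correction — below
  2.3 MeV this overstates the stopping power by ≲ 3%.
* **Stepping**: each step loses at most 5% of the current energy and moves
  at most 0.5 mm; the step's energy is deposited at its midpoint.
* **Multiple scattering**: a Highland/Rossi Gaussian small-angle model per
  step (spatial angle Rayleigh-sampled from the Highland θ₀, logarithmic
  correction clamped below, polar angle capped at 1.5 rad), using the
  material radiation length from the Tsai mixture rule.
* **Cutoff**: electrons below 10 keV (residual range ≈ 2.5 µm) deposit
  their remaining energy locally.
* **Neglected**: bremsstrahlung (radiative yield ≲ 2% for ⁹⁰Y betas in
  water — the collision-only scheme deposits that energy locally instead of
  exporting it to photons), energy-loss straggling, and explicit δ-ray
  transport.

Emission points are uniform in the source cylinder (exactly on the plane
for t = 0), directions isotropic, energies from the spectrum. Doses are
scored per decay on 1 mm cubic voxels spanning 80 × 80 × 25 mm, with
voxel centers at integer mm (z planes −12 … 12 mm; "the plane z = k"
means the voxel layer centered at k). Uncertainties come from 20
independent history batches; the per-voxel batch estimate is unbiased,
whereas any *aggregate* built from per-voxel sigmas (plane means, annulus
means) assumes voxel independence and underestimates the error of
correlated within-track deposits — the test suite therefore does
symmetry-type checks at voxel level.

Fidelity against full condensed-history EM physics: the near field is
reproduced well (plateau dose at z = 0–4 mm within ~2–5% of the reference
simulation's planning table), while beyond ~6 mm the simplified scheme
falls off too fast — at z = 8 mm, where the dose is below 0.2% of its
surface value, it understates the reference by tens of percent. The
fitted profile amplitude a₁ lands within a few percent of the published
170.9 Gy·cm²/MBq at 10⁶–10⁷ histories. This is the accepted trade-off:
the planning-relevant region is the first ~4 mm.

A second backend (`mode = "kernel"`) builds the same grid by superposing a
point-source kernel over the source cylinder: the kernel is scored in
0.025 mm spherical shells from an MC run of an isotropic point source, and
the superposition integrates it over the cylinder with midpoint rules
(128 radial × 128 azimuthal × 8/mm axial nodes), evaluating each voxel
plane at three Gauss–Legendre abscissae through the voxel thickness
(the profile varies by e^0.7 per mm, so a center-point evaluation would
be ~2% below the voxel average that MC scores). The two backends agree
within 3σ of the MC statistics on the depth profile for z = 1–8 mm; the
z = 0 layer of a t = 0 source is singular (the source plane lies inside
it) and the shell-discretized kernel under-resolves its self-dose, so the
kernel backend is not used for that plane.

Dose profiles in media other than water can be approximated by rescaling
depth by the density ratio (for ICRP adipose, 0.95 g/cm³, the stretch
factor is 1/0.95 = 1.053 with per-mass doses unchanged). This holds to
~5% over the first 4 mm. Deeper, the materials genuinely separate: adipose
has a longer radiation length per unit mass (41.5 vs 36.3 g/cm²), so
electrons scatter less per unit mass depth and outrun the pure density
rescale — direct simulation of the target material is preferred beyond the
near field.

## Depth-dose parameterization and planning

The tissue-side profile is fitted as d(z) = a₁ exp(a₂ (z − z₀)) with z₀ =
t/2 fixed, d in Gy·cm²/MBq — absorbed dose per unit *areal* activity
(MBq/cm²) under complete decay. Two conventions deserve care:

* **Units of a₂.** Reference coefficient tables for this device print a₂
  magnitudes around 7 labelled mm⁻¹; the package uses a₂ ≈ −0.7 mm⁻¹
  (i.e. reads the printed values as cm⁻¹). The per-mm reading is forced by
  energy conservation: integrating a₁ exp(−0.72 z) over both sides of the
  plane gives ≈ 0.90 MeV per decay, matching the ⁹⁰Y mean beta energy,
  while |a₂| = 7.2 mm⁻¹ would violate it tenfold. It is also the only
  reading consistent with the published dose-versus-depth values
  (172 → 40.9 Gy·cm²/MBq over 2 mm) and the 11 mm beta range.
* **The z = z₀ plane is tissue-side.** For t = 0 the z = 0 voxel layer is
  the tumour-bed surface (shell depth k = 0): the reference planning table
  prints an entry there, and the published a₁ = 170.9 is only reproduced
  when that plane enters the fit. Planes strictly inside the device
  (|z| < t/2) are flagged and excluded.

Fitting is nonlinear least squares (Levenberg–Marquardt, log-linear start
values) over z ∈ [z₀, 9 mm]; beyond ~9 mm the scored doses are counting
noise at the end of the beta range. The default is **unweighted**: the
true profile steepens towards the beta range end, and because absolute MC
sigmas shrink with depth, inverse-variance weighting hands the fit to that
non-exponential tail (driving a₁ ≈ 199 on data whose reference value is
170.9). Unweighted fitting anchors the curve on the high-dose near field
used for planning — evidently the reference procedure. Inverse-variance
weighting remains available (`weighting = "inverse_variance"`) and is the
right choice when the residuals are model-consistent, e.g. synthetic
fixtures with known multiplicative noise, where the 95% CIs then cover the
truth at nominal rate (95.5% over 200 replicates in the test suite).
Residuals of the single exponential are ≤ 4% for z − z₀ ≤ 2 mm and grow
to ~10–15% by 3–4 mm (the published coefficient/table pair behaves the
same way); the planned activity is still accurate because plan inversion
and dose prediction use the same fitted curve.

Planning inverts D(z) = d(z)·A/S with S = πR²/100 cm²: the areal activity
for a prescription D\* at shell depth k is D\*/d(z₀+k), and the total
activity scales exactly linearly with bed area. The reference case —
20 Gy at k = 3 mm, R = 30 mm, t = 1 mm — yields 36.5 MBq from the
published coefficients, matching the nominal 35 MBq within the ~5% the
source values support.

## Radiobiology

Survival under the exponentially decaying dose rate uses the
linear-quadratic model with a protraction factor:

SF(D) = exp[−αD − λβD²/(λ+μ)]

where μ = 0.5 h⁻¹ is the mono-exponential sublethal-damage repair
constant; with ⁹⁰Y's λ the quadratic term is attenuated by λ/(λ+μ) ≈
0.0212, so the kill is nearly alpha-dominated. Defaults: α/β = 3.6 Gy
(breast tumour), α swept over 0.02–0.90 Gy⁻¹ to represent radiosensitivity
heterogeneity, β re-derived from the ratio at each α.

Clonogen burden: the target shell [z₀, z₀+k] with bed radius R carries
density ρ(z), either constant ρ₀ or decreasing linearly from ρ₀ at the
device surface to zero at the prescription depth. ρ₀ defaults span
10⁴–10⁷ cells/cm³ (measured microscopic-disease densities in breast are
~4.5 × 10⁵ cells/mm³, so the upper curves are conservative). Geometry is
kept in mm and densities in cells/cm³; the shell integrals convert via
πR²ρ dz/1000. The initial count for the constant model is πR²kρ₀/1000
(8.48 × 10⁶ cells for R = 30, k = 3, ρ₀ = 10⁶); the linear model gives
exactly half.

Surviving cells Nₛ integrate πR²ρ(z)·SF(D(z)) over the shell. The
integrand rises extremely steeply towards z₀+k (the dose falls, survival
explodes), so the integral is split on a logarithmic ladder of
sub-intervals accumulating at the upper limit before adaptive quadrature
(rel. tol. 10⁻¹⁰), with a 20 000-panel composite Simpson fallback if the
adaptive pass fails; agreement with a 10⁴-panel Simpson oracle is at the
10⁻⁶ level. The volume SF = Nₛ/N₀ cancels ρ₀ exactly — only the density
*shape* matters — and the tests assert that cancellation at 10⁻¹².

Tumour control: the Poisson form TCP = exp(−Nₛ), and the logistic form on
the equivalent uniform dose. EUD₂Gy is obtained in closed form from the
volume SF by inverting SF = exp(−α·EUD − β·2·EUD) — the quadratic term is
β × (2 Gy per fraction) × EUD, i.e. the EUD is referred to a conventional
2 Gy-per-fraction schedule, which is what makes it comparable with
external-beam dose-response fits. The logistic curve is
TCP = 1/(1 + (D₅₀/EUD)^{4γ}) with D₅₀ = 22.39 Gy and γ = 1.01. For the
reference plan at α = 0.3 Gy⁻¹ this chain gives EUD₂Gy = 19.7 Gy /
TCP = 0.37 (constant density) and 24.5 Gy / 0.59 (linear density),
matching the published 19.8/0.39 and 24.5/0.59 within rounding.

A note on monotonicity: the *Poisson* TCP increases with α, decreases with
ρ₀, bed radius and device thickness, and the suite asserts all four. The
*logistic* TCP decreases along an α sweep even as survival improves,
because EUD₂Gy = −ln SF/(α + 2β) normalizes by the growing α — the two
models answer different questions and should not be averaged.

## Brachytherapy fall-off comparison

The TG-43-style transverse-axis fall-off is f_X(r) =
[G(r,θ₀)/G(r₀,θ₀)]·g_X(r), normalized at r₀ = 1 cm with F ≡ 1 on the
transverse axis; point sources use G = r⁻², line sources the r⁻¹
transverse approximation. The device profile is normalized the same way,
f(r) = exp(a₂·10·(r − 1)), which is exactly log-linear. At 2 cm the
geometry factor alone leaves a photon point source at 0.25 while the
device is at ~10⁻³, so every bundled reference (Xoft Axxent 40/45/50 kV,
I-125 seed, Ir-192 HDR) sits ≥ 100× above the device there — the headline
comparison is insensitive to the radial dose functions. The bundled g(r)
tables are **synthetic stand-ins** shaped like the consensus data (soft
x-ray exponential attenuation for the electronic source, the familiar
I-125 decline, near-flat Ir-192); substitute consensus tables via
`tg43_source()` for clinical-grade curves. Interpolation is linear in r
and never extrapolates (hard error outside the table).

## Synthetic fixtures

`generate_fixture()` builds a dose grid whose plateau depth profile is
*exactly* a₁ exp(a₂(z − z₀)) in Gy·cm²/MBq, optionally perturbed by
plane-wise multiplicative Gaussian noise (seeded), with the per-plane
relative sigma recorded. It emulates what the profile and radiobiology
layers consume: a plateau of radius R, symmetric exponential decay, exact
sigmas. It does **not** emulate the curvature of real beta depth doses,
the singular t = 0 surface layer, within-plane statistical texture, or
the edge fall-off physics — so fixture-based tests validate the
*estimators* (fit recovery to ≥ 6 significant digits when noiseless, CI
coverage under noise), while transport fidelity is tested against the MC
engine itself.

## Problem sizes and determinism

The test suite runs the MC engine at 5 × 10⁴ – 2 × 10⁵ histories for
property checks (symmetry, conservation, plateau shape, backend
agreement; plane-level statistics 0.2–0.5% in the near field) and 10⁶
histories for the water-profile reproduction; the kernel backend uses a
5 × 10⁵-history point kernel. All randomness — the C++ engine (64-bit
Mersenne Twister with uniforms built from raw bits and Box–Muller
normals) and the R-side samplers — is seed-determined, so identical
configurations reproduce grids bit-identically, and every output file
records its seed and a content hash of its configuration.

## Known limitations

* Transport omits bremsstrahlung photons, straggling, δ-rays and the
  density effect: depth doses beyond ~6 mm (< 1% of the surface dose) are
  systematically low, and skin/air interfaces or heterogeneous anatomy are
  out of scope (homogeneous bulk only).
* The exponential profile is a near-field parameterization; do not use it
  beyond ~8 mm or inside the device layer.
* The repair model is mono-exponential with a single μ; multi-exponential
  and reciprocal-time repair, oxygenation, proliferation and inter-patient
  parameter distributions are not modelled — population dose-response
  curves will be shallower than these single-parameter-set curves.
* The logistic parameters (D₅₀, γ) come from external-beam breast data via
  the EUD₂Gy mapping; their transfer to continuous low-dose-rate delivery
  inherits that model's assumptions.
* Bundled TG-43 radial dose functions are synthetic approximations, not
  consensus datasets.
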