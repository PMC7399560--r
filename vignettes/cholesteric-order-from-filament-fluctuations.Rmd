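---
title: "Cholesteric order from filament shape fluctuations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cholesteric order from filament shape fluctuations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(origamiLC)
```

## The problem

Suspensions of stiff chiral filaments — DNA origami bundles, filamentous
viruses, amyloid fibrils — form lyotropic cholesteric liquid crystals whose
director rotates helically with a pitch P of micrometers to millimeters.
Which *molecular* feature sets the handedness and magnitude of P is a
long-standing question: the chirality of the filament's ground-state shape
(e.g. a designed axial twist), or something subtler. This package implements
a complete computational route from ensembles of fluctuating filament
conformations to the macroscopic cholesteric observables, so that the
contribution of thermal shape fluctuations can be separated from that of the
ground-state morphology:

1. a synthetic-conformation generator emulating six-helix DNA bundles
   (`generate_ensemble()`), plus readers for oxDNA-format trajectories
   (`read_oxdna()`);
2. conformational analysis: backbone helicity spectra H(k)
   (`ensemble_helicity()`), duplex twist densities and the local polar
   writhe of the centerline (`ensemble_twist_writhe()`);
3. an extended Onsager second-virial density functional: the
   conformationally averaged Mayer function binned into an orientation
   kernel (`virial_kernel()`), the self-consistent orientation distribution
   (`solve_odf()`), the Frank twist modulus K2 and chiral strength kt
   (`elastic_constants()`), the pitch P = 2 pi K2 / kt (`pitch()`),
   isotropic–cholesteric coexistence (`binodal()`), and a chiral pair
   potential-of-mean-force scan (`chiral_pmf()`).

All geometry is in nm internally; outputs use the field's units
(turns/µm for twist densities, mm⁻¹ for writhe, µm for the pitch, g/L for
concentrations, kT for energies).

## The synthetic ensemble: what it emulates and what it does not

The generator replaces GPU-scale molecular dynamics with a discrete
wormlike chain (WLC) plus a parameterized decoration. Its defaults encode
the six-helix-bundle systems the analysis is aimed at:

* contour length l_c = 420 nm, bundle diameter 6 nm, persistence ratio
  l_p/l_c = 8, six duplexes on a hexagon of radius 2 nm with strands 1 nm
  off each duplex axis, 10.5 bp/turn duplex repeat at 0.34 nm/bp rise.
  The hexagon/strand radii are chosen so the bundle circumscribes the
  6 nm envelope (2·(2 + 1) nm = 6 nm).
* Backbone bending: successive tangents tilt by polar angles drawn from the
  exact WLC distribution p(cos β) ∝ exp((l_p/Δs) cos β); the material frame
  is carried along by the same rotations. The decoration, however, uses a
  freshly parallel-transported (twist-free) frame, so that intrinsic
  torsion of a solenoidal ground state never leaks into the *built* duplex
  winding — the duplex twist measured downstream then reflects only the
  designed winding and the explicit twist–writhe partition below.
* Designed overtwist. Origami crossovers overwind ("deletions", the
  left-handed design convention) or underwind ("insertions") the duplexes
  relative to straight-and-untwisted geometry. `linking_target()` carries
  this `design_overtwist` (turns/µm) and a partition rule: a fraction
  (default 0.5) of the designed overtwist is absorbed by a solenoidal bias
  of the centerline whose writhe has the *same sign* as the twist stress,
  with a dimensionless twist–writhe conversion (default 100) between
  centerline writhe density and relieved duplex overtwist. Both defaults
  were fixed once from the characteristic pattern of thermalized
  twist/writhe statistics in six-helix bundles (residual overtwist roughly
  half the designed value; ~100 turns/µm of relieved overtwist per
  turns/µm of writhe density) and are ordinary exposed parameters.
  The strand winding is reduced pointwise by conversion × local writhe
  density, so each generated ensemble satisfies the linking balance
  mean(ΔTw) + conversion·mean(Wr) ≈ design_overtwist by construction —
  this is the generator-level emulation of the twist–writhe conversion
  that crossover topology enforces in real origamis.
* The solenoidal bias is realized as an intrinsic curvature/torsion pair
  describing one helical turn over the contour (`solenoid_bias()`); the
  amplitude distribution across conformations is degenerate ("fixed") by
  default because no empirical distribution is established for it — the
  bias mode is a parameter, not a claim.

What the generator does **not** emulate: sequence effects, staple-level
design (individual crossover placement), elastic ground-state relaxation,
end fraying beyond the generic trimming, and any correlation between
consecutive ensemble members (members are i.i.d. by construction; the
end-to-end autocorrelation diagnostic `ensemble_autocorrelation()` exists
for imported trajectories). Passing tests on synthetic ensembles therefore
validate the *measurement and theory machinery* and the stated mechanism
qualitatively; they are not a substitute for sampled trajectories of a
specific design.

## Backbone helicity

The backbone is one point per bp plane (mean of the six duplex midpoints),
trimmed by `trim_bp` planes per end (default 10; real filaments fray at
the ends), resampled to uniform arclength and centered. The molecular
frame is the principal frame of the gyration tensor: u = maximum
dispersion (long axis), v = minimum, w = u × v. Principal axes are only
defined up to sign; u is oriented along the first-to-last-point vector and
v along the first transverse displacement, which pins all downstream signs
while leaving relative handedness — the only physically meaningful part —
intact. The transverse displacement r⊥(s) = r(s) − (r·u)u is transformed
with the exact exponential sum r̂⊥(k_n) = Σ_j Δs r⊥(s_j) e^(−2πi k_n s_j)
at k_n = n/l_c (evaluated by FFT, which is that sum on a uniform grid),
and the helicity order parameter is

H(k) = 2 Im{ĉ_vw(k)} / (ĉ_vv(k) + ĉ_ww(k)),

the normalized imaginary cross-spectrum of the two transverse components.
|H| ≤ 1 by Cauchy–Schwarz, H(0) = 0 because zero-frequency components are
real, and H = +1 (−1) exactly when the two components have equal amplitude
and perfect phase quadrature — an ideal right- (left-) handed circular
helical mode (`make_ideal_helix()` realizes this extreme; note that the
*gyration* long axis of a finite helix is tilted from the true helix axis
by an O(a/l_c) end effect, so the exactness check supplies the known axis
via `molecular_frame()`). Ensemble curves average per-conformation H
pointwise; averaging cross-spectra first is available
(`average = "spectra"`) but is a different, inequivalent estimator.
Savitzky–Golay smoothing (order 9, window 15, `signal::sgolayfilt`) is
applied to the displayed mean only, never to raw spectra.

A peak of |⟨H⟩| at the smallest accessible wave number k = 1/l_c is a
finite-size feature of antisymmetric spectra on a finite filament and must
not be read as a preferred physical helical pitch.

**Reference spectrum.** For a free WLC, expanding the bending energy
(l_p/2)∫|r⊥''|² ds in Fourier modes gives the equipartition transverse
power ⟨|r̂⊥|²⟩(k) = 2 l_c / (l_p (2πk)⁴) (`wlc_reference_spectrum()`).
This 1/k⁴ law describes the measured spectrum only at the lowest modes:
the exponential-sum transform of an *open* filament also picks up the
mismatch between its two ends, a contribution decaying like 1/k², which
overtakes the bending signal beyond mode ≈ 2 and makes the apparent
log–log slope over the first decade ≈ −2.8 rather than −4. The package's
tests therefore validate the generated ensembles against an *exact*
discrete equipartition oracle (linear algebra on the harmonic chain,
including centering and tilt removal, no sampling), and check the 1/k⁴
asymptote only where it applies.

## Twist and writhe

Per duplex, cubic splines interpolate the two strands' nucleotide centers
of mass; with centerline r = (r₁+r₂)/2, tangent t = dr/ds and normal
n = (r₁−r₂)/|r₁−r₂|, the twist density is Tw = (1/2πl)∫ t·(n × dn/ds) ds,
evaluated by composite Simpson quadrature on a 4×-oversampled spline grid
(halving the step moves the result by < 0.1%). The reference
Tw₀ = 1/(10.5 bp × 0.34 nm/bp) = 280.1 turns/µm is exposed because the
equilibrium repeat of DNA constrained in origami lattices can differ
slightly. The filament's local polar writhe is
Wr = (1/2πl_c)∫ u·(t × dt/ds)/(1 + u·t) ds, defined only while the curve
is monotone along u (a turning point raises an error naming the
abscissa; the nonlocal polar-writhe term for non-monotone curves is out
of scope). The backbone is Savitzky–Golay pre-smoothed (order 9,
window 15, independently configurable from the display smoothing) to
remove the short-wavelength contour noise inherent in the geometric
centerline definition. Wr > 0 for right-handed winding about u; units are
mm⁻¹, so that for an ideal solenoid of m turns and pitch angle α,
Wr = m(1 − cos α)/l_c. Conformations violating the monotonicity
precondition are excluded and counted; beyond a 5% fraction (stiff
filaments rarely violate it) the ensemble statistics error out rather
than silently dropping data.

## The second-virial stage

**Interactions.** Nucleotide sites interact through hard cores (diameter
0.7 nm) plus a screened-Coulomb tail βU = q² l_B e^(−r/λ_D)/r with an
effective per-site charge (default 0.5 e — deliberately exposed as the
main fidelity knob of the electrostatic stand-in), truncated at 4 λ_D.
The Debye length follows from the salt: 0.6 nm at the 0.26 M assay
conditions (the default), 0.5 M being the common simulation setting.
`steric_model()` switches the tail off for purely entropic branches.
Energies are evaluated in compiled code behind a two-level culling
hierarchy (a bounding capsule per filament, then bounding spheres over
~5-bp contour segments), the appropriate acceleration structure for thin
filaments where a cubic cell list degenerates.

**Conventions.** ψ(cos θ) is normalized to unit integral over d cos θ
(isotropic = 1/2), and the kernel κ(θ,θ′) is the azimuth/spin-conditional
average of ∫dr₁₂ f̄ (nm³), estimated by uniform Monte Carlo over
separations in a bounding ball, orientations on the rotation group, and
conformation pairs, binned in (cos θ₁, cos θ₂). With these choices the
self-consistency equation is simply ψ = exp(ρ ∫ψκ)/Z (Picard iteration
with under-relaxation), and no residual angular normalization factors
appear. The convention is validated end-to-end against the classical
hard-rod limit: with the closed-form needle kernel, the coexistence solver
reproduces the classical dimensionless densities 3.290/4.191 and
order parameter 0.792 to better than 1%.

**Elastic constants.** At second-virial level,
βK₂ = (ρ²/2)∫ f̄ ψ′(x₁)ψ′(x₂) r_z² u₁y u₂y and
βk_t = (ρ²/2)∫ f̄ ψ(x₁)ψ′(x₂) r_z u₂y, in the laboratory frame with
director e_x and helical axis e_z. ψ′ is obtained *analytically* by
differentiating the fixed-point relation through the splined exponent
(chain rule), which is far more robust than differencing the gridded ψ;
finite differences agree and serve as a cross-check. Orientations are
importance-sampled from ψ itself (the uniform sampler wastes nearly all
draws once S ≳ 0.7), and the chiral strength uses an antithetic
mirror-pair estimator: every sample is also evaluated against the
mirror-image bodies with the same random numbers, and k_t keeps the
parity-odd half of the Mayer function. This removes the dominant achiral
noise from the pseudoscalar at twice the cost per sample and enforces the
parity structure at the estimator level. Errors are batch means (32
batches). P = 2πK₂/k_t, positive = right-handed phase; a k_t within one
standard error of zero is flagged achiral-within-error and the pitch
reported as unwound. Bootstrap resampling of the conformational ensemble
(`bootstrap_pitch()`, default 16 runs, 10% dispersion threshold) is the
convergence check for the whole Monte Carlo stage.

**Coexistence.** βF/V = ρ(ln ρ − 1) + ρ∫ψ ln(2ψ) + (ρ²/2)E[ψ] with
E = −∫∫ψψκ; chemical potential and osmotic pressure follow by
differentiation at the self-consistent ψ (the envelope theorem makes the
fixed-ψ derivative exact, which the tests verify to 10⁻⁶ against numerical
differentiation). Coexistence solves μ_iso = μ_chol, Π_iso = Π_chol by
damped Newton with a density-scan bracket; the chiral free-energy gain
k_t²/2K₂ is many orders below f₀ at realistic pitches and is neglected in
the binodal, which therefore coincides with the nematic one at this level.
Mass concentrations assume 650 Da per bp.

**Chiral PMF.** `chiral_pmf()` scans the interaxial angle γ of a pair
with axes perpendicular to their center separation:
W(γ) = −ln⟨e^(−βU)⟩ over separations, spins and conformation pairs,
relative to γ = 0; γ > 0 is a right-handed pair arrangement. The exact
weighting of separations (uniform up to d_max along the separation axis)
is an operational choice documented here rather than a published
definition; the minimizing γ* is meaningful at sign level.

## Design choices where the design was open

* **Trimming**: the number of discarded end planes is a parameter
  (default 10) — end fraying is design-dependent.
* **Frame ordering**: the text convention assigns v to the
  minimum-dispersion axis; the frame is completed right-handedly with
  w = u × v, and sign fixes are calibrated once against the right-handed
  helix fixture (H = +1).
* **k-grid**: one-sided, k_n = n/l_c up to the Nyquist mode; the filament
  is not treated as periodic — the FFT is used only as an evaluation of
  the exact sum.
* **Internal ensemble container**: a single versioned file using native R
  serialization; lossless round trip of positions, indexing, provenance
  and seed, with an explicit format-version check.
* **Duplex assignment for imported origami topologies** requires a
  user-supplied nucleotide → (duplex, strand, bp) map; staple-level
  designs cannot be inferred reliably from connectivity, while plain
  two-strand duplexes are paired automatically.
* **Degenerate gyration spectra** (two equal eigenvalues, e.g. a perfect
  helix's transverse plane) are resolved by the deterministic eigenvector
  returned by the symmetric solver and flagged on the frame object; H is
  invariant under rotations within the degenerate transverse pair, so the
  tie-break cannot affect it.
* **Seeds**: one global seed fans out to per-stage substreams through a
  counter scheme (`derive_seed()`), so stages rerun independently yet
  reproducibly; all compiled Monte Carlo uses R's RNG.

## Problem sizes used in the shipped tests

The test-suite and worked examples run ensembles of 40–60 filaments at
full 420-nm geometry for the conformational-analysis stage, and a
desk-scale chiral stand-in for the virial stage: 60-nm contour at bp-true
rise (176 planes, 2112 sites), l_p/l_c = 8, designed overtwist scaled to
preserve the 1x design's total overtwist per contour (~2.9 turns), with
10⁶-sample kernels and ~10⁷-sample elastic-constant estimates. The
bp-true duplex thread pitch matters qualitatively: coarsening the rise
moves the duplex surface threads from the tightly-wound (isochiral)
regime into the weakly-twisted (antichiral) regime and inverts the
ground-state handedness. At these sizes the handedness physics is
resolved at the 2–5 standard-error level; quantitative pitch magnitudes
for specific designs require imported trajectory ensembles and
cluster-scale Monte Carlo budgets, which the same functions accept
unchanged.

## Known limitations

* Second-virial (Onsager) level only; no biaxial corrections, no
  attractions or hydration forces, no counterion release beyond the
  effective charge.
* The local polar writhe only — filaments with turning points along their
  long axis are excluded, not approximated.
* The generator's twist–writhe partition is phenomenological: it encodes
  the sign and rough magnitude of the conversion, not a microscopic
  elastic model of crossover mechanics.
* H(k) peak positions on finite filaments are finite-size features; no
  attempt is made to read a preferred helical pitch from them.
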