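---
title: "Models and methods behind lnptools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lnptools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnptools)
```

`lnptools` implements the quantitative analyses used to characterize
colloidal lignin nanoparticles (LNPs): solvent thermodynamics,
small-angle X-ray scattering (SAXS), configuration-level structural
analysis, AFM nanomechanics and size statistics.  This vignette states
each model, its assumptions, the unit conventions, and the design
decisions that were genuinely open.

## Unit conventions

The interfaces mix the communities' habitual units, so one convention is
declared everywhere:

* SAXS: q in Å⁻¹, internal intensities in Å⁻¹ (absolute scale; reduced
  data in mm⁻¹ are converted by 10⁻⁷ at ingest), lengths in Å internally,
  diameters reported in nm, SSA in m²/g, SLD in 10⁻⁶ Å⁻².
* Molecular configurations: nm throughout (GRO native; XYZ Å are
  converted), angles in degrees.
* AFM: indentation nm, force nN, modulus GPa.  Since 1 GPa ≡ 1 nN/nm²,
  the Hertz formula needs no numeric conversion factor.

## Solvent thermodynamics

The Flory–Huggins interaction parameter is computed as
χ = V(δ₁ − δ₂)²/(RT), with V a reference molar volume in cm³/mol, the
Hansen total solubility parameters δ in MPa^0.5 and
R = 8.314462618 J mol⁻¹ K⁻¹, T defaulting to 298.15 K.  MPa·cm³/mol is
J/mol, so χ is dimensionless.

For solvent–solute pairs the reference volume is the solvent's molar
volume — the standard convention.  For **solvent–water** pairs the
convention is less settled; this package uses the molar volume of water
(18.07 cm³/mol).  The choice was made by numerical agreement: only the
water reference volume reproduces the accepted χ values of the
aqueous-organic pairs in the packaged solvent table (5.6, 5.9, 5.4, 3.2
for acetone, THF, DXN, DMSO), whereas the organic solvent's volume does
not.  It is therefore documented prominently here and in
`rank_solvents()`, and should be kept in mind when comparing against
other calculators.

Display rounding is one decimal, except χ < 0.1 shown at two decimals so
near-athermal pairs are distinguishable from zero.

## SAXS form-factor model

The intensity model is dilute homogeneous spheres with a number-weighted
log-normal diameter distribution:

I(q) = Δρ² φ ⟨V²P(q)⟩/⟨V⟩ + b,

with the sphere form factor P(q) = [3(sin qR − qR cos qR)/(qR)³]² and
⟨·⟩ the average over the log-normal parameterized by the median diameter
and σ_log (SD of log diameter).  The number density is set by the volume
fraction, n = φ/⟨V⟩.  No structure factor is included: the model is for
dilute dispersions (φ below about a percent), which is also where the
two-phase invariant expressions hold in their φ(1−φ) form.

Numerical choices:

* The size average uses fixed 151-point Gauss–Legendre quadrature on
  log-diameter over median ± 5σ; the quadrature is rejected if it covers
  less than 99.9% of the distribution's mass, and σ_log > 2 is refused
  outright (unphysically broad for a nanoprecipitated dispersion, and
  beyond reliable quadrature).
* The q → 0 limit of P is evaluated by series, avoiding 0/0.
* Fits run on log-transformed parameters (all are positive), with
  Levenberg–Marquardt and up to three jittered restarts.  Weights are
  1/σ² when uncertainties are present and 1/I² otherwise (constant
  relative error, appropriate for counting-dominated data spanning
  decades).
* Contrast is held fixed by default because it is exactly degenerate
  with φ (only Δρ²φ enters); either can be freed instead.
* Initialization scans a coarse grid over median diameter (8–300 nm)
  and width, solving amplitude and background linearly at each node and
  taking the lowest weighted residual (ties broken toward the narrower
  distribution).
* Reported mean and SD are the number-weighted log-normal moments,
  mean = median·exp(σ²/2), SD = mean·√(exp(σ²) − 1).  Whether a given
  instrument report is number- or volume-weighted is often ambiguous;
  the moments of the volume-weighted distribution can be formed from the
  same fitted parameters if needed.

## Invariant route to the specific surface area

For a two-phase system on absolute scale the invariant
Q = ∫₀^∞ I q² dq equals 2π²φ(1−φ)Δρ², the Porod limit is
K_P = lim I q⁴ = 2πΔρ²(S/V), and SSA = (S/V)/(φρ).  The measured window
never reaches 0 or ∞, so the curve is extended: a Guinier head
(closed-form integral, using erf) below q_min and an analytic K_P/q tail
contribution above q_max; the measured body is integrated by the
trapezoid rule.

* **Porod regression.** I q⁴ = K_P + b q⁴ is fitted linearly with
  trapezoid quadrature weights.  On log-spaced grids this makes the
  fitted constant the uniform-in-q oscillation average of I q⁴, which is
  the true Porod limit for sphere form factors; the unweighted regression
  carries a 1–2% bias from unevenly sampled oscillations.  The constant
  must be significantly positive (t ≥ 2), otherwise the window shows no
  sharp-interface q⁻⁴ regime and the fit errors.
* **Background.** The full chain fits the Porod window up to the end of
  the measured range by default: the flat background is only constrained
  where b·q⁴ is comparable to K_P, i.e. at the highest q, and a
  background estimated on a narrow window is amplified by q⁴ when
  extrapolated.  A standalone `porod_fit()` defaults to 0.02–0.1 Å⁻¹,
  the range where sharp-interface behavior is typically observed for
  40–60 nm particles.
* **Splice diagnostics.** Continuity between the extrapolations and the
  data is reported at both ends; above 20% mismatch the chain aborts,
  since the invariant would then be dominated by extrapolation error.
  The high-q diagnostic compares K_P to the oscillation-averaged I q⁴
  over the last half of the measured points — a sphere form factor
  crosses zero each period, so a single-point comparison is meaningless —
  and carries a few percent of oscillation-phase noise for strictly
  monodisperse curves (it is essentially exact for smeared or
  polydisperse ones).
* The Guinier validity criterion q·Rg ≤ 1.3 is enforced as a warning,
  not an error: it is a community convention, and slightly wider windows
  are common practice for compact particles.

The smooth-sphere reference SSA = 6/(dρ) and the composition-based SLD
(r_e N_A ρ Σ wᵢ(Zᵢ + f′ᵢ)/Aᵢ, with approximate Cu Kα f′ corrections and
mass fractions normalized to 1 before use — printed compositions rarely
sum exactly to 100%) provide the independent anchors for the chain.

## Structural analysis

Hydrogen bonds are geometric: donor–acceptor heavy-atom distance
strictly below 0.35 nm **and** hydrogen–donor–acceptor angle (vertex at
the donor heavy atom, not at the hydrogen) strictly below 30°.  Both
the vertex convention and the strict inequalities follow the stated
criteria exactly; changing the vertex to the hydrogen gives materially
different counts.  Donors are N/O atoms with a covalently attached H
(same molecule, within 0.12 nm); acceptors are all N/O atoms;
intra-molecular pairs are excluded by default.  Candidate pairs come
from a cell-list search whose results are bit-identical to the all-pairs
search (both are exposed, and the equivalence is property-tested).

RDFs histogram minimum-image pair distances and normalize by shell
volume × ideal density × group size × frames, so g(r) → 1 for
homogeneous fluids; r_max may not exceed half the smallest box edge
(beyond it the minimum-image shell is no longer spherical).  For
identical groups, self-pairs are excluded and the ideal density uses
N − 1.

SASA is Shrake–Rupley with a deterministic Fibonacci-spiral point set
(default 960 points per atom, <1% from the analytic single-atom value),
Bondi van der Waals radii (overridable), a 0.14 nm probe, and
minimum-image occlusion.  A surface point lying exactly on another
atom's probe sphere is owned by the lower-index atom, so coincident
atoms count their shared surface once.

## Nanomechanics

The Hertz sphere-on-flat model F = (4/3)·E/(1−ν²)·√R·δ^{3/2} treats the
tip as rigid and reports the sample-only modulus; tip compliance is not
deconvolved.  Fits run on the 5–50% force window by default
(corresponding to 2–3 nm indentations at the default R = 50 nm,
ν = 0.3).  The contact-point offset is co-fitted by default, bounded to
±5 nm.  Note that on noisy but already contact-aligned curves the
offset co-fit costs accuracy: at 2% force noise the co-fit biases the
mean recovered modulus several percent low (the low-force end of the
window has order-40% relative noise), whereas pinning the offset at zero
recovers the modulus to well under 1% — so recovery studies on
generator output pin the offset, and the co-fit is reserved for curves
whose contact point is genuinely unknown.

Records with E > 4 GPa or height < 15 nm are flagged substrate-affected
and excluded from particle statistics; a linear regression of modulus on
height over the remaining records tests for a size effect.
Intermodulation-AFM stiffness (arbitrary units, proprietary processing)
is represented only by a documented slope-based proxy: the linear slope
of force versus indentation over the top 20% of the force range, which
for a Hertz curve approaches the analytic contact stiffness
2·E/(1−ν²)·√(Rδ).

## Size statistics

`gaussian_fit_diameters()` reproduces the common microscopy workflow —
histogram then least-squares Gaussian — rather than plain moments,
because that is what instrument software reports; bins default to the
Freedman–Diaconis rule, and samples under 30 particles (or degenerate
ones) fall back to moments with a flag.  The PDI here is SD/mean of the
measured diameters, *not* the DLS cumulant PDI; the two are not
comparable.  Note that a PDI recomputed from rounded published means and
SDs need not reproduce the published PDI (the originals used unrounded
estimates).

## Synthetic data: what it does and does not emulate

The generators produce: absolute-scale SAXS curves from the sphere/log-
normal model with multiplicative Gaussian noise (an approximation to
counting statistics on azimuthally averaged absolute data) on a
200-point 0.003–0.3 Å⁻¹ log grid typical of a laboratory camera; Hertz
force curves with additive Gaussian force noise and an optional
stiff-substrate fraction (10–60 GPa, heights under the substrate
regime); solvent boxes of rigid idealized molecules (water, acetone,
THF, DXN, DMSO) at integer-optimized counts hitting requested weight
fractions (default total density 0.85 g/cm³, the scale of the
aqueous-organic mixtures being emulated), placed uniformly at random so
pair statistics are ideal-gas by construction; and planted hydrogen-bond
scenes whose bonds sit strictly inside both cutoffs with 10% margin and
whose decoys violate exactly one criterion each, laid out on a grid too
wide for cross-scene contacts.

Default study conditions follow the system being modeled: 44 ± 16 nm
and 61 ± 21 nm diameter distributions, volume fraction ≈ 0.005 (a
6.7 mg/mL dispersion at 1.4 g/cm³), contrast 3.13×10⁻⁶ Å⁻²
(lignin 12.6 − water 9.47, in 10⁻⁶ Å⁻²), particle moduli 0.3–4 GPa.

What passing tests on this data do **not** show: real SAXS curves carry
instrumental smearing, concentration effects and imperfect background
subtraction; real liquids have excluded volume and orientational
structure (g(r) ≠ 1); real force curves have adhesion, drift and
cantilever artifacts.  The generators validate the estimators'
correctness, not robustness to those effects.

All generators are deterministic under a fixed integer seed, and every
generator returns its ground truth alongside the data.

## Problem sizes used in the shipped tests

The test suite runs the estimators at sizes where their statistical
guarantees are meaningful yet the whole suite stays interactive:
200-point SAXS curves with 3-seed fit-recovery checks, 100–200 force
curves for Monte-Carlo recovery and flagging, 300–500-atom boxes for
neighbor-search equivalence and RDF bands, 50-atom clusters for SASA
refinement, and 10⁴–10⁶ draws for sampling oracles.

## Known limitations

* No structure factor, smearing or non-spherical form factors in SAXS;
  the invariant chain presumes a two-phase system with sharp interfaces.
* The Porod/Guinier extrapolation diagnostics assume a single particle
  population; bimodal systems can splice "consistently" yet violate the
  two-phase invariant.
* Hydrogen-bond donor detection is distance-based (0.12 nm); exotic
  tautomers or metal hydrides are out of scope.
* SASA is O(N²) per configuration in the worst case and intended for
  single-molecule/solvation-shell systems, not million-atom boxes.
* The stiffness proxy is deliberately simple and is not a reconstruction
  of intermodulation spectra; arbitrary-unit instrument stiffness values
  cannot be reproduced quantitatively.
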