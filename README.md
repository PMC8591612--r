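# lnptools

Quantitative analyses for colloidal **lignin nanoparticles** (LNPs) — the
spherical particles obtained by nanoprecipitating dissolved Kraft lignin
from an aqueous organic solvent into water.  The package covers the
characterization chain a particle lab runs around such a system:

- **Solvent screening** — Flory–Huggins interaction parameters
  χ = V(δ₁ − δ₂)²/(RT) from Hansen solubility parameters, and the
  supersaturation level S = s₇₅/s₂₁ that drives nucleation.
- **SAXS analysis** — an absolute-intensity form-factor model of
  homogeneous spheres with a log-normal diameter distribution, Guinier
  (I ∝ exp(−Rg²q²/3)) and Porod (I ∝ q⁻⁴) fits, and the invariant route
  to the specific surface area:
  Q = ∫ I(q)q²dq = 2π²φ(1−φ)Δρ²,
  Δρ = √(Q/(2π²φ(1−φ))),
  S/V = K_P/(2πΔρ²),
  SSA = (S/V)/(φρ).
- **X-ray scattering length density** from elemental mass fractions,
  SLD = r_e N_A ρ Σ wᵢ(Zᵢ + f′ᵢ)/Aᵢ, with Cu Kα anomalous corrections.
- **Structural analysis of molecular configurations** — geometric
  hydrogen-bond detection (donor–acceptor distance < 0.35 nm,
  H–donor–acceptor angle < 30°), radial distribution functions and
  Shrake–Rupley solvent-accessible surface area (0.14 nm probe), all
  under periodic boundary conditions, with GRO/XYZ readers.
- **AFM nanomechanics** — Hertzian sphere-on-flat fits
  F = (4/3)·E/(1−ν²)·√R·δ^{3/2} on force–indentation curves (5–50% force
  window, ν = 0.3, R = 50 nm defaults), substrate flagging (E > 4 GPa or
  height < 15 nm) and modulus-versus-height statistics.
- **Particle-size statistics** — Gaussian histogram fits of TEM-style
  diameter counts, PDI = SD/mean, log-normal moment conversions.
- **Synthetic-data generators** for every input above with known ground
  truth and full seeded determinism.

## Worked example

Rank the four binary-solvent systems by lignin affinity from the packaged
property table:

```r
library(lnptools)
tbl <- read_solvent_table(system.file("extdata", "solvent_table.csv",
                                      package = "lnptools"))
rank_solvents(tbl, delta_solute = 27.4)
#>      name chi_solvent_solute chi_solvent_water supersaturation
#> 4    DMSO         0.01403413          3.245294      115.555556
#> 1 acetone         1.63686419          5.633506        8.333333
#> 3     DXN         1.64208373          5.432684        8.000000
#> 2     THF         2.09120204          5.879303        9.181818
```

DMSO is the thermodynamically best lignin solvent (χ ≈ 0.01) and carries
by far the largest supersaturation jump on dilution; acetone and dioxane
are nearly tied at χ ≈ 1.6.

Run the full SAXS surface-area chain on a synthetic dispersion of 44 nm
spheres at volume fraction 0.005 and contrast 3.13×10⁻⁶ Å⁻²:

```r
m   <- sphere_lognormal_model(44, 0, 0.005, 3.13e-6, background = 1e-12)
crv <- make_saxs_curve(m, noise_fraction = 0, seed = 1)$curve
invariant_chain(crv, volume_fraction = 0.005)
#> invariant chain: Q = 9.67e-13 A^-4, drho = 3.138e-06 A^-2,
#>   S/V = 6.789e-05 A^-1, SSA = 96.99 m^2/g (phi = 0.005, rho = 1.4 g/cm^3)
```

The recovered contrast (3.138×10⁻⁶, +0.3%) and specific surface area
(97 m²/g, the smooth-sphere value `sphere_ssa(44, 1.4)`) close the
two-phase invariant relations.  Fitting a noisy polydisperse curve
recovers the generating size distribution:

```r
p     <- lognormal_from_moments(44, 16)
truth <- sphere_lognormal_model(p[["median"]], p[["sigma_log"]],
                                0.005, 3.13e-6, 1e-12)
sim <- make_saxs_curve(truth, noise_fraction = 0.01, seed = 1)
fit_sphere_lognormal(sim$curve)
#> sphere/log-normal fit (converged): mean D = 44.1 +/- 16 nm, chi^2/dof = 0.86
```

And a Hertz fit on a synthetic force curve:

```r
fc <- make_force_curves(2.7, n_curves = 1, noise = 0, seed = 1)
fit_hertz(fc$curves[[1]])
#> Hertz fit: E = 2.7 GPa, contact offset = 0 nm, RMS = 0 nN (98 points, 5-50% force window)
```

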