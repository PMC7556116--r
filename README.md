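# ladderNMR

Spin dynamics and relaxation analysis of asparagine/glutamine side-chain
ladders in amyloid fibrils by fast magic-angle-spinning (MAS) solid-state
NMR.

Hydrogen-bonded ladders of primary-amide side-chains stabilize many amyloid
fibrils. Proton-detected fast-MAS NMR distinguishes a rigid, hydrogen-bonded
ladder from a flexible side-chain through a handful of observables: NH2
proton shifts (de-shielding of the donor proton), refocused-INEPT
visibility, the homogeneous proton linewidth Δʰᵒᵐᵒ = R₂′/π = 1/(πT₂′)
from rotor-synchronized spin-echo decays, and rotating-frame relaxation
rates R₁ρ. This package, written for solid-state NMR spectroscopists and
structural biologists analysing such data, implements the full
computational chain:

* **spin systems from coordinates** — multi-model PDB parsing (bio3d),
  dipolar anisotropies δᵢⱼ/2π = −(μ₀/4π)γᵢγⱼħ/(2π rᵢⱼ³) with a coupling
  cutoff;
* **MAS spin-dynamics engine** (compiled core) — piecewise-constant
  propagation of the rotor-modulated secular Hamiltonian, deterministic
  ZCW-type powder averaging, 1D spectra from exact transition sticks, and
  rotor-synchronized spin-echo decays with both site-resolved (peak) and
  total-magnetization detection; exact conserved-sector averaging over ¹⁵N
  spectators;
* **refocused-INEPT editing** — analytic editing factor
  ε = sin(2πJτ_H)·sin(2πJτ_N)·cosⁿ⁻¹(2πJτ_N), its delays (NH₂ null at
  1/(4J), maximum at 1/(8J)), relaxation attenuation 1 − exp(−2τ_H/T₂′),
  and a density-matrix simulator that verifies all of it to 10⁻⁶;
* **relaxometry** — mono-exponential fits (minpack.lm) with
  leverage-adjusted wild-bootstrap 2σ errors;
* **ladder criteria** — a transparent, threshold-configurable classifier
  (rigid_ladder / flexible / non_ladder / insufficient) with a full
  criteria trace, including the ring-current exception for
  aromatic-shielded glutamines;
* **synthetic data** — an idealized, hydrogen-bond-aligned amide-ladder
  geometry generator (labelled synthetic; no structure download needed),
  noisy decay curves, and per-residue observables tables.

## Worked example

Build the synthetic three-layer NH₂ ladder (six protons), simulate its
spin-echo decay at 110 kHz MAS, and fit the coherent homogeneous linewidth:

```r
library(ladderNMR)

pdb <- tempfile(fileext = ".pdb")
make_ladder_pdb(ladder_geometry_spec(n_layers = 3), pdb)
sys <- build_spin_system(read_pdb_sites(pdb, 1, ladder_proton_selectors(3)))
print(sys)
#> <spin_system> 6 sites (6 x 1H), 15 dipolar pair(s) above 50 Hz, 0 scalar J, B0 = 20 T

cond <- mas_conditions(spinning_rate = 110e3, n_crystallites = 233)
sch  <- rotor_synchronized_grid(cond, 0.06, n_points = 12)
fit  <- fit_decay_linewidth(simulate_echo_decay(sys, cond, sch))
round(fit$delta_homo, 2)
#> [1] 0.91
```

The resolved ladder resonance decays with Δʰᵒᵐᵒ ≈ 0.9 Hz — the coherent
dipolar network of an intact ladder is orders of magnitude too weak to
explain the ~100–160 Hz homogeneous linewidths measured on fibrils, which
must therefore be dominated by incoherent (motional/exchange)
contributions. The editing side of the analysis:

```r
signif(suppression_delay(92) * 1e3, 2)   # tau_N that suppresses NH2
#> [1] 2.7
signif(nh2_max_delay(92) * 1e3, 2)       # tau_N that maximizes NH2
#> [1] 1.4
relaxation_attenuation(inept_params(J = 92, tau_H = 2e-3, T2prime_H = 2e-3))
#> [1] 0.8646647
```

so a side-chain broadened to 160 Hz (T₂′ ≈ 2 ms) loses ~87% of its INEPT
signal and disappears from J-based spectra, while narrow glutamines
survive. Classification of the six measured side-chains
(`classify_table(make_observables_table("hets_table1"))`) returns
rigid_ladder for N226/N262, flexible for N243/N279/Q259, and non_ladder
for Q240 (its 2.9 ppm shift difference comes from a ring-current-shielded
proton, not a hydrogen bond).

The `analysis/` directory holds the numbered drivers that run the whole
study end to end (`01_build_ladder_system.R` … `06_full_pipeline.R`),
writing their tables under `results/`. The methods vignette
(`vignettes/ladder-spin-dynamics.Rmd`) documents the model, conventions,
detection observables, and limitations.

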