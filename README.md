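# brushmech

Mechanics analysis for injectable bottlebrush elastomers — soft,
solvent-free networks designed to match the softness and firmness of
biological tissue. The package is aimed at materials scientists and
biomechanics groups who characterize such gels with three bench
instruments: uniaxial tensile testing, oscillatory rheology during cure,
and double-compression texture profile analysis (TPA). It turns each raw
instrument table into the quantities used to design and compare
formulations, and ships seeded synthetic generators so every stage is
testable without instrument data.

## The model

Uniaxial true stress of a strain-stiffening brush network follows the
equation of state

    σ_true(λ) = (E/9)(λ² − λ⁻¹)[1 + 2(1 − β(λ² + 2λ⁻¹)/3)⁻²]

with two mechanical characteristics:

* **E** (kPa) — the *structural modulus*, set by crosslink density;
* **β** ∈ (0, 1) — the *firmness parameter*, β = ⟨R_in²⟩/R_max², the
  squared ratio of a network strand's initial end-to-end distance to its
  contour length. β sets how violently the network stiffens as strands
  approach full extension.

Derived quantities:

* Young's modulus (softness): `E₀ = (E/3)(1 + 2/(1 − β)²)` — the λ→1
  slope of the curve;
* theoretical elongation at break: `λ_max = β^(−1/2)`;
* architectural scaling law: `E ∝ β/(1 + n_sc)^{3/2}`, where `n_sc` is
  the side-chain degree of polymerization — the lever that decouples
  softness from firmness.

`fit_constitutive()` estimates (E, β) from a measured curve by bounded
Levenberg–Marquardt least squares; `find_gel_point()` locates the cure
time where G′ first (and sustainedly) exceeds G″; `tpa_metrics()`
computes springiness, resilience, and cohesiveness from force–time
traces; `calibrate_scaling()` and `propose_architectures()` invert the
scaling law to suggest `[n_x, n_sc]` architectures for target (E₀, β).

## Worked example

```r
library(brushmech)

# a noisy synthetic tensile curve with known ground truth E = 4.2 kPa, β = 0.10
tg  <- gen_tensile(E = 4.2, beta = 0.10, n_points = 60,
                   noise = "multiplicative", noise_sd = 0.02, seed = 7)
fit <- fit_constitutive(tg$curve)
print(fit)
#> Constitutive fit [synthetic-tensile]:
#>   E = 4.234 kPa, beta = 0.09898  (converged)
#>   E0 = 4.889 kPa, lambda_max,theo = 3.18, lambda_max,exp = 3.16
#>   rmse = 0.192 kPa (relative 0.0165), 6 iterations

gel <- find_gel_point(gen_rheology(t_gel = 600, n_points = 200)$sweep)
print(gel)
#> Gel point [synthetic]: t_gel = 600 s, G_cross = 11.1 Pa
#>   bracket [600, 612] s, 1 crossing(s) examined

print(tpa_metrics(gen_tpa()$trace))
#> TPA metrics: springiness 1, resilience 1, cohesiveness 1
#>   peaks 1 / 1 N; areas (N s) down/up: 0.5/0.5, 0.5/0.5
```

The fit recovers the generating parameters to about 1 % under 2 %
multiplicative noise (E = 4.234 vs 4.2 kPa; β = 0.099 vs 0.10); E₀ ≈ 4.9
kPa is the tissue-facing softness, and λ_max,theo ≈ 3.2 says strands
allow ~220 % extension before finite extensibility cuts in. The gel
point lands exactly on the constructed crossover, and an ideal elastic
TPA trace scores 1 on all three texture metrics.

A reference table of eleven published formulations is packaged
(`reference_table()`); `verify_table1()` recomputes its derived E₀ and
λ_max columns from the printed (E, β) cells and reports one-decimal
agreement per row. A thin command-line wrapper for all stages lives at
`inst/cli/brushmech` (`fit`, `gelpoint`, `tpa`, `design`, `simulate`,
`verify-table1`).

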