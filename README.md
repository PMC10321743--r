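# spidr — weak-form sparse discovery of active-nematic hydrodynamics

`spidr` identifies the governing equations of a two-dimensional active
nematic — a film of driven, elongated, apolar units such as kinesin-driven
microtubule bundles at an oil–water interface — directly from gridded
director and velocity field data.  It is aimed at experimentalists and
modelers who have `n(x, y, t)` (from orientation analysis of microscopy
stacks) and `u(x, y, t)` (from particle image velocimetry) and want the
continuum model these data actually obey, rather than a model assumed from
molecular liquid-crystal theory.

## Method

Candidate terms `F^r(u, n)` are generated symbolically from the fields and
their derivatives, grouped into libraries by tensor rank, nematic parity
(`n -> -n`) and irreducible symmetry class, and evaluated in *weak form*:
each term is integrated against smooth compactly supported weights
`(1-x²)^τ (1-y²)^τ (1-t²)^τ · cos(πx_m - θ) · ψ` over randomly placed
space-time subdomains, with derivatives moved off the noisy data by parts
and a mask `ψ` excluding defect cores and dark regions.  The rows form a
homogeneous system `G c = 0`; sequentially thresholded regression on the
minimum-singular-vector solution, validated by half-sample resampling and
exhaustive small-support search, extracts parsimonious relations

    Σ_r c_r F^r = 0 ,   η = ‖Gc‖₂ / Ξ  small,

with per-coefficient uncertainties from 100 half-row refits, and each
relation classified as an identity (holds on any smooth fields) or a
physical relation (holds only on this system's data).  On its validation
fixtures the pipeline recovers the incompressibility condition `∇·u = 0`,
the director evolution equation
`∂ₜn + c₁(u·∇)n + c₂Ωn + c₃P⊥Ān = 0`, and the stress balance
`(Ā:Q̄)Q̄ + c₅Q̄ = 0` with its scalar form `Q̄:Ā + c₅′ = 0`, where
`Q̄ = nn - δ/2` and `Ā`, `Ω` are the traceless-symmetric and antisymmetric
velocity-gradient parts.

## Worked example

Plant the stress balance in an extensional flow with extension rate
`E = 0.56` and rediscover it:

```r
library(spidr)

fx  <- make_fixture("stress-balance", n = 48, E = 0.56)
nd  <- nondimensionalize(fx$fields)
lib <- standard_library(0, "even")          # scalar, even in n
fm  <- build_feature_matrix(lib, nd$fields, seed = 9)
rep <- discover_all(fm)
print(rep)
```

```
discovery_report: 6 relation(s)
   [d_a u_a d_b u_b] = 0    [eta = 5.01e-17, unclassified]
   ...
   [d_a u_a] = 0    [eta = 0.000145, unclassified]
   -0.914 [1] + [n_a n_b d_a u_b] = 0    [eta = 8.23e-17, unclassified]
   ...
```

The single-term relation `d_a u_a = 0` is the incompressibility condition
(weak residual about 1e-4 of the velocity-gradient scale).  The two-term
relation says `Q̄:Ā = n_a n_b ∂_a u_b = 0.914` in nondimensional units;
dividing by the returned time scale (`nd$scales$time = 1.63`) recovers the
planted extension rate 0.56, i.e. `c₅′ = -0.56`.  On the noisy
director-dynamics fixture the same pipeline returns the evolution-equation
coefficients `(c₁, c₂, c₃) = (1, -1, -1)` within a few percent with
half-sample uncertainties near 1 %.

A thin command-line front end mirrors the workflow
(`inst/cli/spider.R synthesize | discover | report | check`), reading
long-format CSV fields and writing JSON reports.

The package also carries the post-discovery physics: active and anisotropic
viscous stress maps, strong-form residual maps of discovered relations, the
Rayleigh friction coefficient `η_f = μ_t/h_t + μ_b/h_b` of the bounding
fluid layers, and the buckling length
`L = r ((h/r)·E_Y/(μ·Ė))^{1/4}` of extending bundles, which for
microtubule parameters (`r = 25 nm`, `E_Y = 1e8 Pa`, `μ = 1e-3 Pa s`,
`h = 50 µm`, `Ė = 0.015 s⁻¹`) evaluates to about 270 µm — the observed
same-charge defect spacing scale.

See `vignettes/weak-form-discovery.Rmd` for the full account of the model,
the weight construction, the regression and validation rules, and the
synthetic fixtures.

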