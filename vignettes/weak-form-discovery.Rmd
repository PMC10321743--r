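---
title: "Weak-form sparse discovery of active-nematic hydrodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak-form sparse discovery of active-nematic hydrodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A dense film of kinesin-driven microtubule bundles at an oil-water interface
is an *active nematic*: its units are elongated, apolar (the director `n` is
physically the same as `-n`), and continuously driven, so the film flows
spontaneously.  Which continuum equations govern the measured director field
`n(x, y, t)` and interfacial velocity `u(x, y, t)` is not known a priori:
classical liquid-crystal models (Leslie-Ericksen, Beris-Edwards) were derived
for three-dimensional molecular nematics and carry a dozen coefficients, few
of them measurable.

`spidr` implements the alternative: identify the governing relations
*directly from field data*, constrained only by locality, smoothness and
symmetry.  Candidate terms are generated symbolically, grouped into libraries
with identical transformation behavior, evaluated in weak form, and pruned to
parsimonious relations

\[
\sum_r c_r F^r(\mathbf u, \mathbf n) = 0
\]

by sequentially thresholded regression on the singular-value problem
\(G c = 0\).  On data from this system the method identifies an
incompressibility condition, a director evolution equation

\[
\partial_t n_i + c_1 u_a \nabla_a n_i + c_2 \Omega_{ia} n_a +
c_3 P^\perp_{ia} \bar A_{ab} n_b = 0,
\]

and a local stress balance \((\bar A\!:\!\bar Q)\,\bar Q_{ij} + c_5 \bar Q_{ij} = 0\)
between an anisotropic viscous stress and an extensile active stress, with a
scalar corollary \(\bar Q\!:\!\bar A + c_5' = 0\).  Here
\(\bar Q_{ij} = n_i n_j - \delta_{ij}/2\), \(\bar A\) and \(\Omega\) are the
traceless-symmetric and antisymmetric parts of \(\nabla_i u_j\), and
\(P^\perp = \delta - n n\).

## Symbolic libraries

Terms are products of `u`, `n` and their derivatives with all inequivalent
index contractions, canonicalized (contracted indices renamed in first-use
order, factors sorted, derivative labels sorted since partials commute) and
simplified with the unit-director identities \(n \cdot n = 1\) and
\(n \cdot \partial n = 0\); second-derivative contractions are rewritten with
the product rule.  Each library fixes a tensor rank (0-2), a nematic parity
(even or odd power of `n`), and for rank 2 an irreducible symmetry class
(symmetric traceless or antisymmetric), because all terms of a relation must
transform identically under rotations and under `n -> -n`.

The grammar bounds are the package's choice: at most 5 field factors and 2
derivative orders (1 in time), with the extra restriction that terms with
more than two field factors carry at most one derivative.  These are the
smallest bounds that contain every term of the relations above — the aligned
strain coupling \(n_i n_a \bar A_{ab} n_b\) has four field factors and the
tensor stress coupling five — while still admitting candidate elastic terms
(\(\nabla^2 n\), \(|\nabla n|^2\), Frank-type gradient products), whose
*absence* from the discovered relations is a physical finding, not a modeling
assumption.  The bounds keep libraries at a few tens of terms, the scale at
which exhaustive combinatorial validation of a selected support is exact.
All bounds are configurable in `library_spec()`.

Levi-Civita (chiral) terms are excluded by default: the system is treated as
reflection symmetric.  The projector and nematic tensor are not primitive
factors; they are reachable as combinations (`Pperp = delta - nn`,
`Qbar = nn - delta/2`), which keeps the grammar minimal.  A discovered
relation is mapped back to the field's notation by
`director_equation_coefficients()` and `render_relation()`.

In two dimensions the unit director satisfies nonobvious *algebraic*
identities — for example the symmetrized projection of
\(\bar A n \otimes n\) equals \(\bar A / 2\), and
\((\nabla\!\cdot\!n)^2 = (\partial_a n_b)(\partial_b n_a)\) — which a
rule-based simplifier does not see.  The package therefore deduplicates
numerically: every term is evaluated on several band-limited random field
sets with spectral derivatives, and terms whose sample vectors lie in the
span of earlier terms (relative tolerance 1e-6) are removed and logged.
Identities that relate *retained* terms remain discoverable as
machine-precision relations, exactly as on experimental data.

## Weak formulation

Each candidate PDE is tested against weight functions
\(w = (1-x^2)^\tau (1-y^2)^\tau (1-t^2)^\tau \times m \times \psi\) on
rectangular subdomains mapped to \([-1,1]^3\), with \(\tau = 4\), modulation
\(m \in \{1, \cos(\pi x - \theta_x), \cos(\pi y - \theta_y),
\cos(\pi t - \theta_t)\}\) with independent random phases, and the
reliability mask \(\psi\).  Derivatives on single-field terms are moved onto
the weight by integration by parts (no boundary terms: the envelope vanishes
with \(\tau - 1\) derivatives); derivatives locked inside products stay on
the data.  Integrals use the trapezoidal rule, which is effectively
spectrally accurate here because the envelope kills all boundary terms of
the Euler-Maclaurin expansion up to high order.  Each (subdomain, weight,
tensor component) triple is one row of the feature matrix `G`; the default
row budget is ten rows per library column.

Subdomain extents default to 54 x 54 x 65 points on a 128 x 128 x 1000
mesh — the scale of the experimental data sets this pipeline targets — and
scale down proportionally (floor 9 points) on smaller grids.  On the cubic
64-point fixture grids used throughout the tests, the *study configuration*
instead passes explicit 36^3 extents (56 % of each axis): with 20 % noise on
a 64-frame series, each weak integral must average enough samples along every
axis for the planted-relation residual (about 0.05 there) to sit well below
the acceptance threshold while subdomains remain meaningfully distinct.
That trade-off is a property of short fixture series, not of the method.

Two numerical details matter for the nematic data.  First, the director is
stored with arbitrary signs; inside each subdomain the package sign-aligns
it by a deterministic sweep (with the overall sign fixed by the mean
direction), so every row of `G` is invariant under arbitrary stored-sign
flips away from defects.  Masked defect cores are exactly the places where
no consistent alignment exists.  Second, the single-term scale
\(\Xi_r\) — the Frobenius norm of the weak integrals of the term's leading
monomial with *all* indices opened — is stored per column: it normalizes
single-term residuals (for the incompressibility relation,
\(\Xi = \lVert \nabla u \rVert_2\)) and flags degenerate columns (a steady
field's time-derivative columns) that would otherwise present as spurious
exact relations.

## Regression

The solve is the right singular vector of `G` for its smallest singular
value, computed in column-normalized coordinates (each column scaled to unit
2-norm, coefficients mapped back): without that scaling the minimizer of
\(\lVert G c \rVert\) drifts toward small-norm columns instead of genuine
cancellations.  Sequentially thresholded regression drops the term with the
smallest \(\lVert c_r G^r \rVert_2\) (ties: the later term in canonical
order) and stops when only one term remains or the residual
\(\eta = \Xi^{-1} \lVert G c \rVert_2\) jumps by more than \(\gamma = 1.15\)
(robust over 1.1-1.3); jumps below an absolute floor of 1e-9 are ignored so
that exactly satisfied relations prune fully instead of freezing at rounding
noise.  Multi-term residuals normalize by the largest term
\(\max_r \lVert c_r G^r \rVert_2\); a single-term survivor is re-normalized
by its \(\Xi_r\) before acceptance (threshold 0.1 by default).

Discovery iterates: columns that are relations by themselves (single-term
residual below the acceptance threshold) are reported and removed first —
on exactly divergence-free synthetic data those columns are numerically zero
and would otherwise make the multi-term normalization 0/0 degenerate — then
STR runs repeatedly, removing the largest term of each accepted relation,
until the full remaining library's residual exceeds 0.4.

A candidate relation must also *validate* before it is accepted: its
coefficients are refit on 40 random half-row subsamples, and a candidate
whose coefficients swing by more than 5 % SD is treated as a noise-enabled
overfit, not a relation.  (On noisy data with a few hundred partially
overlapping subdomains, many-term combinations can reach residuals in the
same 0.05-0.1 band as a genuine relation, but only the genuine one keeps its
coefficients under resampling — planted relations sit near 1 % SD, overfit
combinations near 20-30 %.)  When the STR path fails validation — its greedy
pruning order is not guaranteed to be optimal — the search escalates to the
exact combinatorial optimum over all supports of size 2 to 4, the regime in
which exhaustive search is tractable, and accepts the first validated
optimum.  Only after a relation passes does pruning remove its largest term;
this protects the support of a still-undiscovered relation from being eaten
by a noise artifact found earlier.

Each accepted relation is classified by re-evaluating it on band-limited
random periodic fields: identities (consequences of \(|n| = 1\) and index
algebra) hold at rounding level on any smooth fields, physical relations
fail on generic compressible probe flows.  Classification needs the probe
residual of true identities below 1e-6, which fixes two probe-generator
choices: derivatives are spectral (exact for band-limited fields), and the
director-angle amplitude defaults to 0.3 rad so that the trigonometric
harmonics of the angle stay below double-precision rounding at the grid
Nyquist mode.  Coefficient uncertainty follows by refitting the fixed
support on 100 random half-row subsamples and reporting mean and SD.

## Synthetic fixtures

The generators plant known physics so that every stage is testable without
experimental data:

* `incompressibility` — a two-mode, time-modulated vortex lattice from a
  stream function (exactly divergence-free, including under the discrete
  stencils) with a gently drifting smooth director.  Two superposed
  wavenumbers avoid the Laplacian-eigenfunction degeneracy of a single mode,
  which would plant spurious exact relations.
* `director-dynamics` — the same flow family advecting and rotating the
  director under planted coefficients \((c_1, c_2, c_3) = (1, -1, -1)\),
  integrated as an angle field with RK4 and spectral spatial derivatives
  (stepper error far below the discovery floor).  Noise, when requested, is
  20 % by default: Gaussian with SD 0.2 x RMS on each velocity component and
  0.2 rad on the director angle.
* `stress-balance` — an extensional stream-function flow
  \(\psi = E x y + f(x) + g(y)\) with extension rate `E = 0.56`, cubic mean
  flow (so the vorticity is nonzero and nondimensionalization is defined)
  and uniform director, which satisfies the stress balance exactly with
  \(c_5 = -E\) in physical units.
* `defect-mask` — an isolated +1/2 defect with an intensity hole, for the
  masking path.

Fixture grids are 64^3 by default with `max |u| dt / dx` about 0.2.  What the
fixtures do *not* emulate: defect creation and annihilation, density
evolution, long-range hydrodynamic screening by the bounding layers, and
camera noise statistics beyond additive Gaussian — so passing tests validate
the discovery machinery, not the full phenomenology of the experiment.

## Preprocessing conventions

One index convention is used everywhere, in generation and analysis alike:
\(\nabla_i u_j\) is the derivative along `i` of component `j`,
\(A = (\nabla u + \nabla u^T)/2\), \(\Omega = (\nabla u - \nabla u^T)/2\),
and the scalar vorticity is \(\omega = -2 \Omega_{xy}\).  Discovered
coefficients are convention-independent up to the corresponding signs.

Smoothing is moving least squares: degree-2 local polynomial fits over
5-point windows, implemented as sequential one-dimensional Savitzky-Golay
filters along x, y, t with shifted windows at the boundaries — exact on
multivariate quadratics everywhere, which is precisely the class the
second-order centered differences differentiate exactly.  The director is
smoothed through the nematic tensor components (gauge invariant), then
re-extracted.  Nondimensionalization rescales length and time so the
mask-weighted mean speed and mean absolute vorticity are both 1; reported
constants are converted back through the returned scales.

The mask starts from the Boolean condition (intensity at least 0.15 of its
maximum AND director-gradient norm at most twice its median, with a small
absolute floor so rounding-level gradients of uniform directors are kept),
then 10 passes of a 5-point box filter per axis smooth it into
\(\psi \in [0, 1]\).  Raw image stacks can be reduced to `(n, phi)` with a
Gaussian structure-tensor orientation estimator; points with a near-isotropic
tensor are flagged invalid for the mask.  This estimator is a deliberate
simplification of full coherence-enhancing diffusion filtering and is
documented as such.

## Degenerate inputs and tie-breaks

Sign ties in director alignment break toward +; STR magnitude ties drop the
later term in canonical order; an exactly zero vorticity field refuses to
nondimensionalize (the extensional fixture therefore carries a mean flow);
columns with negligible \(\Xi\) are excluded and logged; subsamples that are
rank deficient during uncertainty estimation are skipped and counted.

## Known limitations

* The weak form assumes a regular grid; scattered data would need
  re-meshing.
* Director sign alignment inside a subdomain containing an unmasked defect
  core is impossible in principle; discovery there relies on the mask.
* The identity/physical classification is numerical: a physical relation
  that happens to hold for all band-limited probe flows would be mislabeled
  (none of the candidate spaces searched here contain such a relation).
* Library bounds are finite by design; a governing term outside the grammar
  (nonlocal, non-polynomial, or higher-derivative) cannot be found.

## Problem sizes used in the shipped analyses

The packaged analyses and tests run fixtures at 64^3 (headline recovery,
incompressibility) and 24^3-48^3 (unit tests), with 60-150 subdomains per
library, 100 half-sample resamples, and three probe field sets per
deduplication or classification — sizes chosen so a full validation run
completes on a laptop-class single core in minutes while leaving each
statistical check (noise robustness, uncertainty scale, seed stability)
comfortably resolved.
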