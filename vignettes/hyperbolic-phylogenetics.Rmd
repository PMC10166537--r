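---
title: "Methods: Bayesian phylogenetics on the hyperboloid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian phylogenetics on the hyperboloid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the model it implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, the numerical conventions, and the design choices that were genuinely
open. It states no empirical claim that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model

### Posterior

Given an alignment `Y` of nucleotide sequences, the target is the
unnormalised posterior over unrooted binary trees `T` (topology and branch
lengths), `p(T | Y) ∝ p(Y | T) p(T)`.

* **Likelihood** `p(Y | T)`: Jukes-Cantor (JC69) substitution — uniform base
  frequencies, a single exchange rate, transition probabilities
  `p_same(t) = 1/4 + (3/4) e^{−4t/3}` and `p_diff(t) = 1/4 − (1/4) e^{−4t/3}`
  for a branch of `t` expected substitutions per site — evaluated by
  Felsenstein pruning over compressed site patterns (`src/core.cpp`). Gaps
  and ambiguity codes are treated as fully missing (all-ones partials), the
  simplest JC69-consistent reading. JC69 has no free parameters, so the tree
  alone determines the likelihood; richer models (GTR etc.) would need extra
  MCMC coordinates outside the embedding and are not implemented.
* **Prior** `p(T)`: uniform over topologies (the constant is implemented as
  0 on the log scale — it cancels in every Metropolis ratio over a fixed
  taxon set) with a Gamma(shape α = 1, rate β = 0.1) distribution on the
  total tree length `TL = Σ l_e` and a symmetric Dirichlet(1) on the
  proportions `p_e = l_e / TL`. The prior is *specified* on `(TL, p)` but
  *evaluated* on branch lengths, which requires the change-of-variables
  factor `TL^{−(K−1)}` for `K` edges; omitting it would silently bias
  Metropolis ratios under moves that change `TL`. With the defaults the
  implied marginal on `TL` is Exponential(0.1), i.e. a mean total length of
  10 substitutions/site — a deliberately weak prior.
* An alternative `embedding_normal` prior mode replaces the tree prior with
  independent standard Normal densities on every tangent coordinate of the
  embedding. It sidesteps the embedding-to-tree change of variables entirely
  (see *Known limitations*), at the cost of a prior that is hard to compare
  with mainstream tree priors.

### State space: the hyperboloid model

Each of the `n` taxa is a point on the upper sheet
`H^d = {x : ⟨x,x⟩ = −1, x0 ≥ 1}` under the Lorentz form
`⟨x,y⟩ = −x0 y0 + Σ_{i≥1} x_i y_i`. Only the `d` free coordinates are stored;
`project_up()` recomputes the time-like coordinate exactly. Distances carry
the curvature through a single scale factor,
`d_κ(x,y) = acosh(−⟨x,y⟩)/sqrt(−κ)`; the sheet itself is fixed at
`⟨x,x⟩ = −1` for all `κ`. Consequences used throughout:

* the four-point-condition violation (Gromov delta, `four_point_delta()`)
  scales exactly as `δ_{d,κ} = δ_{d,−1}/sqrt(−κ)`, so negative enough
  curvature makes any fixed configuration's distances arbitrarily close to
  additive;
* neighbour joining decodes a *unique, stable* topology whenever the
  distances are within half the minimum edge length of an additive matrix
  (its l∞ robustness radius), and within that regime the decoded tree length
  is continuous in the embedding locations, even across topology changes.

`κ = 0` selects a plain Euclidean metric on the tangent coordinates — an
explicit separate branch, since the hyperbolic formula degenerates as
`κ → 0`. Euclidean mode is provided for comparison; the test suite asserts
only that it runs and produces valid traces, not that it is a good sampler.

### Encoding (embedding a distance matrix)

`embed_hydraplus()` initialises the chain: given target distances `D` (JC69
sequence distances, or path distances of a start tree), it first solves the
strain (eigen) problem — form `A = cosh(sqrt(−κ) D)`, take the `d` spatial
coordinate vectors from the eigenvectors of the `d` most negative eigenvalues
scaled by `sqrt(max(−λ, 0))`, and renormalise every point onto the sheet —
then refines by gradient descent on the stress
`σ² = Σ_{i<j} (D_ij − d_κ(x_i, x_j))²` with backtracking line search
(analytic gradient in the tangent coordinates). The refinement never
increases the stress relative to its own initialisation; two points always
embed exactly, and configurations that are realisable in `H^d` round-trip to
numerically zero stress. Tree metrics are generally *not* exactly realisable
in low-dimensional hyperbolic space, so the embedding of an additive matrix
retains a small residual stress — what matters for decoding is that the
residual stays inside the NJ robustness radius, which the topology-recovery
tests check directly.

`place_taxon()` implements the constant-time placement of a new taxon into an
existing embedding: each distance constraint linearises to
`⟨z_i, z'⟩ = −cosh(sqrt(−κ) d*_i)`, giving the linear system
`S H z' = −cosh(sqrt(−κ) d*)`, solved exactly for `q = d + 1` reference
points and by least squares for `q > d + 1`, then re-projected to the sheet
by recomputing the time coordinate. The right-hand side carries the minus
sign required by the defining relation `⟨x,y⟩ = −cosh(sqrt(−κ) d)` for
on-sheet points; the round-trip recovery tests (100 random trials in
`d ∈ {2,3}`) pin this convention down.

### Decoding and sampling

Every generation, for every chain:

1. **Propose**: `vec(X') = vec(X) + S z`, `z ~ N(0, I_{nd})`, a single joint
   Gaussian move of all coordinates with the chain's lower-triangular scale
   factor `S`. The proposal is symmetric, so no Hastings ratio appears.
2. **Decode**: pairwise `d_κ` distances, then neighbour joining — standard
   Q-criterion agglomeration with the usual branch-length formulas. Ties in
   the Q matrix are broken by the lexicographically smallest index pair and
   negative branch-length estimates are clamped to zero, making the decoding
   a deterministic function of the coordinates (important: the posterior is
   defined through this map). A decoded zero-length branch is a valid state;
   the prior density handles support (`TL = 0` maps to −Inf and is rejected).
3. **Score and accept**: `min(1, exp(β (log p' − log p)))` on the tempered
   unnormalised log posterior. *No Jacobian* for the embedding-to-tree map is
   applied: the coordinates-to-distances stage has a structurally zero
   Jacobian determinant (each distance depends on only two points, and
   isometric configurations decode identically) and NJ is non-differentiable,
   so no usable correction exists. This is a known, deliberate property of
   the algorithm, with a visible consequence (below).

**Adaptation.** During the warm-up the proposal factor is the Cholesky factor
of the empirical covariance of the chain's states scaled by `2.38²/(nd)`
(refreshed every 100 generations, initialised at `0.01² I`, with a `1e-10`
ridge) — the standard adaptive-Metropolis warm-up. Afterwards `ram_adapt()`
performs robust adaptive Metropolis: a rank-one update of `S Sᵀ` in the
direction of the last increment with magnitude `η_i (α − α*)`,
`η_i = min(1, nd · i^{−2/3})`, steering acceptance toward `α* = 0.234` (the
standard multivariate target) with diminishing adaptation.

**Coupling.** Chain `i` runs at inverse temperature `β_i = 1/(1 + λ(i−1))`
with `λ = 0.1` (the ladder convention of mainstream MC³ software; the
coupling scheme itself leaves it free). Every `swap_interval` generations,
`swaps_per_interval` adjacent-pair exchanges are attempted with probability
`min(1, exp((β_i − β_j)(log p_j − log p_i)))`; temperatures stay attached to
chain slots and only the cold chain (`β = 1`) is recorded, thinned to
`n_samples` evenly (floor-)spaced post-warm-up generations.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `curvature` κ | −1 | metric scale; distances shrink as `1/sqrt(−κ)` |
| `dimension` d | 3 | tangent coordinates per taxon |
| `generations`, `warmup` | —, 1e4 | MCMC length; warm-up tunes covariance |
| `n_chains`, `temp_lambda` | 4, 0.1 | MC³ chains and ladder increment |
| `swap_interval`, `swaps_per_interval` | 1e3, 10 | swap cadence |
| `n_samples` | 1e4 | retained, evenly spaced cold-chain samples |
| `gamma_shape`, `gamma_rate` | 1, 0.1 | prior on total tree length (subst./site) |
| `dirichlet_alpha` | 1 | prior concentration on branch proportions |
| `ram_target` | 0.234 | RAM acceptance target |
| `max_distance` (JC69 cap) | 10 | subst./site for saturated pairs |

Curvature guidance follows the behaviour the instruments in this package make
visible: near `κ = 0` the four-point violation is large, NJ decoding loses
stability and split estimates degrade; at strongly negative κ the space is so
local that topology moves become rare and coordinates grow exponentially (see
*Numerical choices*). Moderate negative curvature (order −1 to −100 for
substitutions-per-site distance scales) with `d = 3` is the sensible default.

## What the synthetic-data generator emulates

`random_tree()` draws uniform unrooted binary topologies (sequential random
attachment: each new taxon subdivides a uniformly chosen edge) with i.i.d.
Exponential branch lengths of mean 0.1 substitutions/site — the short-tree
regime of curated benchmark alignments. `simulate_alignment()` evolves i.i.d.
sites under exactly the JC69 kernel the likelihood uses;
`additive_distances()` and `perturb_distances()` provide exact tree metrics
and l∞-bounded perturbations for the decoder suites.

What it deliberately does **not** emulate: among-site rate variation, indels
and alignment error, ambiguity codes, non-uniform base composition,
non-homogeneous processes, and linked loci. Passing tests therefore
demonstrate correctness of the machinery *under its own model* — a sampler
that matches an independent tree-space Metropolis baseline on JC69 data — not
robustness of JC69 to real-data violations.

Validation problem sizes are the package's own choice of desk scale: 5-taxon
alignments of 500 sites with internal edges of 0.1 substitutions/site, 1e5
generations, 2000 retained samples, three replicate datasets, and a single
chain (`β = 1`). On 5-taxon problems one chain mixes fully — chain count is a
compute knob, not a model parameter — while the 4-chain default reflects the
regime of realistic data sizes (tens of taxa).

## Numerical choices

* `acosh` arguments are clamped to `[1, ∞)` before evaluation, absorbing
  rounding for near-coincident points.
* NJ tie-breaks are lexicographic; negative NJ length estimates (including
  internal agglomeration distances) clamp to 0. Additive inputs never
  trigger the clamps.
* JC69 distance saturation (`p ≥ 3/4`) maps to the `max_distance` cap rather
  than erroring, so arbitrary alignments embed; pairs with *no* comparable
  sites are an error naming the pair.
* `κ = 0` embedding requests are carried out at `κ = −1e-10` (a minuscule
  curvature standing in for the flat limit) before the Euclidean-metric MCMC
  takes over.
* Stress refinement stops at `max_iterations = 1000` or relative improvement
  below `1e-8`; backtracking halves the step until an Armijo condition holds.
* **Curvature conditioning**: on-sheet coordinates grow like
  `exp(sqrt(−κ) r / 2)` for unit-sheet radius r, and the Lorentz product of
  two far-from-origin points is a difference of huge, nearly equal terms.
  At `κ = −1000` this limits reliable use to short trees (pairwise path
  distances up to a few tenths of a substitution per site — the regime of
  the benchmark datasets this method targets); with unit-scale distances use
  moderate curvature. The continuity suites run in this short-tree regime.
* The pruning likelihood does not rescale partials per node; for the taxon
  counts this package targets (tens of taxa) per-site likelihoods stay far
  from the double-precision underflow boundary.

## Open design decisions

* **Warm-up schedule and RAM constants** (update cadence, `2.38²/nd` scaling,
  0.234 target) follow the standard adaptive-Metropolis literature; they are
  exposed in the configuration rather than hard-coded convictions.
* **Adjacent-pair swaps** were chosen over uniform-pair selection; with a
  geometric-like ladder adjacent swaps carry almost all acceptance mass.
* **Uniform-topology constant** implemented as 0: whether it includes the
  `1/(2n−5)!!` normaliser is unobservable in Metropolis ratios.
* **Taxon placement sign convention**: the linearised placement system is
  solved with the `−cosh` right-hand side that follows from the defining
  relation of the metric; the round-trip tests are the arbiter.
* **Repository shape**: core objects (alignments, `phylo` trees, coordinate
  matrices) are not tabular, so the package follows the ape/phangorn style;
  the genuinely tabular surfaces — traces, split tables, scans — return
  tibbles and come with `tidy()`/`glance()`/`autoplot()` methods.

## Known limitations

* The missing decoding Jacobian means the sampler targets the pullback of
  the tree posterior through a many-to-one map: each topology is implicitly
  reweighted by the embedding volume that decodes to it. In the regime the
  method is intended for — data that resolve the topology — this is
  invisible (the validation suite checks split-frequency agreement with a
  tree-space Metropolis sampler there) and the visible symptom is a tendency
  to overestimate branch lengths. In weakly resolved problems (internal
  edges near zero, short alignments) the volume reweighting can move split
  frequencies measurably away from a tree-space sampler's; the comparison is
  easy to reproduce with `run_mcmc()` vs `run_vanilla_mcmc()` on a
  `simulate_alignment()` fixture with a near-zero internal edge. The
  `embedding_normal` prior mode avoids the issue by defining the posterior
  directly on coordinates, at the cost of comparability.
* JC69 only; no rate heterogeneity, no rooted/clock trees (NJ decodes
  unrooted topologies; ultrametric decoders would need stronger conditions
  than hyperbolicity provides).
* Euclidean mode (`κ = 0`) is a comparison baseline, not a recommended
  sampler.
* `four_point_delta()` enumerates all `C(n,4)` quadruples — fine for the
  diagnostic range (n ≤ ~64), quartic beyond it.
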