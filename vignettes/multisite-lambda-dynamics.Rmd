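---
title: "Multisite lambda-dynamics on reduced Hamiltonians: model, flattening and estimators"
author: "msldyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multisite lambda-dynamics on reduced Hamiltonians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msldyn)
```

## 1. What the package computes

Multisite λ-dynamics (MSλD) estimates relative free energies between many
chemical endstates from a single simulation by making the alchemical
coupling variables λ dynamical. For protein–DNA binding the observable is
the change in binding free energy upon mutating the DNA,

$$\Delta\Delta G_b(S_1 \to S_2)
  = \Delta G_{mut}^{bound} - \Delta G_{mut}^{unbound},$$

a thermodynamic-cycle identity that replaces two hard binding legs by two
tractable alchemical legs. `msldyn` implements the whole chain — composite
potential, implicit constraints, Langevin sampling, adaptive landscape
flattening (ALF), endstate binning, population estimator with bootstrap
errors, cycle assembly — on *reduced model Hamiltonians* whose exact
answers are computable by quadrature, so every stochastic estimate in the
test suite is checked against an independent oracle.

## 2. The reduced composite potential

At full atomistic resolution the composite MSλD potential contains
environment self-interactions, substituent–environment terms scaled
linearly by $\lambda_{si}$, and substituent–substituent terms between
different sites scaled by $\lambda_{si}\lambda_{tj}$. The reduced model
keeps exactly this algebraic structure and collapses each Cartesian
interaction integral to a scalar:

$$V(\lambda) = E_{env}
  + \sum_{s,i} \lambda_{si}\, h_{si}
  + \sum_{s<t}\sum_{i,j} \lambda_{si}\lambda_{tj}\, J_{si,tj}
  + V_{bias}(\lambda),$$

with $h$ (kcal/mol) the effective substituent–environment energy and $J$ a
symmetric inter-site coupling whose within-site blocks are identically
zero (two substituents of one site are never simultaneously physical). The
atomistic rule that bonded terms are not scaled by λ has no analogue here;
nothing in the reduced model corresponds to it.

Assumptions worth stating: the reduced model is *linear* in each site's λ
block (no soft-core shaping), couplings are pairwise, and the "environment"
is a single constant. These are the minimal ingredients that preserve the
estimator's mathematics while making exact enumeration feasible.

## 3. Implicit constraints and the θ-space measure

The per-site simplex constraints are enforced implicitly by the
exponential-normalisation (softmax) transform

$$\lambda_{si} = \frac{e^{c\,\theta_{si}}}{\sum_j e^{c\,\theta_{sj}}},$$

with steepness $c = 5.5$, the conventional value in the λ-dynamics
literature. The transform is evaluated with per-site max-subtraction; for
very negative relative θ a λ underflows to exactly 0, which is harmless.
The exact functional form used by production MSλD engines is not uniquely
fixed by the published equations; softmax is a documented choice here, not
a claim about any particular engine.

Two geometric facts drive several design decisions:

* **Gauge directions.** Adding a constant to a site's θ block leaves λ
  unchanged, and the λ-vertices occupy infinite θ-volume, so the bare
  θ-space Boltzmann measure is improper. The sampled potential therefore
  includes a harmonic confinement $\tfrac{1}{2} k_r |\theta|^2$ with
  $k_r = 1$ kcal/mol (model units). The per-site centre coordinate then
  factorises as an independent Gaussian and cancels in every population
  ratio; the confinement is symmetric under substituent permutation, so
  endstate bin volumes cancel between substituents of a site. With
  $k_BT \approx 0.592$ kcal/mol at 298 K the confinement leaves endstate
  bins (|u| ≳ 0.84 in the θ-difference coordinate) heavily populated and
  transitions facile.
* **Parametrisation entropy.** The λ-marginal of a *flat* θ-landscape is
  not flat: the softmax Jacobian piles θ-volume onto the vertices,
  producing an apparent mid-λ barrier of roughly 1.3 kcal/mol that is
  entropy of the parametrisation, not kinetics. Section 5 explains how ALF
  accounts for it.

## 4. Sampling

θ is propagated by BAOAB-splitting Langevin dynamics (compiled in C++;
`step_langevin()` is the reference R kernel). Defaults, in model units:
timestep 0.01, friction 5, θ-mass 1, temperature 298 K, frames saved every
10 steps, $k_B = 0.0019872041$ kcal/mol/K everywhere. With friction 0 the
O-step is skipped exactly and the integrator reduces to velocity-Verlet.
Initial θ is standard normal and initial velocities Maxwell–Boltzmann,
both from the seeded R RNG; identical seeds give bit-identical
trajectories, and replica seeds are derived from the master seed by a
counter-mixing scheme (`derive_seed()`) so streams are never shared.

The physical fs/ns timescales of atomistic MSλD do not transfer to a
reduced model; the defaults were chosen once so that a flattened symmetric
two-substituent toy shows well over 0.1 transitions per 1000 steps (the
observed rate is several per 1000 under the defaults). Reported rates are
labelled model-time units and claim no nanosecond equivalence.

## 5. Adaptive landscape flattening

The bias family is
$$V_{bias} = -\sum_{s,i} b_{si}\lambda_{si}
  + \sum_s \sum_{i \ne j} \psi_{s,ij} \lambda_{si}\lambda_{sj}
  - \sum_{(s,t)\ paired} \sum_{i,j} \Psi_{si,tj}\lambda_{si}\lambda_{tj},$$
linear flattening plus intra-site quadratic barrier shaping plus the
inter-site coupling of the coupled two-λ scheme ($\Psi$ rows and columns
of the reference substituent are zero by convention; positive Ψ is
attractive for the coupled pair). ALF starts from zero `b` and `ψ` and
alternates short runs with updates through a schedule whose default
mirrors the standard protocol shape: 20 × 1000-step flattening iterations,
10 × 10000-step refinements, then four production phases
(5·10⁴, 2·10⁵, 2·10⁵, 10⁶ steps) with refinement after each run. `Ψ` is a
scheme-level parameter and is never updated.

**Profile estimation.** Each λ coordinate is histogrammed over 25 bins on
[0, 1]; $-k_BT\log p$ with the coordinate's own linear bias term removed
estimates the unbiased profile, min-shifted to zero. Per-bin errors come
from a block bootstrap (block length = frames/20, at least one; 50
resamples). Empty bins are flagged and never imputed.

**Linear update.** The update moves `b` toward the profile's endpoint
difference, `b ← b + d·(D − b)`, clipped to ±5 kcal/mol per iteration.
Because the two coordinates of a two-substituent site move
antisymmetrically, the closed loop obeys `b' = (1 − 2d)·b + d·D_true`: the
textbook damping d = 0.8 has loop gain −0.6 and *rings*, and the
equilibration lag of consecutive short runs turns the ringing into a
sustained limit cycle (we observed sign-flipping endpoint estimates on
two-site systems even in 10⁶-step runs). The default d = 0.5 is the
deadbeat choice — one accurate iteration lands on the fixed point — and
restored oracle agreement on the random-toy suite. When one λ-endpoint
was never visited the full difference is unknown; the update then targets
the climb observed so far plus one $k_BT$ of exploratory push toward the
unexplored end, which guarantees progress and recovers from a mis-tilted
bias instead of deadlocking.

**Quadratic update and the entropy baseline.** The residual mid-λ barrier
is measured as the mean of the sampled marginal over the central third of
the λ-range minus its endpoint mean — means, not an interior maximum,
because the maximum of ~20 noisy bins is biased upward and turns the
update into a one-way ratchet. Crucially the profile is compared against
the exactly computed *parametrisation-entropy baseline* (the λ-marginal a
flat θ-landscape produces under softmax plus confinement, cached per site
size): without this reference ALF "flattens" the entropic vertex pile-up,
digs a mid-simplex trap (we observed ψ drifting to −11 kcal/mol and λ
collapsing to the simplex centre) and destroys endstate dwell. The signed
update `ψ ← ψ − 2d·R` can therefore both deepen and lift the transition
region.

Convergence is logged as the residual imbalance (baseline-corrected,
bias-subtracted endpoint difference), which tends to zero as the biased
landscape flattens.

## 6. Endstate estimators

A frame is assigned to sequence *m* when at every site the substituent
prescribed by *m* has λ ≥ λc, with λc = 0.99; otherwise it is unassigned.
Transitions are counted on the gap-collapsed visit sequence: entry into an
endstate different from the last visited one counts, first visits do not,
so brief unassigned excursions and re-entries are transparent. Raising λc
can only shrink the assigned set (monotonicity is tested).

The population estimator is
$$\Delta G_m = -k_BT\,\ln\frac{P_m}{P_{ref}} - (B_m - B_{ref}),$$
with $B_m$ the applied bias energy *evaluated at vertex m*. At a vertex
the intra-site quadratic vanishes identically, but both the linear terms
and the inter-site coupling Ψ survive; evaluating the full bias there
(rather than only the linear part) keeps the coupled two-λ scheme exactly
correctable. The correction is switchable (`bias_correction = FALSE`) to
mimic the perfectly-flattened assumption. Sequences never observed are
reported as missing, never ±∞. Standard errors use the same block
bootstrap as the profiles; cycle assembly subtracts legs and combines SEs
in quadrature, and missing legs propagate missingness. Antisymmetry under
reference exchange and additivity over a shared population table are exact
identities of logarithms and are tested as such.

## 7. Perturbation schemes

* **One λ per pair** — one site per variant position; substituents are
  Watson–Crick pairs labelled by the primary-strand base. No mispairing is
  representable.
* **Two λ** — two paired sites per position, one per strand, substituents
  are individual bases; of the $2^{2k}$ vertices only the complementary
  combinations are physical sequences, and mispaired vertices carry a
  penalty in the toy Hamiltonians.
* **Coupled two λ** — as two-λ plus the quadratic coupling Ψ between the
  paired non-reference substituents.

**Sign of the coupling.** The coupling exists to *decouple* the two
strands' transitions: the obstacle in the two-λ scheme is the high cost of
mutating one base without its partner. A static analysis of the flattened
landscape shows why the default is a *negative* entry (a penalty on joint
activation of the paired mutant λs, default −2 kcal/mol): with mispair
penalty $p$ and coupling $\Psi$ on the mutant–mutant entry, flattening the
marginals forces the linear bias to $\beta = -\Psi/2$, which places the
mispaired vertices at $p + \Psi/2$ above the matched ones. A
matched-stabilising (positive) Ψ therefore *raises* the mispaired
intermediates and suppresses stepwise transitions, while the negative
default lowers them to $p - \Psi/2$ and lowers both the stepwise and the
concerted barriers. The package reproduces the expected qualitative
behaviour under this choice: the one-λ scheme concentrates the most
transitions on matched states, the uncoupled two-λ scheme transits less,
and the coupled scheme spreads a substantially larger fraction of its
transitions over mismatched states. The magnitude is a free parameter
(`coupling_strength`); no published value exists to compare against.

## 8. The toy generator and the quadrature oracle

`toy_wbox()` encodes the default study system: native GGTCAA mutated to
GATAAA (variant positions 2 and 4), bound well depths (0, 4, 2, 5.7)
kcal/mol for GGTCAA/GATCAA/GGTAAA/GATAAA — the ~5.7 kcal/mol scale and the
ordering of the single-position intermediates echo the magnitudes reported
for this system — an unbound leg flat at 0, and a mispair penalty of
2 kcal/mol for the two-λ schemes. Depths are realised exactly: on `h` for
one variant position, on the inter-site `J` block for two; in two-λ
topologies the sequence terms live on the primary-strand sites and the
penalty on the `J` block between paired sites, so every matched vertex's
energy equals its prescribed depth.

`quadrature_dg()` is the package-wide oracle: dense tensor-grid
integration of $e^{-V/k_BT}$ over the gauge-fixed θ-space (an orthonormal
basis of each site's sum-zero subspace; the centre coordinates factorise
and cancel), accumulating the Boltzmann mass of each sequence's λc-bin and
applying the same vertex bias correction as the estimator. Bin-volume
entropy is integrated exactly rather than assumed to cancel. The grid is
aligned so the λc boundaries of two-substituent sites fall midway between
points, making the indicator-integration error second order in the
spacing; doubling the default 201-point grid moves the results by
~4·10⁻⁵ kcal/mol. The oracle refuses more than 4 gauge-fixed dimensions —
it is deliberately small-scale.

**What the toys do and do not emulate.** They reproduce the *structure* of
the problem — multi-state alchemical topologies, bound/unbound asymmetry,
mispair penalties, sequence-dependent wells — under a smooth, low-barrier
landscape. They contain no solvent, no conformational substates, no
absolute-scale offsets (the ~272–277 kcal/mol absolute legs of the real
system are out of scope by construction), and no slow orthogonal degrees
of freedom. Passing tests therefore validate the estimator machinery and
its uncertainty model, not force-field accuracy or atomistic sampling
behaviour.

## 9. Numerical choices and degenerate inputs

* Softmax with per-site max-subtraction; λ may underflow to exactly 0.
* Exact λ = 1 falls in the last histogram bin (half-open binning with a
  top clamp).
* `max.col` with first-tie-break selects the binned substituent; ties at
  λc are impossible for λc > 0.5.
* Non-finite θ or velocities abort a run naming the first bad step.
* All-unassigned series yield zero transition counts; a reference
  sequence never observed is an error naming the reference; other
  unobserved sequences are flagged missing.
* Bias files round-trip exactly through decimal (17 significant digits);
  trajectory files round-trip bit-exactly at 10 significant digits.

## 10. Problem sizes used by the tests

The suite exercises: 100-instance brute-force energy/gradient oracles;
10⁵-step production runs against quadrature on 20 random one/two-site
toys; the full default ALF schedule (≈1.5·10⁶ steps) for bias-recovery
checks; five seeds × three schemes for the transition-distribution
comparison; 200 repetitions of a known-answer system for bootstrap
calibration (observed 1-SE coverage within the 55–80 % band expected for
a block bootstrap on correlated data); and 20 seeded ranking-recovery
fits with adjacent well-depth gaps of 0.8 kcal/mol. These sizes keep the
whole suite around two minutes on one CPU while leaving every stochastic
acceptance margin wide.

## 11. Known limitations

* Linear λ-scaling only; no soft-core end-point shaping, so strongly
  repulsive intermediates cannot be regularised the way atomistic MSλD
  does.
* Single-ensemble histogram reweighting per iteration (each run is
  re-analysed under its own bias); multi-ensemble WHAM is unnecessary at
  this scale and not implemented.
* Linear + intra-site quadratic biases cannot flatten *joint* inter-site
  structure: toys with strong couplings between sites keep unequal vertex
  populations after flattening (the estimator's bias correction still
  yields consistent ΔG as long as every state is visited). This mirrors a
  known limitation of per-coordinate flattening.
* The quadrature oracle is exact only for the reduced model and ≤ 4
  gauge-fixed dimensions.
* Bootstrap SEs inherit the usual downward bias under residual
  correlation; the calibration test quantifies it.
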