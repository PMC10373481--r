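---
title: "Position-LDA reaction coordinates: model, numerics, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-LDA reaction coordinates: model, numerics, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ldacv)
```

## The problem

Enhanced-sampling methods bias a simulation along a low-dimensional
collective variable (CV), and their usefulness stands or falls with the
quality of that CV. Internal coordinates (distances, angles, dihedrals) are
the traditional choice because they are invariant to rigid motion, but they
require choosing features, and natural choices are often overdetermined.
Particle positions are the most direct representation of a configuration —
`ldacv` makes them usable as a CV by working in *size-and-shape space*, the
quotient of configuration space by rigid translations and rotations, and by
training a one-dimensional linear discriminant between two conformational
states in that space.

## The statistical model

A configuration of $N$ particles is an $N \times 3$ matrix $x$ (Å). Each
metastable state $j$ is modelled as a Gaussian over positions with mean
$\mu_j$ and a *Kronecker* covariance $\Sigma_j = \Sigma_N \otimes I_3$: one
$N \times N$ particle–particle covariance acting identically and
independently on $x$, $y$, $z$. Every frame is identified with the
representative of its equivalence class under rigid motion that minimizes
the Mahalanobis distance to the state mean,

$$d^2(x, \mu) = \sum_{d \in \{x,y,z\}} (x_d - \mu_d)^\top \Sigma_N^{+} (x_d - \mu_d),$$

where $\Sigma_N^{+}$ is a rank-truncated pseudo-inverse (below). The
minimizing rotation is a *precision-weighted Kabsch problem* with the closed
form: SVD of the weighted cross-covariance $x^\top \Sigma_N^{+} \mu$ with a
determinant-sign correction to exclude reflections. Because $\Sigma_N$ is
isotropic over the three Cartesian dimensions, a single SVD solves the
problem exactly — no inner iteration is needed.

State parameters are estimated by alternating (i) alignment of all frames to
the current $(\mu, \Sigma_N)$ and (ii) re-estimation of $\mu$ as the frame
average and $\Sigma_N$ as the positional covariance averaged over the three
Cartesian dimensions (`iterative_mean_cov()`). The first sweep uses an
identity covariance (plain Kabsch against the centered first frame), which
also fixes the otherwise arbitrary global orientation of the result.

### Numerical choices

* **Covariance convention.** $\Sigma_N$ uses the *per-Cartesian-dimension
  average* (divide by $3n$), so the expected squared Mahalanobis distance of
  a frame drawn from the state is $3 \cdot \mathrm{rank}(\Sigma_N)$. The
  alternative (sum over dimensions) would rescale all distances by 3;
  absolute Mahalanobis magnitudes therefore depend on this convention, while
  alignments, assignments and LDA directions do not.
* **Pseudo-inverse.** Centering puts the ones vector in the null space of
  $\Sigma_N$ by construction, so $\Sigma_N$ is always singular. Eigenvalues
  below $\tau \lambda_{\max}$ ($\tau = 10^{-10}$, configurable) are
  truncated and the retained rank is recorded on the `shape_ref`.
* **Convergence.** The default tolerance is $10^{-8}$ Å on the largest
  mean-coordinate change, capped at 200 iterations with a warning (the last
  iterate is still returned).
* **Degenerate input.** Collinear or zero-variance frames make the rotation
  problem ill-posed; `optimal_rotation()` warns and falls back to the
  identity. A zero-variance trajectory yields a zero covariance, reported
  with rank 0 and an identity precision.

## State definition

`assign_states()` labels each frame by the nearest state in Mahalanobis
distance after aligning the frame to every candidate state independently;
ties break towards the lowest state index, so the assignment is
deterministic. `fit_hard_states()` wraps this in a hard-assignment loop
(re-fit each state on its members, re-assign, repeat). This is a deliberate
simplification of a full soft-responsibility EM over the mixture: the
package only needs state *definitions* for LDA training, not calibrated
mixture likelihoods.

A practical note on separation: "well separated" must be judged in the
metric the assignment uses. Squared Mahalanobis distances concentrate around
$3 \cdot \mathrm{rank}$ with standard deviation $\sqrt{6 \cdot
\mathrm{rank}}$, so two states are cleanly separable only when the
inter-mean squared distance exceeds that fluctuation scale by several
standard deviations — a stricter requirement than a large mean separation
along a single direction.

## The discriminant coordinate

Given two labelled states, the frames of both are pooled and aligned to a
*single global* mean and covariance (`global_align()`). Aligning each
cluster to its own reference would give scatter matrices with incompatible
null spaces; aligning to one cluster is asymmetric; the global reference
avoids both problems.

From the aligned frames the within- and between-cluster scatter matrices are
assembled densely in the full $3N$-dimensional coordinate space:

$$S_w = \sum_i \sum_{t \in i} (x_t - \mu_i)(x_t - \mu_i)^\top, \qquad
  S_b = \sum_i n_i\, (\mu_i - \mu)(\mu_i - \mu)^\top,$$

with the population factors $n_i$ included so that $S_w + S_b$ equals the
total scatter exactly (an unweighted $S_b$ is available as an option; for
two classes it only changes the scaling). Dense $3N$ storage is exact and
comfortable for $N$ up to a few hundred particles, the regime of
backbone-atom or C$\alpha$ subsets.

LDA maximizes the trace ratio of projected between- to within-scatter.
Aligned positional data always make $S_w$ singular (translation removal and
rotation fitting confine the data to a subspace of dimension about
$3N - 7$), so the classical generalized eigenproblem is unusable. The
package instead computes the discriminant through the generalized-SVD
formulation: an SVD of the stacked factor matrix
$[H_b^\top; H_w^\top]$ (where $S_b = H_b H_b^\top$, $S_w = H_w H_w^\top$)
with singular values truncated at $\tau \sigma_{\max}$, followed by an SVD
of the leading block. For nonsingular $S_w$ this reproduces the Fisher
solution $S_w^{-1}(\mu_1 - \mu_2)$ to machine precision, and for singular
$S_w$ it returns the discriminant within the data subspace; both equalities
are enforced by oracle tests against independent direct solves.

Conventions for the trained model:

* $v$ has unit Euclidean norm, so $l$ carries Å units of projected
  displacement. Any other normalization would only rescale $l$ and the
  bias-width parameters, not the physics.
* The sign is fixed so the first-named training state projects to negative
  $l$.
* $l(\mu) = 0$ exactly at the model's own reference mean.

## On-the-fly evaluation and biasing

`compute_cv()` evaluates $l$ for a raw frame: translate to zero centroid,
rotate onto the stored reference by the precision-weighted Kabsch solution,
then $l = v \cdot (x_{\text{aligned}} - \mu)$. The optimal rotation depends
on the positions, so differentiating $l$ analytically means differentiating
through an SVD; the package instead uses central finite differences per
coordinate (step $10^{-4}$ Å by default), which captures the
rotation coupling exactly to second order. Tests verify the gradient
against Richardson extrapolation and against directional difference
quotients; a `check` option warns when the step is too large for the local
nonlinearity. Analytic gradients through the alignment are a known,
deliberate omission.

Two adaptive biases act on $l$ (energies in kcal/mol, $k_B$ in
kcal/mol/K):

* **Well-tempered metadynamics.** Gaussian hills of width $\sigma$ are
  deposited every `pace` steps; each hill's height is
  $h \exp[-V(Q,t)/k_B \Delta T]$ with $\Delta T = (\gamma - 1) T$, so
  accumulated bias converges to $-(1 - 1/\gamma) F$. The free energy is
  recovered as $F(Q) = -\frac{\gamma}{\gamma-1} V(Q)$
  (`fes_from_bias()`) or by reweighting.
* **OPES.** A kernel density estimate $P_t$ of the CV distribution is
  updated on the fly (kernels merged when closer than $\sigma/2$ to bound
  memory), and the bias is
  $V(Q) = (1 - 1/\gamma) k_B T [\ln(P_t(Q)/Z_t + \varepsilon) - \ln \varepsilon]$
  with $Z_t$ from integrating $P_t$ over the sampled range and
  $\varepsilon = \exp[-\Delta E / ((1 - 1/\gamma) k_B T)]$ so that unsampled
  regions sit at zero bias and the range is capped near $\Delta E$. Because
  a sharply peaked density can push $P_t/Z_t$ above one, the applied bias is
  additionally min-shifted and clipped at $\Delta E$, making the cap exact
  on any evaluation grid. These prefactor conventions follow the standard
  adaptive-bias literature; the package documents them explicitly since
  small variants circulate.

Quadratic walls $\kappa (Q - b)^2$ outside a chosen interval
(`wall_potential()`) guard against excursions far beyond the trained range,
where the linear model has no support. Typical production settings shipped
as example configurations use $\gamma = 8$, $\Delta E = 10$ kcal/mol and a
500-step pace for OPES, gentle WT-MetaD parameters
($h = 0.005$ kcal/mol, $\gamma = 2$) with walls at a bias coefficient of
125 kcal/mol/Å², and a hill width of one third of the CV's standard
deviation in the starting basin (the $\sigma_l/3$ rule).

## The toy laboratory

Everything above can be exercised end to end with no external data.

**Synthetic Gaussian states** (`sample_gaussian_state()`) draw frames from
exactly the model the alignment assumes — Gaussian positions with a
Kronecker covariance — then hide them behind uniform random rotations and
box-uniform translations. This emulates the statistical structure of an
aligned trajectory of a single metastable state; it deliberately does *not*
emulate anharmonicity, state overlap in time (no dynamics), or
non-Kronecker anisotropy. Passing parameter-recovery tests on these data
shows the estimator is correct under its own assumptions, not that real
trajectories satisfy them. The default test conditions put the positional
noise (0.2 Å) well below the structure's size (radius of gyration ≈ 6 Å),
the regime of folded-protein subsets; at 2000 frames per state the residual
angular error of the trained direction is dominated by the
$\sqrt{p/n}$ finite-sample deflection of the Fisher solution.

**The chiral toy** (`toy_chiral_system()`) is a five-particle chain with
harmonic bonds and angles and a quartic double well on the signed dihedral
of particles 1–2–3–4, giving two exactly mirror-image minima — a desk-scale
stand-in for helix-handedness inversion. The mirror symmetry is exact, so
the free-energy difference between the basins is zero by construction and
any measured asymmetry is sampling error; this is what makes the toy a
quantitative benchmark. A weak harmonic term keeps the second dihedral near
planarity so the state clouds stay compact. `handedness()` (the signed
dihedral) flips sign exactly under mirror reflection.

**Dynamics** (`run_langevin()`) uses the BAOAB Langevin splitting
(friction 1/ps, $\Delta t = 0.002$ ps, masses 12 amu by default), chosen for
its configurational accuracy per step; with zero friction it reduces to
velocity Verlet, and tests verify sub-1% energy drift over $10^4$ steps.
Forces are analytic (bond, angle, dihedral), verified against finite
differences. Bias forces $-\,dV/dl\,\nabla l$ are applied every step; a
non-finite force halts the run immediately with the crash step reported,
since aggressive biasing of a numerically integrated system is a real
failure mode.

### Study conditions for the sampling benchmark

The default dihedral barrier is $6 k_B \cdot 300$ K ≈ 3.58 kcal/mol. A
Kramers estimate with the toy's well and barrier frequencies
(≈ 20 and 14 ps⁻¹) and friction 1/ps puts the unbiased 300 K hopping rate
near $0.05$ ps⁻¹ — transitions every few hundred ps, too fast to
demonstrate rare-event acceleration. The sampling study therefore runs at
**120 K**, where the same barrier is ≈ 15 $k_B T$ and no unbiased
transition is expected within the $10^6$-step (2 ns) control run. The
WT-MetaD demonstration uses $\gamma = 10$ (leaving a residual barrier of
about 1.5 $k_B T$ in the well-tempered ensemble), $h = 0.05$ kcal/mol,
pace 500, hill width from the $\sigma_l/3$ rule measured on the training
data, and walls at $\pm 1.3 \times$ the training range with the
125 kcal/mol/Å² coefficient. Training data are two $2 \times 10^4$-step
unbiased in-state runs labelled by handedness sign, and the pooled
mirror-symmetric fit uses a $5 \times 10^{-4}$ Å alignment tolerance —
the orientation gauge of the pooled mean drifts slowly (≈ $10^{-4}$ Å per
iteration for hundreds of iterations) with no effect on the trained
coordinate. The acceptance suite checks, at these conditions, that the
biased run produces at least ten handedness transitions where the unbiased
control produces none, and that the reweighted free-energy difference
between the basins is below 0.3 kcal/mol in magnitude.

## Validation machinery

* **Committor.** For each frame, scan forward: 1 if region A is reached
  before region B, 0 if B first, undefined if neither occurs before the end
  (trailing undefined values are excluded, not imputed). Regions can be
  state-label sets or intervals on $l$. `binned_committor()` averages
  defined committors in half-open bins and attaches
  $F(l) = -k_B T \ln P(l)$ over the same bins. The implementation is tested
  against the exact linear-algebra committor of simulated Markov chains and
  for stability under 50 → 150 bin refinement. The default bin count is
  150 over a user-chosen range.
* **Free-energy surfaces.** `fes_histogram()` turns (optionally weighted)
  samples into $-k_B T \ln P$, min-shifted, with empty bins reported as
  `NA`, never infinite. `reweight_frames()` implements quasi-static
  (final-bias) reweighting $w_t \propto e^{V(Q_t)/k_B T}$, appropriate once
  the bias evolves slowly; tests check agreement between reweighted biased
  runs and long unbiased runs of the same toy potential.
* **Helicity.** `zeta_prime()` returns minus the sum of signed dihedrals
  (IUPAC convention: right-handed, cis = 0) over supplied atom quadruples.
  For an ideal right-handed 3₁₀ helix with $\phi = -57°$ over five central
  residues it gives ≈ +4.97 rad, and exactly the negation for the mirror
  image; `build_helix_backbone()` constructs such ideal backbones from
  internal coordinates for testing and illustration.

## Problem sizes

The shipped test-suite and acceptance runs use: $N = 4$–10 particles and
30–4000 frames for alignment/LDA oracles; $10^5$-step Markov chains for the
committor oracle; $10^6$-step Langevin runs for the toy sampling benchmark
and $2$–$3 \times 10^6$ steps for the 1D double-well bias validation. These
sizes were chosen so each property is measured well inside its asymptotic
regime while the whole suite completes in minutes on one core.

## Known limitations

* Gradients of $l$ are numerical; cost scales as $6N$ coordinate
  evaluations per force call. Fine for toys and for CV diagnostics, not for
  production MD engines.
* The bias grids are non-periodic; biasing an angle across ±π needs a
  periodic treatment the package does not provide.
* State fitting is hard-assignment only; no soft responsibilities, no
  automatic selection of the number of states.
* Scatter matrices are dense in $3N$; memory grows as $9N^2$ doubles.
* OPES here uses fixed-bandwidth kernels and a simple proximity merge; the
  adaptive-bandwidth refinements of full implementations are out of scope.
* Linear coordinates cannot align states that differ by unbounded motions
  (e.g. dissociation), where no common shape reference exists.
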