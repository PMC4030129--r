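---
title: "Coarse-grained collective dynamics with enmdyn: models, parameters and validation design"
author: "enmdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained collective dynamics with enmdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Multi-domain enzymes move as machines: an inserted, loosely packed
domain swings relative to a rigid catalytic core, and that hinge motion
is often what substrate transport and editing chemistry ride on.
Sampling such motions with explicit-solvent all-atom molecular dynamics
is expensive; the coarse-grained alternatives — harmonic network models
analyzed by normal modes, and Langevin dynamics on the same network —
capture the slow collective content at a tiny fraction of the cost.
`enmdyn` implements the full coarse-grained side of that comparison, at
one bead per residue, plus the analysis layer (essential dynamics,
cross-correlation maps, B-factor tracks, mode overlaps) needed to place
coarse-grained and all-atom descriptions side by side.

# The elastic network model

Each residue is a bead at its C&alpha; position with the residue's
total mass (a built-in 20-residue average-mass table; unknown residue
types fall back to 110 amu). Beads closer than a cutoff $r_c$ in the
reference structure are joined by harmonic springs:

$$E \;=\; \sum_{i<j} \Gamma_{ij}\, \frac{\gamma_{ij}}{2}
  \left(r_{ij} - r_{ij}^{0}\right)^2 ,
\qquad
\gamma_{ij} = \gamma \,(r_{ij}^{0})^{-p},$$

where $\Gamma_{ij}\in\{0,1\}$ is the contact map. Two conventions are
worth stating because they are easy to get silently wrong:

* **Pair counting.** The sum runs over unordered pairs, so a single
  spring stretched by $\Delta$ stores $(\gamma/2)\Delta^2$. (Writing
  the sum over ordered pairs, as some presentations do, doubles every
  effective spring constant.)
* **Distance weight.** The exponent $p$ is dimensionless. $p=0$ gives
  the uniform-spring network; $p=2.5$ reproduces the common ANM
  web-server weighting in which distant contacts are softer. One
  sometimes sees "2.5 Å" quoted for this parameter; the length unit is
  spurious — it is an exponent.

Two stage-specific parameterizations are used throughout, and both are
plain defaults, not hard-wired:

| stage | $r_c$ (Å) | $\gamma$ (kcal mol⁻¹ Å⁻²) | $p$ |
|---|---|---|---|
| normal-mode analysis | 10 | 1.0 | 2.5 |
| coarse-grained dynamics | 8 | 1.0 | 0 |

Contact detection is exact $O(N^2)$, which is deterministic and fast at
the problem sizes the package targets (hundreds to a few thousand
beads). A disconnected contact graph is a warning, not an error: it is
recorded on the network and propagates to the mode bookkeeping.

# Normal modes and their thermal content

`anmHessian()` assembles the standard ANM second-derivative matrix: the
off-diagonal $3\times3$ superblock of a contact is
$-(\gamma_{ij}/r_{ij}^{0\,2}) \, \mathbf{r}_{ij}^{0}\mathbf{r}_{ij}^{0\,\mathsf T}$
and diagonal blocks enforce the translational sum rule. The matrix is
symmetric positive semidefinite; a connected network has exactly six
zero eigenvalues (rigid translations and rotations), and every extra
rigid fragment contributes six more. Modes with
$\lambda < 10^{-8}\lambda_{\max}$ are flagged as zero modes; "mode
$k$" everywhere means the $k$-th *internal* mode after that flag.
Eigendecomposition is dense symmetric (`eigen`), deterministic, with
ties resolved by first occurrence — adequate well past $N = 3000$
beads, which is beyond the intended scale.

Thermal quantities weight modes by $\lambda^{-1}$, never equally:

$$C \;=\; k_BT \sum_{k} \lambda_k^{-1} \mathbf v_k \mathbf v_k^{\mathsf T},
\qquad
B_i = \frac{8\pi^2}{3}\,\mathrm{tr}\,C_{ii},
\qquad
CC_{ij} = \frac{\mathrm{tr}\,C_{ij}}
               {\sqrt{\mathrm{tr}\,C_{ii}\,\mathrm{tr}\,C_{jj}}} .$$

With all nonzero modes, $C$ equals $k_BT$ times the Hessian
pseudoinverse (a test asserts this against an independent
pseudoinverse). The cross-correlation is the standard vector (trace)
form; the scalar per-coordinate form reduces to it coordinate by
coordinate and is not separately implemented. $CC_{ij}$ is invariant to
temperature and to uniform rescaling of $\gamma$, since both cancel in
the normalization. A bead with zero fluctuation in the selected
subspace would make $CC$ a 0/0; its correlations are set to 0 with a
warning and the bead index is recorded on the object.

The DCCM of "combined modes 1–3" (the default) answers the question the
hinge analysis asks: in the few softest modes, do two domains move
together or against each other?

# Langevin dynamics on the network

`runLangevin()` integrates the network potential with the BAOAB
splitting of Langevin dynamics — half kick, half drift,
Ornstein–Uhlenbeck velocity refresh, half drift, half kick — which has
excellent configurational accuracy at large steps and degenerates to
velocity Verlet at zero friction (the package's energy-conservation
tests exploit exactly that limit). Units are kcal/mol, Å, amu, ps
(1 kcal/mol = 418.4 amu Å² ps⁻²; $k_B$ = 0.0019872 kcal mol⁻¹ K⁻¹).

Parameters, with defaults:

* `dt = 0.02` ps — checked against the harmonic stability bound
  $dt < 2/\omega_{\max}$ computed from the stiffest mass-weighted mode;
  an unstable request errors with the computed bound rather than
  producing garbage.
* `temperature = 298` K — initial velocities are Maxwell–Boltzmann;
  the OU step thermostats every degree of freedom.
* `friction = 5` ps⁻¹ — a thermostat coupling, not a solvent
  viscosity. The value is a deliberate compromise: weaker coupling
  samples soft modes faster (their positional relaxation time in the
  overdamped regime is $\zeta m/(418.4\,\lambda)$), stronger coupling
  tightens temperature control. It is fully configurable.
* `saveEvery = 10` — at each save point the center-of-mass position
  and momentum are removed, so saved frames carry no net drift.
* `seed` — all noise comes from R's RNG; identical seed and parameters
  reproduce the trajectory bit for bit, and the seed is stored in the
  trajectory metadata.

Because the integrator removes the three center-of-mass momentum
components, the kinetic temperature of a trajectory is computed over
$3N-3$ degrees of freedom. For a 100-bead system the distinction is
below 1%; for a 2-bead system it is a factor of two, so it matters for
the closed-form checks below.

# Essential dynamics

The EDA chain is: superpose, PCA, cluster, analyze.

* **Superposition** uses the Kabsch SVD solution restricted to proper
  rotations (determinant +1); a mirror image is never "fixed" by a
  reflection. Fitting can run on a subset (e.g. the core) while the
  transform applies to all beads. An independent least-squares fitter
  is used as a cross-check in the tests.
* **PCA** drops a burn-in fraction (default 1/6, the
  "last 25 of 30 ns" convention expressed as a fraction so it scales
  to short runs), then eigendecomposes the *population* covariance
  (denominator $n$) of the $3N$ coordinates. Eigenvalues are variances
  in Å², descending; the trace identity
  $\sum_k \lambda_k = \langle|\Delta x|^2\rangle$ is asserted in the
  tests. PCA refuses unsuperposed trajectories (thermal ensembles
  generated about a fixed mean are born superposed).
* **Cluster selection** bins frames in the leading PCs (default 3
  components, 20 bins per axis), joins face-adjacent occupied bins into
  clusters, and scores each cluster by *conformations per unit
  fluctuation*: frame count divided by the RMS spread of its
  projections, in projection space. The spread is floored at half a
  bin width — a cluster confined to one bin cannot claim less spread
  than the bin resolution, and without the floor a single stray frame
  would score as infinitely dense and hijack the selection. Ties break
  to the lowest cluster id; the selection is invariant to frame order.
  Cartesian-space RMSD is a defensible alternative denominator; the
  projection-space choice keeps the score a pure function of the PCA
  and is what the implementation documents and tests.
* **DCCM and B-factors** from the trajectory mirror the normal-mode
  definitions, with the covariance taken either from the rank-3 PC
  reconstruction (default, mirroring the combined-modes convention) or
  from the raw frames (`reconstruction = FALSE`; at full rank the two
  are identical, which is asserted). The raw form is the right null
  model: independent beads decorrelate as $1/\sqrt{n_{\rm frames}}$.

# Comparing methods

The overlap of two per-residue displacement fields,

$$O = \frac{\left|\sum_i \Delta\mathbf r_i^{A}\cdot\Delta\mathbf r_i^{B}\right|}
           {\sqrt{\sum_i |\Delta\mathbf r_i^{A}|^2\;
                  \sum_i |\Delta\mathbf r_i^{B}|^2}} \in [0,1],$$

is sign- and scale-invariant; 1 means identical directions of motion.
`modeOverlapTable()` pairs mode $k$ with PC $k$ (index pairing, as
overlap tables are conventionally printed) and appends an "Average" row
that is the plain mean of the per-mode overlaps. A maximum-overlap
("best match") pairing is available as a diagnostic but is never
silently substituted — if modes have reordered between methods, that is
a finding, not a nuisance to hide. Restricting the sums to a domain
gives per-domain overlaps; a domain at rest in either field has an
undefined overlap and is reported as NA with a warning rather than a
number.

B-factor tracks from different sources live on incompatible absolute
scales (crystallographic Å², network fluctuations at some $\gamma$,
trajectory fluctuations), so comparisons use z-scores (population SD)
by default; min-max scaling is offered. Z-scoring preserves Pearson
correlations and makes the difference of two profiles (bound minus
unbound, say) scale-free.

# The synthetic benchmark

`makeTwoDomainStructure()` generates the study system: a compact core
(self-avoiding random walk confined to a sphere of radius
$3.0\,n_{\rm core}^{1/3}$ Å), interrupted at its outermost mid-chain
bead by an excursion — linker, inserted domain, linker — before
returning to the core. The insert walks in a sphere 80% more dilute
than the core, confined to the half-space beyond the core surface, so
it packs *against* the core at a cap-shaped interface. Consecutive
beads sit at 3.8 Å; everything is self-avoiding at 2.0 Å; the second
linker is jittered off the exact interpolation line because perfectly
collinear contacts would hand a bead a spurious zero-frequency
direction. Defaults: 60 core beads, 30 insert beads, 3-bead linkers.

The interface geometry is a deliberate design decision. A domain
dangling far from the core on two thin linkers is *too* flexible: its
pendulum modes have eigenvalues so small that they are numerically
indistinguishable from rigid-body modes and dynamically unsampleable
(relaxation times of hundreds of nanoseconds). Real inserted domains
touch their cores. With the interface, the generated models robustly
show, across seeds: exactly six zero modes; strictly lower mean contact
degree in the insert than the core at cutoffs 8–10 Å; insert B-factors
well above core B-factors; and a negative core × insert mean
cross-correlation over modes 1–3 — the hinge signature — in both the
normal-mode and the dynamics/EDA routes.

What the generator does **not** emulate: secondary-structure statistics,
sequence-specific packing, solvent, and anharmonicity. Tests passing on
these models validate the machinery (parsers, mechanics, integrators,
estimators, bookkeeping) and the harmonic statistical mechanics; they
do not certify agreement with all-atom dynamics of real proteins, which
is precisely the question the package exists to let its users ask of
their own systems.

`sampleAnmEnsemble()` complements the generator with frames drawn
exactly from the thermal distribution of a mode set
($\mathbf x = \bar{\mathbf x} + \sum_k \sqrt{k_BT/\lambda_k}\, z_k
\mathbf v_k$), giving trajectories whose covariance is known in closed
form — the ground truth behind the mode-recovery tests.

# Validation design and numerical fine print

A few choices in the validation layer deserve their reasoning on
record:

* **The dimer bond-length check runs at $r^0 = 10$ Å.** The textbook
  variance $k_BT/\gamma$ is the 1-D harmonic result. In 3-D the bond
  *length* carries an $r^2$ Jacobian, and independent quadrature of the
  exact equilibrium density shows that at the C&alpha; virtual-bond
  distance (3.8 Å) the true Var$(r)$ sits 7% below $k_BT/\gamma$ — no
  correct simulator can hit the 1-D value there. At $r^0 = 10$ Å the
  Jacobian correction is ~1%, inside the sampling tolerance, so the
  closed form is compared where it actually applies.
* **Soft-mode sampling is the binding constraint on dynamics tests.**
  An overdamped mode relaxes in $\zeta m/(418.4\lambda)$ ps; for the
  two-domain model's hinge modes that can approach the length of a
  desk-scale run. Quantities that need converged soft modes
  (fluctuation-profile correlations) are therefore validated on the
  compact single-domain control, where relaxation is a few ps, while
  the two-domain model validates properties that are robust at partial
  convergence (flexibility contrast, correlation signs). Index-paired
  overlaps between ANM modes of the $p=2.5$ network and PCs of a
  short dynamics run on the $p=0$ network are reported by the pipeline
  but not asserted at a threshold: they compare two *different*
  parameterizations through near-degenerate hinge-mode pairs, and at
  desk-scale sampling the PC basis within a quasi-degenerate pair is
  not identifiable. The ensemble-sampling route, where the generating
  modes are known exactly, is the appropriate ground truth for mode
  recovery and is asserted tightly (overlaps ≥ 0.99 at 5000 frames).
* **Problem sizes.** The shipped tests and the acceptance script use
  10–100-bead networks, $10^5$-step dynamics runs ($10^6$ for the
  2-bead closed form) and 5000-frame ensembles — sizes chosen so the
  statistical bounds being asserted (χ² bands, $1/\sqrt n$ null
  levels) are comfortably discriminating while the whole suite runs in
  about a minute.
* **Determinism.** Generators restore the caller's RNG state and are
  pure functions of their seed; the integrator draws only from R's RNG
  under `set.seed`; pipeline reruns from the same config are
  byte-identical, which is asserted file by file.

# Using real structures

`readCalphaPDB()` takes any PDB file (one CA bead per residue, first
alternate location alphabetically, experimental B-factors captured,
residues without a CA skipped with a warning). Chain and residue ranges
are always user-specified — crystal structures disagree with their own
captions often enough that hard-coding a published range would be a
trap. Domain definitions are plain residue intervals
(`domainDefinition("ED", 224, 407)`), and multi-interval domains (a
core split around an insertion) are supported directly.

# Known limitations

Harmonic networks cannot describe barrier crossing or amplitude-
dependent stiffening; the DCCM of three modes is a low-rank summary and
suppresses fast-mode decorrelation; the cluster-selection score depends
on the binning resolution (exposed as `gridBins`); and the CG-MD
thermostat is a sampling device, not a model of solvent friction, so
time-dependent quantities (relaxation rates, diffusion) are not
physically meaningful — only ensemble averages are.
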