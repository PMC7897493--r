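---
title: "Resolving rotation-coupled sliding kinetics with Markov state models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving rotation-coupled sliding kinetics with Markov state models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidemsm)
```

## The problem

A repair glycosylase scanning DNA for a rare mismatched base pair moves
along the duplex in short one-dimensional excursions, tracking the minor
groove so that each base-pair step couples a longitudinal advance (one
helical rise, 3.38 Å) to a rotation about the helix axis (one helical
twist, 34.3°). At each site the enzyme can either *interrogate* the base
pair — engaging the groove with its intercalation loop and basic
side chains — or sit in a looser *transit* arrangement between sites. The
kinetics of interest are the site-to-site transfer rates, the equilibrium
preference for the lesion-containing site, and the sequence of states along
the dominant search path.

`slidemsm` estimates these from ensembles of short trajectories via the
standard Markov-state-model (MSM) pipeline: featurize, reduce with tICA,
discretize with k-centers, count transitions at a lag `τ`, estimate a
reversible transition matrix, then coarse-grain (PCCA+), decompose fluxes
(transition path theory) and extract mean first passage times (MFPTs).

## The model

An MSM is a row-stochastic matrix `T(τ)` on microstates; `p(nτ) = p(0) Tⁿ`
propagates populations, `π T = π` gives equilibrium populations, and
`t_k = −τ / ln μ_k(τ)` converts eigenvalues into relaxation timescales.
Markovianity is judged by the usual diagnostics: implied-timescale curves
that level off in `τ`, Chapman–Kolmogorov self-consistency
(`T(2τ) ≈ T(τ)²`), and stability under truncation of the dataset.

Reversible estimation symmetrizes the transition counts,
`Ĉ = (C + Cᵀ)/2`, before row-normalizing. This makes detailed balance an
algebraic identity (with `π` proportional to the symmetrized row sums) and
is deterministic — a deliberate choice over iterative maximum-likelihood
reversible estimation, which is noted as an extension. Sliding-window
counts (every frame a window start) maximize data use; because successive
windows overlap, all standard errors are computed by *trajectory* bootstrap,
never from the raw count numbers.

## The synthetic generator

No public trajectory data exist for this system, so the package ships a
first-class generator whose defaults define the study conditions:

- **Topology.** Nine base-pair sites (`bp8`–`bp16`), two wells per site —
  one interrogated, one transit — arranged in a strict nearest-neighbour
  ladder, so sliding must pass through every intermediate site.
- **Thermodynamics.** Site stationary weights default to 4.1, 15.3, 8.8,
  10.5, 18.4, 12.7, 11.1, 11.0 and 8.1 %, the nine-state equilibrium
  populations reported for this system; the mismatch-interrogating site
  (`bp12`, S5) is therefore the deepest well. Transit wells sit
  `delta_transit = 1.5 kT` above their site's interrogated well
  (≈ 18 % of site mass), and well depths are anchored at
  `depth_floor = 2 kT` for the shallowest site.
- **Rates.** Metropolis/Kramers detailed balance on the ladder:
  `p_ij = ν · exp(−(B_e + d_i))` for neighbouring wells, with barrier
  `B_e = 0.5 kT` within a site, `0.7 kT` between sites, attempt prefactor
  `ν = 0.5` and `d_i` the well depth. Any such rule satisfies detailed
  balance for `π ∝ exp(d)`; the constants were fixed once so that the
  slowest relaxation (≈ 1270 steps ≈ 127 ns at 0.1 ns per step) is an
  order of magnitude shorter than the aggregate dataset and several times
  the single-trajectory length — the "sufficient sampling" regime in which
  a converged MSM is expected, mirroring (at desk scale) a 25 µs dataset
  resolving hundreds-of-µs dynamics.
- **Dataset shape.** 252 trajectories × 1000 frames at 0.1 ns per frame,
  mirroring the 252 × 100 ns production dataset of the motivating study.
  The per-frame saving interval of that dataset is not published; 0.1 ns is
  an assumption recorded in the trajectory manifests.
- **Emissions.** Each well emits Gaussian features: a longitudinal
  coordinate at `3.38 Å × position`, an angular pair
  `(cos, sin)(34.3° × position)` — the rotation-coupled signature — a
  groove-penetration channel separating interrogated from transit wells,
  and optional pure-noise channels. Default noise (1 Å longitudinal, 0.25
  angular, 0.6 penetration, 1.0 noise channels) leaves adjacent sites
  overlapping but separable, so dimensionality reduction is non-trivial but
  solvable.

What the generator does *not* emulate: non-Markovian memory from projected
degrees of freedom, anharmonic well shapes, dissociation/hopping events,
and sequence-dependent emission structure. Passing tests therefore
demonstrate correctness of the estimators on an exactly Markovian truth,
not robustness to the full pathologies of molecular-dynamics data.

## Analysis defaults and why

- **tICA**: correlation lag 20 ns, 4 components retained — the
  hyperparameters selected by the motivating study's scans. The lagged
  covariance is symmetrized, `C_τ ← (C_τ + C_τᵀ)/2`, and the instantaneous
  covariance ridge-stabilized by `1e-6 · trace/d`; neither regularization
  is prescribed by the study, both are stated package choices. Per-
  trajectory accumulation never lets lagged pairs span trajectory
  boundaries, and moment matrices are accumulated in id-sorted order so the
  fit is bitwise independent of input ordering.
- **k-centers**: greedy farthest-point traversal with deterministic
  first-frame initialization (the original initialization is unpublished;
  determinism was preferred, with a seeded random start available). The
  traversal guarantees a covering radius within twice the optimum.
- **MSM lag**: the estimators expose the lag freely; the pipeline default
  for the synthetic conditions is 30 frames (3 ns). The motivating study
  used 30 ns against hundreds-of-µs slowest modes; the generator's dynamics
  are correspondingly faster, and 3 ns sits above the fast intra-well
  relaxations (≈ 1 ns) while remaining well below the slowest hopping
  modes (36–127 ns), which keeps all nine site modes resolvable for PCCA+.
  At much longer lags the higher hopping eigenvectors decay into sampling
  noise and macrostate recovery degrades — the same trade-off practitioners
  face when lumping real models.
- **PCCA+**: memberships from the top `m` right eigenvectors via the
  simplex-vertex construction (farthest-row orthogonalization sweep), crisp
  labels by maximal membership, fuzzy memberships retained. Eigenvalue
  degeneracy at the spectral cut raises an error advising a different `m`.
- **TPT**: committors from the harmonic linear system; net flux
  `F_ij = max(0, f_ij − f_ji)` with `f_ij = π_i q⁻_i T_ij q⁺_j`; pathways by
  iterative widest-path (maximum-bottleneck) decomposition.
- **MFPT**: a 10 ms Monte-Carlo trajectory of the estimated chain
  (333 333 steps at the 30 ns production lag), with errors from 100
  bootstrap lists of 252 resampled trajectories. The averaging convention —
  the study does not state one — is over *entries* into the source
  macrostate under stationary flow, used identically by the Monte-Carlo
  estimator and by the exact linear-algebra solver that cross-checks it.
  Resampled lists whose largest ergodic component loses a whole macrostate
  are redrawn (at most 10 times, logged), echoing the connectivity caveats
  of sequential-transition datasets. Bootstrap resampling is with
  replacement (the standard bootstrap; the study says only "randomly
  selected").

## Geometry conventions

The structural observables operate on labelled coordinate frames; several
are package-defined simplifications of conventions whose exact published
definitions live in unavailable supplementary material, and each is
calibrated against constructed fixtures rather than asserted blindly:

- **Bend angle**: angle between best-fit axes through the base-pair centers
  of the two helical arms flanking a step. A fixture kinked by 30° is
  recovered within 1°.
- **Opening angle**: signed in-plane splay of the two glycosidic C1′→N
  vectors away from the closed-pair reference (the direction from each C1′
  to the C1′–C1′ midpoint), measured in the plane orthogonal to the local
  helix axis; first strand minus second strand, so the sign flips when the
  roles of the strands are exchanged. Zero on the ideal fixture; a base
  rotated 20° in-plane reads 20°.
- **Minor groove width/depth**: minimum cross-strand P–P distance over the
  register centred on the site, minus 5.8 Å (two phosphate radii), floored
  at zero; depth is the distance from the site's base-pair center to the
  minimizing pair's midpoint. On the cylindrical idealized helix the
  minimizing register nearly aligns azimuthally, so the width responds only
  weakly to uniform radial expansion — a property of the idealization worth
  keeping in mind; the operator is therefore tested for the closed-form
  value and for monotone response, not for a fixed sensitivity.
- **Salt bridges**: Lys NZ / Arg NH1/NH2 within 6 Å (inclusive) of any DNA
  backbone oxygen; the backbone set is {OP1/O1P, OP2/O2P, O3′, O5′}, a
  package choice where only "backbone O" is specified.
- **Hydrogen bonds**: donor–acceptor ≤ 3.5 Å and, when a hydrogen is
  present, donor–H–acceptor ≥ 120° — a standard geometric criterion; none
  is published for this system.
- **SASA**: Shrake–Rupley with probe 1.4 Å and 960 deterministic
  golden-spiral points per atom; within 2 % of the closed-form sphere and
  of an independent random-quadrature reference.
- **Base flip**: pairing distance between the thymine O2/N3 and guanine
  N1/O6 edge centers; pseudodihedral over the 5′-flanking pair center, the
  target nucleotide's P, its C1′ and its base center — one documented
  choice among the possible four-center conventions. A fixture built to
  the published flipped-state values (−150°, 16 Å) reproduces them.

PDB input accepts both OP1/O1P spellings and multi-model files; residue and
base-pair numbering is 1-based as in PDB.

## Numerical choices and degenerate inputs

Ties in cluster assignment break to the lowest center index; duplicate
points can never both become centers. Non-positive transition-matrix
eigenvalues yield `NA` timescales ("undefined at this lag"), eigenvalues at
1 yield `+Inf`, never NaN arithmetic. Ergodic trimming keeps the largest
strongly connected component (ties by total counts). Truncation fractions
that disconnect the chain flag the affected cell instead of failing the
scan. All stochastic operations take explicit integer seeds; identical
seeds give bitwise-identical trajectories.

## Problem sizes used by the test suite

The suite regenerates everything programmatically: the default 252 × 1000
synthetic dataset for parameter-recovery and diagnostic checks, chains of
3–10 states for kinetics oracles, 50-atom configurations for SASA
cross-checks, and a reduced 16 × 300 dataset for the end-to-end pipeline
demo. These sizes were chosen so each property is measured in its
intended sampling regime while the whole suite stays fast.

## Known limitations

The reversible estimator is the symmetrization estimator, not the MLE; for
strongly non-equilibrium count matrices the two differ. GMRQ
cross-validation inherits the connectivity fragility of sequential
datasets — with few trajectories the test half may miss transition events
entirely, and scores degrade, which the implementation surfaces as dropped-
state warnings rather than hiding. The geometry operators are calibrated
simplifications, not re-implementations of helicoidal-parameter programs;
their absolute values should be compared only within this package's
conventions. No continuous-time rate matrices, Bayesian MSM posteriors,
hidden-state models, or MD-engine trajectory formats are provided.
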