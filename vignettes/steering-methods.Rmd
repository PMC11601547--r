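---
title: "Physics-guided steering of diffusion samplers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-guided steering of diffusion samplers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steerkit)
```

This vignette is the package's own account of the science it implements:
the tilted diffusion model behind `fkSteer()`, the seven flat-bottom
constraint potentials, the aligned reverse-diffusion step, the
symmetry-aware scoring machinery, the data-pipeline algorithms, and the
design decisions taken where the published descriptions leave freedom.

## The tilted sampling problem

A trained denoiser `f(x, t)` induces a reverse diffusion whose endpoint
distribution `p(x_0)` concentrates on plausible structures, but plausible
is not the same as physically valid.  The steering machinery samples from
the tilted target

$$p_\text{target}(x_0) \propto p(x_0)\, e^{-\lambda E(x_0)},$$

where `E` is a physics-inspired potential that is exactly zero on valid
conformers.  Plain importance re-weighting of finished samples fails when
validity is rare, so the tilt is spread along the trajectory with a
Feynman–Kac / sequential Monte Carlo construction: `k` particles are
propagated through the sampler's transition kernel
`τ(x_t | x̂_{t+1} + Δx̂_{t+1}, x_{t+1})`, and at every
`resample_interval`-th step (default 3, trading correction frequency
against particle diversity) the particles are multinomially resampled
under weights that combine

* the **energy difference** `exp(λ(E(x̂_prev) − E(x̂_now)))` of the
  denoised predictions between consecutive checkpoints (the first
  checkpoint uses `exp(−λE)`), and
* the **proposal-density ratio** `τ(x | x̂)/τ(x | x̂ + Δx̂)`, which
  corrects for having proposed from the guided rather than the plain
  kernel.

Weights are accumulated checkpoint-to-checkpoint (not per step) so the
per-step factors telescope between resampling events; this is the natural
discretisation when resampling is sparser than stepping.  All arithmetic
is in log space; if every weight underflows the ensemble falls back to
uniform with a warning rather than dying on a 0/0.

### Guidance

Between checkpoints each particle carries an offset `Δx̂` applied to the
prediction that parameterises the proposal.  After each resampling the
offset is rebuilt by `m` gradient-descent steps (default 4) on
`E(x̂ + Δx̂)`.  Two numerical choices matter here:

* the **initial step size** is auto-scaled so the first step displaces no
  atom by more than 0.5 Å — large enough to traverse a violation in a few
  steps, small against the ~2.5 Å clash scale;
* each step **backtracks** (halving the step up to six times) until the
  energy does not increase.  The feasible region of the distance-geometry
  bounds is only a few tenths of an Ångström wide, and a fixed-size step
  on a piecewise-linear landscape happily jumps across it; with
  backtracking the guidance is a genuine descent and can only improve the
  prediction it decorates.

`fkSteer()` returns both the literal algorithm output (final sample plus
final offset, `coords`) and the surviving particle's guided prediction
(`prediction = x̂_0 + Δx̂_0`).  With a real denoiser the two coincide up
to terminal noise, because the denoiser folds guided samples back into
its next prediction.  With the deliberately state-independent toy
denoisers used in the test-bed the `prediction` is the meaningful
energy-bearing object, and it is what the paired-seed studies score.

### The sampler contract

The bundled `gaussianSampler()` is the exact ancestral posterior of a
variance-exploding forward process: mean
`x̂ + (σ_next²/σ_t²)(x_t − x̂)`, isotropic standard deviation
`σ_next √(1 − σ_next²/σ_t²)`, on a σ-grid
`(σ_max^{1/ρ} + u(σ_min^{1/ρ} − σ_max^{1/ρ}))^ρ` with ρ = 7 and
structure-scale defaults σ_max = 160 Å, σ_min = 0.05 Å, σ_data = 16 Å.
Sampling and log-density come from the same closed form, which is what
makes the proposal-density ratio available.  Any sampler exposing the
same two functions can be plugged in; one without a tractable density may
set `logDensity = NULL` and forfeits the ratio correction (a documented
degraded mode).  Diffusion time is normalised to t ∈ [0, 1] with t = 1
the fully-noised end.

## The seven constraint potentials

Every component is a flat-bottom hinge: identically zero on satisfied
constraints, growing linearly outside.  Angular terms are built on the
signed dihedral (`dihedralAngle()`, right-hand convention about the
central bond, validated against `bio3d::torsion.xyz`):

* **Chirality** — for a center with substituents in decreasing CIP
  priority, the improper `(A, B, C, Z)` must exceed +π/6 for R and fall
  below −π/6 for S.  The sign *is* the chirality, so the signed angle is
  used.
* **Stereo bonds** — torsions `(A1, Z1, Z2, A2)` and `(B1, Z1, Z2, B2)`
  across the double bond; E requires |φ| ≥ 5π/6, Z requires |φ| ≤ π/6.
  The magnitude is used because trans torsions sit at ±π and both signs
  are equally valid — a flat bottom in the signed angle would not exist.
* **Planarity** — impropers `(A, B, C', C)` at each sp² end, |φ| ≤ π/12.
* **Internal geometry** — all ligand atom pairs against distance-geometry
  bounds: `max(d − 1.2U, 0) + max(0.8L − d, 0)`, identical hinge for the
  bond (1–2), angle (1–3) and remaining pair classes.  Pairs with no
  meaningful upper bound carry `U = Inf` and only the floor acts.
* **Steric clash** — non-bonded cross-chain pairs must satisfy
  `d ≥ 0.725 (r_i + r_j)` with Bondi van der Waals radii (the published
  source does not name its table; Bondi is the standard default).
* **Chain overlap** — centroids of symmetric chains (same entity, more
  than one atom) must stay at least
  `b_t = 1 + 4(e^{−2(1−t)} − 1)/(e^{−2} − 1)` Å apart.  The closed form
  gives b = 1 Å at the noisy end (t = 1) and 5 Å at the data end (t = 0):
  early in sampling overlapping chains are cheap to separate, so the
  requirement tightens as structure crystallises.
* **Covalent cross-chain bonds** — bonded inter-chain pairs within 2 Å.

The weighted total gates the clash term to `t < t_clash` (default 0.5,
the schedule midpoint): at high noise inter-atomic distances are
meaningless and the clash gradient only adds variance.  All α weights
default to 1 and λ to 2; the published description states that weights
are time-dependent without giving values, so beyond the clash gate and
the b_t schedule the package keeps them constant and exposes them in
`potentialWeights()`.

Gradients are fully analytic (including the dihedral chain rule) and are
tested against central finite differences at 1e-4 relative tolerance; at
hinge kinks the subgradient 0 is chosen, so satisfied structures feel no
force at all.

## Kabsch-aligned reverse diffusion

Non-equivariant denoisers are trained under random rigid augmentation
with a rigid-aligned loss.  A denoiser can be perfect under that loss and
still fail at inference: the package ships the canonical counterexample
(`makeDenoiser("dirac_pathological")`) that returns the target whenever
the input lies within 10σ_t of it (Frobenius norm after optimal rigid
alignment) and the zero structure otherwise.  Interpolating a randomly
oriented noisy iterate toward a fixed-frame prediction drifts outside the
trigger and the trajectory collapses to zero.  `alignedReverseStep()`
rigidly superposes the prediction onto the noisy iterate (SVD-based
Kabsch with the det = +1 correction) before interpolating, which keeps
the iterate near a rigid copy of the prediction at all times.  The test
suite runs both variants over 100 seeds: the aligned one never collapses.

## Evaluation machinery

* **LDDT** uses the standard parameters: 15 Å inclusion radius on
  reference distances, thresholds 0.5/1/2/4 Å, pairs within one residue
  excluded.
* **Greedy symmetry correction** searches chain assignments within
  symmetric-entity groups (lexicographic enumeration, capped at 100
  candidates) and then per-ligand bonded-graph automorphisms (igraph VF2
  with element colours, capped at 1000, identity first), greedily keeping
  any permutation that raises the global LDDT; scoring is incremental,
  touching only the distance-matrix rows of the permuted atoms, and is
  tested to equal full recomputation to 1e-9.  Ties keep the first
  candidate in enumeration order.
* **Quality report** mirrors the steering constraints as six booleans:
  ligand bonds and 1–3 distances within 0.8L–1.2U, remaining intra-ligand
  pairs above 0.8L, chirality and stereo by quadruple sign/side, and
  inter-chain clash at the stricter reporting factor 0.75 (the steering
  potential engages earlier, at 0.725).  A ligand without bounds renders
  the three geometric checks `NA` — not evaluable, distinct from failure.
* **Pocket-aligned RMSD** superposes on the Cα/C1′ centers of reference
  residues within 10 Å of the ligand (the radius is a package default;
  the published description leaves it open), then minimises the ligand
  heavy-atom RMSD over graph automorphisms.

## Data-pipeline algorithms

**MSA pairing.**  Rows of per-chain alignments are joined by shared
taxonomy: taxonomies covering ≥ 2 chains are processed in descending
coverage (ties broken lexicographically by taxonomy id — the published
algorithm is silent, and determinism is worth more than any particular
order), chains with fewer sequences cycle via index-mod-count, missing
chains are filled from per-chain queues of leftover rows (popped without
replacement, aligner order preserved since aligners emit
most-similar-first), and remaining rows are appended until exhaustion or
the row cap (default 16384, the depth used with precomputed alignments).
No emitted row is empty — the construction preserves MSA density, which
matters because model cost scales with MSA depth.

**Unified cropping.**  Tokens are visited in ascending distance from a
center token (ties by token index) and each visited token contributes its
*neighborhood* — the same-chain contiguous residue window grown
symmetrically to the configured size, the whole chain if smaller, the
whole entity for non-polymers — atomically, until adding one would exceed
the token or atom budget.  Size 0 is exactly spatial cropping; a window
as large as the token budget is exactly contiguous cropping; sizes are
drawn uniformly from {0, 2, …, 40} at training time.  Windows grow by
index arithmetic regardless of numbering gaps (a deliberate reading of an
underspecified point: gap-aware growth would couple the crop to
deposition quirks).  Unresolved tokens are skipped as visit candidates
but may enter through windows.

**Pocket conditioning.**  With probability 0.3 a training iteration is
pocket-conditioned: a binder chain is drawn uniformly among ligand chains
(all chains if none), candidate tokens are those of other chains whose
nearest resolved heavy atom lies within 6 Å, and
`N = min(#candidates, 1 + M)` of them are revealed, with `M` geometric on
{1, 2, …} (p = 0.3) — so at least two pocket residues are revealed
whenever two qualify, and the expected count stays small, emulating a
user who knows a few key residues rather than the full interface.  The
inference-mode variant (`featurizePocketManual()`) takes an explicit
binder and residue list and bypasses all sampling.  One-hot order is
fixed: UNSPECIFIED, BINDER, POCKET, UNSELECTED.

## The synthetic test-bed

`makeToyComplex()` builds idealised helical pseudo-proteins (Cα plus a
sidechain-centroid pseudo-atom per residue: radius 2.3 Å, rise 1.5 Å,
100°/residue) and two annotated ligand templates — a tetrahedral chiral
center with CIP-ordered substituents (Cl > O > N > C) and an sp² double
bond with stereo/planar annotations plus two rotatable arms.  Bounds
matrices derive from the ideal geometry: exact for bonds, ±10% slack for
1–3 pairs (so that a stretched bond does not also fail the angle check),
and a 3.0 Å non-bonded floor.  Distances between chains (12 Å axis
separation) and to the ligand (≈ 5 Å gap) are chosen so that every
constraint is satisfied with margin and pocket candidates exist.

`injectViolation()` perturbs exactly one energy component: mirroring the
ligand through a plane (an isometry — chirality flips, distances do not),
rotating one end of the double bond by π (E↔Z), pyramidalising one sp²
substituent by 30° (inside the window where planarity fails but stereo
still holds), stretching a terminal arm bond, rotating an arm into a
non-bonded neighbour, translating chains into controlled clash or
overlap, and translating a covalently linked ligand away.  The overlap
injection slides the symmetric copy along the helix axis to a 2.6 Å
centroid offset with interleaved atoms — close enough to violate b_t,
far enough that no atom pair clashes; magnitude 0 gives the exactly
coincident case in which the overlap energy equals b_t by construction
(and clash necessarily fires too, which is why the surgical default is
non-zero).

What the generator does **not** emulate: real backbone geometry and
side-chain packing, flexible ligands with conformer ensembles, unresolved
density patterns, or any sequence–structure relationship.  Passing tests
therefore demonstrate algorithmic correctness — budgets respected,
hinges at the printed thresholds, invariances, convergence of the
steering loop — not predictive accuracy on real complexes.

## Problem sizes and numerical conventions

The shipped studies run on one CPU in a few minutes: steering studies use
21-step schedules, 4 particles and 100 paired seeds per violation
fixture; the distribution-identity check uses 2000 runs of a
one-atom/10-step system against an independent simulation of the same
kernel; the collapse study uses 100 seeds of a 40-step schedule; the
pocket-conditioning rate uses 20,000 seeded featurizations (3 binomial
standard errors ≈ ±1 percentage point); boundary locations use bisection
to 1e-6.  These sizes are the package's chosen operating points for its
test-bed, small enough to run everywhere and large enough that the
statistical assertions have comfortable margins.

Other conventions: coordinates are Ångström, right-handed, in file frame;
residue indices are author-assigned and treated as opaque ordered
integers; unresolved atoms keep placeholder coordinates with
`is_resolved = FALSE` and are masked from every geometric operation;
all randomness flows through explicit seeds and the caller's RNG state is
restored afterwards.

## Known limitations

* The toy denoisers are state-independent; they exercise the steering
  loop's correctness but cannot show the cooperative denoiser–guidance
  repair a trained model exhibits.
* Automatic CIP priority assignment is out of scope — chirality and
  stereo annotations are supplied (by the fixture generator or a JSON
  sidecar), not derived from the molecular graph.
* Chain-assignment search enumerates per-group permutations; for very
  high copy numbers the 100-candidate cap truncates the space, exactly as
  the published procedure's cap does.
* mmCIF support covers the `atom_site` loop (the part the algorithms
  need), not assemblies, alternate locations beyond first-pick, or
  chemical-component dictionaries.
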