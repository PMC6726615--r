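---
title: "Restrained model generation from predicted distance distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restrained model generation from predicted distance distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distfold)
```

## The problem

Modern protein structure predictors emit, for every residue pair, a
*distogram*: a probability distribution over binned Cβ–Cβ distances,
alongside a directional backbone hydrogen-bond donor/acceptor likelihood
map and per-residue φ/ψ torsion predictions with error estimates.
Turning these probabilistic predictions into concrete three-dimensional
backbones is a restrained-optimization problem in the style of NMR
structure determination: distributions become NOE-like flat-bottom
distance bounds, torsion predictions become dihedral wells, and a
restrained annealer searches for conformations satisfying as many of
them as possible.  Because a single round of models can itself inform
the predictor (through the Cβ distance matrix of a representative
model), the whole procedure is iterated a small number of times.

distfold implements that model-generation machinery end to end, with
the deep-learning predictor abstracted behind a function interface.  A
synthetic oracle stands in for the trained networks, deriving noisy
predictions from a known reference structure, so every pipeline stage
is exercisable and testable offline.

## Distograms and restraint derivation

The distance axis is divided into 20 bins: 3.5–4.5 Å, seven 0.5-Å bins
to 8 Å, eleven 1-Å bins to 19 Å, and an unbounded final bin.  Raw
predictor scores for the two triangles are combined by a per-pair
softmax of the score tensor plus its transpose (`symmetrize()`), which
both enforces the physical symmetry of the distance matrix and
ensembles the two independent triangle predictions.

Distance bounds are derived per pair by *likelihood accretion*
(`accrete_bounds()`): starting from the maximum-likelihood bin, the
contiguous bin interval grows toward whichever neighbouring bin carries
more likelihood until the cumulative likelihood reaches a threshold,
0.4 by default.  Flat, uncertain distributions therefore produce wide
bounds and confident ones tight bounds.  The unbounded final bin never
participates: pairs whose maximum-likelihood bin is the final bin
produce no bound, accretion never extends into it, and pairs that
cannot reach the threshold without it are also skipped, so every upper
bound stays at or below the last finite edge (19 Å).  When the two
neighbours tie exactly, the interval extends toward shorter distances;
the tie-break is deterministic so bound sets are reproducible.

Hydrogen-bond restraints come from cells of the donor/acceptor map at
or above a 0.85 likelihood threshold.  The geometric target is a
flat-bottom well on the donor-N to acceptor-O distance of 2.7–3.2 Å,
the range observed in well-resolved crystal structures; satisfaction is
judged at the looser 3.5 Å criterion that also defines a geometric
hydrogen bond in `detect_hbonds()`.  No explicit hydrogens are
modelled; at backbone resolution the N–O distance carries the
constraint.  φ and ψ predictions become dihedral wells whose half-width
is the predictor's own error estimate, floored at 5° (0.087 rad); ω is
discarded because predictors show no skill on rare cis-peptides.
Distance bounds are emitted for pairs at sequence separation ≥ 2;
nearest neighbours are governed by bonded geometry anyway.

## The builder

`build_ensemble()` replaces an external restrained-dynamics engine with
a transparent two-stage scheme:

1. **Distance-geometry embedding** (`embed_initial()`).  Smoothed bound
   matrices (`smooth_bounds()`: sequential-neighbour ladder, shortest-
   path upper-bound tightening, inverse-triangle lower-bound lifting)
   are sampled, double-centred, and eigen-decomposed (classical
   multidimensional scaling).  The resulting trace is then polished
   against the bounds: it is lifted into a fourth spatial dimension in
   which the chain can pass through itself, the summed squared bound
   violations are minimized while a growing harmonic penalty squeezes
   the fourth coordinate away, and leftover violations are attacked by
   jittered three-dimensional restarts.  The four-dimensional squeeze
   is what rescues the embedding from topological traps (knots and
   threaded loops) that defeat purely three-dimensional minimization.

2. **Restrained simulated annealing** (`refine()`).  A full backbone
   (N, CA, C, O, CB) is placed around the trace and all atoms are
   optimized in Cartesian space.  The energy is a sum of flat-bottom
   quadratic wells for distance and H-bond restraints (soft-square
   beyond 1 Å of violation, so a few irreconcilable restraints cannot
   dominate), circular-difference wells for torsions, stiff harmonic
   terms for ideal bonded geometry (bond lengths plus 1–3 distances
   standing in for bond angles), a chirality term, and a soft-clash
   floor at 2.2 Å between atoms of residues two or more apart.
   Annealing runs geometric cooling; each stage jitters coordinates in
   proportion to the temperature, re-minimizes monotonically with
   L-BFGS, and applies a Metropolis test, so energy never rises within
   a stage while stochastic uphill moves remain possible between
   stages.  A final quench re-minimizes the best state with the
   restraint wells up-weighted eight-fold so restraints that sit at a
   well edge settle strictly inside their bounds.

Two numerical devices deserve a note.  Flat-bottom wells have zero
gradient across their plateau, which stalls quasi-Newton descent at
well edges; a weak *centre pull* (default 2% of the well weight,
capped at its own value at the well edge so it can never push another
restraint out of its well) lifts that degeneracy during search.  The
pull is a search heuristic only: the retained optimum and all reported
energies are judged on the physical restraint-plus-geometry energy,
and the final quench runs with the pull off.

**Chirality and mirrors.**  Distance information is invariant under
reflection, so distance geometry happily produces mirror-image folds.
Every embedding is therefore refined in both hands (one axis negated)
and the lower-energy hand kept.  Discrimination comes from two terms:
a per-residue improper dihedral C–N–CA–CB held at +122.6°, the value
measured in high-resolution structures of L-amino acids, and a
left-handed-helix penalty on the CA(i)…CA(i+3) virtual dihedral,
applied only where three consecutive i,i+3 spans are helix-like
(< 6.5 Å) so that isolated tight turns — which legitimately visit
left-handed conformations — are never penalized.

## Ensembles, selection, iteration

Ensemble members are clustered by greedy leader clustering on pairwise
TM-score (threshold 0.6; TM-score is scale-independent where an RMSD
threshold would need retuning per chain length).  Within the largest
cluster the representative is the member with the lowest internal
quality score — restraint-violation energy plus clash energy — an
internal stand-in for the external statistical potentials used in the
original protocol, chosen so that selection requires no third-party
binaries.  Ties break by total energy, then ensemble index.

`run_pipeline()` drives the loop: iteration 1 predicts unseeded and
derives all three restraint classes; dihedral restraints are computed
once there and reused verbatim in later iterations (recomputing them
iteratively showed no benefit in the original protocol and the same
choice keeps the iteration signal attributable to distances and
H-bonds).  Every later iteration passes the previous representative to
the predictor, which conditions on its Cβ distance matrix, then
rebuilds and reselects.  Three iterations are the default; improvement
typically saturates well before five.

## The synthetic oracle

The oracle derives predictions from a reference structure with
controllable degradation:

* **Distograms** — per pair, the bin mass is the Gaussian probability
  mass of each bin interval centred on the true Cβ–Cβ distance with
  standard deviation `distance_sigma` (default 1.0 Å).  Integrated bin
  mass rather than density sampled at bin centres guarantees the
  zero-noise limit puts all mass exactly in the true bin even next to
  bin edges.  The unbounded final bin receives the upper tail; mass
  below 3.5 Å is clamped into the first bin.  A `corruption_rate`
  fraction of pairs (default 0.1) is replaced by exactly uniform mass —
  such pairs emit a wrong, wide bound through accretion, which is the
  intended stress.
* **Seed conditioning** — when a seed model is supplied, pairs whose
  seed distance lies within 2 Å of the truth are re-blurred with sigma
  shrunk by `(1 - seed_coupling)` (default 0.5).  This truth-gated
  sharpening reproduces, without any trained weights, the qualitative
  mechanism by which a partially correct model improves the next
  round's predictions.
* **H-bond maps** — geometrically true donor→acceptor cells (N–O ≤
  3.5 Å) receive likelihood 0.95, others 0.05.  Noise misses true cells
  with probability `corruption_rate` and promotes a budget of false
  cells equal to twice `corruption_rate` times the true count,
  mimicking the ~80% precision of a realistic H-bond predictor.  A
  uniform per-cell flip at the same nominal rate would bury the signal
  under hundreds of false strong restraints, which no restrained
  builder survives and no real predictor produces.
* **Torsions** — true φ/ψ plus wrapped-Gaussian noise of width
  `torsion_sigma` (default 0.2 rad); the reported error estimate is the
  noise width itself, so deviation fields are well calibrated.

Toy reference folds (`make_toy_fold()`) realize a secondary-structure
string with ideal φ/ψ per state and coil angles hill-climbed (seeded,
deterministic) toward compact, clash-free conformations with genuine
long-range contacts — without the hill climb, independently sampled
coil angles almost never fold back on themselves, leaving nothing for
long-range restraints to determine.  What the oracle does **not**
emulate: correlated errors along secondary-structure elements,
alignment-depth-dependent accuracy, multi-domain architecture, or any
relationship between sequence content and error.  Passing tests
therefore demonstrate the correctness and closure of the
model-generation machinery, not predictive performance on real
proteins.

## Estimated model accuracy

Four features summarize a model against the *first-iteration*
distogram: sequence length, alignment effective-sequence count, and the
sum and mean over residue pairs of the likelihood of the bin containing
each pair's model Cβ distance.  A small softmax network (4 inputs, two
SELU hidden layers of 10, 10 outputs over TM-score tenths) is trained
by cross-entropy with Adam at a maximum learning rate of 1e-3 over
repeated random 70/15/15 splits (100 by default); the expected TM-score
is the probability-weighted mean of the class midpoints, and a model is
called fold-correct at expected TM > 0.5.  At desk scale the training
labels come from synthetic pipelines where the true TM is known.

## Alignment statistics

Effective sequence counts use transparent greedy leader clustering on
pairwise identity (matches over columns where at least one row is
non-gap; both-gap columns are ignored): Neff is the cluster count at
62% identity, Nf the count at 80%, optionally divided by the square
root of the alignment length — the normalization convention differs
between studies, hence the explicit flag.  The word-filter heuristics
of fast clustering tools are deliberately not reproduced; the greedy
pass over full pairwise identities in input order is the documented
contract.

## Problem sizes and defaults

The package's own test and validation runs use desk-scale problems
chosen to exercise every mechanism: toy folds of 30–60 residues,
ensembles of 2–10 models, annealing schedules of 4–12 stages with
30–60 minimizer iterations per stage, and a 20-target study for the
iteration-improvement property at the oracle's default noise
(`distance_sigma` 1.0 Å, `corruption_rate` 0.1, `seed_coupling` 0.5).
The builder defaults (`builder_config()`) are tuned for chains up to
about 100 residues; weights are exposed and documented there.  The
annealing default of 12 stages × 60 moves reflects the quasi-Newton
stage minimizer, which converges in far fewer evaluations than the
plain Monte-Carlo moves a molecular-dynamics engine would need for the
same schedule.

## Known limitations

* All-atom detail (side chains beyond Cβ, explicit hydrogens) and
  physics-based force fields are out of scope; models are backbone-only.
* The helix-handedness gate is geometric; exotic non-helical compact
  conformations with three consecutive short i,i+3 spans would be
  penalized even when legitimate.
* Restraint satisfaction after refinement converges to ~95–99% on
  zero-noise toys but not to exactly 100%: the annealer optimizes a
  frustrated many-term objective and small residual violations at well
  edges survive in basins a fraction of an ångström from the global
  optimum.
* TM-score uses the fixed 1:1 residue correspondence; sequence-
  independent structural alignment is out of scope.
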