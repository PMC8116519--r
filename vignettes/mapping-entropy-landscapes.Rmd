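---
title: "Exploring mapping-entropy landscapes of coarse-grained protein representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploring mapping-entropy landscapes of coarse-grained protein representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A decimation coarse-grained (CG) representation of a protein keeps `N` of its
`n` heavy atoms verbatim and integrates the rest out. Different selections of
retained atoms discard different amounts of information about the system's
configurational statistics. The quantity that measures this loss is the
*mapping entropy* `S_map`: the Kullback–Leibler divergence between the
atomistic Boltzmann distribution `p(r)` and the distribution obtained by
pushing each CG macrostate's probability back down uniformly over all
atomistic configurations that map onto it. `S_map >= 0`, it vanishes when the
mapping loses nothing (for example when every microstate is its own
macrostate, or when the distribution is uniform), and it grows as the
coarse-graining grid becomes blinder to the system's structure.

Minimizing `S_map` over the `choose(n, N)` possible subsets singles out
maximally informative reduced representations, but the space is
astronomically large and each direct evaluation of `S_map` from sampled
configurations is expensive. `mapent` implements the full pipeline that makes
this exploration tractable:

1. an **attributed contact graph** encoding of the structure plus a candidate
   mapping (`load_structure()`, `build_graph()`, `encode_mapping()`);
2. **mapping-entropy estimators** — exact for discrete toy systems
   (`exact_smap_discrete()`), variance-based for sampled ensembles
   (`assign_macrostates()`, `estimate_smap()`);
3. a **deep graph-network surrogate** trained to predict `S_map` from the
   graph alone (`train_surrogate()`, `predict()`);
4. **enhanced-sampling engines** over the fixed-`N` subset space:
   simulated annealing for minimization (`simulated_annealing()`) and
   Wang–Landau flat-histogram sampling for the density of states
   (`wl_run()`);
5. a **synthetic module** (toy structures, analytic oracles, discrete
   ensembles, exhaustive enumeration) so the whole pipeline is testable with
   no external data.

## The contact-graph representation

Vertices are heavy atoms (C, N, O, S — anything else is rejected at load,
and hydrogens, waters, ions and hetero ligands are dropped). An undirected
edge joins every pair of atoms strictly closer than a cutoff, 1 nm by
default, and carries the inverse distance (in 1/nm) as its scalar feature.
Each vertex carries 10 binary features: a one-hot element class (C/N/O/S), a
one-hot residue class, the backbone flag (atom name among N, CA, C, O) and
the site flag, which is 1 exactly when the atom is retained by the mapping
under consideration. The site flag is how a candidate mapping is shown to
the network: the graph is static, only that one column changes between
candidates.

The residue classes are hydrophobic = {ALA, VAL, LEU, ILE, PRO, PHE, MET,
GLY}, amphipathic = {TRP, TYR, THR}, polar = {SER, CYS, ASN, GLN, HIS} and
charged = {ASP, GLU, LYS, ARG}. This is a standard hydropathy grouping; the
published feature scheme names the four classes but not the assignment, so
the table lives in one exported constant (`RESIDUE_CLASS`) and can be
swapped wholesale if a different convention is preferred.

Two bookkeeping conventions matter when comparing against published
contact-graph statistics. First, each unordered edge is stored once, but
reported edge counts are directed (twice the stored pairs): published
per-protein figures — e.g. 21,474 edges over 230 vertices giving average
degree 93 — are only reproduced by the ordered-pair count with the ratio
truncated to an integer, which is what `graph_stats()` returns. Second,
distances are computed on the single input conformation with a strict
`d < cutoff` inequality, and coincident atoms are a hard error rather than
an infinite weight. Note that published graphs for real proteins were built
from an MD snapshot rather than the deposited crystal structure, so edge
counts depend on a conformation that is not generally available; vertex
(heavy-atom) counts do not.

## The surrogate network

The surrogate is a graph isomorphism network extended with scalar edge
weights. With hidden width `K` (default 64) and `L` layers (default 5,
counting the embedding layer), the forward pass is:

- embedding: `h1_v = ReLU(W1' x_v + b1)`, independent of edges;
- `L - 1` graph convolutions:
  `h(l+1)_v = ReLU(W' [(1 + eps_l) h(l)_v + sum_{u in N(v)} h(l)_u e_uv] + b)`,
  with one adaptive scalar `eps_l` per layer and no weight sharing across
  layers;
- readout: each vertex's `L` states are concatenated into a length `K*L`
  vector, scaled by the adaptive scalar `w_site` for retained vertices and
  `w_nonsite` otherwise, summed over vertices, and projected onto the
  output vector `w_out`.

Every "MLP" here is deliberately a single affine map plus ReLU: that is what
makes the published weight census hold. Excluding biases, the count is
`10K + K^2 (L-1) + KL + (L-1) + 2`, which is 17,350 at the reference size
(`count_weights()`, verified against an instantiated model's scalar census
by `model_weight_census()`). A uniform mean-pooling readout is also
described alongside the weighted sum in the source architecture sketches;
the weighted sum is canonical here because it is the variant consistent with
the weight census, and the mean variant is kept behind
`readout(..., variant = "mean")` for comparison only — training always uses
the canonical readout.

Training minimizes the mean absolute error with Adam (learning rate 0.001,
no weight decay, mini-batches of 8), an 80/10/10 hold-out split drawn as one
uniform shuffle (no stratification by sample origin), and early stopping
that returns the weights of the epoch with the best validation MAE, halting
once that best has not improved for `patience` epochs. The validation metric
for model selection is the MAE, consistent with the loss; `R^2` is the
headline evaluation metric on the test set. Targets are used in kJ/mol/K
without standardization by default; `surrogate_config(normalize = TRUE)` is
a documented toggle that standardizes targets on the training split and
folds the transformation back into predictions. Affine weights initialize
from a symmetric fan-in-scaled uniform distribution, epsilons at 0, the
readout scalars at 1 (plain sum pooling); all randomness — initialization,
the hold-out shuffle and the per-epoch batch order — derives from the single
`seed` in the configuration, so a rerun is bitwise reproducible. The
forward/backward pass is compiled (RcppArmadillo); the exported R-level ops
`embed_vertices()`, `gin_layer()` and `readout()` define the reference
semantics and the compiled path is tested against their composition.

## Mapping-entropy estimators

For a discrete system (`m` microstates with probabilities `p`, a partition
into macrostates), `exact_smap_discrete()` evaluates the KL divergence
directly: `sum_r p_r log(p_r / pbar_r)` with
`pbar_r = P(macro(r)) / Omega(macro(r))`. The result is in units of `k_B`;
multiply by `KB_KJ_MOL_K` (fixed at 0.0083145 kJ/mol/K so that all outputs
carry the conventional units) to get kJ/mol/K.

For sampled ensembles the package implements the variance-based
approximation: a weighted average over CG macrostates of the variances of
the atomistic potential energies of the frames mapping onto each
macrostate. Three choices are deliberate and documented:

- **Macrostate identification.** Continuous coordinates never repeat
  exactly, so frames are grouped by single linkage under the
  max-over-retained-atoms distance, cut at a user-supplied tolerance in nm.
  The tolerance has *no default*: what counts as "the same CG
  configuration" is an analysis decision, and silently defaulting it would
  hide the most consequential knob of the estimator. Tolerance 0 recovers
  exact coordinate equality.
- **Population variance,** weighted by frame counts. This is the most
  direct reading of "weighted average of the variances"; singleton
  macrostates contribute zero. A sample-variance variant would differ at
  small occupancies only.
- **Prefactor.** The estimator is the second-order term of a cumulant
  expansion of the KL divergence; the constant in front is
  `k_B beta^2 / 2` (`prefactor_mode = "cumulant"`). That this is the right
  constant is checked analytically by the vanishing-fluctuation limit: for
  a discrete system whose within-macrostate probabilities are Boltzmann
  with energy spread `delta -> 0`, `KL -> beta^2 Var(u) / 2` per macrostate,
  and the test suite verifies the estimator converges to
  `k_B ×` exact KL with monotonically shrinking relative error. The exact
  higher-order weights of the full expansion live in the method's original
  derivation and are out of scope; `prefactor_mode = "unit"` isolates the
  structural part for oracle testing.

## Sampling engines

**Simulated annealing.** The elementary move swaps one retained atom with
one non-retained atom — a symmetric proposal (each of the `N(n-N)`
neighbors is equally likely, in both directions) that keeps `N` fixed and
connects the whole subset space. Moves are accepted with the Metropolis
probability `min(1, exp(-(S' - S)/T(i)))` under the exponential schedule
`T(i) = T0 exp(-i/v)`. The published protocol names the criterion and the
schedule but defers `T0` and `v` to earlier work without printing them, so
the defaults here are calibrated per run — `T0` as the score standard
deviation over 100 random mappings, `v = steps/5` — and both are recorded
in the result. For data-set generation the four run-length presets
(20,000 / 10,000 / 5,000 / 2,500 steps, equal shares) mirror the published
composition of optimized-mapping pools.

**Wang–Landau.** The score axis is discretized into bins of width 0.2
(half-open, top edge closed); a swap-move walk is biased by the running log
density of states, accepting with `min(1, exp(Sigma_cur - Sigma_prop))` and
rejecting outright any proposal scoring outside `[s_min, s_max]` — on
rejection the *current* bin is the one updated. Every visit adds `ln f` to
the visited bin's `Sigma` and 1 to its histogram; when the histogram is flat
(every visited bin strictly within `(p_flat, 2 - p_flat)` times the mean,
`p_flat = 0.8`), the histogram resets and `ln f` halves, from `ln f0 = 1`
down past `ln f_end = 1e-6` — exactly 20 halvings. `Sigma` is defined up to
an additive constant; `dos_to_probability()` exponentiates and normalizes it
(log-sum-exp stabilized) into the distribution of scores expected under
uniform random sampling of mappings restricted to the window.

Decisions the published protocol leaves open, fixed here: flatness is
checked every `check_interval = 1000` moves (logged); bins never visited
across the whole run keep a sentinel `Sigma = -Inf` and are excluded from
flatness checks and given probability zero; the first in-range mapping is
found by uniform redraws with a budget of 1e5; `Sigma` starts at zero in
every bin (all densities 1). The sampling window would in production be set
from the score range of the training data set, mirroring how the published
runs bound their landscape by the data-set extrema; the toy validations here
use the enumerated score range for the same reason.

A converged run's `Sigma` carries a residual stochastic error — in practice
a few hundredths in log units for the toy spaces below, far better than the
0.2 log-unit tolerance asserted in the tests but far worse than the binomial
error of a large brute-force sample. Consistency checks against random
sampling therefore average several independent WL replicas and combine the
between-replica standard error with the binomial one; a single run's
`dos_to_probability()` output should be read with that error scale in mind.

## The synthetic module

`make_toy_structure()` produces a self-avoiding chain of pseudo-residues
(0.5 nm center spacing, 1–8 heavy atoms each, elements from {C,N,O,S},
backbone names N/CA/C/O for the first four atoms, at least 0.05 nm between
any two atoms, residue names drawn from the 20 standard codes). It stands in
for a reference protein conformation: every contact-graph invariant holds,
but there is no realistic stereochemistry, secondary structure, or
energetics.

`make_toy_oracle()` provides the analytic scoring rule
`a * (sum of inverse distances over retained pairs within 1 nm) +
b * (retained backbone count) + c * (seeded hash roughness in [-1, 1])`,
with defaults `a = 1`, `b = 0.5`, `c = 0`. The defaults were chosen once, on
the following grounds: the pair term dominates and shares the contact
graph's inverse-distance structure, so the GIN architecture can represent
the smooth landscape exactly (one convolution propagates site indicators
through the weighted adjacency; the readout's site scaling restricts the sum
to retained vertices) — which makes desk-scale training a meaningful
analogue of the real regression task rather than an arbitrary one; the
backbone term adds a feature-dependent offset at roughly a third of the pair
term's scale; and `c = 0` keeps the reference landscape smooth, with
`c > 0` available to destroy learnability on purpose. Scores are
listing-order invariant and deterministic.

`make_discrete_ensemble()` realizes a discrete system as a coordinate
ensemble: two synthetic atoms per frame encode the macrostate label and the
microstate identity respectively, so retaining atom 0 makes
`assign_macrostates()` with tolerance 0 recover the generating partition
exactly, while the identity mapping resolves microstates.
`exhaustive_dos()` enumerates spaces up to 1e6 subsets and is the
ground-truth oracle for the Wang–Landau validations.

## Problem sizes used in the validation suite

The published application trains on thousands of MD-labeled mappings of real
proteins and runs WL for millions of moves; those inputs (200 ns
trajectories and their `S_map` labels) are not shipped here, and headline
numbers tied to them (per-protein test scores, hardware timings, real
landscapes) are out of scope. The package's own validation instead runs the
identical machinery at sizes chosen so the whole suite completes in minutes
on one core while every check retains statistical teeth:

- WL against exhaustive enumeration on `C(10,3) = 120` and
  `C(12,4) = 495` mapping spaces, bin width 0.2, full 20-halving schedule;
  agreement within 0.2 log units RMS after an additive shift at the modal
  bin.
- WL-vs-random-sampling consistency with 1e6 uniform mappings and 8 WL
  replicas, bin-by-bin within 3 combined standard errors.
- Surrogate learnability on a 100-atom toy structure with `N = 22` (the
  residue count, mirroring the one-site-per-residue convention), 3,000
  samples (2,536 random + 464 SA-optimized, the published random:optimized
  ratio), `K = 16`, `L = 3`, 500 epochs with patience 100: test `R^2`
  must reach 0.9, and a permuted-label control must collapse to
  `R^2 ≈ 0`. The reduced width/depth suffices because the smooth oracle is
  exactly representable at this capacity (see above); the reference
  `K = 64, L = 5` architecture is what `count_weights()` certifies and what
  production training would use.
- Estimator checks at 4e5-frame exact-weight ensembles; SA greedy-limit
  optimality over 100 seeded runs on the 120-mapping space.

What passing these does and does not show: it validates the algorithms —
the estimators against analytic values, WL against enumeration, the
surrogate's capacity to regress a graph-structured target — but it cannot
certify accuracy on real proteins, where labels come from MD sampling noise,
the landscape is rougher than the smooth toy oracle, and generalization
across the mapping space is the empirically hard part.

## Known limitations

- Single chain, single model, standard amino acids only; no mmCIF, no
  ligands or nucleic acids.
- `S_map` estimation from ensembles requires energies as inputs; the
  package never evaluates a force field.
- The macrostate tolerance is the user's responsibility, and single-linkage
  grouping can chain distinct basins at generous tolerances.
- Wang–Landau is the plain flat-histogram variant: no 1/t schedule, no
  multi-window stitching; very wide windows converge slowly.
- Cross-protein transfer of a trained surrogate is explicitly not
  attempted: a model is tied to the structure whose graph it was trained
  on.
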