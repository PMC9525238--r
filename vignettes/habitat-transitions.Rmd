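---
title: "Modelling habitat transitions across the salt barrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling habitat transitions across the salt barrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical machinery: the
model of habitat evolution, the priors and samplers, the reconstruction and
counting conventions, what the synthetic-data generator does and does not
emulate, and the choices made where the design was genuinely open.

## The evolutionary model

Habitat preference is treated as a binary trait — `marine` vs `non_marine`,
where non-marine pools soil and freshwater (a fixed, idempotent collapse
map also accepts the four-state vocabulary soil / freshwater /
marine-euphotic / marine-aphotic) — evolving along a phylogeny with branch
lengths in expected substitutions per site. The process is a two-state
continuous-time Markov chain (Mk2) with rates `q_mn` (marine to
non-marine) and `q_nm` (reverse), in transitions per substitution/site.
Because the chain has two states it is automatically time-reversible, with
stationary frequencies `pi = (q_nm, q_mn) / (q_mn + q_nm)` and the closed
form

$$P_{ij}(t) = \pi_j + (\delta_{ij} - \pi_j)\, e^{-(q_{mn}+q_{nm})\,t}.$$

The likelihood of the tip labels is computed by Felsenstein pruning in a
single post-order pass. Numerical notes:

* partial likelihoods are rescaled per node with the log correction
  accumulated separately, so trees with tens of thousands of tips do not
  underflow;
* zero-length branches use the identity matrix exactly (no epsilon), which
  makes pruning after unifurcation collapse well defined; data made
  impossible by conflicting states across zero-length branches give
  `-Inf`, not an error, so samplers can reject such proposals;
* the zero rate matrix (`q_mn = q_nm = 0`) is legal for simulation and
  transition probabilities (identity kernel) but cannot be normalized.

**Rate regimes.** For clade-heterogeneous models, named clades (tip-set
defined, monophyly enforced) are painted onto branches. A clade's regime
covers all branches inside it *and its stem branch* — the rationale is
that a transition "into" a clade should be governed by the clade's rates —
and nested clades resolve to the smallest containing clade. Whether stems
belong inside or outside a clade regime is not observable from any single
convention's output alone, so the convention is fixed, documented, and
applied uniformly; with all regimes equal the painted likelihood collapses
exactly to the homogeneous one (a tested invariant).

**Root policy.** The root state prior is configurable: `equal`
(0.5/0.5, the default and the common MultiState convention), `stationary`
(the chain's equilibrium, under which the likelihood is invariant to
re-rooting by reversibility — also a tested invariant), or `fixed(p)`.
Equal is the neutral default; deep-node analyses should be run under the
alternative rootings of interest rather than relying on any single root
prior.

**Global rate.** For "how fast does this clade cross the salt barrier
overall", the rate matrix is normalized: `r = pi_m q_mn + pi_nm q_nm`
(equivalently `2 q_mn q_nm / (q_mn + q_nm)`) is the expected number of
transitions per unit branch length at stationarity, and `Q/r` retains the
stationary distribution with unit flux. `r` is directly comparable across
clades regardless of directional asymmetry.

## Priors, reversible jump, and marginal likelihoods

Rates get an exponential prior whose mean `m` is itself uniform on
(0, 2) — a weakly informative hyperprior centred on rates of order one
transition per substitution/site. The model indicator (equal vs unequal
rates) has prior probability 0.5 each.

The sampler is Metropolis-within-reversible-jump:

* sliding-window proposals on `m` (rejected outside its support) and
  multiplicative log-normal proposals on each free rate, with the
  `q'/q` Jacobian;
* the dimension-changing move merges the two rates to their geometric mean
  and splits them by factors `exp(±u)` with `u ~ N(0, 0.5)`; the
  acceptance ratio carries the proposal density and the Jacobian `2q`.
  The scheme is validated by prior-only runs (likelihood tempered to
  zero), which recover `m ~ U(0,2)`, the conditional exponential law of
  the rates (by probability integral transform) and a 50/50 model
  indicator;
* proposal scales are auto-tuned toward 20–40% acceptance during burn-in
  and frozen afterwards.

**Tree sets.** Phylogenetic uncertainty enters by running over a set of
trees sharing one tip set. The default schedule (`cycle`) allocates a
fixed number of generations to each tree in turn and pools the
post-burn-in draws — the schedule used with sets of ~100 alternative
phylogenies — while `swap` mode treats the tree index as a sampled
parameter with uniform Metropolis proposals.

**Stepping stone.** Marginal likelihoods use a ladder of power posteriors
`beta_k = (k/K)^{1/0.4}` (Beta(0.4, 1) quantiles, the standard
recommendation; the study-scale settings are K = 50 stones of 5,000
generations). The prior stone is sampled i.i.d. directly; each subsequent
stone starts from the previous stone's final state. The estimator is the
usual sum of log-mean powered likelihood ratios, with a delta-method
Monte-Carlo standard error. It is checked against 1-D adaptive quadrature
on a fixed-hyperparameter model and for internal consistency across K.
Model comparison reports `logBF = 2 (logZ_A - logZ_B)` with 10 as the
decisive threshold.

Per-tree burn-in defaults to half the generations, mirroring the
0.5M-of-1M schedule at study scale; the desk-scale defaults
(`gens_per_tree = 2000`, `thin = 10`) are sized so a 200-tip tree samples
in a couple of seconds.

## Ancestral states and transition events

Marginal per-node posteriors use the standard up-down (inside-outside)
algorithm; sibling products are re-accumulated rather than divided out, so
zero partials (certain tips, zero-length branches) cannot poison the
downward pass. The single best habitat history is the *exact joint*
maximum-likelihood assignment (Pupko dynamic programming), not the
collection of per-node marginal maxima and not a multi-state
MPPA-style set: downstream event counting needs one concrete history, and
the exact joint optimum is reproducible and directly testable against
exhaustive enumeration. Ties (exactly symmetric configurations) are broken
deterministically — higher marginal posterior first, then marine — and
flagged, so downstream counts on tied histories can be read as ranges.

**Counting.** Every edge whose endpoints differ is a directed transition
event. An event is *counted* only if at least `min_clade_size = 2`
descendant tips are reachable from the child through nodes of the new
state — "reachable without a further state change", which resolves what
happens when a reversal occurs inside the founded clade. This persistence
rule filters non-establishing colonists (stray tips) from established
residents; setting `min_clade_size = 1` recovers the raw total, and the
tallies report both populations.

**Timing.** Clade trees are converted to relative chronograms by mean path
length: each node's age is the mean distance to its descendant tips (the
calibration-free core of Pathd8-style dating — the full calibrated
algorithm is deliberately not reproduced since only relative ages are
needed), monotonicity is enforced by lifting a parent to just above its
oldest child (`1e-9` of the root age), and ages are scaled to root = 1,
tips = 0. An event on an edge is placed at the edge midpoint — unbiased
under a uniform position prior; parent- and child-end conventions are
available — and reported as time from the root (0 = root, 1 = present).

## Community analyses

Unweighted UniFrac between two tip sets is the unique fraction of covered
branch length (branches leading to neither set are excluded).
Significance uses a Monte-Carlo null that shuffles tip identities across
the union of the two compared communities only — preserving sizes and
overlap, mirroring the unweighted-test scheme of the mothur
implementation — with `p = (1 + #{null >= obs}) / (1 + n_perm)` and
Bonferroni adjustment across pairs; 1,000 randomizations is the reference
setting. Habitat dendrograms use UPGMA on the distance matrix.

Similarity networks are built from 12-column tabular all-against-all hit
tables. Coverage is alignment length over *query* sequence length (the
denominator must be supplied; subject-coverage is a caller-side swap of
the lengths vector), the reference thresholds being identity 80–97 and
coverage 75. Self-hits are dropped and duplicate pairs collapse to the
maximum identity; reciprocity can be required but is off by default since
single-direction hit lists are common. Assortativity is Newman's nominal
coefficient over the habitat mixing matrix (via igraph); raising the
identity threshold can only remove edges, so assortativity profiles across
thresholds are computed on nested graphs.

## The synthetic-data generator

The generator is the package's stand-in for the study-shaped data every
stage expects:

* **Trees**: birth–death simulations conditioned on the tip count
  (50–5,000 is the intended range), ultrametric in time units, optionally
  rescaled to a substitutions/site regime. Real OTU phylogenies are *not*
  ultrametric and carry topological error; the rescaling knob and the
  jittered tree sets (below) emulate rate variation and branch-length
  uncertainty, but topology is held fixed within a set, which is milder
  than genuine phylogenetic uncertainty.
* **Histories**: exact Gillespie simulation of the two-state chain down
  each branch (regime-aware), recording every event with its position as a
  branch fraction. Replaying recorded events reproduces the tip labels —
  a tested identity — and the recorded truth is what reconstruction and
  counting are scored against.
* **Tree sets**: per-branch i.i.d. log-normal length jitter (mean-corrected
  by default), emulating the "100 alternative phylogenies" design.
* **Bundles**: `study_like_bundle()` writes per-clade tree sets, habitat
  tables, true states/events and a checksummed JSON manifest, with clade
  regimes chosen to contrast a fast, non-marine-biased clade against a
  slow symmetric one — the pattern the inference module must be able to
  tell apart.

Passing tests on these data demonstrate the *estimators* are correct and
calibrated under the model; they cannot demonstrate robustness to model
violations present in real data (habitat misannotation, OTU clustering
artefacts, unsampled extinct lineages, non-Markovian habitat dynamics).

## Problem sizes and calibrated expectations

The test and acceptance workloads are sized for a single CPU:
enumeration oracles use trees of up to 8 tips (exhaustive state spaces);
rate-recovery calibration uses 50 replicates of 200-tip trees at the
homogeneous reference rate 0.19, judged by the 3-posterior-s.d. criterion;
the heterogeneous-vs-homogeneous Bayes factor uses a 400-tip tree with a
10×-asymmetric clade regime (2.0/0.2) over a symmetric 0.3/0.3 background
and 15 stones × 800 generations — at 150 tips a single history draw is
genuinely underpowered for a decisive Bayes factor, which is an honest
property of the statistic, not of the implementation.

Two expectations deserve explicit framing:

* *Symmetric truth does not force a symmetric posterior on every draw.* At
  `q = 0.5` on a 200-tip tree, roughly one simulated history in six
  realizes enough directional imbalance that the unequal-rates model is
  correctly preferred for that dataset (confirmed independently by
  stepping-stone Bayes factors). Consistency claims are therefore judged
  across replicate datasets, with replicate chains checked for agreement
  on a single dataset.
* *"Low rates" for reconstruction concordance* is defined intrinsically as
  about 0.1 expected transitions per root-to-tip lineage (0.02 per time
  unit on trees of height ≈ 4.6). In that regime the joint-ML
  reconstruction recovers the persistence-filtered event counts of the
  recorded truth in ≳95% of replicates; at several-fold higher rates the
  agreement genuinely degrades because distinct histories become
  near-equally likely, which is information loss in the data, not an
  implementation artefact.

## Known limitations

* Two states only; no covarion/hidden-rate expansions, no more-than-binary
  habitat models (the four-state vocabulary is collapsed, not modelled).
* Trees and traits are not inferred jointly: tree sets carry uncertainty
  in, but the trait model cannot reshape the trees.
* Joint histories are point estimates; stochastic character mapping is out
  of scope, so event-count uncertainty comes from tree sets and posterior
  draws, not from history sampling.
* The MPL chronogram is a relative-dating device; it inherits the known
  biases of mean-path-length smoothing near the root and provides no
  absolute ages.
* UniFrac is unweighted (presence/absence) by design; abundance-weighted
  variants and placement-based distances are not implemented.
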