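---
title: "Spatial-component Bayesian networks: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-component Bayesian networks: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scbnet)
```

## The model

`scbnet` classifies subjects from segmented tissue-probability volumes in
three stages.

**Components.** An integer-labeled atlas on the same voxel grid partitions
the brain into M regions. For subject i and region m the feature vector
x_m^(i) is the concatenation of the region's voxel probabilities in a fixed
scan order (x fastest, then y, then z — the array's column-major order).
Any fixed order would do, since the downstream classifiers are
order-agnostic across subjects; what matters is that it is identical for
every subject, which is enforced and tested. No smoothing and no dimension
reduction are applied; voxels with zero probability inside a region are
kept, because masking them would make S subject-dependent.

**Regional classifiers.** Each region gets a binary linear rule
g_m(x) = w·x + w_0, trained either as a soft-margin linear SVM or as a
pooled-variance Gaussian naive Bayes (whose log-odds are linear in x). The
regional outcome is z_m = sign(g_m(x)) ∈ {−1, +1}, with the convention
**+1 = AD** throughout the package; a decision value of exactly zero maps
to +1. In high-dimensional, small-sample settings a linear kernel is an
appropriate and common choice; nonlinear kernels are deliberately out of
scope.

**Aggregation.** The baseline aggregator is unweighted majority voting,
F(z) = Σ_m z_m, classifying AD when F > 0 (F = 0, possible for even M,
resolves to +1 like every other tie in the package). The main aggregator is
a class-rooted augmented Bayesian network on {y, z_1, …, z_M}: the class
node y has no parents and is a parent of every component node, and
augmenting edges among component nodes encode conditional dependencies, so

p(y, z) = p(y) · Π_m p(z_m | Pa_m, y).

Classification is the exact posterior argmax over y, computed from the two
joint evaluations; with an edge-free structure and symmetric homogeneous
CPTs this reduces *exactly* to majority voting (a tested identity).

## Structure learning

The structure score is BIC, `log L̂ − (d/2) log n` with
`d = 1 + Σ_m 2^(1+|Pa_m|)` free parameters, which decomposes over node
families. The search is Metropolis–Hastings over the constrained DAG space:
from the current structure a single augmenting-edge move (add, delete or
reverse) is drawn uniformly among the legal moves — those preserving
acyclicity and the per-node parent cap — and accepted with probability
min(1, exp(Δscore) · N(G)/N(G′)), where N(·) are neighborhood sizes; the
correction makes the chain a proper MH sampler of exp(BIC) as an
unnormalized structure posterior. Only the families a move touches are
rescored. The package both samples properly *and* reports the best
structure visited anywhere in the chain, covering the two reasonable
readings of "search with MH" (sampler vs stochastic hill-climb). The chain
starts from the empty augmenting set (pure naive Bayes) — a deterministic,
constraint-satisfying start. Note that reversing a single augmenting edge
is score-equivalent, so the "optimal structure" is an equivalence class;
comparisons with exhaustive enumeration are made on the attained score and
the undirected skeleton.

Parameters are count-based estimates per parent configuration,
`(count + s)/(total + 2s)` with pseudo-count `s` (`smoothing`): `s = 0` is
maximum likelihood, the default `s = 1` is the posterior mean under a
uniform prior. Parent configurations never observed fall back to 0.5. With
smoothing, every configuration has nonzero probability, so the posterior
denominator cannot vanish; a stochastic initialization of the tables would
have nothing left to initialize and is therefore not used.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| `cost` (SVM soft margin) | 1 | unitless; standard default, results are insensitive in the wide-margin regimes the components produce |
| `kind` | `"svm"` | naive Bayes provided for comparison |
| `smoothing` | 1 | Laplace/uniform-prior MAP; 0 recovers ML |
| `n_iter`, `burn_in` | 20 000, 2 000 | chain length for ≤ 10 nodes; acceptance ratio reported in sliding windows of 500 as the convergence diagnostic |
| `max_parents` | 3 | CPT rows grow as 2^(1+k); cohorts of a few hundred subjects cannot estimate larger tables |
| `max_nodes` | 10 | the constrained-DAG space grows super-exponentially; beyond ~10 nodes the chain does not mix at these budgets |
| `validation_fraction` | 1/3 | stratified by class; MCI converters go entirely to validation |

The node cap is also why regions must be pre-selected (e.g. the
literature-implicated set: hippocampus, parahippocampal gyrus, lingual
gyrus, temporal lobe, frontal lobe, precentral gyrus) rather than using all
48 atlas structures: with 48 binary components the outcome space alone has
2^48 configurations.

## Evaluation protocol

Per-region outcomes used for network learning come from leave-one-out
cross-validation on the training cohort, so each subject's outcome vector
is produced by classifiers that never saw that subject. The network
structure and CPTs are learned from these held-out vectors. Final regional
classifiers for validation-set prediction are trained on the full training
cohort. Validation runs two contrasts — AD vs NC, and MCI converters
(scored as positives) against the same NC validation subjects, which is why
specificity is identical across contrasts. Metrics are accuracy,
sensitivity and specificity from the confusion counts with AD as positive;
if a contrast lacks positives or negatives the undefined ratio is `NA` with
a warning.

## The phantom generator

`simulate_subjects()` emulates the *output* of segmentation and spatial
normalization, not the process: per-voxel tissue probabilities at 1.5 mm on
a shared grid, parcelled by a deterministic block atlas with a background
margin. Regional gray matter sits at baseline 0.6; in AD-class subjects a
set of affected regions atrophies (mean reduction δ = 0.25) with
indicators sampled ancestrally from an acyclic dependency graph (root
regions at rate 0.8, children at 0.9 given an atrophied parent, 0.1
otherwise); NC subjects atrophy independently at a 0.05 baseline rate;
voxel noise is Gaussian with σ = 0.05 and values are clipped to [0, 1].
White matter follows the same scheme with a smaller effect (δ = 0.1). MCI
converters use the AD atrophy process with the effect scaled by 0.7 —
converters are expected to show a milder version of the AD pattern. All
randomness flows from one master seed through per-subject substreams, so
growing a cohort never perturbs existing subjects.

What the phantom does **not** emulate: anatomy, registration error,
scanner and site effects, segmentation bias in atrophic brains, age and sex
structure, label noise from clinical diagnosis. Tests passing on phantoms
therefore validate the *method's mechanics* — that dependencies among
regional outcomes exist and are exploitable — not clinical performance
levels; phantom accuracies are systematically higher than anything
achievable on real MRI.

## Numerical choices

- All ties break to +1 (classifier decision 0, vote sum 0, posterior 0.5):
  one documented deterministic rule everywhere.
- SVM solver: libsvm with tolerance 1e-4; the hyperplane is extracted and
  re-oriented so positive decisions mean +1 regardless of libsvm's internal
  label order. Predictions are scale-invariant in (w, w_0).
- Naive Bayes variances are pooled across classes and floored at 1e-9 to
  survive constant voxels.
- Probability volumes tolerate round-off of 1e-6 outside [0, 1] (clipped);
  anything worse is an input error naming the file. Image/atlas grids must
  match exactly (affines within 1e-4); no resampling is ever attempted.
- Log-likelihoods use 0·log 0 = 0; zero-probability configurations report
  −Inf log-joint, and inference errors only if both classes have zero joint
  (impossible with smoothing > 0).
- Network JSON is written with 17 significant digits so doubles round-trip
  exactly.
- M = 1 has no augmenting-edge moves; the search returns the trivial
  structure with an empty trace.

## Problem sizes in tests and the acceptance script

The package's own test conditions: unit and property tests use 10³-voxel
phantoms with 8 regions and 80–150 subjects, chains of 400–3000 iterations,
and planted networks of 3–6 nodes with n = 2000–5000 outcome vectors —
sizes at which the exhaustive 3-node enumeration (25 constrained DAGs) and
binomial error bounds give sharp oracles. The acceptance script's cohort
uses the study-scale composition (417 NC/AD subjects at AD prevalence
188/417, plus 110 MCI converters) on a 12³ grid. Effect sizes, noise and
dependency rates are the generator defaults in every case.

## Known limitations

- Binary outcomes discard margin information by design; probability-
  calibrated regional outputs are a different method.
- Only the best-visited structure is used; no model averaging over the
  chain.
- The exhaustive oracle is limited to 4 nodes; beyond that, correctness of
  the search is supported by recovery properties rather than enumeration.
- Hold-out metrics at validation sizes of tens of subjects carry binomial
  error of several percentage points; single-seed comparisons between
  aggregators are noisy, which is why directional claims are tested as
  multi-seed medians.
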