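# scbnet

Spatial-component Bayesian networks for structural MRI classification.

## The problem

Voxel-based classifiers for Alzheimer's disease (AD) typically treat the
whole brain as one feature vector, or treat anatomically separate regions as
independent sources of evidence. Neither matches what is known about the
disease: atrophy appears in *several related* regions — hippocampus,
parahippocampal and lingual gyri, temporal and frontal cortex — and the
dependencies between regional findings are themselves informative.

`scbnet` implements the spatial-component (SC) approach for users working
with segmented, atlas-aligned tissue-probability maps (e.g. SPM/VBM output):

1. **Parcellation.** Each subject's gray-matter (or white-matter)
   probability volume is split by an integer-labeled atlas into M regional
   components; the voxel probabilities of region m are concatenated into a
   feature vector x_m in a fixed scan order.
2. **Per-region classification.** A linear soft-margin SVM (or pooled-
   variance Gaussian naive Bayes) g_m is trained per region; its sign gives
   a binary regional outcome z_m ∈ {−1, +1}, with +1 = AD.
3. **Aggregation.** Subjects are classified either by majority voting,
   F(z) = Σ_m z_m (AD if F > 0), or by a **class-rooted augmented Bayesian
   network** over {y, z_1, …, z_M}: the class y is the parentless root and a
   parent of every z_m, and extra edges among the z_m capture dependencies
   between affected regions. The joint factorizes as

   p(y, z) = p(y) · Π_m p(z_m | Pa_m, y)

   Structure is learned by Metropolis–Hastings search over constrained DAGs
   (single-edge add/delete/reverse moves, Hastings neighborhood correction)
   scored by BIC = log L̂ − (d/2)·log n; conditional probability tables are
   count-based estimates with optional Laplace smoothing; classification is
   the exact posterior argmax over y.

Honest evaluation is built in: per-region outcomes come from leave-one-out
cross-validation, the network is learned only from those held-out outcomes,
and generalization is measured on a stratified hold-out third of the NC/AD
cohort plus an MCI-converter contrast. A synthetic phantom generator with
class-dependent, regionally *correlated* atrophy makes the whole pipeline
testable without clinical data.

## Worked example

```r
library(scbnet)

cfg     <- phantom_config(shape = c(12, 12, 12), n = 240, n_mci = 60, seed = 1)
dataset <- simulate_subjects(cfg)   # 240 NC/AD + 60 MCI-c tissue volumes
res     <- run_pipeline(dataset, n_iter = 4000, burn_in = 500, seed = 1)
tidy(res)
#> # A tibble: 4 × 9
#>   contrast  aggregator    tp    tn    fp    fn accuracy sensitivity specificity
#> 1 ad_vs_nc  bayes_net     36    40     0     4    0.95        0.9             1
#> 2 ad_vs_nc  voting        33    40     0     7    0.912       0.825           1
#> 3 mci_vs_nc bayes_net     57    40     0     3    0.97        0.95            1
#> 4 mci_vs_nc voting        49    40     0    11    0.89        0.817           1
```

On this phantom the network aggregator reaches 95% validation accuracy on
AD vs NC against 91.2% for unweighted voting, and 97% vs 89% on the harder
MCI-converter contrast — the gain comes from modeling the dependency chains
among affected regions and from down-weighting the two uninformative
regions, which voting counts at face value. The learned skeleton recovers
exactly the planted atrophy dependencies (chains 1–2–3 and 4–5–6):

```r
tidy(res$search)
#> # A tibble: 4 × 2
#>    from    to
#> 1     2     1
#> 2     3     2
#> 3     5     4
#> 4     5     6
```

`glance(res$search)` summarizes the chain (best BIC, acceptance ratio);
`autoplot(res$search)` plots the acceptance-ratio convergence diagnostic and
`autoplot(res)` the validation metrics. Real data enter the same way:
`read_manifest()` + `load_volume()` for NIfTI tissue maps and atlas,
`decompose_cohort()` → `loocv_outcomes()` → `mh_structure_search()` →
`fit_bn()` → `predict()`, or the bundled command-line wrapper
`inst/cli/scbnet.R` (subcommands `simulate`, `run`, `evaluate`).

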