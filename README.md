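# spotfate

Spatially resolved tumor-architecture analysis on hexagonal spot lattices:
from malignant spot calling to fate-transition graphs, in-silico drug
perturbation, and prognostic signatures.

## The problem

Solid tumors such as oral squamous cell carcinoma are spatially
organized: a keratinized, differentiated **tumor core (TC)**, an
invasive, partial-EMT-like **leading edge (LE)** at the tumor-stroma
border, and a **transitory** state between them. Spatial transcriptomics
captures this architecture as a hexagonal lattice of barcoded spots, each
a small mixture of cells with a count vector, a cell-type deconvolution
profile, and a copy-number (CNV) probability. spotfate implements the
analysis chain that turns those inputs into biology, for computational
biologists who want each step as a tested, reusable function:

1. **Malignant calling** — a spot is malignant iff deconvolved cancer
   proportion > 0.99 *or* CNV probability > 0.99, *and* the pathologist
   called the region carcinoma.
2. **Region annotation** — Louvain clustering (resolution 1.0) of
   malignant spots, a cluster tree cut into three nodal groups, labeled
   TC / transitory / LE by core (*CLDN4*, *SPRR1B*) and edge (*LAMC2*,
   *ITGA5*) markers.
3. **Consensus differential expression** — per-sample Wilcoxon rank-sum
   with Bonferroni correction (significant iff |log2FC| > 0.25 and
   adjusted p < 0.001), aggregated across samples by the
   same-direction-in-≥k-samples rule with cumulative log2FC.
4. **Gene-set scoring** — control-bin module scores, signed up/down
   composites, and rank-based single-sample scores in [−0.5, 0.5].
5. **Neighborhood composition** — which non-malignant cell types sit in
   direct hexagonal contact with the TC versus the LE.
6. **RNA velocity and fate graphs** — steady-state velocity
   `v = u − γ̂·s` from spliced/unspliced layers, a velocity-directed
   cosine-softmax transition kernel, and a row-stochastic 3×3 state
   graph over TC/transitory/LE with the flow signatures
   `edge_outgoing = Q[LE→transitory] + Q[LE→TC]` and
   `core_incoming = Q[LE→TC] + Q[transitory→TC]`.
7. **In-silico drug screens** — DGIdb-style keyword → direction mapping,
   AAC aggregation (dataset means per cell line, 10% trimmed mean across
   ≥25 cell lines), perturbation of each drug's targets (±200 scaling ⇒
   1 SD of target expression per unit time), and rank-sum comparison of
   flow signatures between high- and low-AAC drugs.
8. **Prognosis** — maximally selected log-rank cutpoints (minimum group
   proportion 0.2), Kaplan–Meier curves, Cox proportional-hazards fits,
   and score correlations.

Every stage has a seeded synthetic generator (`simulate_st_sample()`,
`simulate_kinetics()`, `simulate_drug_screen()`,
`simulate_survival_cohort()`) that plants known structure — zones,
kinetics, drug effects, hazards — so the whole chain is testable offline.

## Worked example

```r
library(spotfate)

sample <- simulate_st_sample(seed = 1)       # hex lattice, planted zones
sample <- annotate_sample(sample, seed = 1)  # normalize, call, cluster, label
sample
#> STSample: 1260 spots x 300 genes
#>   layers: counts, spliced, unspliced, norm
#>   malignant: 331 of 1260
#>   regions: LE 162, non-malignant 929, TC 61, transitory 108

vr <- compute_velocity(sample)
velocity_state_graph(vr)
#> StateGraph over TC/transitory/LE
#>                TC transitory     LE
#> TC         0.8751     0.1184 0.0065
#> transitory 0.0234     0.9267 0.0499
#> LE         0.0065     0.0277 0.9659
#> edge_outgoing = 0.0341, core_incoming = 0.0299
```

The baseline graph shows net TC→LE flow (TC spots send 12.5% of their
transition mass outward; LE spots send back only 3.4%) — the
differentiation hierarchy from core to edge. Down-perturbing the planted
LE-driver genes reverses it:

```r
spec <- perturbation_spec(sample$truth$driver_genes, "down", 200)
perturbed <- velocity_state_graph(apply_perturbation(vr, spec))
#> edge_outgoing: baseline 0.0341 -> perturbed 0.0424
```

A synthetic drug screen with a planted association between flow reversal
and drug response recovers it:

```r
drugs <- simulate_drug_screen(
  drug_screen_config(driver_genes = sample$truth$driver_genes), seed = 1)
run_screen(vr, drugs)
#> ScreenResult: 36 drugs retained
#>       signature statistic            p  mean_high   mean_low
#> 1 edge_outgoing       306 6.133367e-07 0.04240701 0.03521466
#> 2 core_incoming       306 6.133367e-07 0.05305023 0.03323700
```

High-AAC (effective) drugs show significantly larger edge-outgoing flow
than low-AAC drugs — the in-silico signature of pushing LE cells back
toward less invasive states. Finally, a prognostic fit on a synthetic
275-patient cohort with a planted LE hazard:

```r
cohort <- simulate_survival_cohort(survival_config(), seed = 1)
fit <- survival_fit(cohort, cohort$sig_le)
#> LE signature cutpoint -0.072; HR 2.94 [2.18, 3.97], p = 1.8e-12
```

The hazard ratio of the high-score group is elevated as planted (note the
cutpoint is maximally selected, so the p-value is descriptive — see the
methods vignette).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch against the installed
package — simulating a spatial cohort, annotating it, running consensus
differential expression, signature scoring, neighborhood composition, the
velocity/perturbation drug screen, and the survival fit — logging each
stage's headline numbers and writing the JSON report to `--out`.

## Documentation

`vignettes/spotfate-methods.Rmd` describes the models, parameter
defaults and their rationale, what the synthetic generators do and do not
emulate, numerical choices, and known limitations.
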