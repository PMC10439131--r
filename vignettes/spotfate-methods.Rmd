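---
title: "spotfate: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spotfate: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotfate)
```

# Scope

spotfate analyzes spatial transcriptomics of solid tumors on Visium-style
hexagonal spot arrays, organized around the architecture of oral squamous
cell carcinoma: a keratinized, differentiated **tumor core (TC)**, an
invasive, partial-EMT-like **leading edge (LE)** at the tumor-stroma
border, and a **transitory** state between them. The package covers the
full analysis chain — malignant spot calling, TC/transitory/LE annotation,
consensus differential expression across samples, gene-set scoring,
hex-neighborhood composition, steady-state RNA velocity with
coarse-grained fate-transition graphs, in-silico drug-target perturbation
with drug-response association, and prognostic survival analysis — plus
seeded generators that synthesize every input the chain consumes, so each
stage is testable without external downloads.

# Malignant spot calling and region annotation

A spot is called malignant iff its cancer deconvolution proportion
exceeds 0.99 **or** its copy-number "mutant versus normal" probability
exceeds 0.99 (strict inequalities), **and** the pathologist annotated the
spot as carcinoma (`pathology == "SCC"`). Both channels are inputs: the
package does not re-implement reference deconvolution or CNV inference.
Non-malignant spots are typed by the largest non-cancer deconvolution
proportion; exact ties resolve to the first declared cell-type column, a
rule pinned by a test.

Counts are filtered (spots detecting fewer than 200 genes are dropped)
and log-normalized to the median library size. The variance-stabilizing
regression used upstream in the original workflow is a published method
external to this package's scope; downstream contracts depend only on a
monotone normalized layer, so median-library log-normalization stands in
(a documented divergence). Batch integration across samples is likewise
out of scope; synthetic cohorts are generated batch-free.

Malignant spots are clustered by Louvain community detection (resolution
1.0) on a shared-nearest-neighbor graph built from 30 principal
components with 20 neighbors and Jaccard weights pruned below 1/15;
`n_pcs` and `k` are package defaults since only the resolution is
prescribed. Cluster-mean PC embeddings are organized into an
average-linkage tree cut into three nodal groups (the linkage is a
package choice; only the tree itself is prescribed upstream). The group
with the highest mean core-marker expression (CLDN4, SPRR1B) becomes TC,
the highest edge-marker group (LAMC2, ITGA5) becomes LE, the remainder
transitory; coincident maxima or degenerate (all-equal) marker scores
raise an error rather than guessing.

# Consensus differential expression

Per sample, TC-vs-LE differential expression uses a two-sided Wilcoxon
rank-sum test per gene with Bonferroni correction over the genes tested
(genes detected in at least 3 spots of either group; groups of fewer
than 3 spots are refused). The fold change is
`log2((mean(expm1 normA) + 1) / (mean(expm1 normB) + 1))`: log2 with a
pseudocount of one on de-logged means, one convention fixed once because
the upstream description mixes "logFC" and "log2FC". Significance
requires `|log2FC| > 0.25` and adjusted p `< 0.001`.

A gene enters the cross-sample consensus iff it is significant **with the
same direction** in at least `min_samples` (default 10) samples;
direction consistency is implied but not stated upstream, so it is
required here and documented. The cumulative log2FC sums the qualifying
samples' values. The region-by-sample structure is summarized by Pearson
correlation of region-mean expression profiles.

# Gene-set scoring

Three scores are provided:

* `module_score()` — the control-bin score: genes are binned into 24
  equal-frequency bins by mean expression; each signature gene draws 100
  control genes with replacement from its bin; the score is mean
  signature expression minus mean control expression per spot. Control
  draws are seeded; bin edges are equal-frequency quantiles.
* `signed_score()` — composite programs with expected up- and
  down-regulated arms are scored as `module(up) - module(down)`
  ("cumulatively added" contributions). A reciprocal transform of a
  single marker gene appears in the source material's figure legend as an
  alternative; reciprocals are unstable at zero expression and are not
  used.
* `rank_score()` — the rank-based single-sample score: genes are
  midranked ascending within a sample and the set's mean rank is min-max
  normalized to `[-0.5, 0.5]` by the extreme achievable mean ranks. It is
  invariant under monotone transforms of expression.

Region comparisons run either paired (per-sample region means, two-sided
Wilcoxon signed-rank across samples) or unpaired (spot-level rank-sum);
the upstream description does not fix the unit of analysis, so both are
provided. Bonferroni or Benjamini-Hochberg correction is selectable.

# Hex neighborhood composition

On the staggered (doubled-width) grid, spots exist where row and column
parity agree and direct contact means offsets `(0, ±2)` or `(±1, ±1)`.
For TC and LE separately, the non-malignant spots in direct contact with
the region are classified by `assign_noncancer_type()` and counted per
cell type; a spot touching both regions counts toward both (the upstream
text is silent; the rule is pinned by a test), and each spot counts once
per region (spots, not contact edges, are counted — also a documented
choice). Per-sample TC and LE counts are compared per cell type by
two-sided rank-sum with BH correction across cell types.

# Steady-state RNA velocity and the state graph

The dynamical maximum-likelihood velocity model and the full vector-field
suite of the upstream workflow are large published systems; spotfate
substitutes a documented steady-state analog that preserves every
contract the downstream analyses test (flow direction, state-graph
probabilities, signature sums):

1. **Moment smoothing.** Spliced and unspliced layers are averaged over
   each spot's 30 nearest neighbors (plus itself) in a 10-PC embedding of
   the log1p spliced layer (`n_pcs = 10`, `n_neighbors = 30` are the
   prescribed embedding parameters).
2. **Degradation rate.** Per gene, `gamma_hat = sum(u s) / sum(s^2)` over
   the top and bottom 5% of spots by smoothed spliced abundance — the
   regression through the origin on near-steady-state spots. Time is
   measured in units of the splicing rate (beta = 1), so `gamma_hat` is
   the steady-state u/s ratio. Genes with zero spliced signal are masked.
3. **Velocity.** `v = u_smoothed - gamma_hat * s_smoothed`, projected to
   the embedding through the log1p chain rule (`v / (1 + s)`), the PCA
   column scaling, and the gene loadings.
4. **Transition kernel.** For each spot and its 30 embedding neighbors,
   transition probability proportional to
   `exp(cos(v_i, x_j - x_i) / sigma)` with `sigma = 0.1`; rows normalize
   to one, there are no self-loops, and zero-velocity spots transition
   uniformly. Row-normalization happens **before** coarse-graining
   (normalize-then-average; the alternative order is unstated upstream
   and this one is pinned by test).
5. **State graph.** `Q[A, B]` is the mean over spots of state `A` of
   their total probability into state `B`. The flow signatures follow
   the prescribed sums: `edge_outgoing = Q[LE→transitory] + Q[LE→TC]`,
   `core_incoming = Q[LE→TC] + Q[transitory→TC]`.

`velocity_confidence()` reports the Pearson correlation between each
spot's gene-space velocity and its neighborhood's mean velocity.
`fit_vector_field()` provides the smooth-field abstraction (Gaussian
kernel ridge with an unpenalized intercept, so infinite ridge shrinks to
the mean velocity); the state graph itself is built from the embedded
velocities directly.

**Perturbation.** A target gene's velocity column is overridden at every
spot to `sign * (|M| / 200) * sd(smoothed spliced)`, i.e. the prescribed
scaling factor of ±200 maps to one standard deviation of the target's
expression per unit time (the upstream factor's units are internal to its
package; this mapping is a convention, not a claim of numerical
equivalence; the checkpoint-gene variant uses 1000). Velocities are then
re-projected and the state graph rebuilt. Zero magnitude is an explicit
no-op. Targets with zero expression are dropped, and an error is raised
only if none remain.

Sensitivity of the screen's ranking to `sigma` over [0.02, 0.5] is
covered by a rank-stability test.

# Drug-response association

Interaction keywords map to directions by exact, case-insensitive
membership in the curated lists (activator/agonist/inducer/partial
agonist/positive modulator/potentiator/stimulator up;
inhibitor/antagonist/partial antagonist/blocker/inverse
agonist/negative modulator/suppressor down); anything else is
direction-less and the target is dropped. Per drug, AAC is averaged per
cell line across datasets, then aggregated by a symmetric 10% trimmed
mean across cell lines (`floor(0.1 n)` dropped per tail — the
conventional symmetric rule; the tail convention is unstated upstream);
drugs measured in fewer than 25 cell lines are excluded. Drugs split at
the median aggregated AAC; the value exactly at the median goes to "low"
(the strict >/< rule upstream leaves it unassigned, so the tie is pinned
here). The screen perturbs each retained drug's directional targets,
records `edge_outgoing` and `core_incoming`, and compares high-vs-low
AAC groups by two-sided rank-sum. A mechanism-of-action utility groups
drugs by fuzzy name matching (edit distance ≤ 3) and compares classes by
Kruskal-Wallis.

# Prognostic analysis

Cohort expression is rank-scored per patient for a gene set; the optimal
cutpoint maximizes the absolute standardized two-group log-rank statistic
over candidate cut values at which both groups retain at least `minprop`
(default 0.2; 0.1 for the pan-cancer variant) of the cohort, ties
resolving to the smaller cutpoint. Kaplan-Meier curves and a Cox
proportional-hazards fit (Efron ties — a package default, unstated
upstream) on the high/low groups complete the analysis. As in the source
workflow, **no selection-bias correction is applied to the reported
p-value**: the p comes from the subsequent Cox fit, and a cutpoint chosen
to maximize separation makes that p anti-conservative. Tests therefore
calibrate the null on pre-specified groupings (permuted labels or the
continuous score), not on re-selected cutpoints. Monotone likelihood
(complete separation) is flagged, not silently returned.

# The synthetic world

`simulate_st_sample()` states the conditions the pipeline assumes:

* **Geometry.** A 42x60 staggered lattice (~1260 spots). Concentric hex
  disks from the lattice center: TC within hex distance 4, transitory to
  7, LE to 10, stroma outside — guaranteeing the LE borders stroma, with
  an ecm-myCAF-rich band hugging the LE, a mixed fibroblast/macrophage
  band beyond it, and immune/other types outside. Pseudotime is the
  normalized hex distance from the center (0 at TC center, 1 at the LE
  rim), matching a TC-to-LE differentiation axis.
* **Expression.** 300 genes (comfortably above the 200-detected-features
  filter): named markers, 10-gene zone programs per region, 4-gene
  stromal cell-type marker sets, and unstructured filler. Zone programs
  are step-wise per region (6-fold peak) with a mild pseudotime gradient;
  purely smooth gradients are not used because they make Louvain at the
  prescribed resolution merge the zones, defeating recoverability —
  step-like regional programs are also what annotated tumor compartments
  look like. Counts are negative binomial (size 10) at a median library
  of 2000 with mild depth variation.
* **Channels.** Tumor spots carry cancer deconvolution ~0.999 and CNV
  probability ~0.999 (a 5% "CNV-only" fraction has deconvolution 0.97,
  exercising the OR branch); stroma spots have cancer proportion ≤ 0.25
  and a dominant proportion on their true type. The noise magnitudes are
  free parameters of this package, not claims about any deconvolution or
  CNV method's error. Pathology is "SCC" exactly on tumor-zone spots.
* **Kinetics.** Spliced/unspliced layers follow the closed-form solution
  of `du/dt = alpha - beta u`, `ds/dt = beta u - gamma s` along
  pseudotime with Poisson sampling noise; the LE-driver genes (edge
  markers + edge program) are induced from zero, core-program genes are
  repressed from steady state, and all other genes sit at steady state.
  Both programs therefore push embedded velocity from TC toward LE,
  which is what makes down-perturbing the LE drivers reverse the flow.
* **Drug screens.** Flow-reversing drugs inhibit the full planted
  LE-driver set and have AAC shifted up by the effect size (default 0.2)
  over a baseline centered at 0.16 (near the reported screen-wide median
  response); decoys target filler genes with random directional keywords,
  and a fraction carries only direction-less keywords, exercising the
  removal rule.
* **Survival cohorts.** 275 patients (the emulated cohort's size), a
  2000-gene panel with 40-gene TC and LE signatures shifted by latent
  activities (bivariate normal, correlation -0.2 — the weak negative
  TC-LE regime). The panel size matters: with 80 signature genes in a
  500-gene panel, rank-score compositional coupling inflates the
  realized score correlation well beyond the configured value. Hazards
  are exponential and proportional
  (`lambda0 * exp(beta_tc z_tc + beta_le z_le)`, default LE hazard ratio
  2 per SD); the threshold variant plants two clearly separated risk
  clusters (latent offset 6 SD) split 60/40. Censoring is exponential
  with its rate solved numerically so the expected censored fraction
  equals the target exactly.

What the generators do **not** emulate: histology, sequencing-read noise,
batch effects, spatial autocorrelation beyond the zone structure,
multi-clonal CNV architecture, or any specific patient. A green test
establishes that the algorithms recover what was planted under the noise
models above — not that they would behave identically on real tissue.

# Numerical choices

* All randomness flows through explicitly passed seeds; generators and
  seeded analyses restore the caller's RNG state.
* Rank-sum p-values: exact enumeration when both groups have ≤ 8
  observations without ties, otherwise midranks with tie-corrected
  variance and continuity correction (via `stats::wilcox.test`, verified
  against full enumeration in tests).
* Row-stochasticity of transition matrices and deconvolution rows is
  enforced to 1e-9.
* The transition softmax subtracts the row maximum before
  exponentiating, so `sigma -> 0` stays finite.
* `beta == gamma` in the kinetics closed form is lifted by an epsilon
  nudge rather than the L'Hopital branch.
* Degenerate inputs error loudly: all-spot filtering, empty marker sets,
  <3 clusters, coincident marker maxima, all-identical AAC, infeasible
  cutpoints.

# Known limitations

* The steady-state velocity model mis-estimates rates for genes far from
  steady state everywhere; the acceptance experiment plants long enough
  time spans that extremes approach equilibrium.
* The maximally selected cutpoint is reported without a selection-bias
  p-value correction, mirroring the source workflow; treat its
  significance as descriptive.
* The in-silico perturbation magnitude mapping (±200 ⇒ 1 SD/unit time)
  is a convention; only directions and orderings, not magnitudes, should
  be interpreted.
* Counts and kinetic layers are generated from separate noise draws, so
  spliced + unspliced does not sum to the counts layer; no analysis
  depends on that identity.
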