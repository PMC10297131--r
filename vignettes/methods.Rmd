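---
title: "Methods: graph-tabular fusion for CKD prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-tabular fusion for CKD prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ckdfusion)
```

# The problem and the model

Chronic kidney disease status is predicted from 24 routine clinical
features (demographics, urinalysis, blood chemistry, comorbidity flags).
The package implements four learners under one training loop and one
metric protocol so they can be compared fairly:

* **baseline** — a single sigmoid unit (logistic regression);
* **tabular** — a feed-forward network `H^(l) = σ(W^(l) H^(l−1) + B^(l))`
  with a sigmoid output;
* **gnn** — a graph convolutional network on the patient-similarity
  graph, `h_i^(l+1) = σ(Σ_{j∈N(i)∪{i}} (1/c_ij) W^(l) h_j^(l) + b^(l))`,
  followed by a dense sigmoid head;
* **fusion** — both branches run in parallel; their embeddings are mapped
  into a shared `p′`-dimensional space with ReLU transforms, averaged
  elementwise, and classified by one sigmoid head. The composite is
  trained end-to-end through a single loss — not by stacking frozen
  branches — because the architecture is presented as one network and
  joint training is the only reading that lets the branches co-adapt.

Graph models are **transductive**: the k-NN graph is built over all rows
(train, validation, and test together) and supervision is restricted to
training nodes by a mask. This mirrors the source protocol, which builds
the graph from the full oversampled table before partitioning. The
consequence — test nodes influence training via graph structure — is a
property of the protocol, not a bug; the `leakage_safe` preprocessing
mode (below) addresses the analogous issue for oversampling but the
transductive graph is inherent to the method.

The training loss is mean binary cross-entropy over supervised rows plus
an optional ridge penalty `l2·‖θ‖²`. The source never names its loss;
BCE is the canonical pairing with sigmoid outputs and is the package's
documented choice. All gradients are hand-derived backpropagation,
validated against central finite differences (step `1e-5`, relative
error `< 1e-4`) for every family in the test suite.

# The preprocessing chain

Default order: missing-value handling → optional IQR winsorization →
min-max normalization → SMOTE → stratified split.

* **Missing values.** `complete_case` drops any row with a missing cell
  (the published protocol: 400 → 158 rows on the UCI table);
  `median_mode` fills numerics with the column median and binary
  categoricals with the modal code (ties to the lower code).
* **Winsorization** clips numeric values outside
  `[Q1 − k·IQR, Q3 + k·IQR]` (default `k = 1.5`). Quartiles use linear
  interpolation (R's type 7) — the most common convention, fixed and
  documented so tests can assert exact values.
* **Normalization** is min-max onto [0, 1]. A constant column maps to 0
  (avoids 0/0, stays in range). When a split is available the statistics
  come from training rows only and the returned state transforms
  validation/test identically.
* **SMOTE** (reimplemented from scratch — it is part of the method, not
  infrastructure): each synthetic point is `x + u·(x′ − x)`, `u ~ U(0,1)`,
  where `x′` is one of the `k = 5` nearest same-class neighbours of a
  randomly chosen seed row `x`. Both classes are raised to
  `target_total/2`; distances are computed **after** normalization, since
  the source gives no scale and raw Euclidean distance would be dominated
  by white-cell counts and glucose. Classes smaller than `k + 1` reduce
  `k` to class size − 1.
* **Ordering.** The published protocol oversamples all 158 complete rows
  to 2000 *before* splitting, which leaks synthetic copies of test
  information into training. The default reproduces that (fidelity
  first); `leakage_safe = TRUE` splits first, fits normalization on the
  training rows, and oversamples the training rows only, to
  `target_total × train_fraction` rounded down to even — the fraction is
  the package's choice, as the source never contemplates this order.
* **Split**: stratified 70/15/15 (unstated in the source; conventional),
  seeded, sizes from rounded cumulative fractions so the 2000-row
  protocol yields exactly 1400/300/300.

# The graph

* `k = 5` neighbours (unstated in the source; a standard small default,
  config-exposed and grid-searchable as `graph_k`).
* The directed k-NN relation is asymmetric; it is symmetrized **by
  union**, which preserves every stated edge.
* Weights `w = 1/s` explode for duplicate rows — inevitable after SMOTE
  interpolation — so the package uses `w = 1/(s + ε)`, `ε = 1e-8`,
  capping duplicate-pair weights at `1/ε`.
* The normalization constant `c_ij` is unspecified; the default is the
  canonical symmetric scheme `√(d_i d_j)` with self-loops (weight 1
  regardless of edge-weight mode, a bounded anchor for each node's own
  features), with degrees including the self-loop. A row-normalized
  scheme (`c_ij = d_i`, rows sum to 1) is offered. Whether aggregation
  uses the inverse-distance weights or bare connectivity is also
  unstated; `use_weights` (default `TRUE`) supports both readings.
* The source calls `s` a "similarity" but instantiates it as a distance
  and weights by its inverse; the code treats `s` as a distance
  throughout.

# Architectures and defaults

| parameter | default | rationale |
|---|---|---|
| GCN conv widths | 24 → 32 → 16 | "several" conv layers at desk scale |
| GCN head | direct 16 → 1 | smallest head; deeper heads configurable |
| tabular hidden | 64, 32 | small net for 24 features |
| p, q, p′ | 16, 32, 16 | p/q fall out of branch widths; p′ matches p |
| hidden activation | ReLU | named by the source for hidden layers |
| transform activation | ReLU | unspecified; sigmoid reserved for heads |
| output | sigmoid | binary classification |
| init | Glorot uniform | standard for sigmoid/ReLU stacks; seeded |
| optimizer | Adam, lr 0.01 | robust default for small nets |
| epochs | 200 | full-batch GCN converges well within this |
| threshold | 0.5, boundary → 1 | unstated; documented tie rule |

The fused dimension `r` is aliased to `p′` (the source defines it as the
column dimension of `F_avg`). The baseline is undefined in the source
beyond its name; the package uses a logistic-regression-equivalent single
sigmoid unit trained by the same loop — the weakest sensible learner for
the comparison's bottom row. Precision/recall/F1 are defined as 0 when
their denominator is 0, keeping comparison tables total. Grid search
selects on validation **accuracy** (the headline metric; F1 offered) and
breaks ties by enumeration order.

# The synthetic generator

`synthetic_spec()` states a two-class world whose class-conditional
feature distributions follow the spreads reported for the real cohort:
non-CKD hemoglobin concentrated in 12.5–17.5 vs CKD dispersed over
5–17.5; CKD blood pressure spanning 60–100; CKD age concentrated in
50–70 vs 20–80; albumin < 1 vs up to 5; glucose 50–150 vs dispersed;
lower packed-cell volume and red-cell counts under CKD; comparable
sodium/potassium; hypertension/diabetes strongly CKD-enriched. Numeric
features use truncated normals centred in the stated range with
`sd = range/4`; features with no reported spread (`sg`, `su`, serum
creatinine) use unit-variance normals with a class mean-shift `delta`
(default 1.0; `delta = 3` is the separable fixture used by the learning
sanity checks). Binary features are class-conditional Bernoulli draws.
Cells are masked independently at `missing_rate`.

What it emulates: class-conditional location/spread differences, mixed
numeric/binary features, missingness, and exact class balance. What it
does **not** emulate: correlations between features (real renal panels
are strongly correlated), non-random missingness (real missingness is
informative), measurement error structure, or the real 250/150 class
imbalance (except in the UCI-dialect stand-in file, which reproduces the
400-record / 158-complete / 250-ckd structure for parser and protocol
exercise). A green test on this world therefore establishes correctness
of the machinery — shapes, equations, determinism, learnability of a
plantable signal — not clinical performance. In particular the default
world is nearly separable, so all four models reach ~100% test accuracy
on it; the published accuracy ordering (fusion > GNN > tabular >
baseline) is a data-dependent stochastic outcome that the package
reports but never asserts.

# Numerical choices

* BCE scores are clamped to `[1e-12, 1 − 1e-12]`; the analytic gradient
  uses the unclamped sigmoid (exact away from the clamp).
* ReLU's subgradient at 0 is taken as 0; gradient tests jitter
  parameters off the kink, where symmetric finite differences would
  legitimately disagree with any subgradient choice.
* k-NN ties are broken by node index (stable ordering), making graphs
  fully deterministic.
* CSV and checkpoint serialization print shortest exact decimal strings,
  so read(write(x)) is bit-identical and reruns produce byte-identical
  artifacts.
* Every stage seed derives from `master_seed` by a documented stage-name
  hash offset (`(master + 131·Σ utf8(stage)) mod (2³¹ − 1)`), so stages
  are independently reproducible.

# Known limitations

* The run config is JSON only (no YAML parser among the dependencies).
* Checkpoints are JSON (text), adequate at these model sizes; the graph
  is serialized separately and must be re-attached on load.
* No ROC/AUC, calibration, or significance testing between models; no
  multi-class support; no approximate nearest neighbours (graphs are
  exact O(n²), fine to a few thousand patients).
* Random oversampling (ROS) is mentioned by the source as considered but
  not used; it is not implemented.
* The source's case-control cohort description (400 cases + 400 matched
  controls with GFR means) is inconsistent with the 400-record table its
  pipeline uses and is not modelled.
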