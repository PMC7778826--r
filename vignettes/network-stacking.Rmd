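---
title: "Patient-similarity networks, centrality features and stacked ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-similarity networks, centrality features and stacked ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(psnstack)
```

## The problem and the model

Clinical registries of assisted-reproduction treatments are tabular,
mixed-type and imbalanced: a couple contributes one row per treatment
cycle, features mix numeric measurements (ages, BMI, semen parameters)
with binary and nominal codes, and the positive outcome (clinical
pregnancy) occurs in roughly one cycle in seven. Single classifiers fitted
to the raw columns struggle because the two classes overlap heavily; the
discriminative signal is relational — a record resembles the records of
its own class more than those of the other class.

`psnstack` operationalises that intuition. For each record to classify it
builds three weighted, undirected patient-similarity networks: CN1 over
the record plus all training records, CN2 over the record plus the
positive-labelled records, CN3 over the record plus the negative-labelled
ones. Nodes are joined when their Euclidean distance (over the
preprocessed, min–max-scaled feature columns; the label never enters the
geometry) is strictly below a threshold, and edges carry the distance
divided by the maximum pairwise distance as weight. Seventeen features
then contrast the query node's position in CN2 against CN3: differences of
degree, weighted degree, closeness, eigenvector centrality, betweenness
and clustering normalised by the CN1 value (F1–F6); the ratio of
nearest-neighbour shortest-path distances and of two-hop neighbourhood
sizes (F7–F8); plain CN2/CN3 centrality ratios (F9–F12); and differences
of per-network max-normalised centralities over their pairwise maximum
(F13–F17, bounded in [−1, 1]). A record embedded deep in its own class
network gets large positive contrasts when it is positive and negative
contrasts otherwise, giving any downstream learner an almost
one-dimensional signal.

The classifier is a two-layer stacked ensemble in normal stacking mode.
Layer-1 candidates from six families — logistic regression, SVM, decision
tree, random forest, AdaBoost and gradient-boosted trees — are tuned by
exhaustive grid search, ranked by validation accuracy and admitted
greedily subject to a diversity constraint: a candidate whose correctness
pattern has |Q| > `q_max` (default 0.9) with an already-admitted member is
rejected, where Q is Yule's association coefficient on the two learners'
correct/incorrect indicators. Admitted layer-1 positive-class scores form
the meta-feature matrix on which layer-2 learners are fitted and selected
the same way; the final score is the weighted mean of layer-2 scores with
each learner's validation accuracy as weight, thresholded at 0.5 (an
exact 0.5 counts as positive — an arbitrary but fixed convention).

The second layer is not decoration. For M independent voters each erring
with probability ε < 0.5, majority voting errs with the binomial tail
probability P(X ≥ (M+1)/2), X ~ Binomial(M, ε) — `majority_vote_error()`
computes it by direct summation. Each layer-2 learner sees the same
meta-features the layer-1 majority vote would see and can only improve on
that hyperplane, so the layer-2 ensemble error is bounded by the tail
probability evaluated at the layer-1 ensemble error
(`stacked_error_bound()`), giving ε_L2 ≤ ε_L1 ≤ ε. For 25 voters at
ε = 0.35 the first-layer error is 0.0604 (the exhaustive binomial sum; a
Monte-Carlo check over 100,000 simulated committees agrees within
sampling error), and five second-layer voters at that rate reach 0.002.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `tau_factor` | 0.7 | Edge threshold as a multiple of the mean pairwise distance. Smaller values give sparser networks with more, smaller communities; 0.7 keeps the giant component while pruning cross-class edges. Shared by CN1/CN2/CN3 so their densities are comparable. |
| `cap` | 10 | Magnitude bound on the ratio features F7–F12 when a denominator vanishes (isolated query). F13–F17 are bounded by construction and never hit it. |
| `missing_threshold` | 0.20 | Features, then records, with a strictly greater missing fraction are dropped (exactly 20% is retained). |
| `low_out`, `high_in` | 0.01, 0.95 | Correlation-filter cutoffs: drop features with \|corr\| < `low_out` against the outcome; of any input pair with \|corr\| > `high_in`, drop the member less correlated with the outcome (ties drop the later column). Both deliberately conservative and logged; the filter runs after dummy coding. |
| `validation_fraction` | 0.20 | Stratified hold-out used for tuning, member selection and vote weights. |
| `q_max` | 0.9 | Diversity admission threshold on \|Q\|. 1 disables the filter; byte-identical learners are always deduplicated because their Q is 1. |
| `size_limit` | 2000 | Node count above which a network is partitioned by seeded Louvain modularity optimisation on the unweighted skeleton, and a node's metrics are computed on its community's induced subgraph. At or below the limit partitioning is a no-op. |

## The synthetic cohort generator

Real registries of this kind are governed by data-protection agreements,
so the package ships a generator whose defaults emulate the published
structure of an IUI registry: 86 numeric, 152 binary, 51 nominal and 7
binominal features; a marginal positive rate of 14.4%; couples
contributing 1–7 cycles with probabilities 0.72 / 0.22 / 0.05 and the
remaining 1% spread over 4–7; and per-feature MCAR missingness including,
when requested, features beyond the 20% drop threshold. Outcomes follow a
logistic model over a configurable informative subset, with the intercept
calibrated by root-finding against the realised linear predictor so the
marginal rate matches the target, plus a couple-level Gaussian random
intercept (variance 0.1 by default) that makes cycles of one couple
positively dependent — repeated cycles are not independent trials, and
the knob defaults near zero so it perturbs rather than dominates.

Two generator choices deserve flagging. "Binominal" features are
two-level nominal draws kept distinct from the binary block, so a type
census of a generated table reproduces the 86/152/51/7 counts; whether
the original registry meant something more specific by the term is
unknowable from the outside, and the choice only affects bookkeeping.
Numeric features are standard normal and categorical features uniform
(binary skew configurable) — no attempt is made to match real clinical
marginals or covariance. Consequently, passing tests demonstrate that the
machinery recovers planted structure under known conditions; they say
nothing about predictive performance on a real registry, whose
feature-feature dependencies, informative missingness and label noise the
generator deliberately does not model.

## Numerical choices and degenerate inputs

* **Edge weights are dissimilarities.** Path-based metrics (closeness,
  betweenness, nearest-node distance) use the weight as a length;
  count-based metrics (degree, clustering, two-hop, eigenvector) use the
  binary adjacency; weighted degree sums the weights literally. This is
  the most literal reading of the feature definitions; an
  inverted-similarity reading exists and would change F2/F3/F5 signs in
  subtle ways, so the choice is documented here once.
* **Exact duplicates.** Two identical records are joined by an edge of
  weight 0; shortest paths may be 0-length. Weighted betweenness then
  routes through an exact Brandes-style implementation (the igraph one
  requires strictly positive weights); a component whose path sums are all
  zero gets closeness 0 by convention. All-identical inputs are a
  degeneracy error at network construction.
* **Eigenvector centrality** is the principal eigenvector of the binary
  adjacency of the node's connected component, L2-normalised per
  component, computed by shifted power iteration (A + I, tolerance 1e-10)
  so bipartite components cannot oscillate. The per-component L2
  convention matters because F4/F11/F15 compare the value across three
  different networks; a max-1 scaling would change them.
* **Isolated nodes** take degree = weighted degree = closeness =
  betweenness = eigenvector = clustering = two-hop = 0 and an infinite
  nearest-node distance; the infinity resolves inside F7 as Inf/Inf → 1,
  finite/Inf → 0, Inf/finite → cap, and every other division runs through
  `safe_ratio()` (0/0 → 0, x/0 → ±cap), so all 17 outputs are finite for
  every input.
* **Normalised metrics with zero maxima** (e.g. betweenness in a network
  where no node lies between others) are defined as 0 rather than 0/0.
* **Ties.** Imputation-mode ties take the lexicographically smallest
  level; the dummy reference level is the most frequent (stable under
  resampling); grid-search ties take the earlier cell; the pairwise
  correlation filter drops the later column on ties; an aggregate vote of
  exactly 0.5 is positive.
* **Leakage discipline.** All preprocessing statistics (means, modes,
  min/max, encodings, correlation selections) are fitted on the training
  split only; oversampling is applied only to the learner-fitting portion
  after the validation hold-out, never to validation or test folds; a
  training record serving as a query is removed from its own networks.

## Evaluation conventions

The F-score reported throughout is the harmonic mean of sensitivity and
specificity — not of precision and recall. This matches the metric
definitions the rest of the package follows and is regression-tested, so
numbers are comparable across functions; readers used to the
precision/recall F1 should note the difference, which is large on
imbalanced data. AUC uses the rank-sum (concordance) formulation with
half-credit for ties. The A-Test balances every fold by seeded minority
oversampling within the fold, trains on K−1 folds and averages the
held-out misclassification percentage over rotations and then over
K = 2..K_max; a memorizing pipeline scores Γ̂ = 0 and a constant one
exactly 50 on balanced folds, which the tests pin down as anchors. MDA is
measured on held-out cross-validation folds in percentage points,
averaged over repetitions with distinct seeds.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes on one CPU: oracle comparisons use 200
random graphs of up to 7 nodes (brute-force path enumeration is factorial
in node count); the stacking-benefit check uses a 2,000-record XOR-like
cohort; MDA recovery plants 5 signals among 30 features over 10
repetitions of 3-fold validation; end-to-end experiments use
100–600-record cohorts with 3-fold validation. The architecture imposes no
such limits — community partitioning exists precisely to keep per-query
metric computation tractable on cohorts of tens of thousands — but
quadratic distance matrices and per-query network construction make the
engineered-feature path the costly stage at registry scale.

## Known limitations

* Per-query construction of three networks is O(n²) in training size per
  record; batch engineering reuses the training distance matrix, but very
  large cohorts need the community partitioning path and patience.
* The generator's independence assumptions (no feature covariance, MCAR
  missingness) make synthetic results an upper bound on how cleanly the
  method can behave.
* Only two stacking layers are implemented; the error analysis suggests
  diminishing returns and growing cost for deeper stacks.
* The outlier-removal hook ships with a robust z-score default detector
  behind a pluggable contract rather than an isolation forest; any scorer
  with the `function(features) -> logical` signature can be plugged in.
* Probability calibration of the aggregate score is out of scope; the 0.5
  threshold is a labelling convention, not a calibrated decision rule.
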