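---
title: "Statistical methods and design choices in metabolokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods and design choices in metabolokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabolokit)
```

metabolokit analyses a feature-by-sample intensity table produced by
upstream peak picking and compound identification. This vignette explains
the models and procedures it implements, the tunable parameters and their
defaults, the numerical decisions taken where the methods literature leaves
room, and what the synthetic-data generator does and does not emulate.

## Data model

A `MetaboSet` extends `SummarizedExperiment` with one assay, `intensity`
(non-negative on the raw scale; missing values allowed). Sample metadata
carries the study design: group factors, a subject id for paired designs, a
`batch` label, an integer `injection_order`, and a `sample_type` of
`biological`, `qc` (pooled quality control) or `blank`.

**Missing values are never imputed implicitly.** Peak tables routinely
contain missing cells whose mechanism (below detection limit vs. missed
integration) is unknown; every downstream statistic is computed per feature
on complete cases, and features that fall below the minimum observation
count are flagged `insufficient_data` in the output rather than dropped.
`readDataset(impute_min = TRUE)` offers the conventional half-minimum
surrogate for workflows (like PCA) that need complete data, but it is off by
default.

## Processing

*Transformation.* `log2`/`log10`/`ln` (requiring strictly positive values —
a zero intensity under a log transform is an error naming the offending
cell, not a silent `-Inf`) and `power` with exponent > 0. Intensities from
GC-TOF instruments are strongly right-skewed; a log transform is the usual
preparation for the t-family tests.

*Sample normalization.* `sum` divides each sample by its intensity total and
rescales by the median total, so values keep their original magnitude;
`metadata` divides by a positive per-sample covariate such as dry mass;
`batch_median` divides feature-wise by the per-batch median vector of a
designated reference sample type. The pipeline default order is
transform → sample normalization → feature scaling; every stage commutes
with feature/sample reordering.

*QC-LOESS drift correction.* Instrument response drifts over an injection
sequence. Per feature and per batch we fit a locally weighted polynomial
regression (degree 2, tricube weights) of QC intensity on injection order;
the span is selected from the grid {0.3, 0.4, …, 1.0} by leave-one-out
cross-validation on the QC samples (minimum squared prediction error). Every
sample is divided by the fitted curve at its injection order and rescaled by
the batch QC median, and batches are then aligned to a common QC median.
Numerical guards: spans whose local fit fails or whose curve is not strictly
positive anywhere in the batch are excluded from the grid; if none survives,
the feature falls back to a degree-1 full-span fit, and failing that passes
through unchanged with a warning. At least 4 QC injections per batch are
required, but the procedure only becomes a genuine smoother from roughly 8–10
QCs per batch; with 4 QC points a local quadratic interpolates them exactly,
which is why the package's own simulations use a QC every 6 injections.
The correction is exactly idempotent on flat QC profiles.

*Feature scaling.* auto = (x−mean)/sd, Pareto = (x−mean)/√sd, range =
(x−mean)/(max−min), with the n−1 sample standard deviation. A constant
feature is set to 0 with a warning rather than dividing by zero.

## The design-driven statistics engine

`designSpec()` declares one of seven study designs; `suggestMethods()` maps
it to an ordered method list, and `testFeatures()` applies the selected
method feature-wise, BH-adjusts across features, and attaches the design's
post hoc table. Choices a user should know about:

* **Defaults.** The Welch family (unequal variances) is the default
  everywhere it exists: metabolite variances routinely differ between
  biological groups, and Welch tests cost essentially nothing when variances
  happen to be equal. Welch's t equals Student's t exactly when group sizes
  and variances coincide; Welch's ANOVA equals the classical F only
  asymptotically (its small-sample denominator correction does not vanish at
  equal *sample* variances for k > 2).
* **Sidedness.** All tests are two-sided.
* **Paired designs** operate on within-subject differences; the
  non-parametric paired analogue is the Wilcoxon signed-rank test on those
  differences.
* **Mann-Whitney exactness.** Exact enumeration when the combined sample
  size is ≤ 20 and there are no ties, otherwise the normal approximation
  with tie correction and continuity correction.
* **Repeated measures.** Classical univariate F with Greenhouse-Geisser
  epsilon estimated from the condition covariance matrix and applied to both
  degrees of freedom; for two conditions epsilon is exactly 1. The
  correction is reported alongside the uncorrected p; note it is only
  guaranteed conservative in the rejection region (F > 1).
* **Factorials.** Type II sums of squares for (possibly unbalanced)
  independent two-way layouts; fully within and mixed layouts use classical
  subject error strata. The interaction is the design's primary hypothesis
  and is the per-feature p-value that enters FDR adjustment; main effects
  ride along in the post hoc table. Simple main effects (each factor tested
  within every level of the other, BH-adjusted) are computed when the
  interaction is significant at unadjusted p < 0.05.
* **Robust two-way ANOVA.** The heteroscedastic Welch-James (Johansen) test
  on 20%-trimmed cell means with winsorized-variance standard errors. The
  implementation is validated by its algebraic reduction: with zero trimming
  and a single factor it reproduces Welch's ANOVA exactly.
* **Post hocs.** Games-Howell uses per-pair Welch statistics with
  Satterthwaite df against the studentized-range distribution; Tukey-Kramer
  uses the pooled error variance; Dunn's rank z tests carry the standard tie
  correction and Bonferroni adjustment. Under balanced homoscedastic
  sampling Games-Howell tracks Tukey closely (identical orderings; adjusted
  p within a few hundredths — the df difference keeps them from coinciding).
* **Bootstrap.** Pooled resampling with replacement under the null of a
  common distribution, p = (1 + #{|t*| ≥ |t|})/(B + 1), B ≥ 100, seed
  required.
* **Power.** Noncentral t/F with Cohen's d (or f); `a_priori` returns the
  smallest integer per-group n reaching the target (e.g. n = 17 per group
  for d = 1, α = 0.05, power 0.8). The two-sided power includes the
  wrong-tail rejection region.
* **Degenerate inputs.** Zero variance in both groups: statistic 0 / p = 1
  at equal means, p = 0 with a `degenerate` flag otherwise. A fully
  constant multi-group input returns F = 0, p = 1.

## Networks

*Correlation networks* use pairwise-complete observations with a minimum of
5 shared samples per pair; edges where |r| exceeds the threshold
(default 0.7), with the signed coefficient as weight. Thresholding on |r|
keeps strong negative associations, which are as informative as positive
ones in metabolite data. Constant features are excluded with a warning.

*Partial correlations* are full-order: the inverse of the correlation
matrix, regularized by shrinkage toward the identity with the analytic
(Ledoit-Wolf-type) intensity λ* = Σ Var(r_ij) / Σ r_ij², so the estimator is
well posed when features outnumber samples. A full-order shrinkage estimator
was chosen over limited-order alternatives because it is deterministic,
desk-scale, and testable against the explicit 3-variable closed form. The
default edge threshold is 0.2 — partial correlations are systematically
smaller than marginal ones.

*Tanimoto networks* operate on substructure fingerprints supplied as
explicit bit-position lists (default bit space 881, the PubChem substructure
keys), so no online fingerprint service is needed.

## Node scoring and subnetwork search

Entity p-values are modelled as a beta-uniform mixture
f(p) = λ + (1−λ)·a·p^(a−1): uniform noise plus a Beta(a, 1) signal spike at
zero. The fit is maximum likelihood over (λ, a) in the open unit square from
a 16-point grid of starts (L-BFGS-B); zero p-values are clipped to machine
epsilon with a warning. From an FDR level (default 0.05) the fit yields the
threshold τ = ((π − fdr·λ)/(fdr·(1−λ)))^(1/(a−1)) with π = λ + (1−λ)a, and
node scores s(p) = (a−1)(ln p − ln τ), positive exactly below τ.

**Identifiability caveat.** λ and a trade off along a likelihood ridge when
the signal is weak (a close to 1). At n = 5000 the MLE is unbiased but
sd(λ̂) ≈ 0.075 at (λ, a) = (0.5, 0.6) — larger than at strong-signal
parameter values by an order of magnitude. Single-draw recovery checks at
weak-signal parameters therefore fail with appreciable probability no matter
how the fit is implemented; the package's tests document this boundary
rather than hiding it.

The maximum-scoring connected subnetwork is NP-hard, so the search is a
deterministic heuristic assembled from three candidates, returning the best:
greedy prize-collecting expansion from every positive node (single-neighbor
moves plus a 1-step negative-bridge lookahead, followed by pruning of
negative nodes whose removal keeps the subgraph connected); the exact
maximum-weight connected subtree (tree DP) of a minimum spanning tree under
edge costs −(s(u)+s(v))/2; and a cluster-merge candidate that contracts
connected positive clusters to supernodes, links them by cheapest
negative-connector paths, solves the supernode tree by DP, and re-runs with
the cost of each promising negative hub waived to capture shared (Steiner)
connectors. Pure stepwise expansion alone cannot justify crossing chains of
several negative connectors whose joint benefit is positive; the tree-based
candidates exist precisely for that case. Ties break deterministically
(higher score, then lexicographic id). The result is always connected, a
subgraph of the input, and scores at least the best single node; if all
scores are negative the best single node is returned with a warning.

## Functional analysis

*FCS* scores a term from its members' entity-level statistics without a
significance cutoff: Fisher (−2Σln p), Stouffer (ΣΦ⁻¹(1−p)/√k), Reporter
(the Stouffer Z standardized by the mean/sd of Z over 1000 random same-size
entity draws), median and mean of the `statistic` column. Significance is by
**entity-label permutation** — random same-size draws from the scored
universe, p = (1 + #{perm ≥ obs})/(n_perm + 1) — because it works from a
statistics table alone; sample permutation would need the raw data matrix
and is out of scope. For the sign-carrying median/mean statistics the
permutation p is two-sided via the absolute deviation from the permutation
mean. BH adjustment across terms.

*ORA* is the hypergeometric upper tail P(X ≥ k) only (overrepresentation;
depletion is not tested), with the selected list required to be a subset of
the universe. For networks mixing node types, per-type ORA p-values are
Fisher-combined across the types in which a term has members.

*Term frequencies* are exact multiset counts ordered by count descending
then term ascending — the numeric input of a word-cloud display, which
itself is out of scope.

## The synthetic-data generator

`simulateIntensityDataset()` emulates the features of a GC-TOF-style
experiment that the package's methods react to: log-normal intensities (base
log-means uniform over ~1e4–1e6, residual log-SD 0.5), a subject random
effect (SD 0.5) for paired designs, effects expressed in units of the
residual log-SD on a designated fraction of features, an injection sequence
with pooled QCs every `qc_interval` injections (QC technical CV 3% — pooled
QC replicates are far less variable than biological samples), multiplicative
drift over injection order (default amplitude 30% across a batch, linear or
half-sine), feature-specific batch offsets, and MCAR missingness. All
generators are deterministic under their mandatory seed, and the returned
truth table supports recovery metrics.

What it does **not** emulate: intensity-dependent (heteroscedastic)
measurement error, missingness that depends on abundance (censoring at the
detection limit), correlated feature blocks from shared pathways, retention
drift that reorders peaks, or batch effects that interact with biology.
Passing tests on these simulations therefore demonstrate correctness of the
statistical machinery under its own assumptions, not robustness to every
pathology of real data.

Test problem sizes are chosen to make the checks sharp but quick: 2000 null
features per test family for type-I calibration (99% binomial band around
α = 0.05), n = 5000 for mixture recovery, 50 random graphs of ≤ 10 nodes
against exhaustive search, 120-feature/2-batch runs for drift correction.

## Pipeline and interchange formats

Every artifact is plain delimited text: intensity tables (samples-in-rows
with metadata columns, or features-in-rows with a separate metadata table),
stats tables, edge lists (`source`, `target`, `relation_type`, `weight`),
GMT annotation sets, and node/edge TSVs for knowledge graphs with a typed
relation schema enforced at load. `runConfig()` executes YAML-described
stage lists (process → stats → network → enrich), pre-flights stage order
and input availability before any computation, logs parameters and seeds,
and reproduces byte-identical artifacts under fixed seeds. Every stage also
accepts file inputs, so each is runnable standalone.

## Known limitations

* Multivariate statistics beyond PCA (PLS-DA, clustering, classification)
  are out of scope.
* The knowledge-graph module enforces a schema and query semantics but ships
  only a toy example graph; real content must be supplied as node/edge
  files.
* FCS permutes entities, not samples (see above); inter-entity correlation
  within a term is therefore not reflected in the null.
* The subnetwork search is heuristic; it attains the exhaustive optimum on
  all sampled small graphs in the test suite, but carries no optimality
  guarantee at scale.
* The BUM fit is weakly identified when the signal component is close to
  uniform; interpret λ̂ and the derived τ cautiously when (1−λ̂)(1−â) is
  small.
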