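---
title: "Sparse projection models for multi-omics signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse projection models for multi-omics signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentsig)
```

## The model

All supervised methods in latentsig are projection-based: samples are
summarised by a small number of *latent components*
$t_1, \dots, t_H$, each a linear combination $t_h = X a_h$ of the original
features, with the feature weights collected in *loading vectors*
$a_1, \dots, a_H$. For classification the categorical outcome $y$ with $K$
classes is coded as an $N \times K$ dummy indicator matrix $Y$, which is
centred and scaled column-wise and treated as one more data block. The
fitting engine maximises, for each component, the design-weighted sum of
covariances between connected blocks' scores,

$$\max_{\;\|a_b\|_2 = 1,\;\|e\| = 1\;} \sum_{b < b'} c_{bb'}\,
  \mathrm{cov}(X_b a_b,\; X_{b'} a_{b'})
  \;+\; \sum_b c_{bY}\, \mathrm{cov}(X_b a_b,\; Y e),$$

subject to a cardinality constraint: at most `keepX` entries of each $a_b$
are nonzero. One generic alternating scheme solves this for every method in
the package:

* **plsda / splsda** — one block $X$ connected to $Y$;
* **block_plsda / block_splsda** — several blocks measured on the same
  samples (N-integration), pairwise connections set by a design matrix;
* **mint_plsda / mint_splsda** — one feature set measured in several
  independent studies (P-integration), with study-wise standardisation;
* **pls / spls** — a continuous response matrix in place of the dummy;
* **pca / spca** — unsupervised variance maximisation (separate NIPALS /
  power-iteration path).

### The alternating update

Each component is fitted by Horst-type alternating least squares: block
$b$'s loading is recomputed from the design-weighted sum of the *other*
connected blocks' current scores (the outcome's score included as a
connected block),

$$w_b \leftarrow X_b^\top \Big( c_{bY}\, u + \sum_{b' \ne b} c_{bb'} t_{b'} \Big),$$

then soft-thresholded to its `keepX` largest entries and renormalised to
unit length; the outcome weight $e$ is updated last. Iteration stops when
the largest absolute loading change falls below `tol` ($10^{-6}$ by
default, at most 100 iterations; both are recorded in the fitted model).
With one block and all features kept, the fixed point is the first singular
direction of $X^\top Y$ — exactly the classical PLS2 weight — and the test
suite verifies this equivalence against an independent NIPALS-PLS2
implementation and a dense SVD.

Initialisation uses the first singular vector of $X_b^\top Y$, making the
fit fully deterministic. A fixed sign convention (the largest-magnitude
entry of every loading is made positive, ties broken by feature index)
removes the remaining sign indeterminacy, so identical input yields
bitwise-identical output.

### Sparsity via keepX

Rather than exposing an abstract $\ell_1$ penalty, sparsity is
parameterised by `keepX`, the number of features retained per component per
block. Internally this is LASSO-style soft-thresholding: the
$(\mathrm{keepX}+1)$-th largest absolute weight is subtracted from the
magnitudes of the kept entries and the rest are zeroed. Exact boundary
ties are broken by feature index order, and a tied kept entry is nudged to
a vanishingly small nonzero value so the advertised invariant — *exactly*
`keepX` nonzero loadings — holds unconditionally. Loadings are renormalised
to unit length after thresholding; we verified this matches the behaviour
of the reference implementation of sPLS-DA to convergence precision.

### Deflation

All supervised methods use regression deflation: after each component,
every block is residualised on its own score,
$X_b \leftarrow X_b - t_b (t_b^\top X_b)/(t_b^\top t_b)$, which makes each
block's successive scores mutually orthogonal (tested at $10^{-8}$). The
response is deflated on the design-weighted mean of the block scores; with
one block this is the standard PLS2 regression-mode deflation. Canonical
deflation is not offered — the supervised methods here are all prediction
oriented.

### Design matrix

For multi-block fits, the $B \times B$ design matrix sets the weight of
each pair of blocks in the objective (0 = ignore the pair's covariance,
1 = full weight). The default connects every pair of omics blocks at 0.1
and every block to the outcome at 1: a weakly-connected compromise that
favours discrimination while still encouraging cross-block agreement.
Users who care more about cross-omics correlation than classification
should raise the off-diagonal weights. The outcome connections are fixed
at 1 and are not user-visible.

### Multi-study standardisation

P-integration fits centre and scale every feature *within each study*
before the single joint fit, removing additive and multiplicative study
batch effects in one step; loadings are global while scores can be read
globally or per study. Each study therefore needs at least two samples
(three, if scaling is on). When predicting, a new study is standardised by
the matching training-study parameters when its name is known; an unseen
study with at least 3 samples is standardised by its own means and
standard deviations, and smaller unseen batches fall back to the global
training parameters. The 3-sample cut-off is a pragmatic floor below which
a standard-deviation estimate is too unstable to help.

## Prediction

Projecting new samples applies the training standardisation and the same
deflation recursion as training, yielding predicted scores per block; the
training-time regression of the scaled dummy on the (orthogonal) scores
then gives predicted dummy values cumulatively at every depth
$h = 1 \dots H$. Three distances convert these into classes:

* **max** — the class with the largest predicted dummy value;
* **centroid** — the class whose training-score centroid is nearest in
  Euclidean distance;
* **mahalanobis** — the same, under the pooled within-class covariance of
  the training scores. The pooled estimator is our choice for the
  covariance; it is the natural LDA-style estimator and reduces to the
  centroid rule when that covariance is the identity (tested). A singular
  covariance falls back to the centroid rule with a warning.

For multi-block models each block votes: a **majority** vote reports ties
as `NA`, and a **weighted** vote weights each block by the mean (over
components) absolute correlation between that block's training scores and
the outcome variate — a symmetric, scale-free aggregation over components
— which resolves most even splits. Predictions are available at every
depth; the headline prediction uses all $H$ components.

`prediction_region()` classifies a grid spanning the first two components
(±10% margin) to visualise how the three distances partition the score
plane.

## Parameter tuning and evaluation

Tuning uses repeated, stratified M-fold cross-validation (fold class
counts within one sample of proportional), or leave-one-group-out CV for
multi-study fits, where each study is left out once. Errors are summarised
as the overall misclassification rate or the balanced error rate (BER, the
unweighted mean of per-class error proportions); BER is the default
because omics class sizes are rarely balanced. `NA` (vote-tie) predictions
count as errors during tuning — a deliberate penalty on unstable models.
The tuning distance defaults to centroid; both the distance and the
measure are exposed because reasonable analyses may want either.

`tune_keepx()` evaluates a user grid one component at a time, fixing each
component's winner before tuning the next; multi-block grids are evaluated
factorially. Ties go to the smallest keepX (smallest total, then
lexicographic, for factorial grids) to favour minimal signatures. The
number of components is chosen by one-sided paired t-tests across CV
repeats ($\alpha = 0.05$): the smallest depth at which adding a component
no longer significantly lowers the error. With a single repeat the test
degenerates to requiring a strict decrease. In practice $K-1$ components
suffice for $K$ classes, which is the default for the discriminant
constructors.

`perf()` refits the model inside every training fold — the sparse
selection is repeated per fold, so the reported stability frequencies
measure the reproducibility of the *selection procedure*, not of a fixed
support — and aggregates error rates, per-feature selection frequencies,
and one-vs-all ROC/AUC (rank-based, ties averaged) over folds and repeats.
AUC is reported as a complement only: the classifiers are distance-based,
so a threshold-sweeping criterion may not reflect their operating
performance. Fold-level parallelism (`cpus`) never changes results — the
fold plan is drawn up-front from the seed and the fits are deterministic.

## Missing values: NIPALS PCA

`nipals_pca()` extracts components by NIPALS power iteration. Missing
cells are handled by expectation-maximisation around the NIPALS core:
initialise missing cells at column means, fit, re-impute from the
rank-$H$ reconstruction, and repeat until imputations stabilise (change
below $10^{-6}$, at most 100 sweeps). On complete data a single pass runs
and reproduces the truncated SVD. On exactly low-rank data with a few
percent of cells masked, held-out cells are recovered to numerical
precision; with substantial noise the recovery error is bounded below by
the noise floor, which no imputation can beat.

## Synthetic data generators

The generators produce the structure the methods assume, so every stage of
the pipeline is testable without external downloads.

* `gen_single()` plants `n_informative` features whose class means follow
  an orthonormal basis of class contrasts with geometrically decaying
  weights (1, 0.5, 0.25): every informative feature carries the full
  primary contrast with a random sign, plus weaker higher-order contrasts.
  This emulates co-regulated feature modules along a dominant biological
  axis while keeping all $K$ classes mutually separated in $K-1$
  dimensions. `effect` is the largest class offset along the primary
  contrast in noise-sd units; 1.5 is our default "realistic signal", as a
  per-feature two-group separation of about 1.5 sd is typical of a clear
  but not trivial expression marker.
* `gen_multiblock()` adds shared latent factors that load on paired
  informative features across blocks with amplitude `2.2 * shared_strength`;
  the factor is outcome-independent, so cross-block correlation and class
  signal are controlled separately. The 2.2 scale is calibrated once so
  that `shared_strength = 1` yields cross-block correlations around
  0.7–0.75 among paired features at realistic sample sizes, matching the
  "highly correlated multi-omics signature" regime N-integration targets.
* `gen_multistudy()` applies per-study, per-feature multiplicative factors
  (log-sd 0.2) and additive offsets (sd 2 by default — strong batches,
  comparable to the class signal) to an identical class signal, the regime
  in which study-aware fitting visibly beats pooling.
* `inject_missing()` masks a fixed fraction of cells, never emptying a row
  or column.
* Noise is standard normal by default; a t(3) option (scaled to unit
  variance) probes robustness to heavy tails.

What the generators do **not** emulate: count overdispersion,
compositionality, library-size artefacts, feature-feature correlation
beyond the planted factors, or nonlinear class boundaries. Passing tests
on these generators therefore demonstrate correctness of the algorithms
under their stated assumptions — not performance on any particular real
platform; real data should be normalised upstream and pre-filtered to a
tractable feature count before fitting.

Preset shapes (`preset_config()`) mirror three classic benchmark layouts —
a 63 x 2,308 four-class microarray, a 150-sample three-block multi-omics
set (200/184/142 features), and a four-study 400-gene stem-cell panel — so
pipeline-scale behaviour can be exercised at familiar dimensions.

## Numerical choices and degenerate inputs

* Column standardisation uses the $N-1$ denominator; constant columns are
  centred and given sd 1 so they can never produce NaN, and they carry
  zero weight thereafter.
* Convergence is declared on the maximum absolute loading change
  ($10^{-6}$, 100 iterations); non-convergence is a recorded warning, not
  an error, since a near-converged sparse fit is still usable.
* An all-zero weight vector (a block orthogonal to its design targets)
  keeps its previous direction for that iteration; `sparsify_loading()` on
  an all-zero input warns and returns it unchanged.
* `ncomp` must be smaller than both the sample count and every block's
  feature count.
* Confidence ellipses on sample plots are per-class bivariate normal 95%
  contours (mean + covariance, radius $\sqrt{\chi^2_{2,0.95}}$) — a
  definition chosen for transparency, as "confidence ellipse" is often
  left unspecified in plotting tools.
* Arrow-plot coordinates are scaled to unit variance per component in both
  the predictor and outcome representations, so arrow length is a
  monotone function of (dis)agreement and vanishes exactly when the two
  representations coincide. Multi-block arrows start at the mean of the
  block variates.
* Relevance-network/circos similarities use each feature's correlation
  with its own block's components, summed over retained components; edges
  pass at $|r| > 0.7$ by default.
* Network export uses GML, the graph interchange format the surrounding
  tooling (igraph, Cytoscape) reads directly.

## Problem sizes used in the shipped checks

The test-suite and acceptance checks run at deliberately modest sizes —
50 x 20 oracle comparisons, 60–500-sample simulations with 100–500
features, 10-seed replicates for the stochastic claims (feature recovery,
batch-robustness gain, null calibration) — chosen so the full pipeline
(generation, tuning, refitting inside CV, evaluation) is exercised
end-to-end in seconds while leaving the statistical conclusions stable
across seeds. Scaling beyond that changes runtimes, not code paths: the
preset shapes above exercise the largest layouts.

## Known limitations

* Canonical-mode two-block analysis, rCCA/rGCCA-style wrappers,
  independent component analysis, and unsupervised multi-block/multi-group
  variants are not exposed, although the engine admits them.
* Missing values are supported only in `nipals_pca()`; the supervised fits
  require complete matrices (impute first, e.g. from the NIPALS
  reconstruction).
* Components are linear; nonlinear (kernel) extensions are out of scope.
* The weighted-vote block weighting and the Mahalanobis covariance
  estimator are documented choices where the field's convention is loose;
  both are tested for their limiting behaviours (equal weights reduce to
  majority voting; identity covariance reduces to the centroid rule).
* P-values, calibrated probabilities and model-comparison tests are not
  provided; the package's claims are about projection, selection and
  cross-validated error.

## A worked example

```{r, eval = FALSE}
set.seed(1)
cfg <- sim_config(n_per_class = 20, p = 500, K = 3, n_informative = 20,
                  effect = 1.5, seed = 1)
sim <- gen_single(cfg)

tuned <- tune_keepx(sim$X, sim$y, ncomp = 2, grid = c(5, 10, 20, 30, 50),
                    nfolds = 5, nrepeats = 3, seed = 2)
fit <- splsda(sim$X, sim$y, ncomp = 2, keepX = tuned$chosen_keepX$X)
report <- perf(fit, nfolds = 5, nrepeats = 3, seed = 3)

report$error["centroid", "ber", ]   # BER per component depth
head(sort(report$stability[[1]][[1]], decreasing = TRUE))
mean(sim$truth$informative %in% selected_features(fit, comp = 1))
```
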