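---
title: "Inferring regulatory networks from joint-moment pair features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring regulatory networks from joint-moment pair features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnmoment)
```

## The problem and the model

Co-expression screens for gene regulatory networks (GRNs) usually rank gene
pairs by linear correlation. Regulation, however, is frequently nonlinear —
saturating responses, repression, dosage effects that look quadratic on a log
scale — and pairs coupled through such links can have a Pearson correlation
near zero while being strongly dependent. `grnmoment` represents every
unordered gene pair $(a, b)$ by the full grid of joint moments of the two
standardized expression profiles,

$$ m_{n,m} = \mathrm{E}[x^n y^m] = \frac{1}{S}\sum_{s=1}^{S} x_s^{\,n}\, y_s^{\,m},
\qquad 1 \le n, m \le 7, $$

where $x$ and $y$ are the z-scored rows of the smaller- and larger-id gene
and $S$ is the number of samples. The $7\times7$ grid gives 49 features;
$m_{1,1}$ is exactly the Pearson correlation (we standardize with the
population convention, dividing by $\sqrt{S^{-1}\sum (x_s-\bar x)^2}$,
precisely so this identity is exact rather than off by $(S-1)/S$). Higher
moments capture the nonlinear dependence correlation misses: a purely
quadratic link leaves $m_{1,1}\approx 0$ but produces a large $m_{2,1}$.

The 49 moments are standardized across pairs (population SD again;
zero-variance columns are set to zero with a warning) and reduced to 36
principal components. PCA is fitted on the full candidate-pair table before
any labeling — the labels only enter afterwards — and the model stores the
standardization vectors so any pair table with the same grid can be
projected.

Classification then proceeds on the reduced features:

* **REWKLR** (rare-event weighted kernel logistic regression), the package's
  own implementation. It maximizes the penalized weighted log-likelihood
  $$ J(\alpha, b) = \sum_i w_{y_i}\left[ y_i \log p_i + (1-y_i)\log(1-p_i)\right]
     - \tfrac{\lambda}{2}\,\alpha^{\mathsf T} K \alpha, \qquad
     p_i = \sigma\!\big((K\alpha)_i + b\big), $$
  with $K$ the RBF Gram matrix $K(u,v)=\exp(-\lVert u-v\rVert^2/2\sigma^2)$.
  The class weights implement the standard case-control prevalence
  correction: with population prevalence $\tau$ and sample prevalence
  $\bar y$, $w_1 = \tau/\bar y$ and $w_0 = (1-\tau)/(1-\bar y)$. True
  interactions are rare among all $G(G-1)/2$ pairs, so a balanced training
  sample badly overstates the prevalence; the weights undo that. Setting
  `tau = "sample"` gives unweighted kernel logistic regression.
* **Two-class SVM** and **one-class SVM** with RBF kernels, delegated to
  libsvm (e1071). The one-class variant is trained on known interactions
  only, for the setting where "not in the database" does not mean
  "not interacting"; its $\nu$ parameter bounds the fraction of training
  positives treated as outliers.

Training labels come from a gold standard of curated TF→target edges,
collapsed to unordered pairs (the network is built undirected). Negatives
are unknowable in principle, so the package adopts the low-correlation
heuristic: all candidate pairs are ranked by $|m_{1,1}|$ ascending and the
lowest $k$ (10,000 at full scale) are labeled unrelated. Gold pairs are
excluded from that pool by default so no pair carries both labels, and ties
are broken by canonical pair id so the selection is deterministic.

## Fitting details and numerical choices

The REWKLR objective is concave in $(\alpha, b)$, so the fit uses damped
Newton steps: the exact Hessian blocks are assembled, the step is
backtracked until $J$ does not decrease, and iteration stops when the
gradient norm over $(\alpha, b)$ drops below `tol` (default $10^{-6}$,
`max_iter` 100). A diagonal jitter of $10^{-8}$ stabilizes the Gram matrix;
fitted probabilities are reported with the unjittered kernel so they equal
`predict()` on the training points. Non-convergence is an error, never a
silently returned point — the test suite confirms every returned optimum
against a central-difference gradient oracle and against a general-purpose
optimizer on small instances.

An explicit unpenalized intercept is included: without one, the weighted
base rate cannot be matched in the strong-regularization limit (as
$\lambda \to \infty$, $\alpha \to 0$ and the prediction tends to the
weighted prevalence, which the tests verify).

Two RBF parameterizations coexist deliberately: REWKLR uses the bandwidth
form $\exp(-d^2/2\sigma^2)$ while the SVMs use libsvm's
$\exp(-\gamma d^2)$; both are exposed and tagged in `rbf_kernel()` because
published parameter tables quote $\sigma$ for the former and $\gamma$ for
the latter ($\gamma = 1/2\sigma^2$).

Hyperparameters are tuned by bootstrap resampling: per grid point,
`n_boot` resamples define in-bag training and out-of-bag test rows; the
score is the mean of the two per-class accuracies (binary) or the
out-of-bag positive-class accuracy (one-class), and the winner is the first
grid point attaining the maximum. The same resamples are reused across grid
points so comparisons are paired. Class-incomplete resamples are redrawn,
up to 25 attempts.

Curves carry uncertainty the same way: ROC and precision-recall points are
recomputed on bootstrap resamples of the evaluation rows (500 by default)
and reported as mean ± SD per threshold. Thresholds sit at evenly spaced
score quantiles (101 by default), bracketed by ±∞ so every curve reaches
(0,0) and (1,1); the AUC is the trapezoidal area under the full-data curve
and is validated in the tests against the Mann–Whitney concordance count.
Resampling is with replacement (a bootstrap proper); subsampling would also
have been defensible, but the bootstrap matches the "resampling the
training data" reading and keeps the effective sample size. The one-class
SVM produces no false-positive rate, so it is excluded from ROC/PR and
reported through positive-class accuracy only.

Gram matrices are quadratic in the training size, so training sets above
`max_per_class` (default 4,000 per class) are subsampled with a recorded
seed; the full 20,000-point kernel problem is cluster-scale, not
desk-scale.

Moment computation is chunked (`chunk_size` pairs at a time, default
5,000) with incrementally built powers, so memory stays bounded and results
are identical for any chunk size. Desk-scale runs use a few hundred genes;
the 18.2-million-pair genome-scale table is out of scope for a single
machine and only its count is exercised.

## Normalization

When the input is a raw count matrix, TPM and FPKM are computed from counts
and annotated gene lengths: TPM scales length-rates to sum to $10^6$ per
sample; FPKM is $c \cdot 10^9/(\ell \cdot T)$ with $T$ the sample's total
count. Two simplifications are deliberate: the effective length is the
annotated length (no fragment-length correction — the pipeline starts at the
count matrix, after quantification), and the per-million denominator is the
column sum (the matrix is the only depth information available). Both
normalizations are within-sample, zero-preserving, and rank-equivalent per
sample; the tests pin the column-sum and depth-invariance identities.
Whether intensity-scale (microarray-like) inputs should be log-transformed
before z-scoring is exposed as `log_transform` (default off, matching the
default treatment of intensities as-is); moments are scale-sensitive, so
the flag matters for heavy-tailed inputs and is worth flipping in
sensitivity analyses.

## What the simulator emulates — and what it does not

`simulate_network()` draws `n_tfs` regulators, each with `targets_per_tf`
distinct targets; `simulate_expression()` gives every regulator an
independent standard-normal latent value per sample and builds each
regulated gene as the sum of per-edge link responses — linear $z$, quadratic
$z^2-1$, saturating $\tanh 2z$, repressive $-z$ — plus one Gaussian noise
term (`noise_sd`), exponentiating everything onto a positive intensity-like
scale. Different TFs may share a target (necessary once the gold standard
must reach 10,000 pairs on a few hundred genes); with a single incoming
edge the construction reduces to exactly one link response plus noise.

Defaults (300 genes, 20 TFs × 10 targets, 300 samples, noise SD 0.3, equal
link mix) are the package's desk-scale study conditions; the feature-width
checks use 250 genes / 50 TFs × 200 targets / 50 samples, the smallest
configuration that supplies 10,000 gold pairs and 10,000 eligible
negatives.

Two caveats matter when reading test results. First, the exponentiation is
convex and monotone, so it leaks some linear correlation back into
quadratic links (mean $|r|\approx 0.3$ on the positive scale, near zero on
the log scale) and shrinks the apparent correlation of repressive links;
the near-invisibility of quadratic links to correlation is therefore
asserted on the log scale, with a weaker ordering check on the positive
scale. Second, the simulator is not a sequencing-noise model: no negative
binomial counts, no library-size variation, no batch structure, no
combinatorial regulation, no time dynamics. Passing tests show the pipeline
recovers planted dependence of the shapes it models — they do not certify
performance on real RNA-seq, where the published full-scale numbers came
from thousands of heterogeneous experimental conditions.

## Design choices that were genuinely open

* **The moment grid.** A 49-vector with $m_{1,1}$ equal to correlation
  forces exponents $\{1..7\}^2$ with no order-0 terms; row-major order is
  fixed for determinism.
* **Orientation.** $m_{n,m} \ne m_{m,n}$, so pairs are canonically oriented
  with $x$ the lexicographically smaller gene id (C collation,
  locale-independent). Recomputing after shuffling gene rows yields an
  identical table.
* **Negative ranking scale.** The lowest-$|m_{1,1}|$ ranking uses the raw
  moment of z-scored genes — i.e. the correlation itself — rather than the
  across-pairs standardized column, whose sign-ambiguity would make
  "lowest absolute value" depend on the pair population.
* **PCA fitting population.** Fitted on all candidate pairs (transform
  before labeling); a leakage-averse alternative (fit on training pairs
  only) is possible by calling `fit_pca()` on a subset, but the default
  mirrors transform-then-label.
* **Prevalence for REWKLR.** `run_pipeline()` defaults `tau` to unit
  weights; when set to `NULL` it uses the gold-pair share of all candidate
  pairs, the natural prevalence estimate for the undirected network.
* **Resampling flavor.** Bootstrap (with replacement), as discussed above.

## Limitations

Genome-scale pair tables (millions of rows × 49) need chunked/cluster
execution; the package keeps the algebra identical but is sized for
hundreds of genes per run. The low-correlation negative heuristic labels
some truly interacting nonlinear pairs as negatives by construction — the
one-class SVM route exists precisely because negatives are not
deterministic. Directionality is discarded (undirected pairs), so regulator
and target cannot be distinguished from moments alone, whose orientation
convention is lexicographic, not causal.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(
  out_dir = tempfile("grn_run_"),
  sim = simulation_config(n_genes = 100, n_tfs = 10, targets_per_tf = 8,
                          n_samples = 200, noise_sd = 0.3, seed = 1),
  k_negatives = 120, n_pos = 60, n_neg = 60,
  classifiers = c("rewklr", "svm"),
  n_boot = 5, n_resamples = 100, seed = 1)
res <- run_pipeline(cfg)
res$reports$rewklr
autoplot(res$reports$rewklr$roc)
```

Every artifact in the run directory (expression matrix, gold edges,
training set, model archive, report and curve tables, checksummed run log)
is regenerable from the configuration and seeds alone.
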