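---
title: "CiteGate: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CiteGate: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

CiteGate trains binary surface-marker classifiers on CITE-seq data — mRNA
counts labeled by antibody-derived-tag (ADT) levels — and applies them to
conventional scRNA-seq count matrices. The motivating marker is CD45RA on
human T cells, whose isoform-level expression short-read scRNA-seq cannot
resolve. This vignette records the model, its assumptions, the tunable
parameters, and the design decisions taken where the procedure was
genuinely open.

## 1. Labeling by Otsu thresholding

The ADT level is taken on the provider's normalized, log-transformed scale.
`otsuThreshold()` bins the values into 256 equal-width bins and returns the
split maximizing the between-class variance
$\sigma_b^2 = \omega_0\omega_1(\mu_0-\mu_1)^2$; `assignLabels()` then calls
cells with ADT $\ge t^* + m$ positive and ADT $\le t^* - m$ negative
(boundaries inclusive), excluding the open band in between from all training.
The margin $m$ defaults to 0.5 on the normalized-log ADT scale and is a free
parameter so other markers, with other ADT dynamic ranges, can retune it.

Two numerical choices deserve note:

* **Bin count.** 256 equal-width bins over the observed range — the common
  reference default; the procedure is insensitive to it for clearly bimodal
  ADT.
* **Tie-break.** For well-separated modes every split inside the empty
  inter-mode gap attains exactly the same $\sigma_b^2$. A first-maximum rule
  would park $t^*$ at the gap's lower edge; we follow Otsu's original
  recommendation and average the maximizing bin centers, placing $t^*$
  mid-gap. Both the implementation and the brute-force test oracle apply
  this rule, by independent computations. With `margin = 0`, a value exactly
  at $t^*$ is assigned negative (the threshold bounds the low class from
  above, matching the between-class-variance derivation).

Assumption: the ADT distribution is bimodal enough that a single global
threshold is meaningful. A constant ADT vector is an error, not a guess.

## 2. Quality control

`gateTCells()` keeps cells with raw count > 0 for at least one of
CD3D/CD3E/CD3G/CD247 (CD3Z accepted as an alias for CD247) and raw count 0
for CD19. The gate is applied to raw counts because a presence/absence call
on lineage markers should not depend on normalization; no count threshold
beyond "> 0" is imposed. `filterCellsGenes()` then removes cells whose
ribosomal fraction (symbols matching `^(RPS|RPL)`, configurable) is below
5% — zero-library cells are removed first, with their own reason, since the
fraction is undefined — and finally genes seen in fewer than 2 cells (a
gene seen in exactly 2 cells survives). Low-UMI (1000) and mitochondrial
(20%) filters exist but default off: public datasets typically arrive with
them pre-applied by the provider. Doublet removal is exposed only as an
external hook (`dropDoublets()`): it is a well-served third-party problem,
not part of this method.

## 3. Normalization contract

`normalizeRegress()` produces per-gene Pearson residuals under a
negative-binomial mean–variance model with a library-size offset:
$\mu_{gi} = \lambda_g\,\ell_i$, $r_{gi} = (y_{gi}-\mu_{gi}) /
\sqrt{\mu_{gi} + \phi_g\mu_{gi}^2}$, clipped at $\pm\sqrt{n_\text{cells}}$.
This is the widely used analytic stand-in for regularized NB normalization;
bit-level parity with any particular reference implementation is a
non-goal.

* **Rate estimator.** $\lambda_g$ is the unweighted mean of per-cell rates
  $\frac1n\sum_i y_{gi}/\ell_i$ rather than the Poisson MLE
  $\sum y / \sum \ell$. The two agree asymptotically; the mean-of-rates form
  is *exactly* invariant to rescaling all counts of one cell (the offset
  absorbs it), which is the behavior a library-size offset should have.
* **Dispersion.** Per-gene method-of-moments estimates
  $\hat\phi_g = \sum[(y-\hat\mu)^2-\hat\mu]/\sum\hat\mu^2$ are smoothed
  against $\log_{10}\lambda_g$ by robust loess. The regularization is what
  makes residual variance informative: with free per-gene $\phi$ every
  gene's residual variance is ≈ 1 by construction and genuinely
  overdispersed genes would be invisible to the highly-variable-gene
  ranking. One consequence, verified by a tolerance-based test: rescaling a
  single cell perturbs other cells' residuals only through the re-estimated
  trend, an $O(1/n)$ effect — exact invariance is unattainable for any
  data-driven dispersion estimate.
* **Covariate regression.** The S-minus-G2M cell-cycle score difference and
  the mitochondrial fraction are regressed out of each gene's residual
  vector by OLS (with intercept); an empty covariate list is the identity.
  The cell-cycle score is the classic bin-control module score on
  log-normalized expression (25 expression bins, 50 seeded control genes per
  set gene), with the standard 43 S-phase / 54 G2M-phase human symbols
  shipped as data files.
* **Corrected counts.** The GLM consumes counts, so corrected counts are
  reconstructed at the median library size:
  $y' = \mathrm{round}(\mu^{med}_g + r_{gi}\sqrt{\mu^{med}_g +
  \phi_g(\mu^{med}_g)^2})$, floored at 0, rounded half-to-even. This keeps
  per-cell variation (clipped of outliers) while removing depth.

The classifier consumes the covariate-regressed residuals. The alternative —
corrected counts — is switchable by constructing the feature matrix
differently, but residuals are the variance-stabilized, covariate-clean
representation and were chosen as the default.

## 4. Differential expression

For each gene, cells are modeled per condition $j \in \{+,-\}$ as
$y \sim \text{QuasiPoisson}(\mu, \phi)$, $\log\mu = X\beta$,
$\mathrm{Var}(y) = \mu + \phi\mu^2$. For the saturated two-group design the
score equations have the closed form $e^{\beta_j} = \sum_{i\in j} y_i /
\sum_{i\in j} e^{o_i}$ — the IRLS fixed point — and, because corrected
counts carry no offset (constant within groups), this is simultaneously the
root of the quasi-score for any $\phi$. The dispersion is method-of-moments
on full-model residuals with an $n/(n-2)$ degrees-of-freedom correction
(two mean parameters), floored at $10^{-8}$; the correction keeps the
likelihood-ratio test's type-I error at its nominal level, which the test
suite checks on null NB simulations.

The statistic $D = 2(\ell_\text{full} - \ell_\text{null})$ uses the
quasi-likelihood kernel $Q(\mu;y) = y\log\mu - (y + 1/\phi)\log(1+\phi\mu)$
with the full model's $\hat\phi$ plugged into both models (the standard
quasi-LRT convention), referred to $\chi^2_1$. $D$ is clamped at 0 against
roundoff. All-zero genes return $D = 0$, $p = 1$ by definition. The test
oracle maximizes $Q$ over the group means by brute-force grid refinement at
the same directly-recomputed $\hat\phi$ — an independent route to the same
defined quantity.

**Fold-change convention.** The link is the natural logarithm, so the raw
coefficient difference $\beta_{C2}-\beta_{C1}$ is on the ln scale;
`log2FoldChange()` divides by $\ln 2$ so the reported value equals
$\log_2(\bar y_{C2}/\bar y_{C1})$. Positive values mean higher expression
in marker-negative cells; the orientation is preserved everywhere,
including feature selection.

Benjamini–Hochberg q-values are computed by the hand-written three-line
step-up (cross-checked against `p.adjust` in the tests); genes are
DE-eligible at q < 0.05.

## 5. Feature selection

Two sources, always computed on the training split (per fold during
cross-validation):

* **DE source:** genes with q < 0.05 and $\log_2\mathrm{FC} \ge t_{DE}^{up}$
  or $\le t_{DE}^{low}$. The two bounds are searched independently over
  (1, 4) and (−4, −1): reported optima differ between them, so a single
  symmetric threshold would be an unwarranted restriction.
* **Correlation source:** Spearman correlation of every gene's residuals
  with the anchor gene (HNRNPLL, the splicing factor steering CD45RA exon
  exclusion), average ranks on ties, two-sided p from the t approximation.
  Genes (anchor excluded) with $|\rho|$ in the top $P_{hn}$ fraction *and*
  p < 0.05 are selected. "$P_{hn}$ percentile" is read as the top-$P_{hn}$
  fraction, consistent with its search range $(10^{-6}, 0.1)$ where smaller
  is stricter. Raw p-values are used (no multiplicity correction): the
  screen is a tunable filter, not an inference.

The union is deduplicated with provenance (`de` / `corr` / `both`) and a
deterministic order: DE genes by decreasing $|\log_2 FC|$, then
correlation-only genes by decreasing $|\rho|$, ties lexicographic. DE runs
on all post-QC genes (not only highly variable ones): restricting the
candidate pool would silently interact with the tunable thresholds.

## 6. Classifiers and joint optimization

Five families, all consuming the residual matrix restricted to the feature
set:

* `lr` — L2 logistic regression via glmnet with
  $\lambda = 1/(C_{LR}\,n)$, `standardize = FALSE`, reproducing the
  C-parameterization of the reference stack; threshold 0.5.
* `svm_linear`, `svm_rbf` — soft-margin C-SVC solved by a compiled SMO
  (maximal-violating-pair selection, KKT tolerance $10^{-3}$, precomputed
  kernel); decision threshold 0. No probability calibration.
* `stack` — meta logistic regression (unpenalized, untuned — it has two
  inputs) on the *hard* 0/1 predictions of the LR and RBF-SVM base models,
  both trained on the same training data.
* `mlp` — 1–3 dense ReLU layers of 16–128 units, inverted dropout
  $\rho \in (0.1, 0.5)$, sigmoid output, binary cross-entropy, Adam with
  learning rate $\eta$, fixed 15 epochs and batch size 32. He-uniform
  initialization and Adam are unstated upstream choices; they are the
  de-facto standard for ReLU networks. The MLP does not search feature
  thresholds: it reuses the feature set optimized for an SVM (the pipeline
  uses the RBF SVM as donor).

Hyperparameters and feature thresholds are tuned jointly by
`bayesOptimize()`: a Gaussian-process surrogate (Matérn $\nu = 5/2$,
isotropic length scale and nugget refit by marginal likelihood each
iteration, inputs min–max scaled to the unit box, values standardized), a
5-point Latin-hypercube design, expected-improvement acquisition maximized
over a seeded random candidate set plus local jitter around the incumbent,
at most 30 iterations past the design or until EI < $10^{-6}$. No priors
are placed on the optimum. The objective is mean 5-fold *stratified*
cross-validation accuracy (negated binary cross-entropy for the MLP), with
the feature set re-derived inside each fold from that fold's training
portion — the per-fold DE and correlation tables are computed once and
sliced by the candidate thresholds, which is an exact cache, not an
approximation. An empty feature set scores 0 (or worst loss), steering the
optimizer away rather than erroring.

Separately published optimized MLP hyperparameter values are typographically
scrambled in their source (layer counts printed as learning rates and so
on) and are deliberately not used as defaults; defaults come from fresh
optimization.

## 7. Leakage discipline and evaluation

The train/test split is a plain shuffle split (test size 0.2, seed 42 —
stratification is not claimed upstream and is therefore not applied). All
feature statistics and fits are functions of the training split;
`auditCells()` instruments DE, the correlation screen and model fitting to
record every barcode they see, and `trainPipeline()` asserts the recorded
sets never intersect the test split. `evaluatePredictions()` reports
accuracy, precision and recall (positive class = marker-positive), the ROC
curve with rank-based AUC, the precision–recall curve with average
precision, and a per-cluster misclassification table when a clustering is
supplied. With no positive truth cells, precision and recall are reported
as `NA` — undefined, not zero.

## 8. Inference on query data

`inferCells()` applies the stored contract: per-gene rates and dispersions
come from training, library sizes are refit on the query, covariate
regression is skipped unless covariates are supplied (plain scRNA-seq
queries rarely carry them). Genes missing from the query are zero-filled
with a warning above 20% missing and an error above 50%
(`alignFeatures()`). Model archives are a directory of `model.rds`, the
feature set as JSON, and a manifest with the payload's MD5 hash;
`readModel()` refuses a mismatching hash. Predictions are per-cell
independent and byte-reproducible under a fixed seed.

## 9. The synthetic world

`simulateCiteSeq()` emulates the structure the pipeline consumes:

* ADT simulated directly on the normalized-log scale as a two-component
  Gaussian mixture (means 1 and 4, sd 0.5, 45% positive); component
  membership is the ground-truth class. Tag-count simulation is skipped
  because the pipeline consumes the provider-normalized scale.
* NB counts (dispersion 0.5) with log-normal library sizes (median ≈ 2500
  UMIs); 30 planted DE genes at $|\log_2 FC| = 2$, half up in each class.
* A 50-gene block rank-correlated with the anchor gene through a Gaussian
  copula, latent correlation $2\sin(\pi\rho_S/6)$ for a Spearman target of
  0.6. The block is simulated depth-free (constant mean across cells) so
  the rank-correlation target transfers to the counts up to discreteness;
  with depth-coupled means the library size would add or subtract rank
  correlation uncontrollably.
* The gene catalog (abundances, planted roles, QC marker genes, a slice of
  real S/G2M symbols so the cell-cycle covariate is live) is drawn under a
  separate fixed `gene_seed`, so simulations with different `seed`s emulate
  different experiments on the same biology. This is what makes
  cross-simulation inference (train on one seed, predict another)
  meaningful.

Not emulated: doublets, ambient RNA, batch effects, depth-coupled
correlation structure, isoform-level read mapping. A green test on this
world establishes that the machinery recovers planted structure at
realistic noise levels — not that any particular biological dataset will
reach the same accuracy.

`workedToy()` ships a 40-cell × 20-gene CSV fixture with a hand-checkable
Otsu threshold, two obviously differential genes and millisecond-scale
brute-force oracles.

## 10. Known limitations

* The SVM stack offers no probability calibration; the stack consumes hard
  base predictions by design.
* Quasi-Poisson DE supports the two-condition design only (no batch
  covariates in $X$).
* Query-time covariate regression requires the caller to supply covariates;
  cell-cycle scores are not recomputed automatically at inference.
* The GP optimizer searches scale-sensitive parameters (γ, C) uniformly in
  their boxes, faithful to the reference setup; with few iterations it can
  settle in mediocre regions of the γ axis. The 30-iteration default is
  usually sufficient.
* Exact parity with reference implementations of Otsu (plateau inputs) and
  NB normalization is deliberately not claimed; the contracts above are the
  specification.
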