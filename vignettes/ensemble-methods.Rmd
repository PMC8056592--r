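---
title: "Ensemble integrative clustering of longitudinal expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble integrative clustering of longitudinal expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longicluster)
```

## The problem

A longitudinal expression study measures the same subjects repeatedly —
here, the motivating design is a skin-disease treatment course with a
non-lesional (NL) reference biopsy plus lesional biopsies at baseline and
several early weeks, and a binary clinical outcome (responder versus
non-responder). The goal is a small gene signature whose early temporal
behaviour separates the two outcome groups.

`longicluster` treats each time point as one *view* of a multi-view
integration problem. All views of a subject are assumed to share a single
low-dimensional latent score, so the time points play the role that assay
platforms play in multi-omics integrative clustering.

## The model

For view (time point) $t$, the standardized expression vector of subject
$i$ follows

$$ X_{it} = W_t Z_i + \varepsilon_{it}, \qquad
   Z_i \sim N(0, I_q), \quad
   \varepsilon_{it} \sim N(0, \Psi_t), $$

with diagonal $\Psi_t$ and, conditional on $Z_i$, independence across
views. Row-stacking the views therefore yields one factor-analysis model
with diagonal noise, which is how `fit_icluster()` computes: EM on the
stacked matrix, with the posterior moments

$$ \mathrm{Var}(Z \mid X) = (I_q + W^\top \Psi^{-1} W)^{-1}, \qquad
   E(Z \mid X) = \mathrm{Var}(Z \mid X)\, W^\top \Psi^{-1} X $$

evaluated through the Woodbury identity so the $p \times p$ covariance is
never formed. With $K$ clusters the latent dimension is $q = K - 1$;
cluster labels come from k-means on the posterior means (10 seeded
restarts, best within-cluster sum of squares, ties to the first
occurrence). After every M-step the loadings pass through the
soft-threshold operator $\mathrm{sign}(w)(|w| - \lambda)_+$, which zeroes
non-informative genes when $\lambda > 0$.

Numerical choices worth knowing:

* **Initialization** is deterministic: the top-$q$ singular vectors of the
  stacked matrix, scaled by $d_j/\sqrt{n}$ and sign-fixed so the largest
  element of each column is positive; $\psi$ starts at 1. Nothing about
  the fit depends on the RNG except the k-means restarts.
* **Convergence**: with $\lambda = 0$ the observed-data log-likelihood is
  monotone under EM, so the stop rule is a relative log-likelihood change
  below `tol` (default $10^{-6}$, `max_iter = 200`). Soft-thresholding
  breaks the monotonicity argument, so with $\lambda > 0$ the trace and
  the stop rule switch to the maximum absolute loading change.
* **Variance floor**: $\psi \ge 10^{-4}$, preventing Heywood collapse on
  features fit exactly.
* **Degeneracy**: if fewer than $K$ distinct latent points exist (for
  example after total shrinkage, when $W = 0$ and every posterior mean is
  zero), the labels collapse and the fit carries a degenerate flag instead
  of failing.

## The ensemble

A single unsupervised fit on all genes is a weak outcome predictor.
The package's core procedure strengthens it with a random-subspace
ensemble (`run_ensemble()`):

1. draw a random subset of `subset_size = 20` genes;
2. fit the latent-variable model on that subset with $\lambda = 0$
   (feature selection is pointless inside a 20-gene subset) and $K = 2$;
3. map the two clusters to the outcome classes by the better of the two
   possible mappings (`map_clusters_to_labels()`); the weak learner's
   *accuracy* is that agreement rate;
4. keep the learner if its accuracy is **strictly** greater than
   `accuracy_cutoff = 0.75`;
5. repeat `n_replicates` times (2000 by default here; 10,000 reproduces
   the original study scale).

Kept learners are aggregated two ways. Genes are scored by **summed
absolute loadings**: $\mathrm{score}(g) = \sum_{\text{kept learners
containing } g} \sum_t |W_t[g]|$, so a gene scores high either through one
large loading or through consistent moderate loadings across time points
(a max-over-views variant is available via `score_stat = "max"` but
deliberately not default, since it misses the second pattern). Subjects
are classified by **majority vote** over the kept learners' mapped
predictions; an exact tie goes to "non-responder", the conservative
clinical call (flip with `tie = "responder"`). Scores are intentionally
not normalized by how often a gene was sampled — the raw sum is the
declared score — with `normalize_scores = TRUE` as a sensitivity check.

Two declared tie-breaks make everything reproducible: cluster-to-class
mapping ties at exactly 0.5 map the responder-heavier (then lower-id)
cluster to "responder", and equal gene scores rank lexicographically.
Each replicate derives its own seed from the master seed by a counter
(`derive_seed()`), so replicate $r$ can be reproduced in isolation and an
identical seed gives a bit-identical result.

If **no** learner passes the cutoff, `run_ensemble()` stops with an
error naming the cutoff. This is deliberate: an accuracy filter that keeps
nothing means the labels carry no signal the weak learners can see, and a
silent empty ensemble would invite misreading downstream.

## Supervised evaluation

Because the accuracy filter looks at the labels, the in-sample vote
accuracy is optimistic. The honest estimate is the **nested leave-one-out**
loop (`nested_loo_ensemble()`): hold out one subject, rebuild the views
and retrain the *entire* ensemble on the rest, take the top-`k = 20`
genes, train an SVM on the training subjects' *pseudo-genes* (a gene's
expression averaged over the early lesional time points,
`make_pseudo_genes()`), and predict the held-out subject. Feature
selection never sees the held-out subject; a sentinel test corrupts the
held-out subject's data and verifies the selected genes do not move.

SVM settings default to the radial kernel with cost 1 and kernel width
`1/ngenes`, the common default of the underlying implementation; features
are standardized with training-fold means and SDs only. The
`random_gene_baseline()` answers "how well would *any* 20 genes do" by
repeating the LOO-SVM over 1000 uniform gene subsets.

Two comparators mirror the evaluation: `lasso_ensemble()` replaces the
weak learner with an L1-penalized logistic model on random 100-gene
subsets of the pseudo-genes (per-replicate penalty by cross-validated
deviance; absolute coefficients are accumulated, matching the
absolute-loading score — switch with `use_abs = FALSE`), and
`single_icluster_selector()` is the no-ensemble control: one whole-gene
fit, ranked by the same summed-|loading| score.

A caveat worth stating: leave-one-out with a flexible classifier is
*pessimistically* biased on uninformative data — the held-out subject's
class is always the minority of its training fold — so null-data LOO
accuracies sit at or below 0.5 rather than scattering symmetrically
around it. Tests assert the absence of optimism (the direction that
would matter) rather than a two-sided chance band on the mean.

## Trajectories and gap closure

`group_mean_trajectories()` tabulates, per gene and outcome group, mean
expression at every time point with group size and standard error, plus
each gene's non-lesional reference mean. `gap_closure()` condenses the
clinically interesting pattern into one ratio per gene and group:
$|\bar{x}_{to} - \mathrm{NL}| / |\bar{x}_{from} - \mathrm{NL}|$. Values
below 1 mean the lesional expression moved back toward its non-lesional
level; 0 is full normalization; a flat non-responder trajectory gives 1.
A starting gap below $10^{-8}$ is flagged undefined rather than divided.

## The synthetic generator

`simulate_longitudinal()` emulates the structure the method assumes, so
the whole stack is testable without any download. Informative gene $g$
has non-lesional mean $\mu_g$ and a signed lesional displacement
$\delta_g$; at lesional step $t$ the responder mean is
$\mu_g + \delta_g r^t$ (the gap to NL closes geometrically, reproducing
the observed U-shaped recovery; a linear mode exists behind
`recovery_mode`) while the non-responder mean stays at
$\mu_g + \delta_g$ (plus an optional drift). Non-informative genes follow
one law in both groups. Noise is a subject random intercept (shared
across all of a subject's cells) plus i.i.d. residuals.

The defaults are the package's fixed study-shaped scenario, chosen once
to mirror the motivating design and used unchanged everywhere
(`reference_simulation()`, seed 20210420): 30 subjects split 15/15, 300
genes with 20 informative, $|\delta| \in [1.5, 2.5]$ with random sign,
$r = 0.5$, subject SD 0.3, residual SD 0.5, time points NL, LS0, W1, W2,
W4. The non-lesional means are drawn from $[6, 10]$, a realistic log2
microarray intensity range. Week 16 is omitted because the analysis views
stop at week 4. With $|\delta| \approx 2$ the standardized group
separation grows from 0 at LS0 to about $3$ SD at W4 — strong signal, by
design, so recovery checks measure the machinery rather than borderline
power.

What the generator does *not* emulate: probe-level artifacts, batch
structure, quantile-normalization residue, heavy-tailed noise, and
correlated gene modules beyond the shared subject intercept. Passing
recovery tests therefore demonstrates correctness of the procedure under
its own assumptions, not field performance on microarray data.

One generator subtlety surfaced by testing: the shared subject intercept
correlates all genes within a subject, which (a) makes per-gene
two-group test counts overdispersed relative to a binomial reference and
(b) gives every random gene subset a common nuisance factor the weak
learners must look past. Both behaviours are real features of repeated
biopsies, and the tests account for them explicitly.

## Problem sizes used in the checks

The packaged checks run the reference scenario at 2000 ensemble
replicates (and 2000 per nested fold), 1000 random-baseline sets, and
500 LASSO-ensemble replicates — sizes chosen so the full suite completes
comfortably on a laptop while leaving every qualitative conclusion
unchanged at the original 10,000-replicate scale, which any run can
request via `n_replicates`.

## Known limitations

* The kept-learner majority vote is an in-sample quantity; report the
  nested LOO accuracy when a predictive claim is intended.
* With two clusters the latent dimension is 1; multi-class outcomes
  (`K > 2`) are supported by the fitting core but the mapping and voting
  layer is binary by design.
* The accuracy cutoff interacts with cohort size: at $n = 30$ the
  smallest accuracy above 0.75 is 23/30, so the filter is effectively
  ">= 76.7%". Tiny cohorts quantize the filter coarsely.
* Wall-clock scales linearly in `n_replicates` and in the number of LOO
  folds; the nested evaluation is the expensive step.
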