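#' LASSO-ensemble gene selector
#'
#' The comparator built from the same random-subspace recipe with an
#' L1-penalized logistic model as the weak learner: per replicate, a
#' random subset of `subset_size` pseudo-gene covariates is fit against
#' the response, and each gene accumulates the absolute value of its
#' estimated coefficient (raw coefficients via `use_abs = FALSE`). The
#' top-`k` genes by accumulated score form the signature.
#'
#' The per-replicate penalty is chosen by cross-validated deviance by
#' default; pass a numeric `lambda` for a fixed penalty.
#'
#' @param pseudo genes x subjects pseudo-gene matrix.
#' @param labels binary response labels.
#' @param subset_size covariates per replicate (default 100).
#' @param n_replicates number of replicates (study scale: 10000).
#' @param k signature size (default 20).
#' @param lambda `NULL` (cross-validated, default) or a fixed penalty.
#' @param nfolds folds for the internal cross-validation (default 5).
#' @param use_abs accumulate `|coef|` (default) rather than signed
#'   coefficients.
#' @param seed master seed; replicate `r` derives its own.
#' @return list with `gene_scores`, `top_k`, `n_replicates`,
#'   `subset_size`, `seed`.
#' @export
lasso_ensemble <- function(pseudo, labels, subset_size = 100,
                           n_replicates = 2000, k = 20, lambda = NULL,
                           nfolds = 5, use_abs = TRUE, seed = 1L) {
  truth <- canon_response(labels)
  if (length(unique(truth)) < 2)
    stop("degenerate labels: both classes must be present")
  p <- nrow(pseudo)
  if (subset_size > p) stop("subset_size exceeds the gene count")
  if (k > p) stop("k exceeds the gene count")
  y <- factor(truth, levels = RESPONSE_LEVELS)
  scores <- setNames(numeric(p), rownames(pseudo))
  for (r in seq_len(n_replicates)) {
    rs <- derive_seed(seed, r)
    idx <- sample_gene_subset(p, subset_size, rs)
    x <- t(pseudo[idx, , drop = FALSE])
    cf <- with_seed(rs, {
      if (is.null(lambda)) {
        # tiny-n folds trigger harmless grouped-CV notes
        cv <- suppressWarnings(
          glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            nfolds = nfolds))
        as.numeric(coef(cv, s = "lambda.min"))[-1]
      } else {
        fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                              lambda = lambda)
        as.numeric(coef(fit))[-1]
      }
    })
    scores[idx] <- scores[idx] + if (use_abs) abs(cf) else cf
  }
  if (all(scores == 0))
    warning("all LASSO coefficients shrank to zero; top-k ordering is ",
            "purely lexicographic")
  list(gene_scores = scores,
       top_k = select_top_k(scores, k),
       n_replicates = n_replicates,
       subset_size = subset_size,
       k = k, use_abs = use_abs,
       seed = as.integer(seed))
}

#' Single-fit latent-variable gene selector
#'
#' The no-ensemble comparator: one joint latent-variable fit on all genes
#' (`lambda = 0`, `K = 2`), genes ranked by their summed absolute
#' loadings over views, plus the fit's own cluster-vs-label accuracy.
#' Equivalent to a one-replicate ensemble whose subset is every gene.
#'
#' @param views a `view_stack`.
#' @param labels binary response labels (default: the stack's own).
#' @param k signature size.
#' @param seed k-means seed.
#' @return list with `top_k`, `gene_scores`, `accuracy`, `fit`.
#' @export
single_icluster_selector <- function(views, labels = NULL, k = 20,
                                     seed = 1L) {
  stopifnot(inherits(views, "view_stack"))
  labels <- canon_response(labels %||% views$labels)
  wl <- run_weak_learner(views, seq_along(views$gene_ids), labels,
                         lambda = 0, K = 2, seed = seed)
  scores <- wl$w_abs
  if (k > length(scores)) stop("k exceeds the gene count")
  list(top_k = select_top_k(scores, k),
       gene_scores = scores,
       accuracy = wl$accuracy,
       predicted = wl$predicted,
       fit = wl$fit,
       seed = as.integer(seed))
}
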