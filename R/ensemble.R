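#' Draw a random gene subset
#'
#' `m` distinct gene indices uniformly without replacement, reproducible
#' from the seed.
#'
#' @param p total number of genes.
#' @param m subset size.
#' @param seed integer seed.
#' @return integer vector of length `m`.
#' @export
sample_gene_subset <- function(p, m, seed = 1L) {
  if (m < 1 || m > p) stop("need 1 <= m <= p (m = ", m, ", p = ", p, ")")
  with_seed(seed, sample.int(p, m))
}

#' Map unsupervised cluster ids to response classes
#'
#' A 2-cluster solution admits two cluster-to-class mappings; both are
#' evaluated against the true labels and the more accurate one is kept
#' (they are complementary, so this is `max(a, 1 - a)`). On an exact tie at
#' accuracy 0.5 the cluster holding more responders maps to "responder";
#' if that also ties, the lower cluster id does.
#'
#' @param cluster_labels integer labels with at most 2 distinct values.
#' @param true_labels binary response labels (see [canon_response()]).
#' @return list with `mapping` (named character, cluster id -> class),
#'   `accuracy`, `predicted` (per-subject class).
#' @export
map_clusters_to_labels <- function(cluster_labels, true_labels) {
  truth <- canon_response(true_labels)
  ids <- sort(unique(as.integer(cluster_labels)))
  if (length(ids) > 2)
    stop("more than 2 distinct cluster labels")
  pred_a <- ifelse(cluster_labels == ids[1], RESPONDER, NONRESPONDER)
  acc_a <- mean(pred_a == truth)
  acc_b <- 1 - acc_a
  pick_a <- if (acc_a > acc_b) TRUE
  else if (acc_b > acc_a) FALSE
  else {
    # both mappings score exactly 0.5
    r_by_cluster <- vapply(ids, function(i)
      sum(truth == RESPONDER & cluster_labels == i), integer(1))
    if (length(ids) == 1) TRUE
    else if (r_by_cluster[1] > r_by_cluster[2]) TRUE
    else if (r_by_cluster[2] > r_by_cluster[1]) FALSE
    else TRUE  # lower id -> responder
  }
  mapping <- if (pick_a)
    setNames(c(RESPONDER, NONRESPONDER)[seq_along(ids)], ids)
  else
    setNames(c(NONRESPONDER, RESPONDER)[seq_along(ids)], ids)
  predicted <- unname(mapping[as.character(cluster_labels)])
  list(mapping = mapping,
       accuracy = if (pick_a) acc_a else acc_b,
       predicted = predicted)
}

#' Run one weak learner
#'
#' Restricts every view to a gene subset, fits the joint latent-variable
#' model (defaults: `lambda = 0`, `K = 2`, i.e. feature selection disabled
#' because the subset is already small), and maps the resulting clusters to
#' the response classes.
#'
#' @param views a `view_stack`.
#' @param gene_indices integer indices into the stack's genes.
#' @param labels binary response labels (default: the stack's own).
#' @param lambda,K,max_iter,tol,seed passed to [fit_icluster()].
#' @return object of class `weak_learner`: `gene_indices`, `fit`,
#'   `label_mapping`, `accuracy`, `predicted`, `w_abs` (per-gene sum of
#'   absolute loadings over views and latent dims).
#' @export
run_weak_learner <- function(views, gene_indices, labels = NULL,
                             lambda = 0, K = 2, max_iter = 200,
                             tol = 1e-6, seed = 1L) {
  stopifnot(inherits(views, "view_stack"))
  labels <- labels %||% views$labels
  sub <- subset_genes(views, gene_indices)
  fit <- fit_icluster(sub, K = K, lambda = lambda, max_iter = max_iter,
                      tol = tol, seed = seed)
  mp <- map_clusters_to_labels(fit$cluster_labels, labels)
  m <- length(gene_indices)
  w_abs <- rowSums(vapply(fit$W, function(w) rowSums(abs(w)),
                          numeric(m)))
  structure(list(gene_indices = gene_indices,
                 fit = fit,
                 label_mapping = mp$mapping,
                 accuracy = mp$accuracy,
                 predicted = setNames(mp$predicted, views$subject_ids),
                 w_abs = setNames(w_abs, sub$gene_ids)),
            class = "weak_learner")
}

#' Aggregate gene scores over kept weak learners
#'
#' A gene's importance is the sum of its absolute loadings (over views and
#' latent dimensions) across every kept learner that sampled it; genes
#' never sampled into a kept learner score 0. Scores are intentionally not
#' normalized by sampling frequency (a frequency-normalized variant is
#' available via `normalize`).
#'
#' @param kept list of `weak_learner` objects.
#' @param gene_ids character vector of all gene ids (defines the score
#'   support).
#' @param normalize divide each gene's score by the number of kept learners
#'   containing it.
#' @param stat `"sum"` (default) or `"max"`: how a single learner's
#'   per-view absolute loadings enter its contribution. The max variant
#'   risks missing genes whose loadings are modest at every time point but
#'   add up, and is provided for sensitivity analysis only.
#' @return named numeric vector over `gene_ids`.
#' @export
aggregate_scores <- function(kept, gene_ids, normalize = FALSE,
                             stat = c("sum", "max")) {
  stat <- match.arg(stat)
  scores <- setNames(numeric(length(gene_ids)), gene_ids)
  times <- setNames(integer(length(gene_ids)), gene_ids)
  for (wl in kept) {
    contrib <- if (stat == "sum") wl$w_abs
    else vapply(seq_along(wl$gene_indices), function(i)
      max(vapply(wl$fit$W, function(w) max(abs(w[i, ])), numeric(1))),
      numeric(1))
    idx <- wl$gene_indices
    scores[idx] <- scores[idx] + contrib
    times[idx] <- times[idx] + 1L
  }
  if (normalize) {
    nz <- times > 0
    scores[nz] <- scores[nz] / times[nz]
  }
  scores
}

#' Majority vote over kept weak learners
#'
#' Each kept learner casts one class vote per subject (its mapped cluster
#' prediction); a strict majority of "responder" votes classifies the
#' subject as a responder, a strict majority of "non-responder" votes as a
#' non-responder. An exact tie goes to the class named by `tie`
#' (default "non-responder", the conservative clinical call).
#'
#' @param kept non-empty list of `weak_learner` objects.
#' @param n_subjects number of subjects.
#' @param tie class awarded on an exact tie.
#' @return list with `voted_labels`, `vote_counts` (subjects x 2 integer
#'   matrix).
#' @export
majority_vote <- function(kept, n_subjects,
                          tie = c("non-responder", "responder")) {
  tie <- match.arg(tie)
  if (!length(kept)) stop("majority_vote needs at least one kept learner")
  preds <- vapply(kept, function(wl) unname(wl$predicted),
                  character(n_subjects))
  preds <- matrix(preds, nrow = n_subjects)
  n_resp <- rowSums(preds == RESPONDER)
  n_non <- rowSums(preds == NONRESPONDER)
  voted <- ifelse(n_resp > n_non, RESPONDER,
           ifelse(n_non > n_resp, NONRESPONDER, tie))
  counts <- cbind(n_non, n_resp)
  colnames(counts) <- c(NONRESPONDER, RESPONDER)
  subj <- names(kept[[1]]$predicted)
  if (!is.null(subj)) {
    names(voted) <- subj
    rownames(counts) <- subj
  }
  list(voted_labels = voted, vote_counts = counts)
}

#' Select the top-k genes by score
#'
#' Genes sorted by score descending; ties broken by lexicographic gene id.
#'
#' @param scores named numeric vector (gene -> score).
#' @param k number of genes to return.
#' @return character vector of `k` gene ids, best first.
#' @export
select_top_k <- function(scores, k) {
  if (k > length(scores))
    stop("k (", k, ") exceeds the number of scored genes (",
         length(scores), ")")
  ord <- order(-scores, names(scores), method = "radix")
  names(scores)[ord][seq_len(k)]
}

#' Fit the random-subspace ensemble of latent-variable clusterings
#'
#' The core procedure: draw `n_replicates` random gene subsets of size
#' `subset_size`, fit the joint latent-variable model (`lambda = 0`,
#' `K = 2`) on each, map clusters to the response classes, and keep the
#' weak learners whose label agreement is strictly greater than
#' `accuracy_cutoff`. Kept learners are aggregated two ways: per-gene
#' importance scores (summed absolute loadings, [aggregate_scores()]) and
#' per-subject majority-vote class predictions ([majority_vote()]).
#'
#' Each replicate runs on its own derived seed, so any replicate is
#' reproducible in isolation; the whole result is bit-identical under an
#' identical seed and configuration.
#'
#' @param views a `view_stack` over the analysis time points.
#' @param labels binary response labels (default: the stack's own).
#' @param n_replicates number of weak learners (study scale: 10000;
#'   default here 2000 keeps desk-scale runs fast).
#' @param subset_size genes per weak learner (default 20).
#' @param accuracy_cutoff keep learners with accuracy strictly above this
#'   (default 0.75).
#' @param seed master seed.
#' @param vote `"kept"` (default) tallies votes over kept learners only;
#'   `"all"` over every replicate.
#' @param tie vote tie rule, see [majority_vote()].
#' @param normalize_scores,score_stat passed to [aggregate_scores()].
#' @param K,lambda,max_iter,tol weak-learner model settings.
#' @return object of class `icluster_ensemble`: `gene_scores`,
#'   `voted_labels`, `vote_counts`, `vote_accuracy`, `kept_count`,
#'   `kept` (reduced learner records), `accuracies` (all replicates),
#'   `times_sampled`, `times_kept`, configuration echo and `seed`.
#' @export
run_ensemble <- function(views, labels = NULL, n_replicates = 2000,
                         subset_size = 20, accuracy_cutoff = 0.75,
                         seed = 1L, vote = c("kept", "all"),
                         tie = c("non-responder", "responder"),
                         normalize_scores = FALSE,
                         score_stat = c("sum", "max"),
                         K = 2, lambda = 0, max_iter = 200, tol = 1e-6) {
  vote <- match.arg(vote)
  tie <- match.arg(tie)
  score_stat <- match.arg(score_stat)
  stopifnot(inherits(views, "view_stack"))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (accuracy_cutoff < 0 || accuracy_cutoff >= 1)
    stop("accuracy_cutoff must be in [0, 1)")
  labels <- labels %||% views$labels
  truth <- canon_response(labels)
  p <- length(views$gene_ids)
  n <- length(views$subject_ids)
  if (subset_size > p) stop("subset_size exceeds the gene count")

  kept <- vector("list", n_replicates)
  n_kept <- 0L
  accuracies <- numeric(n_replicates)
  all_preds <- if (vote == "all") matrix(NA_character_, n, n_replicates)
  times_sampled <- setNames(integer(p), views$gene_ids)
  times_kept <- setNames(integer(p), views$gene_ids)

  for (r in seq_len(n_replicates)) {
    rs <- derive_seed(seed, r)
    idx <- sample_gene_subset(p, subset_size, rs)
    # slow EM convergence on a noise-only subset is routine here; the
    # per-fit non-convergence warning stays available on direct fits
    wl <- suppressWarnings(
      run_weak_learner(views, idx, truth, lambda = lambda, K = K,
                       max_iter = max_iter, tol = tol, seed = rs))
    accuracies[r] <- wl$accuracy
    times_sampled[idx] <- times_sampled[idx] + 1L
    if (vote == "all") all_preds[, r] <- unname(wl$predicted)
    if (wl$accuracy > accuracy_cutoff) {
      n_kept <- n_kept + 1L
      # full fits are retained for kept learners only (typically few)
      kept[[n_kept]] <- structure(
        list(gene_indices = idx, fit = wl$fit, w_abs = wl$w_abs,
             accuracy = wl$accuracy, predicted = wl$predicted,
             label_mapping = wl$label_mapping, replicate = r),
        class = "weak_learner")
      times_kept[idx] <- times_kept[idx] + 1L
    }
  }
  if (n_kept == 0L)
    stop("no weak learner exceeded accuracy_cutoff = ", accuracy_cutoff,
         "; lower the cutoff or check the labels")
  kept <- kept[seq_len(n_kept)]

  gene_scores <- aggregate_scores(kept, views$gene_ids,
                                  normalize = normalize_scores,
                                  stat = score_stat)
  mv <- if (vote == "kept") majority_vote(kept, n, tie = tie)
  else {
    n_resp <- rowSums(all_preds == RESPONDER)
    n_non <- n_replicates - n_resp
    voted <- ifelse(n_resp > n_non, RESPONDER,
             ifelse(n_non > n_resp, NONRESPONDER, tie))
    counts <- cbind(n_non, n_resp)
    colnames(counts) <- c(NONRESPONDER, RESPONDER)
    names(voted) <- rownames(counts) <- views$subject_ids
    list(voted_labels = voted, vote_counts = counts)
  }
  vote_accuracy <- mean(mv$voted_labels == truth)

  structure(list(gene_scores = gene_scores,
                 voted_labels = mv$voted_labels,
                 vote_counts = mv$vote_counts,
                 vote_accuracy = vote_accuracy,
                 kept_count = n_kept,
                 kept = kept,
                 accuracies = accuracies,
                 times_sampled = times_sampled,
                 times_kept = times_kept,
                 truth = setNames(truth, views$subject_ids),
                 n_replicates = n_replicates,
                 subset_size = subset_size,
                 accuracy_cutoff = accuracy_cutoff,
                 vote = vote, tie = tie,
                 normalize_scores = normalize_scores,
                 score_stat = score_stat,
                 K = K, lambda = lambda,
                 seed = as.integer(seed)),
            class = "icluster_ensemble")
}

#' @exportS3Method base::print
print.icluster_ensemble <- function(x, ...) {
  cat("Random-subspace latent-variable clustering ensemble\n")
  cat("  replicates:", x$n_replicates, "; subset size:", x$subset_size,
      "; accuracy cutoff >", x$accuracy_cutoff, "\n")
  cat("  kept learners:", x$kept_count, "\n")
  cat("  majority-vote accuracy:", sprintf("%.4f", x$vote_accuracy), "\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.icluster_ensemble <- function(object, k = 10, ...) {
  print(object)
  k <- min(k, length(object$gene_scores))
  top <- select_top_k(object$gene_scores, k)
  cat("  top", k, "genes by summed |loading| score:\n")
  df <- data.frame(gene = top,
                   score = unname(object$gene_scores[top]),
                   times_sampled = unname(object$times_sampled[top]),
                   times_kept = unname(object$times_kept[top]))
  print(df, row.names = FALSE)
  invisible(object)
}

#' @export
coef.icluster_ensemble <- function(object, ...) object$gene_scores

#' @export
predict.icluster_ensemble <- function(object, ...) object$voted_labels

#' @export
plot.icluster_ensemble <- function(x, k = 20, ...) {
  top <- select_top_k(x$gene_scores, min(k, length(x$gene_scores)))
  barplot(rev(x$gene_scores[top]), horiz = TRUE, las = 1,
          xlab = "summed |loading| score", ...)
  invisible(x)
}
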