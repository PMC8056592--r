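#' Collapse a longitudinal set to pseudo-gene covariates
#'
#' A pseudo-gene is a subject-level covariate: a gene's expression averaged
#' over the requested (early lesional) time points, using whatever values
#' are available. Subjects missing all requested values for some gene are
#' dropped with a warning.
#'
#' @param data a `longexpr_set`.
#' @param use_timepoints non-empty character vector of time-point labels.
#' @return genes x subjects numeric matrix.
#' @export
make_pseudo_genes <- function(data, use_timepoints) {
  stopifnot(inherits(data, "longexpr_set"))
  if (!length(use_timepoints)) stop("use_timepoints must be non-empty")
  unknown <- setdiff(use_timepoints, data$timepoint_labels)
  if (length(unknown))
    stop("unknown timepoint label(s): ", paste(unknown, collapse = ", "))
  sub <- data$values[, , use_timepoints, drop = FALSE]
  out <- apply(sub, c(1, 2), function(v) mean(v, na.rm = TRUE))
  out[is.nan(out)] <- NA_real_
  drop_subj <- colSums(is.na(out)) > 0
  if (any(drop_subj)) {
    warning("dropping ", sum(drop_subj),
            " subject(s) with no available value for some gene")
    out <- out[, !drop_subj, drop = FALSE]
  }
  out
}

# z-score feature rows with train-fold parameters (no leakage); zero-variance
# rows are centered only
std_train_apply <- function(train, test = NULL) {
  ctr <- rowMeans(train)
  scl <- apply(train, 1, sd)
  scl[scl < 1e-12] <- 1
  list(train = (train - ctr) / scl,
       test = if (!is.null(test)) (test - ctr) / scl)
}

fit_svm_fold <- function(xtr, ytr, svm_params) {
  e1071::svm(x = xtr, y = factor(ytr, levels = RESPONSE_LEVELS),
             type = "C-classification",
             kernel = svm_params$kernel %||% "radial",
             cost = svm_params$cost %||% 1,
             gamma = svm_params$gamma %||% (1 / ncol(xtr)),
             scale = FALSE)
}

new_evaluation_result <- function(pred, truth, svm_params, seed = NULL,
                                  per_fold_selected = NULL) {
  pf <- factor(pred, levels = RESPONSE_LEVELS)
  tf <- factor(truth, levels = RESPONSE_LEVELS)
  confusion <- table(predicted = pf, truth = tf)
  structure(list(fold_predictions = pred,
                 truth = truth,
                 confusion = confusion,
                 accuracy = mean(pred == truth),
                 per_fold_selected = per_fold_selected,
                 svm_params = svm_params,
                 seed = seed),
            class = "evaluation_result")
}

#' @exportS3Method base::print
print.evaluation_result <- function(x, ...) {
  cat("Leave-one-out SVM evaluation\n")
  cat("  accuracy:", sprintf("%.4f", x$accuracy),
      sprintf("(%d/%d)", sum(x$fold_predictions == x$truth),
              length(x$truth)), "\n")
  print(x$confusion)
  invisible(x)
}

#' Leave-one-out SVM accuracy on fixed features
#'
#' For every subject in turn: standardize features with the training
#' subjects' means and standard deviations, train an SVM on the training
#' subjects, and predict the held-out subject (transformed with the
#' training parameters — no leakage). Defaults mirror the usual radial
#' kernel with cost 1 and kernel width `1/ngenes`.
#'
#' @param features genes x subjects numeric matrix (e.g. pseudo-genes).
#' @param labels binary response labels, one per subject.
#' @param gene_subset optional gene ids or indices restricting the
#'   features.
#' @param svm_params list: `kernel` ("radial"/"linear"), `cost`, `gamma`.
#' @return an `evaluation_result`: per-fold predictions, confusion matrix,
#'   accuracy.
#' @export
loo_svm_accuracy <- function(features, labels, gene_subset = NULL,
                             svm_params = list()) {
  truth <- canon_response(labels)
  if (min(table(factor(truth, RESPONSE_LEVELS))) < 2)
    stop("need at least 2 subjects per class for leave-one-out training")
  if (!is.null(gene_subset)) {
    if (!length(gene_subset)) stop("gene_subset must be non-empty")
    features <- features[gene_subset, , drop = FALSE]
  }
  n <- ncol(features)
  pred <- character(n)
  for (i in seq_len(n)) {
    ytr <- truth[-i]
    if (length(unique(ytr)) < 2)
      stop("training fold ", i, " contains a single class; need larger n")
    sd_ <- std_train_apply(features[, -i, drop = FALSE],
                           features[, i, drop = FALSE])
    fit <- fit_svm_fold(t(sd_$train), ytr, svm_params)
    pred[i] <- as.character(predict(fit, t(sd_$test)))
  }
  names(pred) <- colnames(features)
  new_evaluation_result(pred, setNames(truth, colnames(features)),
                        svm_params)
}

#' Nested leave-one-out evaluation of the ensemble signature
#'
#' The honest estimate of the signature's predictive accuracy: for each
#' held-out subject, views are rebuilt on the remaining subjects, the whole
#' ensemble is retrained there, the top-`k` genes are selected, an SVM is
#' trained on the training subjects' pseudo-genes restricted to those
#' genes, and the held-out subject is predicted. Feature selection never
#' sees the held-out subject.
#'
#' @param data a `longexpr_set`.
#' @param labels binary response labels (default: the set's metadata).
#' @param view_timepoints time points used as ensemble views.
#' @param pseudo_timepoints time points averaged into the SVM covariates
#'   (default: same as `view_timepoints`).
#' @param k signature size (default 20).
#' @param ensemble_config list of [run_ensemble()] arguments
#'   (`n_replicates`, `subset_size`, `accuracy_cutoff`, ...).
#' @param svm_params see [loo_svm_accuracy()].
#' @param seed master seed; each fold derives its own.
#' @param folds optional subject ids to hold out (default: all), useful
#'   for inspecting single folds.
#' @return an `evaluation_result` with `per_fold_selected` gene lists.
#' @export
nested_loo_ensemble <- function(data, labels = NULL,
                                view_timepoints,
                                pseudo_timepoints = view_timepoints,
                                k = 20,
                                ensemble_config = list(),
                                svm_params = list(),
                                seed = 1L, folds = NULL) {
  stopifnot(inherits(data, "longexpr_set"))
  meta <- data$sample_meta
  truth <- canon_response(labels %||% setNames(meta$response, meta$subject))
  names(truth) <- names(labels) %||% meta$subject
  subjects <- data$subject_ids
  folds <- folds %||% subjects
  pred <- setNames(character(length(folds)), folds)
  selected <- setNames(vector("list", length(folds)), folds)

  pseudo_all <- make_pseudo_genes(data, pseudo_timepoints)

  for (f in seq_along(folds)) {
    held <- folds[f]
    train_ids <- setdiff(subjects, held)
    tr <- subset_subjects(data, train_ids)
    views <- build_views(tr, view_timepoints, standardize = TRUE)
    fold_seed <- derive_seed(seed, match(held, subjects))
    ens <- tryCatch(
      do.call(run_ensemble,
              c(list(views = views, labels = truth[train_ids],
                     seed = fold_seed), ensemble_config)),
      error = function(e)
        stop("ensemble failed in fold for subject '", held, "': ",
             conditionMessage(e)))
    top <- select_top_k(ens$gene_scores, k)
    selected[[f]] <- top

    xtr <- pseudo_all[top, train_ids, drop = FALSE]
    xte <- pseudo_all[top, held, drop = FALSE]
    sd_ <- std_train_apply(xtr, xte)
    svfit <- fit_svm_fold(t(sd_$train), truth[train_ids], svm_params)
    pred[f] <- as.character(predict(svfit, t(sd_$test)))
  }
  new_evaluation_result(pred, truth[folds], svm_params, seed = seed,
                        per_fold_selected = selected)
}

# drop subjects from a longitudinal set (keeps gene/timepoint structure)
subset_subjects <- function(data, subject_ids) {
  stopifnot(inherits(data, "longexpr_set"))
  v <- data$values[, subject_ids, , drop = FALSE]
  m <- data$sample_meta[data$sample_meta$subject %in% subject_ids, ,
                        drop = FALSE]
  longexpr_set(v, m)
}

#' Random gene-set baseline accuracy
#'
#' How well does a *random* k-gene signature predict? Draws `n_sets`
#' uniform k-gene subsets, evaluates each by [loo_svm_accuracy()] on the
#' pseudo-gene covariates, and reports the mean and the per-set
#' accuracies.
#'
#' @param data a `longexpr_set`.
#' @param labels binary response labels (default: metadata).
#' @param k genes per random set (default 20).
#' @param n_sets number of random sets (study scale: 1000).
#' @param use_timepoints time points averaged into pseudo-genes.
#' @param svm_params see [loo_svm_accuracy()].
#' @param seed master seed; set `j` uses a derived seed.
#' @return list with `mean_accuracy`, `accuracies`, `k`, `n_sets`, `seed`.
#' @export
random_gene_baseline <- function(data, labels = NULL, k = 20,
                                 n_sets = 1000, use_timepoints,
                                 svm_params = list(), seed = 1L) {
  stopifnot(inherits(data, "longexpr_set"))
  meta <- data$sample_meta
  truth <- canon_response(labels %||% setNames(meta$response, meta$subject))
  pseudo <- make_pseudo_genes(data, use_timepoints)
  p <- nrow(pseudo)
  if (k > p) stop("k (", k, ") exceeds the gene count (", p, ")")
  acc <- numeric(n_sets)
  for (j in seq_len(n_sets)) {
    idx <- sample_gene_subset(p, k, derive_seed(seed, j))
    acc[j] <- loo_svm_accuracy(pseudo, truth, gene_subset = idx,
                               svm_params = svm_params)$accuracy
  }
  list(mean_accuracy = mean(acc), accuracies = acc, k = k,
       n_sets = n_sets, seed = as.integer(seed))
}

#' Group mean trajectories over time
#'
#' Per gene and response group, the mean expression at every time point
#' (the non-lesional reference included), with group size and standard
#' error — the tabular form of the connected-means trajectory display.
#'
#' @param data a `longexpr_set`.
#' @param gene_subset gene ids to summarize (default: all).
#' @param labels binary response labels (default: metadata).
#' @param reference_timepoint label of the non-lesional reference
#'   (default `"NL"`); per-gene reference means (all subjects pooled) are
#'   attached as `attr(, "reference_means")`.
#' @return a data.frame of class `trajectory_summary` with columns
#'   `gene`, `group`, `timepoint`, `mean`, `n`, `se`.
#' @export
group_mean_trajectories <- function(data, gene_subset = NULL,
                                    labels = NULL,
                                    reference_timepoint = "NL") {
  stopifnot(inherits(data, "longexpr_set"))
  meta <- data$sample_meta
  truth <- canon_response(labels %||% setNames(meta$response, meta$subject))
  genes <- gene_subset %||% data$gene_ids
  missing_g <- setdiff(genes, data$gene_ids)
  if (length(missing_g))
    stop("unknown gene id(s): ", paste(missing_g, collapse = ", "))
  groups <- intersect(RESPONSE_LEVELS, unique(truth))
  if (!length(groups)) stop("no non-empty response group")

  rows <- list()
  for (g in genes) for (grp in groups) {
    subj <- data$subject_ids[truth == grp]
    for (tp in data$timepoint_labels) {
      v <- data$values[g, subj, tp]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, group = grp, timepoint = tp,
        mean = mean(v), n = length(v),
        se = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (reference_timepoint %in% data$timepoint_labels) {
    ref <- vapply(genes, function(g) {
      v <- data$values[g, , reference_timepoint]
      mean(v[!is.na(v)])
    }, numeric(1))
    attr(out, "reference_means") <- ref
    attr(out, "reference_timepoint") <- reference_timepoint
  }
  class(out) <- c("trajectory_summary", "data.frame")
  out
}

#' @export
plot.trajectory_summary <- function(x, gene = NULL, ...) {
  gene <- gene %||% x$gene[1]
  d <- x[x$gene == gene, , drop = FALSE]
  tps <- unique(d$timepoint)
  xi <- seq_along(tps)
  plot(range(xi), range(d$mean), type = "n", xaxt = "n",
       xlab = "timepoint", ylab = "mean expression", main = gene, ...)
  graphics::axis(1, at = xi, labels = tps)
  cols <- c(`non-responder` = 2, responder = 4)
  for (grp in unique(d$group)) {
    dg <- d[d$group == grp, ]
    lines(match(dg$timepoint, tps), dg$mean, col = cols[[grp]], type = "b",
          pch = 19)
  }
  ref <- attr(x, "reference_means")
  if (!is.null(ref)) graphics::abline(h = ref[[gene]], lty = 3)
  legend("topright", legend = unique(d$group),
         col = cols[unique(d$group)], lty = 1, bty = "n")
  invisible(x)
}

#' Gap-closure ratio toward the non-lesional reference
#'
#' How much of the lesional-vs-non-lesional expression gap has closed
#' between two time points:
#' `|mean(to) - NL| / |mean(from) - NL|` for one gene in one response
#' group. A ratio below 1 means the expression moved back toward its
#' non-lesional level; 0 is full recovery. When the starting gap is below
#' `1e-8` the ratio is undefined and `NA` is returned with attribute
#' `undefined = TRUE`.
#'
#' @param traj a `trajectory_summary` carrying reference means.
#' @param gene gene id.
#' @param group response group.
#' @param from_tp,to_tp time-point labels.
#' @return non-negative ratio (or flagged `NA`).
#' @export
gap_closure <- function(traj, gene, group, from_tp, to_tp) {
  stopifnot(inherits(traj, "trajectory_summary"))
  ref <- attr(traj, "reference_means")
  if (is.null(ref)) stop("trajectory summary carries no reference means")
  pick <- function(tp) {
    r <- traj[traj$gene == gene & traj$group == group &
                traj$timepoint == tp, ]
    if (!nrow(r)) stop("no trajectory row for gene '", gene, "', group '",
                       group, "', timepoint '", tp, "'")
    r$mean
  }
  if (!gene %in% names(ref)) stop("unknown gene: ", gene)
  num <- abs(pick(to_tp) - ref[[gene]])
  den <- abs(pick(from_tp) - ref[[gene]])
  if (den < 1e-8)
    return(structure(NA_real_, undefined = TRUE))
  num / den
}
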