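#' Soft-threshold operator
#'
#' Elementwise shrinkage `sign(w) * max(|w| - lambda, 0)`; applied to the
#' loading matrix after every M-step to zero out non-informative genes.
#'
#' @param w numeric scalar, vector or matrix.
#' @param lambda non-negative shrinkage amount.
#' @return object shaped like `w`.
#' @export
#' @examples
#' soft_threshold(2, 0.5)   # 1.5
#' soft_threshold(-0.3, 0.5) # 0
soft_threshold <- function(w, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) || lambda < 0)
    stop("lambda must be a single non-negative number")
  sign(w) * pmax(abs(w) - lambda, 0)
}

#' E-step of the latent-variable model
#'
#' Posterior moments of `Z ~ N(0, I_q)` given `X = W Z + eps`,
#' `eps ~ N(0, diag(psi))`:
#' `VarZ = (I_q + W' Psi^-1 W)^-1`, `EZ = VarZ W' Psi^-1 X`.
#' The posterior covariance is shared across subjects.
#'
#' @param X stacked data, `p_total x n`.
#' @param W loadings, `p_total x q`.
#' @param psi residual variances, length `p_total`, all `> 0`.
#' @return list with `EZ` (`q x n`) and `VarZ` (`q x q`).
#' @export
e_step <- function(X, W, psi) {
  X <- as.matrix(X); W <- as.matrix(W)
  if (!all(is.finite(X)) || !all(is.finite(W)) || !all(is.finite(psi)))
    stop("non-finite inputs to e_step")
  stopifnot(nrow(X) == nrow(W), length(psi) == nrow(X), all(psi > 0))
  q <- ncol(W)
  Wp <- W / psi
  M <- diag(q) + crossprod(W, Wp)
  VarZ <- chol2inv(chol(M))
  EZ <- VarZ %*% crossprod(Wp, X)
  list(EZ = EZ, VarZ = VarZ)
}

#' M-step of the latent-variable model
#'
#' `W_new = (X EZ')(n VarZ + EZ EZ')^-1`; `psi_new` is the per-feature
#' residual second moment `diag(S - W_new (EZ X')/n)`, clamped at the
#' variance floor `1e-4`.
#'
#' @param X stacked data, `p_total x n`.
#' @param EZ posterior means, `q x n`.
#' @param VarZ posterior covariance, `q x q`.
#' @return list with `W` and `psi`.
#' @export
m_step <- function(X, EZ, VarZ) {
  X <- as.matrix(X); EZ <- as.matrix(EZ); VarZ <- as.matrix(VarZ)
  n <- ncol(X)
  A <- n * VarZ + tcrossprod(EZ)
  XEZt <- tcrossprod(X, EZ)
  W_new <- t(solve(A, t(XEZt)))
  psi_new <- rowMeans(X^2) - rowSums(W_new * XEZt) / n
  psi_new <- pmax(psi_new, PSI_FLOOR)
  list(W = W_new, psi = psi_new)
}

# observed-data log-likelihood of Sigma = WW' + diag(psi) via Woodbury
factor_loglik <- function(X, W, psi) {
  n <- ncol(X); p <- nrow(X); q <- ncol(W)
  Wp <- W / psi
  M <- diag(q) + crossprod(W, Wp)
  ch <- chol(M)
  U <- crossprod(Wp, X)
  quad <- sum(X^2 / psi) - sum(U * (chol2inv(ch) %*% U))
  logdet <- sum(log(psi)) + 2 * sum(log(diag(ch)))
  -0.5 * (n * p * log(2 * pi) + n * logdet + quad)
}

#' Assign cluster labels from posterior latent scores
#'
#' k-means on the `n` subject points in latent space, 10 restarts from the
#' seeded RNG, best within-cluster sum of squares kept (ties broken by
#' first occurrence). When fewer than `K` distinct points exist the
#' assignment is degenerate: identical points share a label and the result
#' carries `attr(, "degenerate") = TRUE`.
#'
#' @param EZ posterior latent means, `q x n`.
#' @param K number of clusters.
#' @param seed integer seed for the restarts.
#' @return integer labels of length `n` with attribute `degenerate`.
#' @export
assign_clusters <- function(EZ, K, seed = 1L) {
  pts <- t(as.matrix(EZ))
  n <- nrow(pts)
  if (n < K) stop("need at least K subjects to form K clusters")
  distinct <- unique(pts)
  if (nrow(distinct) < K) {
    key <- apply(pts, 1, paste, collapse = "\r")
    labs <- as.integer(factor(key, levels = unique(key)))
    return(structure(labs, degenerate = TRUE))
  }
  km <- with_seed(seed, {
    tryCatch(
      suppressWarnings(kmeans(pts, centers = K, nstart = 10, iter.max = 50)),
      error = function(e)
        # duplicated sampled centers: start from K distinct points instead
        suppressWarnings(kmeans(pts, centers = distinct[seq_len(K), , drop = FALSE],
                                iter.max = 50)))
  })
  structure(as.integer(km$cluster), degenerate = FALSE,
            wcss = km$tot.withinss)
}

#' Fit the joint latent-variable clustering model
#'
#' All views (time points) of a subject regress on one shared
#' `q = K - 1` dimensional latent score: `X_t = W_t Z + eps_t` with
#' diagonal residual variance. Estimation is EM on the row-stacked views;
#' after each M-step the loadings are soft-thresholded by `lambda`
#' (feature selection; `lambda = 0` disables it). Cluster labels come from
#' k-means on the posterior latent means.
#'
#' With `lambda = 0` the convergence trace is the observed-data
#' log-likelihood (non-decreasing, EM); with `lambda > 0` the likelihood
#' argument no longer applies, so the trace records `max |delta W|` and
#' convergence is declared on parameter change.
#'
#' @param views a `view_stack` from [build_views()], or a plain list of
#'   aligned genes x subjects matrices.
#' @param K number of clusters (`>= 2`); the latent dimension is `K - 1`.
#' @param lambda non-negative soft-threshold amount.
#' @param max_iter maximum EM iterations (default 200).
#' @param tol convergence tolerance (default 1e-6): relative log-likelihood
#'   change when `lambda = 0`, max absolute loading change otherwise.
#' @param seed seed for the k-means restarts.
#' @return an object of class `icluster_fit`: per-view loadings `W`,
#'   residual variances `psi`, posterior `EZ`/`VarZ`, `cluster_labels`,
#'   `loglik_trace`, `converged`, `n_iter`, `lambda`, `K`, `seed`.
#' @export
fit_icluster <- function(views, K = 2, lambda = 0, max_iter = 200,
                         tol = 1e-6, seed = 1L) {
  if (!is.numeric(K) || K < 2) stop("K must be >= 2")
  if (lambda < 0) stop("lambda must be non-negative")
  X <- stack_views(views)
  if (!all(is.finite(X))) stop("views must be finite")
  n <- ncol(X); p <- nrow(X); q <- as.integer(K - 1)
  if (n < K) stop("fewer subjects (", n, ") than clusters (", K, ")")

  view_rows <- if (inherits(views, "view_stack"))
    vapply(views$views, nrow, integer(1)) else vapply(views, nrow, integer(1))

  # deterministic init: scaled top-q singular vectors, sign-fixed
  sv <- svd(X, nu = q, nv = 0)
  W0 <- sv$u[, seq_len(q), drop = FALSE] %*%
    diag(sv$d[seq_len(q)] / sqrt(n), q, q)
  for (j in seq_len(q)) {
    piv <- which.max(abs(W0[, j]))
    if (W0[piv, j] < 0) W0[, j] <- -W0[, j]
  }
  psi0 <- rep(1, p)

  res <- em_loop_cpp(X, W0, psi0, lambda, as.integer(max_iter), tol,
                     PSI_FLOOR)
  if (!res$converged)
    warning("EM did not converge in ", max_iter, " iterations")

  labels <- assign_clusters(res$EZ, K, seed)

  idx <- rep(seq_along(view_rows), view_rows)
  W_views <- lapply(seq_along(view_rows), function(t)
    res$W[idx == t, , drop = FALSE])

  subj <- if (inherits(views, "view_stack")) views$subject_ids else colnames(X)
  gene <- if (inherits(views, "view_stack")) views$gene_ids else NULL

  structure(list(W = W_views,
                 W_stacked = res$W,
                 psi = as.numeric(res$psi),
                 EZ = res$EZ,
                 VarZ = res$VarZ,
                 cluster_labels = setNames(as.integer(labels),
                                           subj %||% seq_len(n)),
                 degenerate = isTRUE(attr(labels, "degenerate")),
                 loglik_trace = as.numeric(res$trace),
                 converged = res$converged,
                 n_iter = res$n_iter,
                 lambda = lambda,
                 K = as.integer(K),
                 q = q,
                 seed = as.integer(seed),
                 gene_ids = gene,
                 view_rows = view_rows),
            class = "icluster_fit")
}

#' @exportS3Method base::print
print.icluster_fit <- function(x, ...) {
  cat("Joint latent-variable clustering fit\n")
  cat("  K =", x$K, " (latent dim q =", x$q, "),  lambda =", x$lambda, "\n")
  cat("  views:", length(x$W), "; features per view:",
      paste(x$view_rows, collapse = ", "), "\n")
  cat("  EM:", x$n_iter, "iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("  cluster sizes:",
      paste(table(x$cluster_labels), collapse = " / "), "\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.icluster_fit <- function(object, ...) {
  zeros <- sum(object$W_stacked == 0)
  cat("Call: joint latent-variable model over", length(object$W), "views\n")
  print(object)
  cat("  exact-zero loadings:", zeros, "of", length(object$W_stacked), "\n")
  if (object$lambda == 0)
    cat("  final log-likelihood:",
        format(tail_val(object$loglik_trace)), "\n")
  invisible(object)
}

tail_val <- function(x) if (length(x)) x[length(x)] else NA_real_

#' @export
coef.icluster_fit <- function(object, ...) object$W

#' @export
logLik.icluster_fit <- function(object, ...) {
  if (object$lambda > 0)
    stop("log-likelihood trace is not recorded when lambda > 0")
  structure(tail_val(object$loglik_trace), class = "logLik",
            df = length(object$W_stacked) + length(object$psi))
}

#' @export
plot.icluster_fit <- function(x, ...) {
  z <- t(x$EZ)
  if (ncol(z) == 1)
    plot(z[, 1], col = x$cluster_labels, pch = 19,
         xlab = "subject", ylab = "latent score", ...)
  else
    plot(z[, 1], z[, 2], col = x$cluster_labels, pch = 19,
         xlab = "latent dim 1", ylab = "latent dim 2", ...)
  invisible(x)
}
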