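# fixtures are generated in code; nothing is read from disk

# small longitudinal set with hand-picked values
tiny_set <- function(n_genes = 3, n_subjects = 4, timepoints = c("NL", "LS0"),
                     values = NULL, responses = NULL) {
  genes <- paste0("g", seq_len(n_genes))
  subjects <- paste0("s", seq_len(n_subjects))
  v <- array(values %||% seq_len(n_genes * n_subjects * length(timepoints)),
             dim = c(n_genes, n_subjects, length(timepoints)),
             dimnames = list(genes, subjects, timepoints))
  meta <- data.frame(
    subject = subjects,
    response = responses %||% rep(c("responder", "non-responder"),
                                  length.out = n_subjects),
    stringsAsFactors = FALSE)
  longexpr_set(v, meta)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# aligned views carrying a planted two-group signal along a random loading
planted_views <- function(n = 30, p = 25, T_views = 4, sep = 4, noise = 1,
                          seed = 1) {
  set.seed(seed)
  grp <- rep(c(-1, 1), length.out = n)
  views <- lapply(seq_len(T_views), function(t) {
    w <- rnorm(p)
    w <- w / sqrt(sum(w^2))
    m <- w %*% t(grp * sep / 2) + matrix(rnorm(p * n, 0, noise), p, n)
    dimnames(m) <- list(sprintf("g%03d", seq_len(p)), paste0("s", seq_len(n)))
    m
  })
  labels <- setNames(ifelse(grp > 0, "responder", "non-responder"),
                     paste0("s", seq_len(n)))
  structure(list(views = views,
                 view_labels = paste0("V", seq_len(T_views)),
                 gene_ids = sprintf("g%03d", seq_len(p)),
                 subject_ids = paste0("s", seq_len(n)),
                 labels = labels,
                 standardized = FALSE,
                 standardization = vector("list", T_views),
                 zero_variance = replicate(T_views, rep(FALSE, p),
                                           simplify = FALSE)),
            class = "view_stack")
}

# mirror of the package's substream derivation, for reduction identities
derive_seed_oracle <- function(seed, r) longicluster:::derive_seed(seed, r)

# adjusted Rand index between two labelings (mclust's implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# central 95% binomial band for an accuracy out of n trials
chance_band <- function(n, prob = 0.5) {
  c(qbinom(0.025, n, prob), qbinom(0.975, n, prob)) / n
}
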