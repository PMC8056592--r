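#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state, so
#' seeded internals never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible substream seed
#'
#' Counter-based derivation: stage `r` of a run with master seed `seed` gets
#' a fixed seed of its own, so any single replicate or fold can be re-run in
#' isolation. Kept inside 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param r counter (replicate, fold, ...).
#' @return integer seed.
#' @export
derive_seed <- function(seed, r) {
  s <- (abs(as.double(seed)) %% 2147483647) * 7919 + as.double(r) * 104729
  as.integer(s %% 2147483629) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonicalize binary response labels
#'
#' Accepts "responder"/"non-responder" (case-insensitive) and the common
#' shorthands "R"/"NR", returning a character vector over the canonical
#' levels.
#'
#' @param x vector of labels.
#' @return character vector with values in `c("non-responder", "responder")`.
#' @keywords internal
canon_response <- function(x) {
  x <- tolower(as.character(x))
  out <- ifelse(x %in% c("responder", "r", "res"), RESPONDER,
         ifelse(x %in% c("non-responder", "nonresponder", "nr", "non_responder"),
                NONRESPONDER, NA_character_))
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unrecognized response label(s): ", paste(bad, collapse = ", "),
         "; expected 'responder'/'non-responder' (or R/NR)")
  }
  out
}

# sort structural keys recursively so serialized reports are byte-stable;
# fields whose element order is meaningful (ranked scores, per-subject
# records) are passed through untouched
sort_keys <- function(x, preserve = c("gene_scores", "times_sampled",
                                      "times_kept", "voted_labels",
                                      "vote_counts", "fold_predictions",
                                      "truth", "confusion", "top_k",
                                      "accuracies", "group", "mu", "delta",
                                      "informative_gene_ids")) {
  if (!is.list(x)) return(x)
  if (!is.null(names(x)) && length(x))
    x <- x[order(names(x), method = "radix")]
  nm <- names(x) %||% rep("", length(x))
  for (i in seq_along(x))
    if (!nm[i] %in% preserve) x[[i]] <- sort_keys(x[[i]], preserve)
  x
}
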