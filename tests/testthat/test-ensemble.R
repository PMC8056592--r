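test_that("gene subsets are uniform, distinct and reproducible", {
  expect_setequal(sample_gene_subset(20, 20, seed = 1), 1:20)
  expect_identical(sample_gene_subset(662, 20, seed = 99),
                   sample_gene_subset(662, 20, seed = 99))
  expect_error(sample_gene_subset(10, 11), "1 <= m <= p")

  # inclusion frequency over many draws stays within 4 sigma of m/p
  n_draws <- 10000; p <- 662; m <- 20
  counts <- integer(p)
  for (r in seq_len(n_draws)) {
    idx <- sample_gene_subset(p, m, seed = r)
    counts[idx] <- counts[idx] + 1L
  }
  expected <- n_draws * m / p
  sigma <- sqrt(n_draws * (m / p) * (1 - m / p))
  expect_true(all(abs(counts - expected) <= 4 * sigma))
})

test_that("cluster-to-label mapping picks the better of the two mappings", {
  m <- map_clusters_to_labels(c(1, 1, 2, 2), c("R", "R", "NR", "NR"))
  expect_equal(m$accuracy, 1.0)
  expect_equal(unname(m$mapping["1"]), "responder")

  # alternating clusters: both mappings score 0.5, tie-break applies
  m <- map_clusters_to_labels(c(1, 2, 1, 2), c("R", "R", "NR", "NR"))
  expect_equal(m$accuracy, 0.5)
  expect_equal(unname(m$mapping["1"]), "responder")

  expect_error(map_clusters_to_labels(c(1, 2, 3), c("R", "NR", "R")),
               "more than 2")

  # brute-force oracle on all random instances with n <= 8
  set.seed(33)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    cl <- sample(1:2, n, replace = TRUE)
    tr <- sample(c("responder", "non-responder"), n, replace = TRUE)
    got <- map_clusters_to_labels(cl, tr)$accuracy
    accs <- vapply(list(c("responder", "non-responder"),
                        c("non-responder", "responder")), function(mp)
      mean(mp[cl] == tr), numeric(1))
    expect_equal(got, max(accs))
  }
})

test_that("weak learners find strong planted signal and stay honest on noise", {
  v <- planted_views(n = 30, p = 40, T_views = 4, sep = 6, seed = 21)
  # a subset containing many informative genes (all genes load here)
  wl <- run_weak_learner(v, 1:20, seed = 1)
  expect_gte(wl$accuracy, 0.9)
  expect_s3_class(wl$fit, "icluster_fit")
  expect_equal(wl$accuracy, mean(wl$predicted == v$labels))

  # pure-noise views, permuted labels: accuracy centers near majority rate
  set.seed(22)
  noise <- planted_views(n = 30, p = 40, T_views = 2, sep = 0, seed = 22)
  accs <- vapply(1:40, function(r) {
    idx <- sample_gene_subset(40, 10, seed = r)
    run_weak_learner(noise, idx, sample(noise$labels), seed = r)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.45)
  expect_lt(mean(accs), 0.70)
})

test_that("a weak learner on all genes equals the full fit", {
  v <- planted_views(n = 16, p = 12, T_views = 2, sep = 5, seed = 13)
  wl <- run_weak_learner(v, seq_len(12), seed = 2)
  full <- fit_icluster(v, K = 2, lambda = 0, seed = 2)
  expect_identical(unname(wl$fit$cluster_labels),
                   unname(full$cluster_labels))
  expect_equal(wl$fit$W_stacked, full$W_stacked)
})

test_that("gene scores are summed absolute loadings over kept learners", {
  fake <- function(idx, w_abs, pred = NULL) {
    structure(list(gene_indices = idx,
                   w_abs = w_abs,
                   accuracy = 1,
                   predicted = pred %||%
                     setNames(rep("responder", 2), c("s1", "s2"))),
              class = "weak_learner")
  }
  genes <- paste0("g", 1:5)
  a <- fake(c(1, 2), c(1.0, 0.5))
  b <- fake(c(1, 3), c(0.2, 0.3))
  sc <- aggregate_scores(list(a, b), genes)
  expect_equal(unname(sc), c(1.2, 0.5, 0.3, 0, 0))
  expect_equal(unname(aggregate_scores(list(), genes)), rep(0, 5))
  # frequency-normalized variant averages over containing learners
  scn <- aggregate_scores(list(a, b), genes, normalize = TRUE)
  expect_equal(unname(scn[1]), 1.2 / 2)
})

test_that("a single learner's score is the sum of per-view absolute loadings", {
  v <- planted_views(n = 10, p = 6, T_views = 4, sep = 5, seed = 14)
  wl <- run_weak_learner(v, 1:6, seed = 1)
  manual <- rowSums(vapply(wl$fit$W, function(w) abs(w[, 1]), numeric(6)))
  expect_equal(unname(wl$w_abs), unname(manual))
})

test_that("majority vote follows strict majority with declared tie rule", {
  fake <- function(preds) structure(
    list(predicted = setNames(preds, paste0("s", seq_along(preds)))),
    class = "weak_learner")
  kept <- list(fake(c("responder", "responder")),
               fake(c("responder", "non-responder")),
               fake(c("responder", "non-responder")),
               fake(c("non-responder", "non-responder")))
  mv <- majority_vote(kept, 2)
  expect_equal(unname(mv$voted_labels), c("responder", "non-responder"))
  expect_equal(unname(mv$vote_counts[1, ]), c(1, 3))

  tied <- kept[1:2]  # subject 2: 1 vs 1
  expect_equal(unname(majority_vote(tied, 2)$voted_labels[2]),
               "non-responder")
  expect_equal(unname(majority_vote(tied, 2,
                                    tie = "responder")$voted_labels[2]),
               "responder")
  expect_error(majority_vote(list(), 2), "at least one")

  one <- kept[2]
  expect_identical(majority_vote(one, 2)$voted_labels, one[[1]]$predicted)
})

test_that("select_top_k ranks by score with lexicographic ties", {
  sc <- c(g1 = 1.2, g2 = 0.5, g3 = 0.3)
  expect_identical(select_top_k(sc, 2), c("g1", "g2"))
  expect_identical(select_top_k(c(b = 1, a = 1), 1), "a")
  expect_setequal(select_top_k(sc, 3), names(sc))
  expect_error(select_top_k(sc, 4), "exceeds")
})

test_that("the ensemble is reproducible, tallies consistently, and fails loudly", {
  v <- planted_views(n = 20, p = 30, T_views = 3, sep = 6, seed = 31)
  e1 <- run_ensemble(v, n_replicates = 60, subset_size = 8,
                     accuracy_cutoff = 0.6, seed = 5)
  e2 <- run_ensemble(v, n_replicates = 60, subset_size = 8,
                     accuracy_cutoff = 0.6, seed = 5)
  expect_identical(e1, e2)

  # vote tallies sum to kept_count for every subject
  expect_true(all(rowSums(e1$vote_counts) == e1$kept_count))
  # score support: positive score implies membership in a kept learner
  expect_true(all(e1$times_kept[e1$gene_scores > 0] >= 1))
  # genes never kept have score zero
  expect_true(all(e1$gene_scores[e1$times_kept == 0] == 0))

  noise <- planted_views(n = 16, p = 30, T_views = 2, sep = 0, seed = 32)
  expect_error(run_ensemble(noise, n_replicates = 40, subset_size = 8,
                            accuracy_cutoff = 0.999, seed = 1),
               "accuracy_cutoff = 0.999")
})

test_that("a one-replicate ensemble votes exactly as its single learner", {
  v <- planted_views(n = 14, p = 18, T_views = 2, sep = 5, seed = 41)
  ens <- run_ensemble(v, n_replicates = 1, subset_size = 6,
                      accuracy_cutoff = 0, seed = 9)
  expect_equal(ens$kept_count, 1)
  expect_identical(ens$voted_labels, ens$kept[[1]]$predicted)
  expect_equal(ens$vote_accuracy, ens$kept[[1]]$accuracy)
})

test_that("permuted labels never enrich kept learners or planted genes", {
  v <- planted_views(n = 30, p = 40, T_views = 4, sep = 5, seed = 51)
  e_true <- run_ensemble(v, n_replicates = 150, subset_size = 10,
                         accuracy_cutoff = 0.75, seed = 3)
  frac_true <- e_true$kept_count / 150
  set.seed(52)
  for (i in 1:3) {
    perm <- sample(v$labels)
    e_perm <- tryCatch(
      run_ensemble(v, labels = perm, n_replicates = 150, subset_size = 10,
                   accuracy_cutoff = 0.75, seed = 3),
      error = function(e) NULL)
    frac_perm <- if (is.null(e_perm)) 0 else e_perm$kept_count / 150
    expect_lte(frac_perm, frac_true)
  }
})
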