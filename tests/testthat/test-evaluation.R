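test_that("pseudo-genes average the requested timepoints, using what's available", {
  x <- tiny_set(1, 4, c("LS0", "W1", "W2", "W4"),
                values = rep(c(1, 2, 3, 4), each = 4))
  pg <- make_pseudo_genes(x, c("LS0", "W1", "W2", "W4"))
  expect_equal(unname(pg[1, ]), rep(2.5, 4))

  x$values[1, "s1", "W4"] <- NA
  pg <- make_pseudo_genes(x, c("LS0", "W1", "W2", "W4"))
  expect_equal(unname(pg[1, "s1"]), 2.0)

  # single timepoint: identity with that slice
  pg1 <- make_pseudo_genes(x, "W2")
  expect_equal(pg1, x$values[, , "W2", drop = TRUE], ignore_attr = TRUE)

  expect_error(make_pseudo_genes(x, character(0)), "non-empty")
})

test_that("averaging commutes: timepoints-then-subjects equals subjects-then-timepoints", {
  sim <- simulate_longitudinal(sim_config(n_subjects = 10, p_genes = 15,
                                          n_informative = 5, seed = 61))
  tps <- c("LS0", "W1", "W2", "W4")
  pg <- make_pseudo_genes(sim$data, tps)
  a <- rowMeans(pg)
  b <- rowMeans(apply(sim$data$values[, , tps], c(1, 3), mean))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("LOO SVM is perfect on a separated feature and deterministic", {
  feat <- matrix(c(rep(-10, 5), rep(10, 5)), 1,
                 dimnames = list("g1", paste0("s", 1:10)))
  labels <- rep(c("non-responder", "responder"), each = 5)
  ev <- loo_svm_accuracy(feat, labels)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(sum(ev$confusion), 10)
  expect_equal(sum(diag(ev$confusion)), 10)

  set.seed(62)
  feat2 <- matrix(rnorm(20 * 12), 20, 12,
                  dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  lab2 <- rep(c("responder", "non-responder"), 6)
  e1 <- loo_svm_accuracy(feat2, lab2)
  e2 <- loo_svm_accuracy(feat2, lab2)
  expect_identical(e1, e2)

  expect_error(loo_svm_accuracy(feat[, 1:6, drop = FALSE],
                                c("responder", rep("non-responder", 5))),
               "2 subjects per class")
})

test_that("LOO SVM on noise with shuffled labels sits in the chance band", {
  set.seed(63)
  feat <- matrix(rnorm(20 * 30), 20, 30,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:30)))
  labels <- rep(c("responder", "non-responder"), 15)
  accs <- vapply(1:20, function(i) {
    loo_svm_accuracy(feat, sample(labels))$accuracy
  }, numeric(1))
  # no optimism: the mean never rises above the chance band. (LOO is
  # *pessimistically* biased on noise — the held-out subject's class is
  # always the training minority — so accuracies sit at or below 0.5.)
  band <- chance_band(20 * 30)
  expect_lte(mean(accs), band[2])
  expect_lte(max(accs), chance_band(30)[2])
  expect_gte(mean(accs), 0.15)
})

test_that("nested LOO retrains per fold and never sees the held-out subject", {
  sim <- simulate_longitudinal(sim_config(n_subjects = 12, p_genes = 30,
                                          n_informative = 8,
                                          delta_range = c(2.5, 3.5),
                                          seed = 64))
  cfg <- list(n_replicates = 80, subset_size = 8, accuracy_cutoff = 0.6)
  tps <- c("LS0", "W1", "W2", "W4")
  held <- "S05"
  ev1 <- nested_loo_ensemble(sim$data, view_timepoints = tps,
                             k = 5, ensemble_config = cfg, seed = 2,
                             folds = held)
  # corrupt ONLY the held-out subject: selection must be unchanged
  poisoned <- sim$data
  poisoned$values[, held, ] <- poisoned$values[, held, ] + 1000
  ev2 <- nested_loo_ensemble(poisoned, view_timepoints = tps,
                             k = 5, ensemble_config = cfg, seed = 2,
                             folds = held)
  expect_identical(ev1$per_fold_selected, ev2$per_fold_selected)
})

test_that("nested LOO runs one fold per subject", {
  sim <- simulate_longitudinal(sim_config(n_subjects = 8, p_genes = 20,
                                          n_informative = 6,
                                          delta_range = c(2.5, 3.5),
                                          seed = 65))
  ev <- nested_loo_ensemble(sim$data, view_timepoints = c("LS0", "W1"),
                            k = 4,
                            ensemble_config = list(n_replicates = 40,
                                                   subset_size = 6,
                                                   accuracy_cutoff = 0.5),
                            seed = 3)
  expect_length(ev$fold_predictions, 8)
  expect_length(ev$per_fold_selected, 8)
  expect_equal(sum(ev$confusion), 8)
})

test_that("random baseline reduces to a single LOO run and is seeded", {
  sim <- simulate_longitudinal(sim_config(n_subjects = 10, p_genes = 25,
                                          n_informative = 5, seed = 66))
  tps <- c("LS0", "W1", "W2", "W4")
  rb <- random_gene_baseline(sim$data, k = 6, n_sets = 1,
                             use_timepoints = tps, seed = 4)
  pseudo <- make_pseudo_genes(sim$data, tps)
  idx <- sample_gene_subset(25, 6, seed = derive_seed_oracle(4, 1))
  direct <- loo_svm_accuracy(pseudo, sim$data$sample_meta$response,
                             gene_subset = idx)
  expect_equal(rb$mean_accuracy, direct$accuracy)

  rb2 <- random_gene_baseline(sim$data, k = 6, n_sets = 5,
                              use_timepoints = tps, seed = 4)
  rb3 <- random_gene_baseline(sim$data, k = 6, n_sets = 5,
                              use_timepoints = tps, seed = 4)
  expect_identical(rb2$accuracies, rb3$accuracies)
  expect_error(random_gene_baseline(sim$data, k = 26, n_sets = 1,
                                    use_timepoints = tps), "exceeds")
})

test_that("group trajectories report means, sizes and standard errors", {
  x <- tiny_set(1, 6, c("NL", "W4"),
                values = c(1, 2, 3, 4, 5, 6,   # NL
                           7, 8, 9, 4, 5, 6),  # W4
                responses = c(rep("responder", 3), rep("non-responder", 3)))
  tr <- group_mean_trajectories(x, reference_timepoint = "NL")
  r_w4 <- tr[tr$group == "responder" & tr$timepoint == "W4", ]
  expect_equal(r_w4$mean, 8.0)
  expect_equal(r_w4$n, 3)
  expect_equal(r_w4$se, sd(c(7, 8, 9)) / sqrt(3))
  expect_equal(unname(attr(tr, "reference_means")["g1"]), mean(1:6))

  # single-subject group: trajectory equals that subject's values
  y <- tiny_set(1, 4, c("NL", "W4"),
                responses = c("responder", rep("non-responder", 3)))
  tr1 <- group_mean_trajectories(y)
  expect_equal(tr1[tr1$group == "responder" & tr1$timepoint == "W4", "mean"],
               unname(y$values[1, "s1", "W4"]))
})

test_that("responder trajectories track the geometric-recovery closed form", {
  cfg <- sim_config(n_subjects = 200, p_genes = 4, n_informative = 4,
                    delta_range = c(2, 2), recovery_rate = 0.5,
                    sigma_subject = 0.2, sigma_noise = 0.4, seed = 67)
  sim <- simulate_longitudinal(cfg)
  tr <- group_mean_trajectories(sim$data)
  for (g in sim$truth$informative_gene_ids) {
    mu <- sim$truth$mu[[g]]; dl <- sim$truth$delta[[g]]
    for (tp in c("LS0", "W1", "W2", "W4")) {
      t <- match(tp, c("LS0", "W1", "W2", "W4")) - 1
      row <- tr[tr$gene == g & tr$group == "responder" &
                  tr$timepoint == tp, ]
      expect_lt(abs(row$mean - (mu + dl * 0.5^t)), 3 * row$se + 1e-12)
    }
  }
})

test_that("gap closure is exact in the noise-free generator", {
  cfg <- sim_config(n_subjects = 10, p_genes = 3, n_informative = 3,
                    delta_range = c(2, 2), recovery_rate = 0.5,
                    sigma_subject = 0, sigma_noise = 0, seed = 68)
  sim <- simulate_longitudinal(cfg)
  tr <- group_mean_trajectories(sim$data)
  g <- sim$truth$informative_gene_ids[1]
  # responders: three geometric steps close the gap to 0.5^3
  expect_equal(gap_closure(tr, g, "responder", "LS0", "W4"), 0.125,
               tolerance = 1e-12)
  # non-responders: flat trajectory, gap unchanged
  expect_equal(gap_closure(tr, g, "non-responder", "LS0", "W4"), 1.0,
               tolerance = 1e-12)
  expect_error(gap_closure(tr, "nope", "responder", "LS0", "W4"),
               "unknown gene|no trajectory row")
})

test_that("full recovery and vanishing gaps are handled", {
  # hand-built set: W4 equals the NL mean exactly -> ratio 0
  x <- tiny_set(1, 4, c("NL", "LS0", "W4"),
                values = c(rep(5, 4), rep(7, 4), rep(5, 4)),
                responses = rep(c("responder", "non-responder"), 2))
  tr <- group_mean_trajectories(x)
  expect_equal(gap_closure(tr, "g1", "responder", "LS0", "W4"), 0.0)
  # zero starting gap -> undefined flag
  out <- gap_closure(tr, "g1", "responder", "W4", "LS0")
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
})
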