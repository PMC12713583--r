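test_that("feature table layout and counting oracle", {
  ds <- tiny_dataset(seed = 30, n_per = c(2, 2, 1), n_trials = 3)
  ft <- build_feature_table(ds, window = c(-600, 600))
  n_contra <- sum(ds$trials$direction == "contra")
  expect_equal(dim(ft$x), c(n_contra, 1200L))
  expect_equal(length(unique(ft$group)), 5L)
  # feature sums equal direct spike counts in the window per (neuron, trial)
  for (i in sample(nrow(ft$x), 10)) {
    tid <- ft$trial_id[i]
    t_on <- ds$trials$target_on[ds$trials$trial_id == tid]
    sp <- ds$spikes$spike_time_ms[ds$spikes$trial_id == tid]
    rel <- sp - t_on
    expect_equal(sum(ft$x[i, ]), sum(rel >= -600 & rel < 600))
  }
  # a silenced neuron yields all-zero rows
  ds2 <- ds
  mute <- ds$neurons$neuron_id[1]
  ds2$spikes <- ds2$spikes[ds2$spikes$neuron_id != mute, ]
  ft2 <- build_feature_table(ds2, window = c(-600, 600))
  expect_true(all(Matrix::rowSums(ft2$x[ft2$group == mute, ]) == 0))
})

test_that("pseudo-population mode concatenates neurons into samples", {
  ds <- tiny_dataset(seed = 31, n_per = c(2, 2, 0), n_trials = 3)
  ft <- build_feature_table(ds, window = c(-100, 100),
                            mode = "pseudo_population")
  expect_equal(ncol(ft$x), 4L * 200L)
  expect_true(all(table(ft$choice) >= 1))
  expect_equal(length(unique(ft$group)), nrow(ft$x))
})

test_that("grouped folds partition samples without splitting groups", {
  g <- rep(paste0("n", 1:10), each = 7)
  f <- grouped_folds(g, k = 10, seed = 1)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(tapply(f, g, function(v) length(unique(v))) == 1))
  # unequal groups: greedy balancing keeps fold sizes close
  g2 <- rep(paste0("n", 1:23), times = sample(3:12, 23, TRUE))
  f2 <- grouped_folds(g2, k = 5, seed = 2)
  expect_true(all(tapply(f2, g2, function(v) length(unique(v))) == 1))
  expect_equal(length(f2), length(g2))
  expect_lt(diff(range(table(f2))), max(table(g2)) + 1)
  expect_error(grouped_folds(rep("a", 5), k = 2), "fewer groups")
})

test_that("pooled AUC equals the brute-force pairwise oracle", {
  set.seed(71)
  for (r in 1:10) {
    n <- sample(20:60, 1)
    y <- factor(sample(c("reject", "accept"), n, TRUE),
                levels = c("reject", "accept"))
    score <- round(stats::rnorm(n), 1)   # coarse scores force ties
    expect_equal(spikechoice:::.auc(y, score), brute_auc(y, score),
                 tolerance = 1e-10)
  }
})

test_that("elastic-net coefficient norm shrinks with lambda", {
  set.seed(72)
  x <- matrix(stats::rnorm(80 * 50), 80)
  y <- factor(ifelse(x[, 1] + stats::rnorm(80) > 0, "accept", "reject"),
              levels = c("reject", "accept"))
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0.5, nlambda = 30)
  norms <- Matrix::colSums(abs(fit$beta))
  expect_true(all(diff(rev(norms)) <= 1e-8))  # non-increasing in lambda
  # extreme shrinkage: coefficients vanish, predictions are constant
  co <- as.vector(stats::coef(fit, s = max(fit$lambda) * 10))[-1]
  expect_true(all(abs(co) < 1e-10))
})

test_that("nested grouped CV separates planted signal from null labels", {
  g <- default_response_gain()
  g[1, , ] <- g[2, , ]; g[3, , ] <- g[2, , ]
  g[, "good", "contra"] <- 30; g[, "bad", "contra"] <- -15
  ds <- simulate_dataset(simulation_config(
    n_neurons_per_cluster = c(6, 6, 6), n_trials_per_condition = 4,
    response_gain = g, seed = 2))
  ft <- build_feature_table(ds)
  res <- nested_cv_elastic_net(ft, "choice", k_outer = 4, k_inner = 3,
                               nlambda = 15, seed = 1)
  expect_gt(res$metric, 0.85)
  expect_equal(sum(res$per_fold$n_test), nrow(ft$x))
  expect_true(all(tapply(res$predictions$fold, res$predictions$group,
                         function(v) length(unique(v))) == 1))
  # shuffling labels within neuron destroys decodability
  set.seed(5)
  ftn <- ft
  for (nid in unique(ft$group)) {
    i <- which(ft$group == nid)
    ftn$choice[i] <- sample(ft$choice[i])
  }
  resn <- nested_cv_elastic_net(ftn, "choice", k_outer = 4, k_inner = 3,
                                nlambda = 15, seed = 1)
  expect_lt(abs(resn$metric - 0.5), 0.12)
})

test_that("RT decoding reports a cross-validated R-squared", {
  ds <- tiny_dataset(seed = 33, n_per = c(4, 4, 4), n_trials = 4)
  ft <- build_feature_table(ds)
  res <- nested_cv_elastic_net(ft, "rt", k_outer = 4, k_inner = 3,
                               nlambda = 10, seed = 1)
  expect_equal(res$metric_name, "r2")
  expect_lt(res$metric, 1)
  expect_equal(nrow(res$predictions), sum(!is.na(ft$rt_ms)))
})

test_that("ablation keeps the full analysis reproducible on the full subset", {
  ds <- tiny_dataset(seed = 34, n_per = c(4, 4, 4), n_trials = 4)
  labels <- stats::setNames(ds$neurons$true_cluster, ds$neurons$neuron_id)
  ft <- build_feature_table(ds, assignments = labels)
  full <- nested_cv_elastic_net(ft, "choice", k_outer = 4, k_inner = 3,
                                nlambda = 10, seed = 9)
  again <- nested_cv_elastic_net(spikechoice:::.ft_subset(ft, seq_along(ft$group)),
                                 "choice", k_outer = 4, k_inner = 3,
                                 nlambda = 10, seed = 9)
  expect_equal(full$metric, again$metric, tolerance = 1e-12)
  tab <- ablation_and_single_cluster(ft, k_outer = 4, k_inner = 3,
                                     nlambda = 10, seed = 9)
  expect_equal(tab$metric[tab$analysis == "full"], full$metric)
  expect_equal(nrow(tab), 7L)   # full + (ablate, single) x 3 clusters
})

test_that("permutation test saturates on separable data", {
  g <- default_response_gain()
  g[2, "good", "contra"] <- 35; g[2, "bad", "contra"] <- -18
  ds <- simulate_dataset(simulation_config(
    n_neurons_per_cluster = c(0, 12, 0), n_trials_per_condition = 4,
    response_gain = g, seed = 3))
  ft <- build_feature_table(ds)
  pt <- permutation_test(ft, n_perm = 9, seed = 1, k_outer = 4,
                         k_inner = 3, nlambda = 10)
  expect_equal(pt$p, 1 / 10)
  expect_true(all(abs(pt$null_auc - 0.5) < 0.2))
})
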