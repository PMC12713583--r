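test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_trials_per_condition = 1),
               "n_trials_per_condition")
  bad_policy <- default_choice_policy()
  bad_policy$bad_strategy["stable", ] <- c(0.5, 0.5, 0.5)
  expect_error(simulation_config(choice_policy = bad_policy), "summing to 1")
  bad_policy2 <- default_choice_policy()
  bad_policy2$good_accept["stable"] <- 1.4
  expect_error(simulation_config(choice_policy = bad_policy2), "\\[0, 1\\]")
  expect_error(simulation_config(n_neurons_per_cluster = c(5, 5)),
               "non-negative")
})

test_that("condition rate function: baseline before onset, rectified after", {
  cfg <- simulation_config(seed = 1)
  b <- exp(cfg$baseline_log_mean)
  expect_equal(sample_condition_rate(1, "good", "contra", t = c(-200, 0, 50),
                                     cfg, onset_ms = 100),
               rep(b, 3))
  # bidirectional profile: suppressed below baseline for bad objects
  r_bad <- sample_condition_rate(2, "bad", "contra", t = 400, cfg,
                                 onset_ms = 100)
  expect_lt(r_bad, b)
  # rectification at zero for gains below -baseline
  g <- default_response_gain()
  g[2, "bad", "contra"] <- -2 * b
  cfg2 <- simulation_config(response_gain = g, seed = 1)
  expect_equal(sample_condition_rate(2, "bad", "contra", t = 1000, cfg2,
                                     onset_ms = 100, baseline_hz = b), 0)
  expect_error(sample_condition_rate(7, "good", "contra", 0, cfg),
               "unknown cluster")
})

test_that("zero-gain config yields baseline-rate firing in every epoch", {
  g <- default_response_gain(); g[, , ] <- 0
  cfg <- simulation_config(n_neurons_per_cluster = c(2, 2, 2),
                           n_trials_per_condition = 25,
                           response_gain = g, seed = 42)
  ds <- simulate_dataset(cfg)
  ac <- align_and_bin(ds, event = "target", window = c(0, 400))
  cnt <- rowsum(colSums(ac$values), ac$index$neuron_id)
  n_tr <- table(factor(ac$index$neuron_id, levels = rownames(cnt)))
  obs_hz <- as.vector(cnt) / (as.vector(n_tr) * 0.4)
  exp_hz <- ds$neurons$baseline_rate_hz[match(rownames(cnt),
                                              ds$neurons$neuron_id)]
  se <- sqrt(as.vector(cnt)) / (as.vector(n_tr) * 0.4)
  expect_true(all(abs(obs_hz - exp_hz) < 3 * pmax(se, 0.5)))
})

test_that("spike counts match the integral of the planted rate (3 MC SE)", {
  cfg <- simulation_config(n_neurons_per_cluster = c(1, 1, 1),
                           n_trials_per_condition = 40, seed = 7)
  ds <- simulate_dataset(cfg)
  grid <- seq(0, 499)   # post-target ms
  for (nid in ds$neurons$neuron_id) {
    cl <- ds$neurons$true_cluster[ds$neurons$neuron_id == nid]
    b <- ds$neurons$baseline_rate_hz[ds$neurons$neuron_id == nid]
    tr <- ds$trials[ds$trials$neuron_id == nid, ]
    on <- ds$truth$true_onset
    expected <- sum(vapply(seq_len(nrow(tr)), function(j) {
      lat <- on$onset_latency_ms[on$trial_id == tr$trial_id[j]]
      sum(sample_condition_rate(cl, tr$value[j], tr$direction[j], grid, cfg,
                                onset_ms = lat, baseline_hz = b)) / 1000
    }, numeric(1)))
    ac <- align_and_bin(ds$spikes[ds$spikes$neuron_id == nid, ], tr,
                        "target", c(0, 500))
    observed <- sum(ac$values)
    expect_lt(abs(observed - expected), 3 * sqrt(expected))
  }
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- simulation_config(n_neurons_per_cluster = c(2, 2, 2),
                           n_trials_per_condition = 3, seed = 9)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$spikes, ds2$spikes)
  expect_identical(ds1$trials, ds2$trials)
  expect_identical(ds1$truth, ds2$truth)
})

test_that("behavioral structure: accept faster than reject, null slope flat", {
  ds <- tiny_dataset(seed = 3, n_per = c(5, 5, 5), n_trials = 10)
  tr <- ds$trials
  expect_lt(mean(tr$rt_ms[tr$choice == "accept"], na.rm = TRUE),
            mean(tr$rt_ms[tr$choice == "reject_return"], na.rm = TRUE))
  # planted slope recovered by OLS on true latencies
  acc <- tr[tr$choice == "accept", ]
  lat <- ds$truth$true_onset$onset_latency_ms[
    match(acc$trial_id, ds$truth$true_onset$trial_id)]
  fit <- stats::lm(acc$rt_ms ~ lat)
  expect_lt(abs(stats::coef(fit)[2] - 0.4),
            3 * summary(fit)$coefficients[2, 2])
  # and a b = 0 config gives a flat relation
  rtm <- simulation_config()$rt_model; rtm$slope <- 0
  ds0 <- simulate_dataset(simulation_config(
    n_neurons_per_cluster = c(5, 5, 5), n_trials_per_condition = 10,
    rt_model = rtm, seed = 4))
  acc0 <- ds0$trials[ds0$trials$choice == "accept", ]
  lat0 <- ds0$truth$true_onset$onset_latency_ms[
    match(acc0$trial_id, ds0$truth$true_onset$trial_id)]
  fit0 <- stats::lm(acc0$rt_ms ~ lat0)
  expect_lt(abs(stats::coef(fit0)[2]), 3 * summary(fit0)$coefficients[2, 2])
})
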