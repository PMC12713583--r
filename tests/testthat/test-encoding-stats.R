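test_that("trial response parameters follow their closed forms", {
  time <- 0:399
  # saturating ramp: z = t/50 capped at 4; first bin strictly above 2 is 101
  z <- pmin(time / 50, 4)
  p <- extract_response_params(z, time)
  expect_equal(p$onset_ms, 101)
  expect_equal(p$peak_z, 4)
  expect_equal(p$slope_z_per_ms, (4 - 101 / 50) / (200 - 101))
  # step to z = 3 at t = 80: peak at onset, slope defined as 0
  z2 <- ifelse(time >= 80, 3, 0)
  p2 <- extract_response_params(z2, time)
  expect_equal(p2$onset_ms, 80)
  expect_equal(p2$peak_z, 3)
  expect_equal(p2$slope_z_per_ms, 0)
  # never exceeding the threshold flags a non-response
  expect_false(extract_response_params(rep(1.5, 400), time)$responded)
  # the onset search respects the saccade bound
  z3 <- ifelse(time >= 300, 3, 0)
  expect_false(extract_response_params(z3, time, search_end = 250)$responded)
})

test_that("Bonferroni thresholds are exact", {
  expect_equal(bonferroni_threshold(0.05, 9), 0.05 / 9)
  expect_equal(round(bonferroni_threshold(0.05, 9), 4), 0.0056)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 5), 0.002)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("condition LMM recovers planted effects and supports post-hoc tests", {
  set.seed(41)
  d <- expand.grid(neuron_id = sprintf("n%02d", 1:16),
                   scene = factor(1:2), value = c("good", "bad"),
                   direction = c("contra", "ipsi"),
                   stringsAsFactors = FALSE)
  d$monkey_id <- ifelse(as.integer(factor(d$neuron_id)) <= 8, "C", "S")
  u <- stats::rnorm(16, 0, 0.5)
  delta <- 1  # planted value effect in z units
  d$activity <- u[as.integer(factor(d$neuron_id))] +
    ifelse(d$value == "good", delta, 0) + stats::rnorm(nrow(d), 0, 0.3)
  d$value <- factor(d$value, c("good", "bad"))
  d$direction <- factor(d$direction, c("contra", "ipsi"))
  fit <- fit_activity_lmm(d)
  expect_s3_class(fit, "activity_lmm")
  expect_lt(abs(fit$fixed["valuebad", "Estimate"] + delta), 0.2)
  ph <- posthoc_pairwise(fit)
  expect_equal(nrow(ph), 12L)  # 6 contrasts within each of 2 scenes
  sig <- ph[grepl("good", ph$contrast) & grepl("bad", ph$contrast), ]
  expect_true(any(sig$p.value < 0.001))
  expect_true(all(ph$p.value >= 0 & ph$p.value <= 1))
})

test_that("post-hoc p-values cap at 1 for identical condition means", {
  set.seed(42)
  d <- expand.grid(neuron_id = sprintf("n%02d", 1:12),
                   scene = factor(1:2), value = factor(c("good", "bad")),
                   direction = factor(c("contra", "ipsi")), rep = 1:2)
  d$monkey_id <- ifelse(as.integer(factor(d$neuron_id)) <= 6, "C", "S")
  d$activity <- stats::rnorm(nrow(d))
  fit <- suppressMessages(fit_activity_lmm(d))
  ph <- posthoc_pairwise(fit)
  expect_true(all(ph$p.value > 0.05))
  expect_true(max(ph$p.value) == 1)   # Bonferroni cap reached
})

test_that("parametric bootstrap saturates correctly at both extremes", {
  d <- gen_null_lmm_data(5)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  null <- lme4::lmer(activity ~ 1 + (1 | neuron_id), d, REML = FALSE,
                     control = ctrl)
  # full identical to null: LR ~ 0 and p ~ 1
  same <- parametric_bootstrap_test(null, null, n_boot = 39, seed = 1)
  expect_lt(abs(same$lr_obs), 1e-6)
  expect_gt(same$p, 0.5)
  # huge planted fixed effect: p at its attainable minimum
  d2 <- d; d2$activity <- d2$activity + 50 * (d2$cond == "a")
  full2 <- lme4::lmer(activity ~ cond + (1 | neuron_id), d2, REML = FALSE,
                      control = ctrl)
  null2 <- lme4::lmer(activity ~ 1 + (1 | neuron_id), d2, REML = FALSE,
                      control = ctrl)
  bt <- parametric_bootstrap_test(full2, null2, n_boot = 39, seed = 2)
  expect_equal(bt$p, 1 / (39 - bt$n_failed + 1))
})

test_that("RT mixed model recovers a planted slope and rejects degenerates", {
  f <- fit_rt_lmm(gen_rt_params(b = 0.4, seed = 1), "onset_ms")
  expect_lt(abs(f$beta - 0.4), stats::qt(0.975, f$df) * f$se)
  expect_true(is.finite(f$p))
  d <- gen_rt_params(0.4, 2); d$onset_ms <- 100
  expect_error(fit_rt_lmm(d, "onset_ms"), "degenerate")
  expect_error(fit_rt_lmm(gen_rt_params(0.4, 3), "nope"), "unknown parameter")
})

test_that("response-parameter extraction feeds the RT model end to end", {
  g <- default_response_gain()
  g[1, "good", "contra"] <- 40   # strong response so most trials cross z = 2
  ds <- simulate_dataset(simulation_config(
    n_neurons_per_cluster = c(6, 0, 0), n_trials_per_condition = 8,
    response_gain = g, seed = 6))
  al <- aligned_activity(ds, event = "target", window = c(-580, 400))
  params <- suppressMessages(response_params_table(al, ds$trials))
  expect_true(!is.null(params) && nrow(params) > 20)
  expect_true(all(params$onset_ms > 0))
  expect_true(all(params$peak_z > 2))
  f <- fit_rt_lmm(params, "onset_ms")
  expect_true(is.finite(f$beta) && is.finite(f$p))
})

test_that("behavioral tests match their exact oracles", {
  # Fisher table (10,0 / 0,10): two-sided p = 2 / choose(20,10)
  trials <- data.frame(
    trial_id = paste0("t", 1:24),
    scene = c(rep(1, 10), rep(3, 10), 1, 1, 3, 3),
    value = c(rep("bad", 20), rep("good", 4)),
    choice = c(rep("reject_stay", 10), rep("reject_return", 10),
               rep(c("accept", "reject_return"), 2)),
    rt_ms = c(rep(NA, 10), stats::rnorm(10, 260, 10),
              stats::rnorm(2, 180, 10), stats::rnorm(2, 260, 10)))
  bt <- behavior_tests(trials)
  expect_equal(bt$stay_fisher$p.value, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(unname(bt$stay_table["stable", "stay"]), 10)
  # generator-default behavior: accept RTs reliably faster than reject
  ds <- tiny_dataset(seed = 10, n_per = c(4, 4, 4), n_trials = 10)
  bt2 <- behavior_tests(ds$trials)
  expect_lt(bt2$rt_welch$p.value, 1e-4)
  expect_lt(diff(bt2$rt_welch$estimate)[1] * -1, 0)  # accept mean smaller
})
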