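test_that("binning follows the half-open convention and matches brute force", {
  trials <- data.frame(trial_id = c("t1", "t2"), neuron_id = "n1",
                       target_on = c(1000, 2000))
  spikes <- data.frame(neuron_id = "n1", trial_id = c("t1", "t1", "t2"),
                       spike_time_ms = c(1000, 1010, 2009.999))
  ac <- align_and_bin(spikes, trials, "target", c(0, 10))
  m <- neuron_matrix(ac, "n1")
  expect_equal(unname(m["t1", 1]), 1)  # spike exactly at t0 -> first bin
  expect_equal(sum(m["t1", ]), 1)      # spike at t1 excluded
  expect_equal(unname(m["t2", 10]), 1) # just inside the last bin
  # all-zero vector when no spikes fall in the window
  ac0 <- align_and_bin(spikes[3, ], trials, "target", c(100, 150))
  expect_true(all(ac0$values == 0))

  # property: binned totals equal direct enumeration on random instances
  set.seed(11)
  for (rep in 1:25) {
    n_tr <- sample(2:5, 1)
    trials <- data.frame(trial_id = paste0("t", 1:n_tr), neuron_id = "n1",
                         target_on = stats::runif(n_tr, 500, 1500))
    n_sp <- sample(5:60, 1)
    spikes <- data.frame(neuron_id = "n1",
                         trial_id = sample(trials$trial_id, n_sp, TRUE),
                         spike_time_ms = stats::runif(n_sp, 0, 2500))
    w <- sort(stats::runif(2, -400, 400)); w <- c(floor(w[1]), ceiling(w[2]) + 1)
    ac <- align_and_bin(spikes, trials, "target", w)
    rel <- spikes$spike_time_ms -
      trials$target_on[match(spikes$trial_id, trials$trial_id)]
    expect_equal(sum(ac$values), sum(rel >= w[1] & rel < w[2]))
  }
})

test_that("trials with missing event times are excluded with a warning", {
  trials <- data.frame(trial_id = c("t1", "t2"), neuron_id = "n1",
                       saccade_on = c(1500, NA))
  spikes <- data.frame(neuron_id = "n1", trial_id = "t1",
                       spike_time_ms = 1490)
  expect_warning(ac <- align_and_bin(spikes, trials, "saccade", c(-20, 20)),
                 "missing saccade_on")
  expect_equal(nrow(ac$index), 1L)
  expect_equal(ac$n_excluded, 1L)
})

test_that("SDF conserves spike mass and reproduces constant rates", {
  # all-zero counts -> all-zero SDF
  expect_true(all(compute_sdf(rep(0, 200), 20) == 0))
  # single spike: unit-area Gaussian bump peaking at the spike bin
  x <- rep(0, 1000); x[500] <- 1
  s <- compute_sdf(x, 20)
  expect_equal(which.max(s), 500)
  expect_equal(sum(s) / 1000, 1, tolerance = 1e-4)   # area ~ 1 spike
  # constant 1 count/ms -> interior SDF = 1000 spikes/s exactly
  s2 <- compute_sdf(rep(1, 600), 20)
  expect_equal(s2[100:500], rep(1000, 401), tolerance = 1e-9)
  # mass conservation for interior spikes
  set.seed(2)
  x3 <- rep(0, 800); x3[sample(100:700, 40)] <- 1
  expect_equal(sum(compute_sdf(x3, 20)) / 1000, 40, tolerance = 1e-6)
  expect_error(compute_sdf(x, 0), "positive")
})

test_that("FFT and compiled sparse convolution agree", {
  set.seed(5)
  cm <- matrix(stats::rpois(30 * 250, 0.05), nrow = 250)  # bins x samples
  ac <- structure(list(values = cm,
                       index = data.frame(neuron_id = "n1",
                                          trial_id = paste0("t", 1:30)),
                       time = 0:249, event = "target", window = c(0, 250),
                       n_excluded = 0L),
                  class = "aligned_counts")
  via_cpp <- compute_sdf(ac, 7)$values
  via_fft <- apply(cm, 2, function(col) compute_sdf(col, 7))
  expect_equal(via_cpp, via_fft, tolerance = 1e-10)
})

test_that("z-scoring matches hand-computed values and flags silent units", {
  # baseline bins {3,7,3,7,5}: mu = 5, sd = 2; a bin at 9 gives z = 2
  vals <- matrix(c(3, 7, 3, 7, 5, 9, 5, 5, 5, 5), ncol = 1)
  sdf <- make_aligned(vals, time = -5:4, neuron_id = "n1", trial_id = "t1",
                      class = "aligned_sdf")
  z <- zscore_activity(sdf, baseline_window = c(-5, 0))
  expect_equal(z$values[6, 1], 2)
  expect_equal(z$baseline_stats$mu, 5)
  expect_equal(z$baseline_stats$sd, 2)
  # constant unit: flagged and excluded
  vals2 <- cbind(vals, matrix(4, 10, 1))
  sdf2 <- make_aligned(vals2, time = -5:4, neuron_id = c("n1", "n2"),
                       trial_id = c("t1", "t2"), class = "aligned_sdf")
  expect_warning(z2 <- zscore_activity(sdf2, c(-5, 0)), "zero baseline SD")
  expect_equal(z2$excluded_neurons, "n2")
  expect_false("n2" %in% z2$index$neuron_id)
})

test_that("z-scoring is invariant to affine rescaling of rates", {
  set.seed(8)
  vals <- matrix(stats::rlnorm(200 * 6, 2, 0.5), nrow = 200)
  mk <- function(v) make_aligned(v, time = -100:99,
                                 neuron_id = rep(c("n1", "n2"), each = 3),
                                 trial_id = paste0("t", 1:6),
                                 class = "aligned_sdf")
  z1 <- zscore_activity(mk(vals), c(-100, 0))
  z2 <- zscore_activity(mk(vals * 3.7 + 11), c(-100, 0))
  expect_equal(z1$values, z2$values, tolerance = 1e-10)
})

test_that("per-trial z-scoring centers each trial's own baseline", {
  set.seed(9)
  vals <- matrix(stats::rlnorm(200 * 4, 2, 0.5), nrow = 200)
  sdf <- make_aligned(vals, time = -100:99, neuron_id = "n1",
                      trial_id = paste0("t", 1:4), class = "aligned_sdf")
  z <- zscore_activity(sdf, c(-100, 0), method = "per_trial")
  base_means <- colMeans(z$values[z$time < 0, ])
  expect_equal(base_means, rep(0, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("epoch means follow closed forms", {
  time <- 0:399
  x <- time / 100
  expect_equal(epoch_mean(x, c(100, 300), time), 1.995)  # mean(100:299)/100
  expect_equal(epoch_mean(rep(2.5, 400), c(0, 400), time), 2.5)
  expect_equal(epoch_mean(seq(-1, 1, length.out = 400), c(0, 400), time), 0)
  expect_error(epoch_mean(x, c(300, 100), time), "empty epoch")
  expect_error(epoch_mean(x, c(1000, 1100), time), "outside")
})

test_that("baseline rate is spikes per unit pre-scene time", {
  trials <- data.frame(trial_id = paste0("t", 1:20), neuron_id = "n1",
                       scene_on = 500)
  spikes <- data.frame(neuron_id = "n1",
                       trial_id = sample(trials$trial_id, 10, TRUE),
                       spike_time_ms = stats::runif(10, 0, 500))
  expect_equal(unname(baseline_rate(spikes, trials)), 1.0)  # 10 / 10 s
  expect_equal(unname(baseline_rate(spikes[0, ], trials)), 0)
  # homogeneous Poisson at its configured rate, many trials
  g <- default_response_gain(); g[, , ] <- 0
  ds <- simulate_dataset(simulation_config(
    n_neurons_per_cluster = c(1, 0, 0), n_trials_per_condition = 30,
    response_gain = g, seed = 21))
  r <- baseline_rate(ds)
  b <- ds$neurons$baseline_rate_hz
  n_base_s <- nrow(ds$trials) * 0.5
  expect_lt(abs(r - b), 3 * sqrt(b / n_base_s))
})
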