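# shared fixtures: all synthetic, built in code at test time

# minimal aligned_activity / aligned_sdf built directly from a values matrix
# (bins x samples); index maps columns to neurons/trials
make_aligned <- function(values, time, neuron_id, trial_id,
                         class = "aligned_activity", event = "target",
                         sigma_ms = 20) {
  structure(list(values = values,
                 index = data.frame(neuron_id = neuron_id,
                                    trial_id = trial_id),
                 time = time, event = event, sigma_ms = sigma_ms,
                 baseline_window = c(min(time), 0),
                 excluded_neurons = character(0), method = "pooled"),
            class = class)
}

# small spike dataset for pipeline-level tests
tiny_dataset <- function(seed = 1, n_per = c(4, 4, 4), n_trials = 4) {
  simulate_dataset(simulation_config(n_neurons_per_cluster = n_per,
                                     n_trials_per_condition = n_trials,
                                     seed = seed))
}

# feature table with neuron-specific temporal signatures and per-neuron
# label imbalance independent of trial-level activity: the construction for
# demonstrating leakage under trial-level (non-grouped) cross-validation
make_leak_ft <- function(n_neurons = 30, n_trials = 40, nb = 300,
                         amp = 0.3, p_hi = 0.9, seed = 1) {
  set.seed(seed)
  base <- stats::rlnorm(n_neurons, log(0.02), 0.4)
  onset <- sample(30:230, n_neurons, TRUE)
  x <- matrix(0L, n_neurons * n_trials, nb)
  grp <- character(n_neurons * n_trials)
  ch <- character(n_neurons * n_trials)
  r <- 0
  for (i in seq_len(n_neurons)) {
    lam <- rep(base[i], nb)
    sel <- onset[i]:min(nb, onset[i] + 60)
    lam[sel] <- lam[sel] + amp
    p <- if (i %% 2 == 0) p_hi else 1 - p_hi
    for (t in seq_len(n_trials)) {
      r <- r + 1
      x[r, ] <- stats::rpois(nb, lam)
      grp[r] <- sprintf("n%02d", i)
      ch[r] <- if (stats::runif(1) < p) "accept" else "reject"
    }
  }
  structure(list(x = methods::as(Matrix::Matrix(x, sparse = TRUE),
                                 "CsparseMatrix"),
                 choice = factor(ch, levels = c("reject", "accept")),
                 rt_ms = rep(NA_real_, r), group = grp,
                 cluster = rep(1L, r), trial_id = as.character(seq_len(r)),
                 time = 0:(nb - 1), mode = "per_neuron"),
            class = "feature_table")
}

# trial response parameters with planted RT-latency slope and random
# intercepts for subject and neuron (recovery harness for the RT mixed model)
gen_rt_params <- function(b, seed, n_neurons = 20, n_trials = 20,
                          sd_monkey = 10, sd_neuron = 15, sd_resid = 25) {
  set.seed(seed)
  nid <- sprintf("n%02d", seq_len(n_neurons))
  monk <- rep(c("C", "S"), length.out = n_neurons)
  u_m <- stats::rnorm(2, 0, sd_monkey)
  u_n <- stats::rnorm(n_neurons, 0, sd_neuron)
  d <- data.frame(neuron_id = rep(nid, each = n_trials),
                  monkey_id = rep(monk, each = n_trials))
  i <- as.integer(factor(d$neuron_id))
  d$onset_ms <- stats::rnorm(nrow(d), 110, 15)
  d$rt_ms <- 150 + b * d$onset_ms +
    u_m[as.integer(factor(d$monkey_id))] + u_n[i] +
    stats::rnorm(nrow(d), 0, sd_resid)
  d
}

# small null-true mixed-model dataset for bootstrap calibration
gen_null_lmm_data <- function(seed, n_neurons = 8, n_obs = 4) {
  set.seed(seed)
  d <- expand.grid(neuron_id = sprintf("n%02d", seq_len(n_neurons)),
                   obs = seq_len(n_obs))
  d$cond <- factor(rep(c("a", "b", "c", "d"),
                       length.out = nrow(d)))
  u <- stats::rnorm(n_neurons, 0, 1)
  d$activity <- u[as.integer(factor(d$neuron_id))] + stats::rnorm(nrow(d))
  d
}

# O(N^2) brute-force mean silhouette (independent oracle)
brute_silhouette <- function(x, labels) {
  n <- nrow(x)
  D <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# brute-force pairwise AUC (independent oracle; ties count 1/2)
brute_auc <- function(y, score) {
  pos <- score[y == "accept"]; neg <- score[y == "reject"]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}
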