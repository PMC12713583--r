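#' Configuration for the synthetic choice-task spike generator
#'
#' Builds a validated configuration object for [simulate_dataset()].  The
#' generator emulates a population of task-responsive neurons recorded (one
#' neuron per session) while a subject performs a sequential value-guided
#' choice task: a background scene is shown for 1000 ms, followed by a 700-ms
#' central fixation period, after which a "good" (rewarded) or "bad"
#' (unrewarded) object appears in the contralateral or ipsilateral hemifield.
#' The subject accepts the object with a saccade or rejects it by a return
#' saccade, by staying at fixation, or by looking elsewhere.  Scenes 1-2 carry
#' stable object values; scenes 3-4 reverse the contingencies ("flexible"
#' scenes), which the generator expresses only through the choice policy.
#'
#' Each neuron belongs to one of three planted response profiles:
#' \describe{
#'   \item{1}{facilitative: firing increases for both object values, more for
#'     good objects;}
#'   \item{2}{bidirectional value coding: firing increases for good objects and
#'     decreases for bad objects;}
#'   \item{3}{firing increases for both values, more for bad objects.}
#' }
#' All profiles respond more strongly to contralateral targets.  A neuron's
#' firing rate is baseline before its per-trial response onset latency, then
#' ramps linearly over `ramp_ms` to a plateau of baseline + gain, rectified at
#' zero.  Reaction times on accept trials follow the planted linear model
#' `RT = intercept + slope * latency + noise`; reject-trial reaction times are
#' shifted slower and more variable.
#'
#' @param n_neurons_per_cluster integer vector of length 3, neurons per
#'   planted profile.
#' @param n_trials_per_condition trials per (scene, value, direction) cell,
#'   at least 2.
#' @param baseline_log_mean,baseline_log_sd parameters of the log-normal
#'   distribution of per-neuron baseline rates (Hz); the default median is
#'   15 Hz with moderate spread, typical of tonically active basal-ganglia
#'   units.
#' @param response_gain numeric array `3 x 2 x 2` (cluster x value x
#'   direction) of plateau gains in Hz added to baseline.
#' @param onset_latency_ms matrix `3 x 2` with columns `mean` and `sd`: the
#'   per-trial response onset latency distribution for each cluster (ms after
#'   target onset).
#' @param rt_model list with `intercept_ms`, `slope` (ms of RT per ms of
#'   onset latency), `resid_sd_ms` for accept trials, and `reject_shift_ms`,
#'   `reject_sd_ms` for the slower, wider reject-trial distribution.
#' @param choice_policy list with `good_accept` (accept probability for good
#'   objects, named `stable`/`flexible`) and `bad_strategy` (2 x 3 matrix of
#'   return/stay/other probabilities for bad objects, rows `stable` and
#'   `flexible`, each row summing to 1).
#' @param ramp_ms ramp duration from response onset to plateau (ms).
#' @param kernel_sigma_ms Gaussian kernel SD carried as metadata for
#'   downstream smoothing (ms).
#' @param scenes scene identifiers to simulate (subset of 1:4).
#' @param seed master integer seed; per-neuron streams are derived from it
#'   deterministically.
#' @return object of class `simulation_config`.
#' @seealso [simulate_dataset()], [sample_condition_rate()]
#' @export
simulation_config <- function(n_neurons_per_cluster = c(50L, 50L, 50L),
                              n_trials_per_condition = 20L,
                              baseline_log_mean = log(15),
                              baseline_log_sd = 0.4,
                              response_gain = default_response_gain(),
                              onset_latency_ms = cbind(mean = c(110, 95, 125),
                                                       sd = c(15, 15, 15)),
                              rt_model = list(intercept_ms = 150,
                                              slope = 0.4,
                                              resid_sd_ms = 25,
                                              reject_shift_ms = 60,
                                              reject_sd_ms = 40),
                              choice_policy = default_choice_policy(),
                              ramp_ms = 150,
                              kernel_sigma_ms = 20,
                              scenes = 1:4,
                              seed = 1L) {
  if (length(n_neurons_per_cluster) != 3L || any(n_neurons_per_cluster < 0))
    stop("n_neurons_per_cluster must be 3 non-negative integers")
  if (length(n_trials_per_condition) != 1L || n_trials_per_condition < 2)
    stop("n_trials_per_condition must be a single integer >= 2")
  if (!is.array(response_gain) || !identical(dim(response_gain), c(3L, 2L, 2L)))
    stop("response_gain must be a 3 x 2 x 2 array (cluster x value x direction)")
  dimnames(response_gain) <- list(cluster = 1:3,
                                  value = c("good", "bad"),
                                  direction = c("contra", "ipsi"))
  if (!is.matrix(onset_latency_ms) || nrow(onset_latency_ms) != 3L ||
      !all(c("mean", "sd") %in% colnames(onset_latency_ms)))
    stop("onset_latency_ms must be a 3-row matrix with columns 'mean' and 'sd'")
  if (any(onset_latency_ms[, "sd"] < 0))
    stop("onset latency SDs must be non-negative")
  ga <- choice_policy$good_accept
  bs <- choice_policy$bad_strategy
  if (any(ga < 0) || any(ga > 1))
    stop("accept probabilities must lie in [0, 1]")
  if (!is.matrix(bs) || ncol(bs) != 3L || any(bs < 0) || any(bs > 1) ||
      any(abs(rowSums(bs) - 1) > 1e-8))
    stop("bad_strategy rows must be probability vectors over (return, stay, other) summing to 1")
  if (!all(scenes %in% 1:4) || !length(scenes))
    stop("scenes must be a non-empty subset of 1:4")
  if (ramp_ms <= 0) stop("ramp_ms must be positive")
  if (kernel_sigma_ms <= 0) stop("kernel_sigma_ms must be positive")
  structure(list(n_neurons_per_cluster = as.integer(n_neurons_per_cluster),
                 n_trials_per_condition = as.integer(n_trials_per_condition),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 response_gain = response_gain,
                 onset_latency_ms = onset_latency_ms,
                 rt_model = rt_model,
                 choice_policy = choice_policy,
                 ramp_ms = ramp_ms,
                 kernel_sigma_ms = kernel_sigma_ms,
                 scenes = as.integer(scenes),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default plateau gains for the three planted response profiles
#'
#' Cluster 1 responds to both values with a good-object preference, cluster 2
#' is excited by good and suppressed by bad objects, cluster 3 prefers bad
#' objects.  Ipsilateral gains are half the contralateral ones, expressing the
#' contralateral preference of the recorded population.
#'
#' @return numeric array `3 x 2 x 2` (cluster x value x direction), Hz.
#' @export
default_response_gain <- function() {
  g <- array(0, dim = c(3L, 2L, 2L),
             dimnames = list(cluster = 1:3,
                             value = c("good", "bad"),
                             direction = c("contra", "ipsi")))
  g[1, "good", "contra"] <- 22; g[1, "bad", "contra"] <- 8
  g[2, "good", "contra"] <- 20; g[2, "bad", "contra"] <- -10
  g[3, "good", "contra"] <- 5;  g[3, "bad", "contra"] <- 20
  g[, , "ipsi"] <- g[, , "contra"] / 2
  g
}

#' Default choice policy
#'
#' Good objects are accepted with probability 0.95 (matching the high
#' discrimination accuracy typical of over-trained subjects).  Bad objects are
#' rejected via return/stay/other strategies; the stay strategy is used more
#' often in flexible-value scenes, so stay proportions differ between stable
#' and flexible scenes.
#'
#' @return list with elements `good_accept` and `bad_strategy`.
#' @export
default_choice_policy <- function() {
  list(good_accept = c(stable = 0.95, flexible = 0.95),
       bad_strategy = rbind(stable = c(return = 0.70, stay = 0.20, other = 0.10),
                            flexible = c(return = 0.55, stay = 0.33, other = 0.12)))
}

#' Deterministic condition rate function of the generator
#'
#' Returns the noiseless firing rate (Hz) of a neuron of the given planted
#' cluster for one condition at times `t` relative to target onset: baseline
#' before the response onset latency, then baseline + gain times a linear
#' ramp reaching its plateau `ramp_ms` later, rectified at zero.
#'
#' @param cluster planted profile label in 1:3.
#' @param value `"good"` or `"bad"`.
#' @param direction `"contra"` or `"ipsi"`.
#' @param t numeric vector of times (ms relative to target onset).
#' @param config a [simulation_config()].
#' @param onset_ms response onset latency for this trial (ms); defaults to the
#'   cluster's configured mean.
#' @param baseline_hz baseline rate; defaults to the median of the configured
#'   baseline distribution.
#' @return numeric vector of rates (Hz), same length as `t`.
#' @export
sample_condition_rate <- function(cluster, value, direction, t, config,
                                  onset_ms = config$onset_latency_ms[cluster, "mean"],
                                  baseline_hz = exp(config$baseline_log_mean)) {
  if (!cluster %in% 1:3) stop("unknown cluster label: ", cluster)
  value <- match.arg(value, c("good", "bad"))
  direction <- match.arg(direction, c("contra", "ipsi"))
  gain <- config$response_gain[cluster, value, direction]
  .ramp_rate(t, onset_ms, baseline_hz, gain, config$ramp_ms)
}

# rectified linear-ramp rate; vectorized over t / onset / gain
.ramp_rate <- function(t, onset, baseline, gain, ramp_ms) {
  frac <- pmin(pmax((t - onset) / ramp_ms, 0), 1)
  pmax(baseline + gain * frac, 0)
}

# fixed per-trial event clock (ms from trial start): spikes are simulated on
# [0, .trial_end); 500 ms of pre-scene time precedes scene onset, scene is
# shown for 1000 ms, fixation for 700 ms, then the target appears
.scene_on <- 500
.fix_on <- 1500
.target_on <- 2200
.trial_end <- 3100

#' Simulate a synthetic choice-task spike dataset with planted ground truth
#'
#' Generates spike trains for `sum(n_neurons_per_cluster)` neurons, each with
#' its own session of trials, as an inhomogeneous Poisson process (thinning)
#' whose rate is the neuron's baseline plus its cluster/condition response
#' ramp starting at a per-trial onset latency.  Choices follow the configured
#' policy; accept-trial reaction times follow the planted linear dependence on
#' the trial's onset latency, and reject reaction times are drawn slower and
#' wider.  Neurons are split between two subjects ("C", "S").
#'
#' Event times in the trial table are on a per-trial clock with scene onset at
#' 500 ms and target onset at 2200 ms, so spike times are non-negative and a
#' 500-ms pre-scene baseline period is always covered.
#'
#' @param config a [simulation_config()].
#' @return object of class `spike_dataset`: a list with
#' \describe{
#'   \item{spikes}{data.frame `neuron_id`, `trial_id`, `spike_time_ms` (trial
#'     clock), sorted within trial;}
#'   \item{trials}{data.frame `trial_id`, `neuron_id`, `monkey_id`, `scene`,
#'     `value`, `direction`, `choice`, `rt_ms`, `scene_on`, `fix_on`,
#'     `target_on`, `saccade_on` (`rt_ms`/`saccade_on` are `NA` on stay
#'     trials);}
#'   \item{neurons}{data.frame `neuron_id`, `monkey_id`, `true_cluster`,
#'     `baseline_rate_hz`;}
#'   \item{truth}{list `true_cluster` (named integer vector),
#'     `true_onset` (data.frame `neuron_id`, `trial_id`, `onset_latency_ms`),
#'     `true_rt_slope`, `true_divergence_time_ms` (cluster mean onset
#'     latencies, the planted separation times under zero latency SD);}
#'   \item{config}{the configuration used.}
#' }
#' @examples
#' cfg <- simulation_config(n_neurons_per_cluster = c(2, 2, 2),
#'                          n_trials_per_condition = 2, seed = 7)
#' ds <- simulate_dataset(cfg)
#' head(ds$trials)
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("config must be a simulation_config object")
  set.seed(config$seed)
  n_per <- config$n_neurons_per_cluster
  n_neurons <- sum(n_per)
  if (n_neurons == 0L) stop("configuration yields zero neurons")
  true_cluster <- rep.int(1:3, n_per)
  neuron_id <- sprintf("n%03d", seq_len(n_neurons))
  monkey_id <- rep(c("C", "S"), length.out = n_neurons)
  baseline <- stats::rlnorm(n_neurons, config$baseline_log_mean, config$baseline_log_sd)
  neuron_seed <- sample.int(.Machine$integer.max - 1L, n_neurons)

  grid <- expand.grid(scene = config$scenes,
                      value = c("good", "bad"),
                      direction = c("contra", "ipsi"),
                      stringsAsFactors = FALSE)
  grid <- grid[rep(seq_len(nrow(grid)), each = config$n_trials_per_condition), ]
  n_tr <- nrow(grid)

  spikes_l <- vector("list", n_neurons)
  trials_l <- vector("list", n_neurons)
  onset_l <- vector("list", n_neurons)
  trial_counter <- 0L

  for (i in seq_len(n_neurons)) {
    set.seed(neuron_seed[i])
    cl <- true_cluster[i]
    tr <- grid
    tr$trial_id <- sprintf("%s_t%04d", neuron_id[i], seq_len(n_tr))
    trial_counter <- trial_counter + n_tr

    lat <- stats::rnorm(n_tr, config$onset_latency_ms[cl, "mean"],
                        config$onset_latency_ms[cl, "sd"])
    lat <- pmax(lat, 30)

    flexible <- tr$scene %in% 3:4
    regime <- ifelse(flexible, "flexible", "stable")
    p_acc <- config$choice_policy$good_accept[regime]
    choice <- character(n_tr)
    good <- tr$value == "good"
    u <- stats::runif(n_tr)
    choice[good] <- ifelse(u[good] < p_acc[good], "accept", "reject_return")
    if (any(!good)) {
      bs <- config$choice_policy$bad_strategy
      cum <- t(apply(bs, 1, cumsum))
      ub <- u[!good]
      rb <- regime[!good]
      pick <- 1L + (ub > cum[rb, 1]) + (ub > cum[rb, 2])
      choice[!good] <- paste0("reject_", c("return", "stay", "other")[pick])
    }

    rtm <- config$rt_model
    rt_mu <- rtm$intercept_ms + rtm$slope * lat
    rt <- ifelse(choice == "accept",
                 stats::rnorm(n_tr, rt_mu, rtm$resid_sd_ms),
                 stats::rnorm(n_tr, rt_mu + rtm$reject_shift_ms, rtm$reject_sd_ms))
    rt <- pmax(rt, 60)
    rt[choice == "reject_stay"] <- NA_real_

    tr$choice <- choice
    tr$rt_ms <- rt
    tr$scene_on <- .scene_on
    tr$fix_on <- .fix_on
    tr$target_on <- .target_on
    tr$saccade_on <- .target_on + rt
    tr$neuron_id <- neuron_id[i]
    tr$monkey_id <- monkey_id[i]

    gain <- config$response_gain[cbind(cl, match(tr$value, c("good", "bad")),
                                       match(tr$direction, c("contra", "ipsi")))]
    onset_abs <- .target_on + lat
    rmax <- baseline[i] + pmax(gain, 0)
    n_cand <- stats::rpois(n_tr, rmax * .trial_end / 1000)
    tot <- sum(n_cand)
    if (tot > 0L) {
      idx <- rep.int(seq_len(n_tr), n_cand)
      tt <- stats::runif(tot, 0, .trial_end)
      rate <- .ramp_rate(tt, onset_abs[idx], baseline[i], gain[idx], config$ramp_ms)
      keep <- stats::runif(tot) < rate / rmax[idx]
      idx <- idx[keep]; tt <- tt[keep]
      o <- order(idx, tt)
      spikes_l[[i]] <- list(trial_id = tr$trial_id[idx[o]],
                            spike_time_ms = tt[o])
    }
    trials_l[[i]] <- tr
    onset_l[[i]] <- data.frame(neuron_id = neuron_id[i],
                               trial_id = tr$trial_id,
                               onset_latency_ms = lat)
  }

  trials <- do.call(rbind, trials_l)
  rownames(trials) <- NULL
  trials <- trials[, c("trial_id", "neuron_id", "monkey_id", "scene", "value",
                       "direction", "choice", "rt_ms", "scene_on", "fix_on",
                       "target_on", "saccade_on")]
  n_sp <- vapply(spikes_l, function(s) if (is.null(s)) 0L else
    length(s$spike_time_ms), integer(1))
  spikes <- data.frame(
    neuron_id = rep(neuron_id, n_sp),
    trial_id = unlist(lapply(spikes_l, `[[`, "trial_id"), use.names = FALSE),
    spike_time_ms = unlist(lapply(spikes_l, `[[`, "spike_time_ms"),
                           use.names = FALSE))
  neurons <- data.frame(neuron_id = neuron_id, monkey_id = monkey_id,
                        true_cluster = true_cluster,
                        baseline_rate_hz = baseline)
  truth <- list(true_cluster = stats::setNames(true_cluster, neuron_id),
                true_onset = do.call(rbind, onset_l),
                true_rt_slope = config$rt_model$slope,
                true_divergence_time_ms =
                  stats::setNames(config$onset_latency_ms[, "mean"], 1:3))
  rownames(truth$true_onset) <- NULL
  structure(list(spikes = spikes, trials = trials, neurons = neurons,
                 truth = truth, config = config),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat("<spike_dataset>\n")
  cat("  neurons:", nrow(x$neurons),
      sprintf("(clusters %s)", paste(table(x$neurons$true_cluster), collapse = "/")), "\n")
  cat("  trials :", nrow(x$trials), "\n")
  cat("  spikes :", nrow(x$spikes), "\n")
  invisible(x)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat("  neurons per cluster:", paste(x$n_neurons_per_cluster, collapse = "/"), "\n")
  cat("  trials per condition:", x$n_trials_per_condition,
      "| scenes:", paste(x$scenes, collapse = ","), "\n")
  cat("  rt model: RT =", x$rt_model$intercept_ms, "+",
      x$rt_model$slope, "* latency + noise\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
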