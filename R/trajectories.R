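#' Trial-averaged, baseline-corrected condition matrices for one cluster
#'
#' For every neuron of a cluster with at least one contralateral accept and
#' one contralateral reject trial, computes the trial-averaged spike density
#' function per choice and subtracts each row's pre-target baseline mean.
#' Neurons lacking a choice class are excluded from both matrices.
#'
#' @param sdf target-aligned `aligned_sdf` (unscaled spike densities).
#' @param trials trial table.
#' @param neuron_ids neurons belonging to the cluster (default: all).
#' @param baseline_window `c(a, b)` ms used for the row-wise baseline
#'   correction.
#' @param reject_strategies choices counted as reject.
#' @return list with `accept` and `reject` (neurons x time matrices on a
#'   common axis), `time`, `excluded` neuron ids.
#' @export
build_condition_matrices <- function(sdf, trials, neuron_ids = NULL,
                                     baseline_window = c(-600, 0),
                                     reject_strategies = c("reject_return",
                                                           "reject_stay",
                                                           "reject_other")) {
  if (!inherits(sdf, "aligned_sdf")) stop("sdf must be an aligned_sdf")
  if (is.null(neuron_ids)) neuron_ids <- unique(sdf$index$neuron_id)
  bsel <- sdf$time >= baseline_window[1] & sdf$time < baseline_window[2]
  ctr <- trials[trials$direction == "contra", ]
  acc_l <- list(); rej_l <- list(); excluded <- character(0)
  for (nid in neuron_ids) {
    cols <- which(sdf$index$neuron_id == nid)
    if (!length(cols)) { excluded <- c(excluded, nid); next }
    ch <- ctr$choice[match(sdf$index$trial_id[cols], ctr$trial_id)]
    a <- cols[!is.na(ch) & ch == "accept"]
    r <- cols[!is.na(ch) & ch %in% reject_strategies]
    if (!length(a) || !length(r)) { excluded <- c(excluded, nid); next }
    ra <- rowMeans(sdf$values[, a, drop = FALSE])
    rr <- rowMeans(sdf$values[, r, drop = FALSE])
    acc_l[[nid]] <- ra - mean(ra[bsel])
    rej_l[[nid]] <- rr - mean(rr[bsel])
  }
  if (!length(acc_l)) stop("no neuron has both choice classes")
  list(accept = do.call(rbind, acc_l), reject = do.call(rbind, rej_l),
       time = sdf$time, excluded = excluded)
}

#' Population trajectories in a shared principal-component space
#'
#' Fits a single PCA to the concatenation of the accept and reject condition
#' matrices (time points as observations, neurons as variables; centered,
#' unscaled), projects both conditions onto the first three components and
#' computes the Euclidean distance between the two trajectories at each time
#' step.
#'
#' @param accept,reject neurons x time matrices on a common time axis.
#' @param time time axis (ms relative to target onset).
#' @return object of class `trajectory_model`: list with `time`,
#'   `traj_accept`, `traj_reject` (T x npc score matrices), `distance`,
#'   `var_explained`, `npc` (3, or fewer with a flag `rank_deficient` when
#'   the data span fewer dimensions).
#' @export
fit_trajectories <- function(accept, reject, time) {
  if (!identical(dim(accept), dim(reject)))
    stop("accept and reject matrices must have identical shape")
  Tn <- ncol(accept)
  X <- rbind(t(accept), t(reject))           # (2T) x neurons
  X <- scale(X, center = TRUE, scale = FALSE)
  p <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  npc <- min(3L, sum(p$sdev > 1e-10))
  rank_deficient <- npc < 3L
  sco <- p$x[, seq_len(npc), drop = FALSE]
  ta <- sco[seq_len(Tn), , drop = FALSE]
  tr <- sco[Tn + seq_len(Tn), , drop = FALSE]
  structure(list(time = time, traj_accept = ta, traj_reject = tr,
                 distance = sqrt(rowSums((ta - tr)^2)),
                 var_explained = p$sdev^2 / sum(p$sdev^2),
                 npc = npc, rank_deficient = rank_deficient),
            class = "trajectory_model")
}

#' Divergence time of accept and reject trajectories
#'
#' The first post-target time point at which the inter-trajectory distance
#' exceeds three standard deviations above its mean over a pre-target
#' baseline window.  Returns `NA` when no such point exists.  When the
#' baseline distance is identically zero, any positive post-target distance
#' diverges at its first sample (degenerate noiseless case).
#'
#' @param model a `trajectory_model`.
#' @param baseline_window `c(a, b)` ms, before target onset.
#' @param n_sd threshold in baseline SDs (default 3).
#' @return list with `divergence_ms` (or `NA`), `mu_d`, `sd_d`, `threshold`.
#' @export
divergence_time <- function(model, baseline_window = c(-600, 0), n_sd = 3) {
  if (baseline_window[2] > 0) stop("baseline window must precede target onset")
  bsel <- model$time >= baseline_window[1] & model$time < baseline_window[2]
  if (!any(bsel)) stop("baseline window outside the time axis")
  mu <- mean(model$distance[bsel])
  s <- stats::sd(model$distance[bsel])
  thr <- mu + n_sd * s
  post <- which(model$time >= 0 & model$distance > thr)
  list(divergence_ms = if (length(post)) model$time[post[1]] else NA_real_,
       mu_d = mu, sd_d = s, threshold = thr)
}

#' Per-cluster trajectory divergence from a spike dataset
#'
#' Convenience wrapper: computes target-aligned SDFs, builds per-cluster
#' accept/reject condition matrices, fits the shared-PCA trajectories and
#' extracts the divergence time for each cluster.
#'
#' @param dataset a `spike_dataset`.
#' @param assignments named cluster labels per neuron.
#' @param window aligned analysis window (ms around target onset).
#' @param sigma_ms Gaussian kernel SD.
#' @param baseline_window pre-target window for baseline correction and the
#'   divergence threshold.
#' @return data.frame `cluster`, `n_neurons`, `divergence_ms`.
#' @export
cluster_divergence <- function(dataset, assignments, window = c(-700, 400),
                               sigma_ms = 20, baseline_window = c(-600, 0)) {
  sdf <- compute_sdf(align_and_bin(dataset, event = "target", window = window),
                     sigma_ms)
  out <- lapply(sort(unique(assignments)), function(cl) {
    ids <- names(assignments)[assignments == cl]
    cm <- build_condition_matrices(sdf, dataset$trials, ids,
                                   baseline_window = baseline_window)
    tm <- fit_trajectories(cm$accept, cm$reject, cm$time)
    dv <- divergence_time(tm, baseline_window = baseline_window)
    data.frame(cluster = cl, n_neurons = nrow(cm$accept),
               divergence_ms = dv$divergence_ms)
  })
  do.call(rbind, out)
}
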