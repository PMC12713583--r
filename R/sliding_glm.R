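#' Sliding-window regression of activity on choice
#'
#' At each window position the per-trial mean z-scored activity in a 50-ms
#' window is regressed on the upcoming choice, coded +1 for accept and -1
#' for reject (`MeanActivity = b0 + bAction * Action`).  The window is moved
#' in 1-ms steps; coefficients are reported at window centers for which the
#' full window fits inside the time axis.  With this coding and balanced
#' classes, `bAction` equals half the difference between the accept and
#' reject class means; the implementation is exact least squares for
#' unbalanced classes too.
#'
#' @param z numeric matrix of z-scored activity, trials x time bins.
#' @param time time axis (1-ms bin left edges).
#' @param action numeric vector (+1 accept / -1 reject), one per trial; both
#'   classes must be present.
#' @param window_ms window length (ms).
#' @param step_ms step between window positions (ms).
#' @return object of class `beta_series`: list with `time` (window centers),
#'   `beta0`, `beta_action`.
#' @export
sliding_beta <- function(z, time, action, window_ms = 50L, step_ms = 1L) {
  if (!all(sort(unique(action)) %in% c(-1, 1)) || length(unique(action)) < 2L)
    stop("action must contain both +1 and -1")
  if (nrow(z) != length(action)) stop("one action code per trial required")
  L <- as.integer(window_ms)
  nb <- ncol(z)
  if (nb < L) stop("window longer than the time axis")
  starts <- seq.int(1L, nb - L + 1L, by = as.integer(step_ms))
  # rolling window means per trial via cumulative sums
  cs <- cbind(0, t(apply(z, 1, cumsum)))
  y <- (cs[, starts + L, drop = FALSE] - cs[, starts, drop = FALSE]) / L
  x <- action
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  beta_action <- as.vector(crossprod(xc, y)) / sxx
  beta0 <- colMeans(y) - beta_action * mean(x)
  structure(list(time = time[starts] + (L - 1) / 2,
                 beta0 = beta0, beta_action = beta_action),
            class = "beta_series")
}

#' Sliding choice-regression series for a population
#'
#' Runs [sliding_beta()] on the contralateral trials of every neuron,
#' skipping (with a warning) neurons lacking either choice class.  Reject
#' trials include all rejection strategies by default.
#'
#' @param aligned target-aligned `aligned_activity`.
#' @param trials trial table.
#' @param reject_strategies choices counted as reject.
#' @param window_ms,step_ms see [sliding_beta()].
#' @return list with `beta` (neurons x positions matrix of action
#'   coefficients), `time` (window centers), `skipped` neuron ids.
#' @export
sliding_beta_population <- function(aligned, trials,
                                    reject_strategies = c("reject_return",
                                                          "reject_stay",
                                                          "reject_other"),
                                    window_ms = 50L, step_ms = 1L) {
  ctr <- trials[trials$direction == "contra", ]
  rows <- list(); skipped <- character(0); tax <- NULL
  for (nid in neuron_ids(aligned)) {
    m <- neuron_matrix(aligned, nid)
    ch <- ctr$choice[match(rownames(m), ctr$trial_id)]
    act <- ifelse(is.na(ch), NA_real_,
                  ifelse(ch == "accept", 1,
                         ifelse(ch %in% reject_strategies, -1, NA_real_)))
    keep <- !is.na(act)
    if (length(unique(act[keep])) < 2L) { skipped <- c(skipped, nid); next }
    bs <- sliding_beta(m[keep, , drop = FALSE], aligned$time, act[keep],
                       window_ms, step_ms)
    rows[[nid]] <- bs$beta_action
    tax <- bs$time
  }
  if (length(skipped))
    warning(length(skipped), " neuron(s) without both choice classes skipped")
  list(beta = do.call(rbind, rows), time = tax, skipped = skipped)
}

# centered moving average preserving series length; edge windows use the
# available points only (partial means)
.moving_average <- function(x, n = 21L) {
  h <- (n - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  N <- length(x)
  lo <- pmax(seq_len(N) - h, 1L)
  hi <- pmin(seq_len(N) + h, N)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth and sort choice-regression series for display
#'
#' Smooths each neuron's action-coefficient series with a centered 21-ms
#' moving average (edges use partial windows, preserving length), then sorts
#' neurons first by response preference (sign of the coefficient at its
#' largest post-target magnitude; accept-preferring first) and within sign by
#' encoding latency, the first time the smoothed magnitude exceeds twice the
#' SD of the neuron's pre-target coefficients.  Neurons never exceeding the
#' threshold sort last within their sign group.
#'
#' @param beta neurons x positions matrix of action coefficients.
#' @param time window-center time axis.
#' @param ma_ms moving-average length (ms).
#' @return list with `smoothed` (sorted matrix), `order`, `preference`,
#'   `latency_ms` (in original row order; `Inf` when never above threshold).
#' @export
smooth_and_sort <- function(beta, time, ma_ms = 21L) {
  sm <- t(apply(beta, 1, .moving_average, n = as.integer(ma_ms)))
  pre <- time < 0
  post <- time >= 0
  pref <- numeric(nrow(sm)); lat <- numeric(nrow(sm))
  for (i in seq_len(nrow(sm))) {
    v <- sm[i, ]
    pk <- which.max(abs(v[post]))
    pref[i] <- sign(v[post][pk])
    thr <- 2 * stats::sd(v[pre])
    hit <- which(post & abs(v) > thr)
    lat[i] <- if (length(hit)) time[hit[1]] else Inf
  }
  pref[pref == 0] <- -1  # all-zero series sort with the reject group, last
  o <- order(-pref, lat)
  list(smoothed = sm[o, , drop = FALSE], order = o,
       preference = pref, latency_ms = lat, time = time)
}
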