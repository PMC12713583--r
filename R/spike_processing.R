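#' Align spike trains to a task event and bin them at 1 ms
#'
#' For every trial that has a time for the requested event, spike times are
#' re-expressed relative to that event and counted into half-open 1-ms bins:
#' bin `b` covers `[t0 + b, t0 + b + 1)` ms.  Trials whose event time is
#' missing (e.g. saccade onset on stay trials) are excluded with a warning.
#'
#' Aligned containers are matrix-backed for efficiency: `values` holds one
#' column per (neuron, trial) sample with time bins in rows, and `index`
#' maps columns to neurons and trials.  [neuron_matrix()] recovers the
#' conventional trials x bins matrix of one neuron.
#'
#' @param spikes a `spike_dataset` or a data.frame with columns `neuron_id`,
#'   `trial_id`, `spike_time_ms`.
#' @param trials trial table (taken from the dataset when `spikes` is a
#'   `spike_dataset` and `trials` is `NULL`); must contain `trial_id`,
#'   `neuron_id` and the event-time column.
#' @param event one of `"scene"`, `"target"`, `"saccade"`.
#' @param window numeric `c(t0, t1)` in ms relative to the event; bins cover
#'   `[t0, t1)`.
#' @return object of class `aligned_counts`: list with `values` (integer
#'   matrix, bins x samples), `index` (data.frame `neuron_id`, `trial_id`
#'   per column), `time` (bin left edges), `event`, `window`, `n_excluded`.
#' @export
align_and_bin <- function(spikes, trials = NULL,
                          event = c("target", "scene", "saccade"), window) {
  if (inherits(spikes, "spike_dataset")) {
    if (is.null(trials)) trials <- spikes$trials
    spikes <- spikes$spikes
  }
  event <- match.arg(event)
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(t0, t1) with t0 < t1")
  ev_col <- paste0(event, "_on")
  if (!ev_col %in% names(trials)) stop("trials lack column ", ev_col)
  t0 <- window[1]; t1 <- window[2]
  nbins <- as.integer(t1 - t0)
  ev <- trials[[ev_col]]
  excl <- is.na(ev)
  if (any(excl))
    warning(sum(excl), " trial(s) excluded: missing ", ev_col)
  keep <- trials[!excl, , drop = FALSE]
  ev <- ev[!excl]
  o <- order(keep$neuron_id)        # stable: trials stay in table order
  keep <- keep[o, , drop = FALSE]
  ev <- ev[o]
  ns <- nrow(keep)

  col <- match(spikes$trial_id, keep$trial_id)
  ok <- !is.na(col)
  rel <- spikes$spike_time_ms[ok] - ev[col[ok]]
  inb <- rel >= t0 & rel < t1
  bin_idx <- floor(rel[inb] - t0) + 1L
  lin <- (col[ok][inb] - 1L) * nbins + bin_idx
  values <- matrix(tabulate(lin, nbins = nbins * ns), nrow = nbins)

  structure(list(values = values,
                 index = data.frame(neuron_id = keep$neuron_id,
                                    trial_id = keep$trial_id),
                 time = seq.int(t0, t1 - 1L),
                 event = event, window = c(t0, t1),
                 n_excluded = sum(excl)),
            class = "aligned_counts")
}

#' Per-neuron trials-by-bins matrix from an aligned container
#'
#' @param aligned an `aligned_counts`, `aligned_sdf` or `aligned_activity`.
#' @param neuron_id neuron to extract.
#' @return numeric matrix trials x bins with trial ids as rownames.
#' @export
neuron_matrix <- function(aligned, neuron_id) {
  cols <- which(aligned$index$neuron_id == neuron_id)
  if (!length(cols)) stop("unknown neuron: ", neuron_id)
  m <- t(aligned$values[, cols, drop = FALSE])
  rownames(m) <- aligned$index$trial_id[cols]
  m
}

#' Neuron identifiers present in an aligned container
#'
#' @param aligned an aligned container.
#' @return character vector of neuron ids.
#' @export
neuron_ids <- function(aligned) unique(aligned$index$neuron_id)

# unit-area Gaussian kernel on the 1-ms grid, truncated at +/- 4 sigma
.gauss_kernel <- function(sigma_ms) {
  m <- ceiling(4 * sigma_ms)
  k <- stats::dnorm(seq.int(-m, m), 0, sigma_ms)
  k / sum(k)
}

# FFT "same"-length convolution of each column of X (bins x series) with a
# symmetric kernel; edges zero-padded (no mass renormalization)
.smooth_cols <- function(X, kernel) {
  nb <- nrow(X)
  m <- (length(kernel) - 1L) / 2L
  P <- stats::nextn(nb + 2L * m)
  Xp <- rbind(X, matrix(0, P - nb, ncol(X)))
  kp <- c(kernel, rep(0, P - length(kernel)))
  Y <- Re(stats::mvfft(stats::mvfft(Xp) * as.vector(stats::fft(kp)),
                       inverse = TRUE)) / P
  Y[(m + 1L):(m + nb), , drop = FALSE]
}

#' Spike density function by Gaussian smoothing of 1-ms counts
#'
#' Converts binned counts to rates (spikes/s) and convolves with a unit-area
#' Gaussian kernel (truncated at 4 SD, zero-padded edges).  Smoothing
#' conserves total spike mass away from the window edges.
#'
#' @param counts an `aligned_counts` object, a numeric matrix (trials x
#'   bins), or a numeric vector of 1-ms counts.
#' @param sigma_ms kernel SD in ms (default 20).
#' @return same shape as the input, in spikes/s; for `aligned_counts` input,
#'   an object of class `aligned_sdf` with the same matrix-backed structure.
#' @export
compute_sdf <- function(counts, sigma_ms = 20) {
  if (sigma_ms <= 0) stop("sigma_ms must be positive")
  k <- .gauss_kernel(sigma_ms)
  if (inherits(counts, "aligned_counts")) {
    out <- counts
    # counts are sparse: compiled direct convolution; x1000 folded into the
    # kernel converts counts/ms to spikes/s without an extra pass
    out$values <- .smooth_counts_cpp(counts$values, k * 1000)
    out$sigma_ms <- sigma_ms
    class(out) <- "aligned_sdf"
    return(out)
  }
  if (is.matrix(counts)) return(t(.smooth_cols(t(counts) * 1000, k)))
  drop(.smooth_cols(matrix(as.numeric(counts) * 1000, ncol = 1), k))
}

#' Baseline z-transformation of spike density functions
#'
#' Standardizes each neuron's SDF by the mean and SD of its activity in a
#' pre-event baseline window.  By default the statistics are pooled across
#' all of the neuron's trials (all baseline bins of all trials), which is
#' stable for low-rate neurons; `method = "per_trial"` standardizes each
#' trial by its own baseline instead.  Neurons (or, per-trial, trials) whose
#' baseline SD is zero - silent or constant units - are excluded with a
#' warning and listed in `excluded_neurons`.
#'
#' @param sdf an `aligned_sdf` object.
#' @param baseline_window `c(a, b)` ms relative to the aligned event,
#'   covering `[a, b)`; default the 500 ms preceding the event.
#' @param method `"pooled"` (default) or `"per_trial"`.
#' @return object of class `aligned_activity`: matrix-backed container with
#'   `values` (z units), `index`, `time`, `baseline_stats` (neuron_id, mu,
#'   sd), `excluded_neurons`, `sigma_ms`, `method`.
#' @export
zscore_activity <- function(sdf, baseline_window = c(-500, 0),
                            method = c("pooled", "per_trial")) {
  if (!inherits(sdf, "aligned_sdf")) stop("sdf must be an aligned_sdf object")
  method <- match.arg(method)
  bsel <- sdf$time >= baseline_window[1] & sdf$time < baseline_window[2]
  if (!any(bsel)) stop("baseline window lies outside the aligned window")
  nid <- sdf$index$neuron_id
  base <- sdf$values[bsel, , drop = FALSE]
  if (method == "pooled") {
    nb <- sum(bsel)
    s1 <- rowsum(colSums(base), nid)                 # per-neuron sums
    s2 <- rowsum(colSums(base^2), nid)
    n <- as.vector(table(factor(nid, levels = rownames(s1)))) * nb
    mu <- as.vector(s1) / n
    sd_ <- sqrt(pmax((as.vector(s2) - n * mu^2) / (n - 1), 0))
    stats_df <- data.frame(neuron_id = rownames(s1), mu = mu, sd = sd_)
    bad <- stats_df$neuron_id[!is.finite(sd_) | sd_ < 1e-12]
    keep_col <- !(nid %in% bad)
    x <- if (length(bad)) sdf$values[, keep_col, drop = FALSE] else sdf$values
    i <- match(nid[keep_col], stats_df$neuron_id)
    vals <- .zscale_cols_cpp(x, stats_df$mu[i], stats_df$sd[i])
    stats_df <- stats_df[!stats_df$neuron_id %in% bad, ]
  } else {
    mu <- colMeans(base)
    sd_ <- sqrt(pmax(colMeans(base^2) - mu^2, 0) * nrow(base) / (nrow(base) - 1))
    bad_col <- !is.finite(sd_) | sd_ < 1e-12
    bad <- unique(nid[bad_col])
    keep_col <- !(nid %in% bad)
    vals <- .zscale_cols_cpp(sdf$values[, keep_col, drop = FALSE],
                             mu[keep_col], sd_[keep_col])
    stats_df <- data.frame(neuron_id = unique(nid[keep_col]))
    stats_df$mu <- as.vector(rowsum(mu[keep_col], nid[keep_col])[stats_df$neuron_id, ]) /
      as.vector(table(factor(nid[keep_col], levels = stats_df$neuron_id)))
    stats_df$sd <- NA_real_
  }
  if (length(bad))
    warning(length(bad),
            " neuron(s) excluded from z-scoring (zero baseline SD): ",
            paste(bad, collapse = ", "))
  structure(list(values = vals,
                 index = sdf$index[keep_col, , drop = FALSE],
                 time = sdf$time, event = sdf$event,
                 baseline_stats = stats_df,
                 baseline_window = baseline_window,
                 excluded_neurons = as.character(bad),
                 sigma_ms = sdf$sigma_ms, method = method),
            class = "aligned_activity")
}

#' Mean activity over a time epoch
#'
#' Arithmetic mean over the 1-ms bins in the half-open epoch `[a, b)`.
#'
#' @param x numeric vector, matrix (rows = trials), or an aligned container
#'   (`aligned_activity` / `aligned_sdf`).
#' @param epoch `c(a, b)` in ms on the object's time axis.
#' @param time time axis (bin left edges); taken from the object when `x` is
#'   an aligned container.
#' @return vector input: scalar.  Matrix: one mean per row.  Aligned
#'   container: data.frame `neuron_id`, `trial_id`, `value` with one row per
#'   (neuron, trial) sample.
#' @export
epoch_mean <- function(x, epoch, time = NULL) {
  if (length(epoch) != 2L || epoch[1] >= epoch[2]) stop("empty epoch")
  if (inherits(x, c("aligned_activity", "aligned_sdf", "aligned_counts"))) {
    sel <- x$time >= epoch[1] & x$time < epoch[2]
    if (!any(sel)) stop("epoch outside the time axis")
    out <- x$index
    out$value <- colMeans(x$values[sel, , drop = FALSE])
    rownames(out) <- NULL
    return(out)
  }
  if (is.null(time)) stop("time axis required for vector/matrix input")
  sel <- time >= epoch[1] & time < epoch[2]
  if (!any(sel)) stop("epoch outside the time axis")
  if (is.matrix(x)) return(rowMeans(x[, sel, drop = FALSE]))
  mean(x[sel])
}

#' Baseline firing rate per neuron
#'
#' Total spikes in the 500-ms pre-scene baseline period across trials,
#' divided by the total baseline time.
#'
#' @param spikes a `spike_dataset` or spike table.
#' @param trials trial table (taken from the dataset if omitted).
#' @param window_ms length of the pre-scene baseline period (ms).
#' @return named numeric vector of rates (Hz), one per neuron appearing in
#'   the trial table.
#' @export
baseline_rate <- function(spikes, trials = NULL, window_ms = 500) {
  if (inherits(spikes, "spike_dataset")) {
    if (is.null(trials)) trials <- spikes$trials
    spikes <- spikes$spikes
  }
  if (!nrow(trials)) stop("empty trial table")
  ev <- trials$scene_on
  tr_row <- match(spikes$trial_id, trials$trial_id)
  ok <- !is.na(tr_row)
  rel <- spikes$spike_time_ms[ok] - ev[tr_row[ok]]
  inb <- rel >= -window_ms & rel < 0
  cnt <- table(factor(spikes$neuron_id[ok][inb],
                      levels = unique(trials$neuron_id)))
  n_tr <- table(factor(trials$neuron_id, levels = unique(trials$neuron_id)))
  rate <- as.vector(cnt) / (as.vector(n_tr) * window_ms / 1000)
  stats::setNames(rate, names(cnt))
}

#' One-call event-aligned z-scored activity
#'
#' Convenience composition of [align_and_bin()], [compute_sdf()] and
#' [zscore_activity()].
#'
#' @inheritParams align_and_bin
#' @inheritParams zscore_activity
#' @param sigma_ms Gaussian kernel SD (ms).
#' @return an `aligned_activity` object.
#' @export
aligned_activity <- function(spikes, trials = NULL, event = "target",
                             window = c(-700, 500), sigma_ms = 20,
                             baseline_window = c(-500, 0),
                             method = "pooled") {
  ac <- align_and_bin(spikes, trials, event, window)
  zscore_activity(compute_sdf(ac, sigma_ms), baseline_window, method)
}
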