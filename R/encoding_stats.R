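#' Condition-mean activity table for mixed-effects modelling
#'
#' Epoch-mean z-scored activity per neuron x scene x value x direction,
#' trial-averaged within each cell, with subject and neuron identifiers for
#' the random-effects structure.
#'
#' @param aligned an `aligned_activity` object.
#' @param trials trial table (must carry `monkey_id`).
#' @param epoch `c(a, b)` ms on the aligned time axis.
#' @return data.frame with columns `monkey_id`, `neuron_id`, `scene`,
#'   `value`, `direction`, `activity` (factors for the design columns).
#' @export
build_condition_table <- function(aligned, trials, epoch) {
  em <- epoch_mean(aligned, epoch)
  names(em)[names(em) == "value"] <- "activity"
  em <- merge(em, trials[, c("trial_id", "monkey_id", "scene", "value",
                             "direction")], by = "trial_id")
  agg <- stats::aggregate(activity ~ monkey_id + neuron_id + scene + value + direction,
                          data = em, FUN = mean)
  agg$scene <- factor(agg$scene)
  agg$value <- factor(agg$value, levels = c("good", "bad"))
  agg$direction <- factor(agg$direction, levels = c("contra", "ipsi"))
  agg
}

#' Mixed-effects model of condition effects on normalized activity
#'
#' Fits `activity ~ scene * value * direction + (1 | monkey_id) +
#' (1 | monkey_id:neuron_id)` by REML.  With only two subjects the subject
#' intercept variance is weakly identified; the fit proceeds with a
#' boundary-tolerant optimizer and singular fits are flagged rather than
#' hidden.
#'
#' @param table output of [build_condition_table()] (or any data.frame with
#'   those columns).
#' @return list of class `activity_lmm`: `fit` (a `lmerModLmerTest`),
#'   `singular` flag, `fixed` (coefficient table with Satterthwaite tests).
#' @export
fit_activity_lmm <- function(table) {
  fit <- lmerTest::lmer(
    activity ~ scene * value * direction + (1 | monkey_id) + (1 | monkey_id:neuron_id),
    data = table, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE))
  structure(list(fit = fit,
                 singular = lme4::isSingular(fit),
                 fixed = stats::coef(summary(fit))),
            class = "activity_lmm")
}

#' @export
print.activity_lmm <- function(x, ...) {
  cat("<activity_lmm>", if (x$singular) "(singular random effects)\n" else "\n")
  print(round(x$fixed, 4))
  invisible(x)
}

#' Parametric bootstrap comparison of nested mixed models
#'
#' Computes the observed likelihood-ratio statistic between a full and a
#' nested null model (both refitted by maximum likelihood), then simulates
#' `n_boot` response vectors from the fitted null, refits both models to each
#' and returns `p = (1 + #\{LR_sim >= LR_obs\}) / (n_successful + 1)`.
#' Refit failures are counted and excluded.
#'
#' @param full,null fitted `merMod` objects (or `activity_lmm` wrappers);
#'   `null` must be nested in `full`.
#' @param n_boot number of bootstrap simulations (10000 at full scale; 999 is
#'   a practical default for routine runs).
#' @param seed integer seed.
#' @return list with `p`, `lr_obs`, `lr_sim`, `n_failed`.
#' @export
parametric_bootstrap_test <- function(full, null, n_boot = 999L, seed = 1L) {
  if (inherits(full, "activity_lmm")) full <- full$fit
  if (inherits(null, "activity_lmm")) null <- null$fit
  fullML <- if (lme4::isREML(full)) lme4::refitML(full) else full
  nullML <- if (lme4::isREML(null)) lme4::refitML(null) else null
  lr_obs <- 2 * (as.numeric(stats::logLik(fullML)) -
                 as.numeric(stats::logLik(nullML)))
  set.seed(seed)
  ysim <- stats::simulate(nullML, nsim = n_boot)
  lr_sim <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    lr_sim[b] <- tryCatch(suppressWarnings(suppressMessages({
      f <- lme4::refit(fullML, ysim[[b]])
      n <- lme4::refit(nullML, ysim[[b]])
      2 * (as.numeric(stats::logLik(f)) - as.numeric(stats::logLik(n)))
    })), error = function(e) NA_real_)
  }
  ok <- !is.na(lr_sim)
  list(p = (1 + sum(lr_sim[ok] >= lr_obs)) / (sum(ok) + 1),
       lr_obs = lr_obs, lr_sim = lr_sim[ok], n_failed = sum(!ok))
}

#' Post-hoc pairwise contrasts among the four target conditions
#'
#' Pairwise t contrasts among the value x direction condition means within
#' each scene, Bonferroni-adjusted over the six contrasts of that scene
#' (the declared family).
#'
#' @param fit an `activity_lmm` or `merMod`.
#' @return data.frame of contrasts with Bonferroni-adjusted p-values.
#' @export
posthoc_pairwise <- function(fit) {
  if (inherits(fit, "activity_lmm")) fit <- fit$fit
  emm <- emmeans::emmeans(fit, ~ value * direction | scene)
  as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                  adjust = "bonferroni"))
}

#' Extract trial response parameters from a single-trial z series
#'
#' Onset latency is the first time bin after target onset at which the
#' z-score strictly exceeds the threshold; the peak is the maximum z within
#' the following 150 ms (including the onset bin); the slope is the rate of
#' change of z from onset to peak (0 when the peak is at the onset bin).
#' When no bin exceeds the threshold the trial is flagged as non-responsive.
#'
#' @param z numeric z-scored SDF for one trial.
#' @param time time axis (ms relative to target onset).
#' @param search_end end of the onset search window (ms); defaults to the
#'   end of the series.  Typically the trial's saccade onset, so that the
#'   response precedes the action.
#' @param threshold z threshold (default 2, exceeded strictly).
#' @param peak_window_ms window length after onset for the peak search.
#' @return list with `responded`, `onset_ms`, `peak_z`, `slope_z_per_ms`.
#' @export
extract_response_params <- function(z, time, search_end = NULL, threshold = 2,
                                    peak_window_ms = 150) {
  if (is.null(search_end)) search_end <- max(time) + 1
  search <- which(time > 0 & time <= search_end & z > threshold)
  if (!length(search))
    return(list(responded = FALSE, onset_ms = NA_real_, peak_z = NA_real_,
                slope_z_per_ms = NA_real_))
  i0 <- search[1]
  onset <- time[i0]
  win <- which(time >= onset & time < onset + peak_window_ms)
  ipk <- win[which.max(z[win])]
  slope <- if (ipk == i0) 0 else (z[ipk] - z[i0]) / (time[ipk] - time[i0])
  list(responded = TRUE, onset_ms = onset, peak_z = z[ipk],
       slope_z_per_ms = slope)
}

#' Trial response parameters for accept trials on contralateral good targets
#'
#' Applies [extract_response_params()] to every accept trial with a
#' contralateral good object, searching for the onset between target and
#' saccade onset.  Non-responsive trials are dropped with a message giving
#' their count.
#'
#' @param aligned target-aligned `aligned_activity`.
#' @param trials trial table.
#' @param threshold,peak_window_ms see [extract_response_params()].
#' @return data.frame `monkey_id`, `neuron_id`, `trial_id`, `onset_ms`,
#'   `peak_z`, `slope_z_per_ms`, `rt_ms`.
#' @export
response_params_table <- function(aligned, trials, threshold = 2,
                                  peak_window_ms = 150) {
  sel <- trials$choice == "accept" & trials$value == "good" &
    trials$direction == "contra" & !is.na(trials$rt_ms)
  tt <- trials[sel, ]
  cols <- which(aligned$index$trial_id %in% tt$trial_id)
  out <- list(); n_noresp <- 0L
  for (ci in cols) {
    id <- aligned$index$trial_id[ci]
    row <- tt[match(id, tt$trial_id), ]
    p <- extract_response_params(aligned$values[, ci], aligned$time,
                                 search_end = row$rt_ms,
                                 threshold = threshold,
                                 peak_window_ms = peak_window_ms)
    if (!p$responded) { n_noresp <- n_noresp + 1L; next }
    out[[length(out) + 1L]] <- data.frame(
      monkey_id = row$monkey_id, neuron_id = aligned$index$neuron_id[ci],
      trial_id = id, onset_ms = p$onset_ms, peak_z = p$peak_z,
      slope_z_per_ms = p$slope_z_per_ms, rt_ms = row$rt_ms)
  }
  if (n_noresp > 0L)
    message(n_noresp, " trial(s) without a threshold-crossing response excluded")
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mixed-effects model of reaction time on one neuronal response parameter
#'
#' Fits `rt_ms ~ parameter + (1 | monkey_id) + (1 | monkey_id:neuron_id)` and
#' reports the unstandardized slope with its Satterthwaite-approximated
#' p-value.  If the full random structure is singular, the model falls back
#' to the neuron-level intercept alone and the fallback is flagged.
#'
#' @param params data.frame from [response_params_table()] (or simulated
#'   parameters with the same columns).
#' @param parameter name of the predictor column (e.g. `"onset_ms"`).
#' @return list with `beta`, `se`, `df`, `p`, `singular_fallback`, `fit`.
#' @export
fit_rt_lmm <- function(params, parameter = "onset_ms") {
  if (!parameter %in% names(params)) stop("unknown parameter: ", parameter)
  x <- params[[parameter]]
  if (stats::sd(x) < 1e-12) stop("degenerate predictor: ", parameter, " is constant")
  if (length(unique(params$neuron_id)) < 2L)
    stop("need >= 2 neurons")
  dat <- params
  dat$.param <- x
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE)
  fit <- lmerTest::lmer(rt_ms ~ .param + (1 | monkey_id) + (1 | monkey_id:neuron_id),
                        data = dat, REML = TRUE, control = ctrl)
  fallback <- FALSE
  if (lme4::isSingular(fit)) {
    fit2 <- tryCatch(
      lmerTest::lmer(rt_ms ~ .param + (1 | monkey_id:neuron_id),
                     data = dat, REML = TRUE, control = ctrl),
      error = function(e) NULL)
    if (!is.null(fit2)) { fit <- fit2; fallback <- TRUE }
  }
  co <- stats::coef(summary(fit))
  list(beta = co[".param", "Estimate"], se = co[".param", "Std. Error"],
       df = co[".param", "df"], p = co[".param", "Pr(>|t|)"],
       singular_fallback = fallback, fit = fit)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return exact `alpha / m` (round to 4 decimals only for display).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Behavioral tests: reaction times and rejection strategies
#'
#' Welch's t-test comparing reaction times on accept trials against reject
#' trials with a return saccade, and Fisher's exact test comparing the
#' proportion of stay rejections between stable (scenes 1-2) and flexible
#' (scenes 3-4) scenes on bad-object trials.
#'
#' @param trials trial table.
#' @return list with `rt_welch` (htest), `stay_fisher` (htest), and
#'   `stay_table` (2 x 2 counts).
#' @export
behavior_tests <- function(trials) {
  acc <- trials$rt_ms[trials$choice == "accept" & !is.na(trials$rt_ms)]
  rej <- trials$rt_ms[trials$choice == "reject_return" & !is.na(trials$rt_ms)]
  if (!length(acc) || !length(rej)) stop("both RT groups must be non-empty")
  if (stats::sd(acc) < 1e-12 || stats::sd(rej) < 1e-12)
    stop("zero-variance RT group")
  rt_welch <- stats::t.test(acc, rej, var.equal = FALSE)
  bad <- trials[trials$value == "bad", ]
  regime <- ifelse(bad$scene %in% 3:4, "flexible", "stable")
  stay <- factor(bad$choice == "reject_stay", levels = c(TRUE, FALSE),
                 labels = c("stay", "non_stay"))
  tab <- table(regime = factor(regime, levels = c("stable", "flexible")), stay)
  list(rt_welch = rt_welch, stay_fisher = stats::fisher.test(tab),
       stay_table = tab)
}
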