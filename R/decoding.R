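#' Feature table for population decoding
#'
#' One sample per (neuron, trial): the neuron's spike counts in 1-ms bins
#' over a window around target onset (1200 features for the default -600 to
#' 600 ms window), with the trial's choice and reaction time as labels and
#' the neuron as the sample's group.  Only contralateral trials are used.
#' Trials recorded in separate sessions make neuron the unit of
#' non-independence, so cross-validation folds are later grouped by neuron.
#' A pseudo-population mode is available for sensitivity analysis: samples
#' are condition-matched pseudo-trials whose features concatenate all
#' neurons' bins.
#'
#' @param dataset a `spike_dataset` (or spike table, with `trials` supplied).
#' @param trials trial table when `dataset` is a bare spike table.
#' @param assignments optional named cluster labels per neuron, attached to
#'   samples.
#' @param window counting window `c(t0, t1)` ms around target onset.
#' @param mode `"per_neuron"` (default) or `"pseudo_population"`.
#' @param reject_strategies choices collapsed into the reject class.
#' @return object of class `feature_table`: list with `x` (sparse samples x
#'   features matrix), `choice` (factor reject/accept), `rt_ms`, `group`
#'   (neuron id per sample), `cluster`, `time` (bin left edges), `mode`.
#' @export
build_feature_table <- function(dataset, trials = NULL, assignments = NULL,
                                window = c(-600, 600),
                                mode = c("per_neuron", "pseudo_population"),
                                reject_strategies = c("reject_return",
                                                      "reject_stay",
                                                      "reject_other")) {
  mode <- match.arg(mode)
  if (inherits(dataset, "spike_dataset")) {
    if (is.null(trials)) trials <- dataset$trials
  }
  ctr <- trials[trials$direction == "contra", , drop = FALSE]
  ac <- align_and_bin(dataset, ctr, event = "target", window = window)
  x <- methods::as(Matrix::Matrix(t(ac$values), sparse = TRUE),
                   "CsparseMatrix")
  group <- ac$index$neuron_id
  trial_id <- ac$index$trial_id
  info <- ctr[match(trial_id, ctr$trial_id), ]
  choice <- factor(ifelse(info$choice == "accept", "accept",
                          ifelse(info$choice %in% reject_strategies,
                                 "reject", NA_character_)),
                   levels = c("reject", "accept"))
  keep <- !is.na(choice)
  x <- x[keep, , drop = FALSE]
  group <- group[keep]; trial_id <- trial_id[keep]
  choice <- choice[keep]; rt <- info$rt_ms[keep]
  cl <- if (is.null(assignments)) rep(NA_integer_, length(group)) else
    unname(assignments[group])

  if (mode == "pseudo_population") {
    # condition-matched pseudo-trials: the j-th accept (reject) trial of every
    # neuron is concatenated into one sample; limited by the smallest
    # per-neuron class count
    neurons <- unique(group)
    xs2 <- list(); ch2 <- c(); rt2 <- c()
    for (lab in levels(choice)) {
      n_min <- min(tapply(choice == lab, group, sum))
      if (n_min < 1L) next
      for (j in seq_len(n_min)) {
        rows <- vapply(neurons, function(nid)
          which(group == nid & choice == lab)[j], integer(1))
        xs2[[length(xs2) + 1L]] <- as.vector(t(as.matrix(x[rows, , drop = FALSE])))
        ch2 <- c(ch2, lab); rt2 <- c(rt2, mean(rt[rows], na.rm = TRUE))
      }
    }
    x <- methods::as(Matrix::Matrix(do.call(rbind, xs2), sparse = TRUE),
                     "CsparseMatrix")
    group <- paste0("pseudo", seq_len(nrow(x)))
    choice <- factor(ch2, levels = c("reject", "accept"))
    rt <- rt2
    cl <- rep(NA_integer_, nrow(x))
    trial_id <- group
  }
  structure(list(x = x, choice = choice, rt_ms = rt, group = group,
                 cluster = cl, trial_id = trial_id,
                 time = seq.int(window[1], window[2] - 1L), mode = mode),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table>", nrow(x$x), "samples x", ncol(x$x), "features,",
      length(unique(x$group)), "groups (mode:", x$mode, ")\n")
  invisible(x)
}

# subset a feature table by sample index
.ft_subset <- function(ft, idx) {
  out <- ft
  out$x <- ft$x[idx, , drop = FALSE]
  for (f in c("choice", "rt_ms", "group", "cluster", "trial_id"))
    out[[f]] <- ft[[f]][idx]
  out
}

#' Group-respecting cross-validation folds
#'
#' Assigns whole groups to folds so that no group spans two folds, balancing
#' fold sample counts by greedy bin packing (largest group first into the
#' currently lightest fold, with seeded random tie order).
#'
#' @param groups group id per sample.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold assignment per sample.
#' @export
grouped_folds <- function(groups, k = 10L, seed = 1L) {
  ug <- unique(groups)
  if (length(ug) < k)
    stop("fewer groups (", length(ug), ") than folds (", k,
         "); use a smaller k")
  set.seed(seed)
  sizes <- table(factor(groups, levels = ug))
  o <- order(-as.vector(sizes), stats::runif(length(ug)))
  fold_of_group <- integer(length(ug))
  load <- numeric(k)
  for (g in o) {
    f <- which.min(load)
    fold_of_group[g] <- f
    load[f] <- load[f] + sizes[g]
  }
  fold_of_group[match(groups, ug)]
}

# AUC of scores against a reject/accept factor, fixed direction
.auc <- function(y, score) {
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                 levels = c("reject", "accept"),
                                 direction = "<", quiet = TRUE)))
}

#' Nested, group-aware cross-validated elastic-net decoding
#'
#' Outer k-fold cross-validation with folds grouped by neuron estimates
#' performance; within each outer training set an inner grouped
#' cross-validation selects the regularization strength lambda that
#' maximizes the pooled out-of-fold AUC (choice, logistic loss) or minimizes
#' the pooled MSE (reaction time, squared loss) along a lambda path computed
#' on that training set.  A final model at the selected lambda, trained on
#' the full outer training set, predicts the held-out fold; the overall AUC
#' or cross-validated R-squared is computed from the pooled out-of-fold
#' predictions.  Feature standardization is performed inside each glmnet
#' fit, i.e. on training data only.
#'
#' @param ft a `feature_table`.
#' @param task `"choice"` or `"rt"`.
#' @param alpha elastic-net mixing parameter (0.5 a priori).
#' @param k_outer,k_inner fold counts (reduced automatically when a training
#'   set has fewer groups).
#' @param nlambda length of the lambda path.
#' @param lambda_min_ratio smallest lambda as a fraction of the
#'   coefficient-zeroing lambda_max (default spans four decades).
#' @param seed integer seed (controls fold assignment).
#' @param group_folds set `FALSE` to assign folds per sample, ignoring
#'   groups; only useful to demonstrate the leakage this causes.
#' @return object of class `decoding_result`: list with `task`, `metric`
#'   (`auc` or `r2`), `predictions` (data.frame observed/predicted/fold/
#'   group), `per_fold` (selected lambda and test size), `weights`
#'   (features x folds coefficient matrix), `time`.
#' @export
nested_cv_elastic_net <- function(ft, task = c("choice", "rt"), alpha = 0.5,
                                  k_outer = 10L, k_inner = 10L,
                                  nlambda = 50L, lambda_min_ratio = 1e-4,
                                  seed = 1L, group_folds = TRUE) {
  task <- match.arg(task)
  if (task == "rt") {
    ok <- !is.na(ft$rt_ms)
    ft <- .ft_subset(ft, which(ok))
  }
  n <- nrow(ft$x)
  y <- if (task == "choice") ft$choice else ft$rt_ms
  family <- if (task == "choice") "binomial" else "gaussian"
  folds <- if (group_folds) {
    grouped_folds(ft$group, k_outer, seed)
  } else {
    set.seed(seed)
    sample(rep_len(seq_len(k_outer), n))
  }
  preds <- rep(NA_real_, n)
  per_fold <- data.frame(fold = seq_len(k_outer), lambda = NA_real_,
                         n_test = NA_integer_)
  weights <- matrix(NA_real_, ncol(ft$x), k_outer)
  for (f in seq_len(k_outer)) {
    tr <- which(folds != f); te <- which(folds == f)
    if (!length(te)) next
    if (task == "choice" && length(unique(y[tr])) < 2L)
      stop("a class is absent from the training set of outer fold ", f)
    path <- glmnet::glmnet(ft$x[tr, , drop = FALSE], y[tr], family = family,
                           alpha = alpha, nlambda = nlambda,
                           lambda.min.ratio = lambda_min_ratio,
                           standardize = TRUE)
    lam <- path$lambda
    lam_star <- .inner_select(ft$x[tr, , drop = FALSE], y[tr], ft$group[tr],
                              lam, family, alpha, k_inner,
                              seed + 1000L * f, group_folds)
    preds[te] <- as.vector(stats::predict(path, ft$x[te, , drop = FALSE],
                                          s = lam_star, type = "response"))
    weights[, f] <- as.vector(stats::coef(path, s = lam_star))[-1]
    per_fold$lambda[f] <- lam_star
    per_fold$n_test[f] <- length(te)
  }
  metric <- if (task == "choice") {
    .auc(y, preds)
  } else {
    1 - sum((y - preds)^2) / sum((y - mean(y))^2)
  }
  structure(list(task = task,
                 metric = metric,
                 metric_name = if (task == "choice") "auc" else "r2",
                 predictions = data.frame(observed = y, predicted = preds,
                                          fold = folds, group = ft$group),
                 per_fold = per_fold, weights = weights, time = ft$time),
            class = "decoding_result")
}

# inner grouped CV over a fixed lambda path; returns the selected lambda
.inner_select <- function(x, y, group, lam, family, alpha, k_inner, seed,
                          group_folds = TRUE) {
  k <- min(k_inner, length(unique(group)))
  repeat {
    if (k < 2L) stop("cannot build a valid inner cross-validation")
    inner <- if (group_folds) grouped_folds(group, k, seed) else {
      set.seed(seed); sample(rep_len(seq_len(k), length(y)))
    }
    if (family != "binomial") break
    ok <- vapply(seq_len(k), function(f)
      length(unique(y[inner != f])) == 2L, logical(1))
    if (all(ok)) break
    k <- k - 1L   # a class vanished from an inner training set; coarsen folds
  }
  pr <- matrix(NA_real_, length(y), length(lam))
  for (f in seq_len(k)) {
    tr <- which(inner != f); te <- which(inner == f)
    if (!length(te)) next
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = family,
                          alpha = alpha, lambda = lam, standardize = TRUE)
    pr[te, ] <- stats::predict(fit, x[te, , drop = FALSE], s = lam,
                               type = "response")
  }
  score <- if (family == "binomial") {
    apply(pr, 2, function(p) .auc(y, p))
  } else {
    -colMeans((pr - y)^2)
  }
  lam[which.max(score)]
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result>", x$task, "decoding:",
      toupper(x$metric_name), "=", round(x$metric, 3), "\n")
  invisible(x)
}

#' Ablation and single-cluster decoding
#'
#' Reruns the full nested grouped cross-validation on subsets of the feature
#' table: once with each cluster removed (ablation) and once with each
#' cluster alone, alongside the full-population analysis.  Clusters whose
#' subset is empty or spans fewer groups than the outer fold count are marked
#' not applicable.
#'
#' @param ft a `feature_table` with cluster labels.
#' @param ... further arguments to [nested_cv_elastic_net()].
#' @return data.frame `analysis` (`full`/`ablate`/`single`), `cluster`,
#'   `metric`, `n_neurons`.
#' @export
ablation_and_single_cluster <- function(ft, ...) {
  cls <- sort(unique(ft$cluster))
  if (length(cls) < 2L) stop("need >= 2 clusters")
  run <- function(idx) {
    if (!length(idx)) return(NA_real_)
    tryCatch(nested_cv_elastic_net(.ft_subset(ft, idx), ...)$metric,
             error = function(e) NA_real_)
  }
  rows <- list(data.frame(analysis = "full", cluster = NA_integer_,
                          metric = run(seq_along(ft$cluster)),
                          n_neurons = length(unique(ft$group))))
  for (cl in cls) {
    keep <- which(ft$cluster != cl)
    only <- which(ft$cluster == cl)
    rows[[length(rows) + 1L]] <-
      data.frame(analysis = "ablate", cluster = cl, metric = run(keep),
                 n_neurons = length(unique(ft$group[keep])))
    rows[[length(rows) + 1L]] <-
      data.frame(analysis = "single", cluster = cl, metric = run(only),
                 n_neurons = length(unique(ft$group[only])))
  }
  do.call(rbind, rows)
}

#' Permutation test for decoding performance
#'
#' Shuffles choice labels within each neuron (preserving per-neuron class
#' balance), reruns the entire nested grouped cross-validation for each
#' permutation and computes `p = (1 + #\{AUC_null >= AUC_obs\}) /
#' (n_perm + 1)`.  Groups with a single class contribute nothing to a
#' shuffle and are skipped.
#'
#' @param ft a `feature_table`.
#' @param n_perm number of permutations (2000 at full scale; far fewer are
#'   adequate for routine use).
#' @param seed integer seed.
#' @param ... further arguments to [nested_cv_elastic_net()].
#' @return list with `auc_obs`, `null_auc` (vector), `p`.
#' @export
permutation_test <- function(ft, n_perm = 2000L, seed = 1L, ...) {
  obs <- nested_cv_elastic_net(ft, task = "choice", seed = seed, ...)$metric
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  null_auc <- rep(NA_real_, n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(perm_seeds[b])
    ftp <- ft
    for (nid in unique(ft$group)) {
      idx <- which(ft$group == nid)
      if (length(unique(ft$choice[idx])) < 2L) next
      ftp$choice[idx] <- sample(ft$choice[idx])
    }
    null_auc[b] <- nested_cv_elastic_net(ftp, task = "choice",
                                         seed = seed, ...)$metric
  }
  list(auc_obs = obs, null_auc = null_auc,
       p = (1 + sum(null_auc >= obs, na.rm = TRUE)) / (sum(!is.na(null_auc)) + 1))
}
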