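#' Default pipeline configuration
#'
#' Returns the full set of pipeline parameters as a nested list; any subset
#' can be overridden via `...` (top-level names) or loaded from a YAML file
#' with [read_pipeline_config()].  Stages run in dependency order; switching
#' a stage off removes its outputs and makes dependent stages fail with a
#' clear error.
#'
#' @param ... top-level overrides, e.g. `seed = 42` or
#'   `stages = list(decoding = FALSE)`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    input = "simulate",          # or list(spikes =, trials = ) of file paths
    outdir = NULL,               # NULL: nothing written, report only
    seed = 1L,
    simulation = list(),         # overrides for simulation_config()
    alignment = list(window = c(-700, 500), sigma_ms = 20,
                     baseline_window = c(-500, 0)),
    clustering = list(epoch = c(100, 300), k_range = 2:6, n_repeats = 200L),
    pca = list(window = c(0, 300), k_values = c(2L, 3L)),
    encoding = list(epoch = c(100, 300), n_boot = 199L),
    sliding = list(window_ms = 50L, step_ms = 5L),
    trajectories = list(window = c(-400, 400), baseline_window = c(-300, 0)),
    decoding = list(window = c(-600, 600), alpha = 0.5, k_outer = 5L,
                    k_inner = 5L, nlambda = 30L, run_ablation = FALSE),
    stages = list(clustering = TRUE, pca = TRUE, encoding = TRUE,
                  sliding = TRUE, trajectories = TRUE, decoding = TRUE)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], ov[[nm]])
    else cfg[[nm]] <- ov[[nm]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [pipeline_config()].
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.required_trial_cols <- c("trial_id", "neuron_id", "scene", "value",
                          "direction", "choice", "rt_ms", "scene_on",
                          "target_on", "saccade_on")

#' Read and validate a trial table
#'
#' @param path CSV file with the trial-table schema (see
#'   [simulate_dataset()]).
#' @return validated data.frame.
#' @export
read_trial_table <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.required_trial_cols, names(tr))
  if (length(missing))
    stop("trial table missing required column(s): ",
         paste(missing, collapse = ", "))
  if (any(!is.na(tr$rt_ms) & tr$rt_ms < 0))
    stop("invalid trial table: negative value in column rt_ms")
  if (!all(tr$value %in% c("good", "bad")))
    stop("invalid trial table: column value must be 'good'/'bad'")
  if (!all(tr$direction %in% c("contra", "ipsi")))
    stop("invalid trial table: column direction must be 'contra'/'ipsi'")
  bad_sacc <- !is.na(tr$saccade_on) & tr$saccade_on < tr$target_on
  if (any(bad_sacc))
    stop("invalid trial table: saccade_on before target_on")
  tr
}

#' Read and validate a spike table
#'
#' @param path CSV file with columns `neuron_id`, `trial_id`,
#'   `spike_time_ms`.
#' @return validated data.frame, spike times sorted within trial.
#' @export
read_spike_table <- function(path) {
  sp <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("neuron_id", "trial_id", "spike_time_ms"), names(sp))
  if (length(missing))
    stop("spike table missing required column(s): ",
         paste(missing, collapse = ", "))
  sp[order(sp$neuron_id, sp$trial_id, sp$spike_time_ms), , drop = FALSE]
}

#' Write a spike dataset to plain-text tables
#'
#' Writes `spikes.csv`, `trials.csv` and, when ground truth is present,
#' `neurons.csv` and `true_onset.csv` sidecars.
#'
#' @param dataset a `spike_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(spikes = file.path(dir, "spikes.csv"),
             trials = file.path(dir, "trials.csv"),
             neurons = file.path(dir, "neurons.csv"),
             true_onset = file.path(dir, "true_onset.csv"))
  utils::write.csv(dataset$spikes, paths["spikes"], row.names = FALSE)
  utils::write.csv(dataset$trials, paths["trials"], row.names = FALSE)
  utils::write.csv(dataset$neurons, paths["neurons"], row.names = FALSE)
  if (!is.null(dataset$truth))
    utils::write.csv(dataset$truth$true_onset, paths["true_onset"],
                     row.names = FALSE)
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data simulation (or ingestion), event-aligned
#' z-scored activity, window-based functional clustering with silhouette K
#' selection, PC-space validation, condition and reaction-time mixed models,
#' sliding-window choice regression, per-cluster trajectory divergence, and
#' population choice decoding.  A stage failure is recorded in the report
#' and stages depending on it are skipped; independent stages still run.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report` with one summary entry per stage,
#'   accumulated warnings, and the full configuration (provenance).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t_start <- Sys.time()
  report <- list(config = unclass(config), stages = list(), warnings = list())
  note <- function(stage, w) {
    report$warnings[[stage]] <<- c(report$warnings[[stage]], conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  run_stage <- function(stage, expr) {
    res <- tryCatch(
      withCallingHandlers(expr, warning = function(w) note(stage, w)),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "stage_failure"))
    report$stages[[stage]] <<- if (inherits(res, "stage_failure"))
      list(status = "failed", error = res$error) else list(status = "ok")
    res
  }
  out <- list()

  # --- data ----------------------------------------------------------------
  ds <- run_stage("data", {
    if (identical(config$input, "simulate")) {
      sim_args <- utils::modifyList(list(seed = config$seed), config$simulation)
      simulate_dataset(do.call(simulation_config, sim_args))
    } else {
      spikes <- read_spike_table(config$input$spikes)
      trials <- read_trial_table(config$input$trials)
      structure(list(spikes = spikes, trials = trials,
                     neurons = data.frame(
                       neuron_id = unique(trials$neuron_id),
                       monkey_id = trials$monkey_id[
                         match(unique(trials$neuron_id), trials$neuron_id)]),
                     truth = NULL, config = NULL),
                class = "spike_dataset")
    }
  })
  if (inherits(ds, "stage_failure")) stop("data stage failed: ", ds$error)
  report$stages$data$n_neurons <- length(unique(ds$trials$neuron_id))
  report$stages$data$n_trials <- nrow(ds$trials)

  al <- config$alignment
  aligned <- run_stage("alignment", aligned_activity(
    ds, event = "target", window = al$window, sigma_ms = al$sigma_ms,
    baseline_window = al$baseline_window))

  assignments <- NULL
  if (isTRUE(config$stages$clustering)) {
    cl_res <- run_stage("clustering", {
      feats <- build_features(aligned, ds$trials, config$clustering$epoch)
      sel <- select_k(feats, config$clustering$k_range,
                      n_repeats = config$clustering$n_repeats,
                      seed = config$seed)
      a <- assign_clusters(feats, sel$chosen_k, seed = config$seed)
      labels <- canonicalize_labels(a$cluster, a$centers)
      rates <- baseline_rate(ds)
      kw <- compare_baseline_rates(rates[names(labels)], labels)
      list(features = feats, selection = sel, labels = labels,
           centers = a$centers, kruskal = kw)
    })
    if (!inherits(cl_res, "stage_failure")) {
      assignments <- cl_res$labels
      report$stages$clustering$chosen_k <- cl_res$selection$chosen_k
      report$stages$clustering$sizes <- as.list(table(cl_res$labels))
      report$stages$clustering$kruskal_p <- cl_res$kruskal$p.value
      out$clustering <- cl_res
    }
  }

  if (isTRUE(config$stages$pca)) {
    pca_res <- run_stage("pca", {
      sm <- build_stacked_matrix(aligned, ds$trials, config$pca$window)
      p <- fit_pca(sm$matrix)
      feats6 <- pc_score_features(p, sm$neuron_ids)
      cl <- cluster_pc_space(feats6, config$pca$k_values, seed = config$seed,
                             reference = assignments)
      list(pca = p, features = feats6, clusters = cl)
    })
    if (!inherits(pca_res, "stage_failure")) {
      report$stages$pca$var_explained_pc123 <-
        sum(pca_res$pca$var_explained[1:3])
      out$pca <- pca_res
    }
  }

  if (isTRUE(config$stages$encoding)) {
    enc_res <- run_stage("encoding", {
      tab <- build_condition_table(aligned, ds$trials, config$encoding$epoch)
      fit <- fit_activity_lmm(tab)
      null <- lme4::lmer(activity ~ 1 + (1 | monkey_id) + (1 | monkey_id:neuron_id),
                         data = tab, REML = TRUE,
                         control = lme4::lmerControl(
                           check.conv.singular = "ignore", calc.derivs = FALSE))
      boot <- parametric_bootstrap_test(fit$fit, null,
                                        n_boot = config$encoding$n_boot,
                                        seed = config$seed)
      ph <- posthoc_pairwise(fit)
      params <- response_params_table(aligned, ds$trials)
      rt_fits <- NULL
      if (!is.null(params) && !is.null(assignments)) {
        rt_fits <- list()
        for (cl in sort(unique(assignments))) {
          sub <- params[params$neuron_id %in%
                          names(assignments)[assignments == cl], ]
          for (par in c("onset_ms", "peak_z", "slope_z_per_ms")) {
            key <- paste0("cluster", cl, ".", par)
            rt_fits[[key]] <- tryCatch({
              f <- fit_rt_lmm(sub, par)
              list(beta = f$beta, p = f$p)
            }, error = function(e) list(beta = NA_real_, p = NA_real_))
          }
        }
      }
      beh <- behavior_tests(ds$trials)
      list(condition_table = tab, activity_lmm = fit, bootstrap = boot,
           posthoc = ph, rt_models = rt_fits, behavior = beh,
           rt_threshold = bonferroni_threshold(0.05, 9))
    })
    if (!inherits(enc_res, "stage_failure")) {
      report$stages$encoding$bootstrap_p <- enc_res$bootstrap$p
      report$stages$encoding$welch_p <- enc_res$behavior$rt_welch$p.value
      out$encoding <- enc_res
    }
  }

  if (isTRUE(config$stages$sliding)) {
    sl_res <- run_stage("sliding", {
      bp <- sliding_beta_population(aligned, ds$trials,
                                    window_ms = config$sliding$window_ms,
                                    step_ms = config$sliding$step_ms)
      ss <- smooth_and_sort(bp$beta, bp$time)
      list(beta = bp, sorted = ss)
    })
    if (!inherits(sl_res, "stage_failure")) out$sliding <- sl_res
  }

  if (isTRUE(config$stages$trajectories)) {
    tr_res <- run_stage("trajectories", {
      if (is.null(assignments))
        stop("trajectories require cluster assignments (clustering stage off or failed)")
      cluster_divergence(ds, assignments,
                         window = config$trajectories$window,
                         baseline_window = config$trajectories$baseline_window)
    })
    if (!inherits(tr_res, "stage_failure")) {
      report$stages$trajectories$divergence_ms <-
        stats::setNames(as.list(tr_res$divergence_ms), tr_res$cluster)
      out$trajectories <- tr_res
    }
  }

  if (isTRUE(config$stages$decoding)) {
    dec <- config$decoding
    de_res <- run_stage("decoding", {
      ft <- build_feature_table(ds, assignments = assignments,
                                window = dec$window)
      res <- nested_cv_elastic_net(ft, task = "choice", alpha = dec$alpha,
                                   k_outer = dec$k_outer,
                                   k_inner = dec$k_inner,
                                   nlambda = dec$nlambda,
                                   seed = config$seed)
      abl <- if (isTRUE(dec$run_ablation) && !is.null(assignments))
        ablation_and_single_cluster(ft, alpha = dec$alpha,
                                    k_outer = dec$k_outer,
                                    k_inner = dec$k_inner,
                                    nlambda = dec$nlambda,
                                    seed = config$seed) else NULL
      list(feature_table_dim = dim(ft$x), choice = res, ablation = abl)
    })
    if (!inherits(de_res, "stage_failure")) {
      report$stages$decoding$auc <- de_res$choice$metric
      out$decoding <- de_res
    }
  }

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  report$results <- out
  class(report) <- "pipeline_report"
  if (!is.null(config$outdir)) write_report(report, config$outdir, ds)
  report
}

#' Write pipeline outputs to an output directory
#'
#' Figure-ready CSVs per stage plus a JSON report containing every stage
#' summary, accumulated warnings and the serialized configuration.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @param dataset optionally, the `spike_dataset` to write alongside.
#' @return invisibly, the report path.
#' @export
write_report <- function(report, dir, dataset = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- report$results
  if (!is.null(dataset)) write_dataset(dataset, file.path(dir, "data"))
  if (!is.null(res$clustering)) {
    utils::write.csv(res$clustering$selection$silhouette_table,
                     file.path(dir, "silhouette_by_k.csv"), row.names = FALSE)
    utils::write.csv(data.frame(neuron_id = names(res$clustering$labels),
                                cluster = as.integer(res$clustering$labels)),
                     file.path(dir, "cluster_assignments.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$sliding))
    utils::write.csv(cbind(time = res$sliding$beta$time,
                           t(res$sliding$beta$beta)),
                     file.path(dir, "sliding_beta.csv"), row.names = FALSE)
  if (!is.null(res$trajectories))
    utils::write.csv(res$trajectories, file.path(dir, "divergence.csv"),
                     row.names = FALSE)
  summary_json <- list(stages = report$stages, warnings = report$warnings,
                       config = .serializable(report$config),
                       elapsed_s = report$elapsed_s)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(summary_json, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

# drop non-serializable members (arrays become lists automatically)
.serializable <- function(x) {
  rapply(x, function(v) if (is.function(v)) NULL else v, how = "replace")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-12s %s", nm, s$status))
    extra <- setdiff(names(s), c("status", "error"))
    if (length(extra))
      cat(" |", paste(vapply(extra, function(e)
        paste0(e, "=", paste0(unlist(s[[e]]), collapse = "/")),
        character(1)), collapse = " "))
    if (!is.null(s$error)) cat(" |", s$error)
    cat("\n")
  }
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}
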