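#' Stacked condition-response matrix for PCA validation
#'
#' Builds the input matrix for the data-driven validation of the functional
#' groupings: the contralateral trial-averaged z-scored response of each
#' neuron to good and to bad objects over a short post-stimulus window,
#' stacked as separate rows.  Row order is all good-condition rows (neuron
#' order) followed by all bad-condition rows; a neuron missing either
#' condition is excluded from both.
#'
#' @param aligned target-aligned `aligned_activity`.
#' @param trials trial table.
#' @param window `c(a, b)` ms post-stimulus (default 0-300, one column per
#'   1-ms bin).
#' @return list with `matrix` (2N x T, rownames `<id>.good` / `<id>.bad`),
#'   `neuron_ids` (length N, row i and N+i belong to neuron i), `time`.
#' @export
build_stacked_matrix <- function(aligned, trials, window = c(0, 300)) {
  sel <- aligned$time >= window[1] & aligned$time < window[2]
  if (!any(sel)) stop("window outside the time axis")
  info <- trials[match(aligned$index$trial_id, trials$trial_id), ]
  use <- which(info$direction == "contra" & info$value %in% c("good", "bad"))
  grp <- paste(aligned$index$neuron_id[use], info$value[use], sep = ".")
  sums <- rowsum(t(aligned$values[sel, use, drop = FALSE]), grp)
  means <- sums / as.vector(table(factor(grp, levels = rownames(sums))))
  ids_all <- unique(aligned$index$neuron_id)
  have <- ids_all[paste0(ids_all, ".good") %in% rownames(means) &
                    paste0(ids_all, ".bad") %in% rownames(means)]
  dropped <- setdiff(ids_all, have)
  if (length(dropped))
    warning(length(dropped), " neuron(s) missing a condition, excluded: ",
            paste(dropped, collapse = ", "))
  if (!length(have)) stop("no neuron has both conditions")
  X <- rbind(means[paste0(have, ".good"), , drop = FALSE],
             means[paste0(have, ".bad"), , drop = FALSE])
  rownames(X) <- c(paste0(have, ".good"), paste0(have, ".bad"))
  list(matrix = X, neuron_ids = have, time = aligned$time[sel])
}

#' PCA on a per-time-point standardized matrix
#'
#' Standardizes every column (time point) to mean 0 and SD 1, then computes
#' the principal components of the rows.  Zero-variance columns are dropped
#' with a warning.  Component signs follow a fixed convention: each loading
#' vector is flipped so that its largest-magnitude element is positive,
#' making score features reproducible.
#'
#' @param x numeric matrix (rows = stacked condition responses).
#' @return list with `loadings` (columns = components), `scores` (rows
#'   projected), `sdev`, `var_explained` (fractions summing to 1),
#'   `dropped_cols`.
#' @export
fit_pca <- function(x) {
  if (nrow(x) < 2L) stop("need at least 2 rows")
  s <- apply(x, 2, stats::sd)
  dropped <- which(s < 1e-12)
  if (length(dropped)) {
    warning(length(dropped), " zero-variance column(s) dropped")
    x <- x[, -dropped, drop = FALSE]
    s <- s[-dropped]
  }
  xs <- scale(x, center = TRUE, scale = TRUE)
  p <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  rot <- sweep(p$rotation, 2, flip, `*`)
  sco <- sweep(p$x, 2, flip, `*`)
  list(loadings = rot, scores = sco, sdev = p$sdev,
       var_explained = p$sdev^2 / sum(p$sdev^2),
       dropped_cols = dropped)
}

#' Six-dimensional PC-score features per neuron
#'
#' Combines each neuron's scores on the first three principal components for
#' the good and bad condition rows into one feature vector
#' `(PC1_good, PC2_good, PC3_good, PC1_bad, PC2_bad, PC3_bad)`.
#'
#' @param pca result of [fit_pca()] on a stacked matrix.
#' @param neuron_ids the `neuron_ids` element of [build_stacked_matrix()].
#' @return numeric matrix N x 6 with neuron ids as rownames.
#' @export
pc_score_features <- function(pca, neuron_ids) {
  n <- length(neuron_ids)
  if (nrow(pca$scores) != 2L * n)
    stop("score rows do not match 2 x neuron count")
  sc <- pca$scores[, 1:3, drop = FALSE]
  out <- cbind(sc[seq_len(n), , drop = FALSE],
               sc[n + seq_len(n), , drop = FALSE])
  colnames(out) <- c("PC1_good", "PC2_good", "PC3_good",
                     "PC1_bad", "PC2_bad", "PC3_bad")
  rownames(out) <- neuron_ids
  out
}

#' K-means in PC-score space
#'
#' Clusters the six-dimensional PC-score features for each requested K and,
#' when reference assignments are given, cross-tabulates the solutions
#' against them.
#'
#' @param features N x 6 matrix from [pc_score_features()].
#' @param k_values cluster numbers to examine (default `c(2, 3)`).
#' @param seed integer seed.
#' @param reference optional named labels (e.g. window-based cluster
#'   assignments) to cross-tabulate against.
#' @return list with one element per K: `assignments`, `centers`, and, when a
#'   reference is supplied, `crosstab`.
#' @export
cluster_pc_space <- function(features, k_values = c(2L, 3L), seed = 1L,
                             reference = NULL) {
  out <- list()
  for (k in k_values) {
    a <- assign_clusters(features, k, seed = seed + k)
    res <- list(assignments = a$cluster, centers = a$centers)
    if (!is.null(reference)) {
      ref <- reference[rownames(features)]
      res$crosstab <- table(pc_space = a$cluster, reference = ref)
    }
    out[[paste0("K", k)]] <- res
  }
  out
}
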