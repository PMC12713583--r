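#' Window features for functional clustering
#'
#' Per neuron, the mean z-scored activity in a 200-ms window (100-300 ms by
#' default) after the onset of contralateral good and of contralateral bad
#' targets: trials are epoch-averaged, then averaged within condition.
#' Neurons missing either condition are excluded with a warning.
#'
#' @param aligned target-aligned `aligned_activity`.
#' @param trials trial table matching the aligned object.
#' @param epoch `c(a, b)` ms after target onset.
#' @return numeric matrix N x 2 with columns `good`, `bad` and neuron ids as
#'   rownames.
#' @export
build_features <- function(aligned, trials, epoch = c(100, 300)) {
  em <- epoch_mean(aligned, epoch)
  i <- match(em$trial_id, trials$trial_id)
  v <- trials$value[i]
  use <- which(trials$direction[i] == "contra" & v %in% c("good", "bad"))
  key <- paste(em$neuron_id[use], v[use], sep = ".")
  s <- rowsum(em$value[use], key)
  means <- as.vector(s) / as.vector(table(factor(key, levels = rownames(s))))
  names(means) <- rownames(s)
  ids_all <- unique(em$neuron_id)
  ids <- ids_all[paste0(ids_all, ".good") %in% names(means) &
                   paste0(ids_all, ".bad") %in% names(means)]
  dropped <- setdiff(ids_all, ids)
  if (length(dropped))
    warning(length(dropped), " neuron(s) missing a condition, excluded: ",
            paste(dropped, collapse = ", "))
  out <- cbind(good = means[paste0(ids, ".good")],
               bad = means[paste0(ids, ".bad")])
  rownames(out) <- ids
  out
}

# k-means++ style seeding: spread initial centers with probability
# proportional to squared distance from the nearest chosen center
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, rowSums((x - matrix(x[centers[j], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  x[centers, , drop = FALSE]
}

#' K-means clustering with seeded k-means++ restarts
#'
#' Runs `stats::kmeans` from `n_restarts` k-means++ style initializations and
#' keeps the solution with the lowest within-cluster sum of squares.
#' Deterministic given `seed`.
#'
#' @param features numeric matrix, one row per neuron.
#' @param k number of clusters (>= 2; `k = nrow(features)` gives singleton
#'   clusters with zero WCSS).
#' @param seed integer seed.
#' @param n_restarts restarts kept-best by WCSS.
#' @return list with `cluster` (named integer vector), `centers`,
#'   `tot_withinss`.
#' @export
assign_clusters <- function(features, k, seed = 1L, n_restarts = 10L) {
  if (k < 2) stop("k must be >= 2")
  if (nrow(features) < k) stop("more clusters than rows")
  if (nrow(unique(features)) < k)
    stop("non-clusterable input: fewer than k distinct rows")
  if (k == nrow(features))   # singleton clusters: zero WCSS by definition
    return(list(cluster = stats::setNames(seq_len(k), rownames(features)),
                centers = features, tot_withinss = 0))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- .kmeanspp_init(features, k)
    km <- tryCatch(suppressWarnings(stats::kmeans(features, centers = init,
                                                  iter.max = 100L)),
                   error = function(e) NULL)  # empty cluster: try next restart
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best))
    stop("k-means failed for all restarts (persistent empty clusters)")
  list(cluster = stats::setNames(best$cluster, rownames(features)),
       centers = best$centers,
       tot_withinss = best$tot.withinss)
}

#' Mean silhouette width of a clustering
#'
#' Average silhouette over all points, computed with Euclidean distances via
#' \pkg{cluster}.
#'
#' @param features numeric matrix.
#' @param labels integer cluster labels.
#' @return scalar mean silhouette in `[-1, 1]`.
#' @export
mean_silhouette <- function(features, labels) {
  sil <- cluster::silhouette(as.integer(labels), stats::dist(features))
  mean(sil[, "sil_width"])
}

#' Select the number of clusters by repeated silhouette evaluation
#'
#' For each candidate K, k-means is repeated `n_repeats` times from random
#' initializations (each repeat itself the best of `n_restarts` k-means++
#' starts) and the mean silhouette width of each repeat's solution is
#' recorded.  The chosen K maximizes the across-repeat average silhouette.
#'
#' @param features numeric matrix, one row per neuron.
#' @param k_range candidate cluster numbers (default 2:6).
#' @param n_repeats silhouette repeats per K (5000 at full scale; reduce for
#'   quick runs).
#' @param seed integer seed.
#' @param n_restarts k-means restarts within each repeat.
#' @return object of class `cluster_selection`: list with
#'   `silhouette_table` (data.frame `k`, `mean_silhouette`, `sd_silhouette`),
#'   `chosen_k`, `n_repeats`.
#' @export
select_k <- function(features, k_range = 2:6, n_repeats = 5000L, seed = 1L,
                     n_restarts = 10L) {
  if (nrow(features) <= max(k_range))
    stop("need more rows than the largest candidate K")
  if (nrow(unique(features)) < 2L)
    stop("non-clusterable input: all feature rows identical")
  d <- stats::dist(features)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(k_range) * n_repeats),
                      nrow = length(k_range))
  tab <- data.frame(k = k_range, mean_silhouette = NA_real_,
                    sd_silhouette = NA_real_)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    sil <- vapply(seq_len(n_repeats), function(r) {
      a <- assign_clusters(features, k, seed = rep_seeds[i, r],
                           n_restarts = n_restarts)
      mean(cluster::silhouette(as.integer(a$cluster), d)[, "sil_width"])
    }, numeric(1))
    tab$mean_silhouette[i] <- mean(sil)
    tab$sd_silhouette[i] <- stats::sd(sil)
  }
  structure(list(silhouette_table = tab,
                 chosen_k = k_range[which.max(tab$mean_silhouette)],
                 n_repeats = n_repeats),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat("<cluster_selection> chosen K =", x$chosen_k,
      "over", x$n_repeats, "repeats per K\n")
  print(x$silhouette_table, row.names = FALSE)
  invisible(x)
}

#' Canonical functional labels for a three-cluster solution
#'
#' Maps arbitrary k-means labels onto the canonical functional labels:
#' label 2 is the centroid with the most negative bad-object feature (the
#' bidirectional value-coding profile); of the remaining two, label 1 is the
#' one whose good-object feature exceeds its bad-object feature (the
#' good-preferring facilitative profile) and label 3 the other (the
#' bad-preferring profile).  Ties are broken by descending good-object
#' feature.  For K != 3 the raw labels are returned with attribute
#' `canonical = FALSE`.
#'
#' @param assignments integer labels per neuron.
#' @param centers centroid matrix with columns `good`, `bad`.
#' @return integer labels in 1:3 (attribute `canonical = TRUE`), or the raw
#'   labels when K != 3.
#' @export
canonicalize_labels <- function(assignments, centers) {
  k <- nrow(centers)
  if (k != 3L) {
    attr(assignments, "canonical") <- FALSE
    return(assignments)
  }
  lab2 <- which.min(centers[, "bad"])
  rest <- setdiff(seq_len(3L), lab2)
  diffs <- centers[rest, "good"] - centers[rest, "bad"]
  o <- order(-diffs, -centers[rest, "good"])
  map <- integer(3L)
  map[lab2] <- 2L
  map[rest[o[1]]] <- 1L
  map[rest[o[2]]] <- 3L
  out <- map[assignments]
  names(out) <- names(assignments)
  attr(out, "canonical") <- TRUE
  out
}

#' Compare baseline firing rates across clusters
#'
#' Kruskal-Wallis rank-sum test of per-neuron baseline rates across the
#' functional clusters (tie-corrected H statistic from base R).
#'
#' @param rates named numeric vector of baseline rates (Hz).
#' @param assignments cluster labels, aligned with `rates` by name or
#'   position.
#' @return `htest` object from [stats::kruskal.test()].
#' @export
compare_baseline_rates <- function(rates, assignments) {
  if (!is.null(names(rates)) && !is.null(names(assignments)))
    assignments <- assignments[names(rates)]
  g <- factor(assignments)
  if (nlevels(g) < 2L || any(table(g) < 1L))
    stop("need >= 2 non-empty groups")
  stats::kruskal.test(rates, g)
}
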