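#' Best-of-restarts K-means
#'
#' Runs Lloyd's K-means `restarts` times, each restart initialized with k
#' distinct data points drawn under a seeded stream, and returns the labels of
#' the run with the lowest within-cluster sum of squared Euclidean distances.
#' Deterministic given `seed`. If an initialization fails (e.g. an emptied
#' cluster), fresh centers are resampled for that restart.
#'
#' @param data N x d numeric matrix (rows = points).
#' @param k Number of clusters, `1 <= k <= N`.
#' @param restarts Number of random restarts (>= 1).
#' @param max_iter Iteration cap per restart; convergence is declared when
#'   assignments stop changing, so the cap is rarely reached.
#' @param seed Integer seed.
#' @return Integer vector of cluster labels in `1..k` with attribute
#'   `"tot_withinss"` (the winning objective value).
#' @export
kmeans_restarts <- function(data, k, restarts = 1000L, max_iter = 1e9,
                            seed = 1L) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (!is.finite(k) || k < 1L || k > n) {
    stop("k must be between 1 and the number of points", call. = FALSE)
  }
  if (any(!is.finite(data))) stop("non-finite data", call. = FALSE)
  if (k == 1L) {
    ctr <- colMeans(data)
    obj <- sum(sweep(data, 2L, ctr)^2)
    return(structure(rep(1L, n), tot_withinss = obj))
  }
  max_iter <- min(max_iter, .Machine$integer.max)
  best <- NULL
  best_obj <- Inf
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  for (r in seq_len(restarts)) {
    fit <- NULL
    for (attempt in 1:20) {
      centers <- data[sample.int(n, k), , drop = FALSE]
      if (anyDuplicated(centers)) next
      fit <- tryCatch(
        stats::kmeans(data, centers = centers, iter.max = max_iter,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) next
    if (fit$tot.withinss < best_obj) {
      best_obj <- fit$tot.withinss
      best <- fit$cluster
    }
  }
  if (is.null(best)) {
    stop("K-means failed on every restart (degenerate data?)", call. = FALSE)
  }
  structure(as.integer(best), tot_withinss = best_obj)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Binary co-membership matrix of one clustering
#'
#' Entry (i, j) is 1 when cells i and j share a cluster label, else 0;
#' the diagonal is 1.
#'
#' @param labels Integer vector of cluster labels.
#' @return N x N binary matrix.
#' @export
co_membership <- function(labels) {
  out <- outer(labels, labels, `==`)
  storage.mode(out) <- "double"
  out
}

#' Average co-membership over clustering runs
#'
#' The consensus matrix: entry (i, j) is the fraction of runs in which cells
#' i and j were clustered together. Symmetric, entries in `[0, 1]`,
#' diagonal 1.
#'
#' @param runs List of label vectors, all of the same length.
#' @return N x N consensus matrix.
#' @export
consensus_matrix <- function(runs) {
  if (!is.list(runs) || length(runs) == 0L) {
    stop("need at least one clustering run", call. = FALSE)
  }
  n <- length(runs[[1L]])
  if (any(vapply(runs, length, 1L) != n)) {
    stop("all runs must label the same number of cells", call. = FALSE)
  }
  acc <- matrix(0, n, n)
  for (l in runs) acc <- acc + co_membership(l)
  acc / length(runs)
}

#' Consensus matrix of a log-expression matrix
#'
#' The full similarity pipeline: per-gene variance weights, weighted Spearman
#' distance matrix, PCA, a plan of principal-component sub-datasets, restarted
#' K-means on each sub-dataset, and the average co-membership matrix over all
#' runs. One independent sub-seed per sub-dataset is drawn from `seed`, so
#' the result is reproducible bit-for-bit.
#'
#' @param t Genes x cells log-expression matrix, >= 3 cells.
#' @param k Number of clusters (from prior knowledge of the data).
#' @param cfg Parameter list from [ccimpute_config()].
#' @param seed Integer master seed.
#' @return A list of class `"ccimpute_consensus"`: `consensus` (N x N),
#'   `plan` (component counts used), `runs` (list of label vectors),
#'   `pca`, `distance`, `weights`.
#' @export
build_consensus <- function(t, k, cfg = ccimpute_config(), seed = 1L) {
  if (!is.matrix(t) || ncol(t) < 3L) {
    stop("need a genes x cells matrix with at least 3 cells", call. = FALSE)
  }
  n <- ncol(t)
  w <- gene_weights(t)
  d <- weighted_spearman_distance_matrix(t, w)
  p <- pca_transform(d)
  plan <- plan_subdatasets(
    p, n_cells = n, max_subsets = cfg$max_subsets,
    small_cutoff = cfg$small_dataset_cutoff,
    small_lo = cfg$small_range_lo, small_hi = cfg$small_range_hi,
    rel_var_start = cfg$rel_var_start, rel_var_stop = cfg$rel_var_stop)
  restarts <- if (n > cfg$restart_cutoff) cfg$restarts_large
              else cfg$restarts_small
  sub_seeds <- .spawn_seeds(seed, length(plan))
  runs <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    # unit-scaled components: see ?pca_transform for why not the scores
    sub <- p$vectors[, seq_len(plan[i]), drop = FALSE]
    runs[[i]] <- kmeans_restarts(sub, k, restarts = restarts,
                                 max_iter = cfg$max_iter,
                                 seed = sub_seeds[i])
  }
  cm <- consensus_matrix(runs)
  dimnames(cm) <- list(colnames(t), colnames(t))
  structure(list(consensus = cm, plan = plan, runs = runs, pca = p,
                 distance = d, weights = w),
            class = "ccimpute_consensus")
}

# derive independent 32-bit sub-seeds from a master seed
.spawn_seeds <- function(seed, n) {
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' @export
print.ccimpute_consensus <- function(x, ...) {
  cat("consensus matrix over", length(x$runs), "K-means runs on",
      nrow(x$consensus), "cells\n")
  cat("sub-dataset dimensions:", paste(x$plan, collapse = ", "), "\n")
  invisible(x)
}
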