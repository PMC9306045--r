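#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same cells,
#' computed from the contingency table in the Hubert-Arabie form:
#' `(Index - Expected) / (Max - Expected)` over all-pairs agreement counts.
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones; can be negative.
#'
#' @param x,y Label vectors of equal length (>= 2); any atomic type.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) {
    stop("partitions must label the same cells", call. = FALSE)
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  tab <- table(x, y)
  choose2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- choose2(as.vector(tab))
  sum_a <- choose2(rowSums(tab))
  sum_b <- choose2(colSums(tab))
  n2 <- n * (n - 1) / 2
  expected <- sum_a * sum_b / n2
  maxim <- (sum_a + sum_b) / 2
  if (maxim == expected) return(1)  # both partitions trivial (all one block)
  (sum_ij - expected) / (maxim - expected)
}

#' Average silhouette width
#'
#' Mean over points of `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with
#' Euclidean distances: `a(i)` is the mean distance to the other members of
#' i's cluster and `b(i)` the smallest mean distance to any other cluster.
#' Points in singleton clusters contribute `s(i) = 0`.
#'
#' @param data N x d numeric matrix, rows = points (cells).
#' @param labels Cluster labels, length N, at least 2 distinct values.
#' @return Average silhouette width in `[-1, 1]`.
#' @export
average_silhouette <- function(data, labels) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (length(labels) != n) stop("one label per row required", call. = FALSE)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) {
    stop("silhouette is undefined for a single cluster", call. = FALSE)
  }
  dm <- as.matrix(stats::dist(data))
  sizes <- tabulate(labels, k)
  # mean distance from each point to each cluster (self excluded for own)
  sums <- matrix(0, n, k)
  for (cl in seq_len(k)) {
    sums[, cl] <- rowSums(dm[, labels == cl, drop = FALSE])
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    cl <- labels[i]
    if (sizes[cl] == 1L) next  # singleton: s(i) = 0
    a <- sums[i, cl] / (sizes[cl] - 1L)
    b <- min(sums[i, -cl] / sizes[-cl])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Fraction of original zeros altered by imputation
#'
#' Out of all entries that were zero before imputation, the fraction whose
#' imputed value in non-log (count) space is at least `cutoff`. Imputed
#' values below the cutoff are regarded as still zero, so the statistic
#' measures how aggressively a method rewrites zeros.
#'
#' @param original Matrix before imputation (its zero pattern is used).
#' @param imputed Matrix after imputation, in non-log space, same shape.
#' @param cutoff Values >= this count as changed (default 0.5).
#' @return Fraction in `[0, 1]`.
#' @export
zero_change_fraction <- function(original, imputed, cutoff = 0.5) {
  if (!all(dim(original) == dim(imputed))) {
    stop("matrices must have the same shape", call. = FALSE)
  }
  zeros <- original == 0
  if (!any(zeros)) {
    stop("no zero entries; the statistic is undefined", call. = FALSE)
  }
  sum(imputed[zeros] >= cutoff) / sum(zeros)
}

#' Downstream clustering quality of an expression matrix
#'
#' The benchmark harness: reduce the cells of a log-expression matrix (PCA,
#' keeping enough components for `var_target` cumulative variance up to
#' `max_components`; or a 2-D t-SNE embedding), cluster with restarted
#' K-means, and report the mean adjusted Rand index against the true labels
#' over `reps` seeded repetitions.
#'
#' @param t Genes x cells log-expression matrix.
#' @param true_labels Ground-truth labels, length = cells.
#' @param method `"pca"` or `"tsne"` (t-SNE requires the Rtsne package and
#'   `perplexity < N / 3`).
#' @param k Number of clusters for K-means.
#' @param reps Clustering repetitions averaged over (default 3).
#' @param seed Integer seed.
#' @param restarts K-means restarts per repetition (default 50).
#' @param var_target,max_components PCA component selection: smallest count
#'   reaching `var_target` cumulative variance (default 0.85), capped at
#'   `max_components` (default 50).
#' @param perplexity t-SNE perplexity (default 30).
#' @return Mean adjusted Rand index over repetitions.
#' @export
downstream_ari <- function(t, true_labels, method = c("pca", "tsne"), k,
                           reps = 3L, seed = 1L, restarts = 50L,
                           var_target = 0.85, max_components = 50L,
                           perplexity = 30) {
  method <- match.arg(method)
  n <- ncol(t)
  if (length(true_labels) != n) {
    stop("one true label per cell required", call. = FALSE)
  }
  cells <- base::t(t)
  if (method == "pca") {
    pc <- stats::prcomp(cells, center = TRUE, scale. = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    d <- min(max(2L, match(TRUE, cum >= var_target)), max_components,
             ncol(pc$x))
    emb <- pc$x[, seq_len(d), drop = FALSE]
  } else {
    if (!requireNamespace("Rtsne", quietly = TRUE)) {
      stop("method = \"tsne\" requires the Rtsne package", call. = FALSE)
    }
    if (perplexity >= n / 3) {
      stop("t-SNE perplexity must be below N / 3", call. = FALSE)
    }
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
    emb <- Rtsne::Rtsne(cells, dims = 2, perplexity = perplexity,
                        check_duplicates = FALSE)$Y
  }
  rep_seeds <- .spawn_seeds(seed + 1L, reps)
  aris <- vapply(seq_len(reps), function(i) {
    lab <- kmeans_restarts(emb, k, restarts = restarts, seed = rep_seeds[i])
    adjusted_rand_index(lab, true_labels)
  }, numeric(1))
  mean(aris)
}

#' Evaluate an imputation run against ground truth
#'
#' Computes the benchmark metrics comparing a matrix before and after
#' imputation: downstream PCA/K-means ARI of both, average silhouette width
#' of both (Euclidean, true labels), and the zero-change fraction of the
#' imputed output in count space.
#'
#' @param t_before,t_after Log-expression matrices before/after imputation.
#' @param counts Raw counts matching `t_before` (for the count-space
#'   back-transform).
#' @param true_labels Ground-truth cell labels.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param reps Clustering repetitions for [downstream_ari()].
#' @param restarts K-means restarts for [downstream_ari()].
#' @return One-row `data.frame` with columns `ari_before`, `ari_after`,
#'   `silhouette_before`, `silhouette_after`, `zero_change_fraction`,
#'   `seed`, `k`.
#' @export
evaluate_imputation <- function(t_before, t_after, counts, true_labels, k,
                                seed = 1L, reps = 3L, restarts = 50L) {
  imp_counts <- log_to_counts(t_after, counts)
  data.frame(
    ari_before = downstream_ari(t_before, true_labels, "pca", k = k,
                                reps = reps, seed = seed,
                                restarts = restarts),
    ari_after = downstream_ari(t_after, true_labels, "pca", k = k,
                               reps = reps, seed = seed,
                               restarts = restarts),
    silhouette_before = average_silhouette(base::t(t_before), true_labels),
    silhouette_after = average_silhouette(base::t(t_after), true_labels),
    zero_change_fraction = zero_change_fraction(t_before, imp_counts),
    seed = seed, k = k)
}
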