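#' PCA transform of a cell-cell distance matrix
#'
#' Columns of the distance matrix are centered to mean zero and scaled to unit
#' variance, then a singular value decomposition is taken. The principal
#' component scores are the columns `sigma_i * u_i`; the relative variance of
#' component i is `sigma_i^2 / sum(sigma^2)`. Columns with zero variance
#' cannot be scaled; they are left centered-only with a warning.
#'
#' Consensus clustering runs K-means on the *unit-scaled* component columns
#' (`vectors`, the right singular vectors) rather than on the
#' variance-scaled scores: in cell-cell distance matrices the leading
#' component is typically a technical gradient (library size / zero
#' fraction), and on variance-scaled coordinates it swamps the biological
#' structure carried by later components. Unit scaling gives every retained
#' component equal weight, as in the consensus-clustering pipelines this
#' method descends from.
#'
#' @param d Symmetric N x N distance matrix, N >= 3.
#' @return A list of class `"ccimpute_pca"` with elements
#'   `scores` (N x r matrix of component coordinates `sigma_i u_i`,
#'   rows = cells), `vectors` (N x r matrix of unit-norm component columns),
#'   `relative_variance` (length-r, non-increasing, sums to 1), and `r`
#'   (number of strictly positive singular values).
#' @export
pca_transform <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("expected a square distance matrix", call. = FALSE)
  }
  n <- nrow(d)
  if (n < 3L) stop("PCA needs at least 3 cells", call. = FALSE)
  sds <- apply(d, 2L, stats::sd)
  zero_var <- sds == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance column(s) centered but not scaled",
            call. = FALSE)
    sds[zero_var] <- 1
  }
  x <- scale(d, center = TRUE, scale = sds)
  s <- svd(x)
  tol <- max(s$d) * max(dim(x)) * .Machine$double.eps
  r <- sum(s$d > tol)
  if (r == 0L) stop("distance matrix has rank 0 after centering",
                    call. = FALSE)
  scores <- s$u[, seq_len(r), drop = FALSE] %*%
    diag(s$d[seq_len(r)], nrow = r)
  vectors <- s$v[, seq_len(r), drop = FALSE]
  rownames(scores) <- rownames(vectors) <- rownames(d)
  rv <- s$d[seq_len(r)]^2 / sum(s$d^2)
  structure(list(scores = scores, vectors = vectors,
                 relative_variance = rv, r = r),
            class = "ccimpute_pca")
}

#' @export
print.ccimpute_pca <- function(x, ...) {
  cat("PCA of distance matrix:", nrow(x$scores), "cells, rank", x$r, "\n")
  cat("top relative variances:",
      paste(signif(utils::head(x$relative_variance, 5), 3), collapse = ", "),
      "\n")
  invisible(x)
}

# round half away from zero (round() rounds half to even)
.round_half_up <- function(x) floor(x + 0.5)

#' Plan the principal-component sub-datasets for consensus clustering
#'
#' Consensus clustering runs K-means on a family of sub-datasets, the i-th
#' consisting of the first `dims[i]` principal-component score columns, so
#' that the consensus averages clusterings under varying amounts of retained
#' structure. The candidate dimensions are:
#'
#' * fewer than `small_cutoff` cells (default 500): every integer from
#'   `round(small_lo * N)` to `round(small_hi * N)` (defaults 0.04 and 0.07;
#'   half-up rounding) — at these sizes relative component variances are too
#'   noisy to be informative;
#' * `small_cutoff` cells or more: from the first component whose relative
#'   variance drops to `rel_var_start` (default 0.01) or below, through the
#'   first component at or below `rel_var_stop` (default 0.008), one
#'   component at a time. If no component reaches `rel_var_stop`, the range
#'   runs to the last component.
#'
#' Candidates are clamped to `[2, r]`. If more than `max_subsets` remain,
#' every `floor(M / max_subsets)`-th candidate is kept starting from the
#' first, then the list is truncated to `max_subsets`.
#'
#' @param p A `"ccimpute_pca"` object from [pca_transform()].
#' @param n_cells Number of cells N.
#' @param max_subsets Cap on the number of sub-datasets (default 15).
#' @param small_cutoff Cell-count boundary between the two rules (default 500,
#'   inclusive for the variance rule).
#' @param small_lo,small_hi Fractions of N bounding the small-dataset range.
#' @param rel_var_start,rel_var_stop Relative-variance thresholds opening and
#'   closing the large-dataset range.
#' @return Strictly increasing integer vector of component counts, each in
#'   `[2, r]`, length <= `max_subsets`.
#' @export
plan_subdatasets <- function(p, n_cells, max_subsets = 15L,
                             small_cutoff = 500L,
                             small_lo = 0.04, small_hi = 0.07,
                             rel_var_start = 0.01, rel_var_stop = 0.008) {
  stopifnot(inherits(p, "ccimpute_pca"), n_cells >= 3, max_subsets >= 1)
  r <- p$r
  if (n_cells < small_cutoff) {
    lo <- .round_half_up(small_lo * n_cells)
    hi <- .round_half_up(small_hi * n_cells)
  } else {
    rv <- p$relative_variance
    lo <- match(TRUE, rv <= rel_var_start)
    if (is.na(lo)) {
      stop("no principal component reaches relative variance <= ",
           rel_var_start, call. = FALSE)
    }
    hi <- match(TRUE, rv <= rel_var_stop)
    if (is.na(hi)) hi <- r
  }
  lo <- max(2L, as.integer(lo))
  hi <- min(as.integer(hi), r)
  if (hi < lo) {
    stop("empty sub-dataset range after clamping (lo = ", lo, ", hi = ", hi,
         ", rank = ", r, ")", call. = FALSE)
  }
  dims <- seq.int(lo, hi)
  m <- length(dims)
  if (m > max_subsets) {
    stride <- m %/% max_subsets
    dims <- dims[seq.int(1L, m, by = stride)]
    dims <- dims[seq_len(min(length(dims), max_subsets))]
  }
  dims
}
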