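#' Per-gene variance weights
#'
#' Weights for the weighted Spearman distance: the sample variance
#' (denominator n - 1) of each gene's row across cells of the log-transformed
#' matrix. Genes with high variance carry more information about cell-cell
#' similarity and are less dominated by dropout noise.
#'
#' @param t Genes x cells log-expression matrix with >= 2 cells.
#' @return Numeric vector of per-gene variances.
#' @export
gene_weights <- function(t) {
  if (!is.matrix(t) || ncol(t) < 2L) {
    stop("gene weights need a matrix with at least 2 cells", call. = FALSE)
  }
  w <- apply(t, 1L, stats::var)
  if (all(w == 0)) {
    stop("all genes are constant across cells; weights are degenerate",
         call. = FALSE)
  }
  w
}

#' Weighted rank of a vector
#'
#' Ranks the entries of `beta` with observation weights `w`. The rank of
#' element j is `a_j + b_j`, where `a_j` is the total weight of entries
#' strictly smaller than `beta[j]`, and `b_j` handles ties: for the tied group
#' containing j (size n_g, mean weight w-bar), `b_j = (n_g + 1) / 2 * w-bar` —
#' the average, over all orderings of the tied units, of the mean
#' cumulative-weight rank, shared by every member of the group. A singleton is
#' a tied group of size 1, so an untied element gets
#' (weight strictly below) + its own weight.
#'
#' With unit weights this reproduces standard fractional (mid-rank) ranking.
#'
#' @param beta Numeric vector to rank.
#' @param w Non-negative weights, same length as `beta`.
#' @return Numeric vector of weighted ranks.
#' @export
#' @examples
#' weighted_rank(c(3, 1, 2), c(1, 1, 1))   # 3 1 2
#' weighted_rank(c(1, 2, 2), c(1, 1, 1))   # 1 2.5 2.5
weighted_rank <- function(beta, w) {
  if (length(beta) != length(w)) {
    stop("beta and w must have the same length", call. = FALSE)
  }
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  n <- length(beta)
  if (n == 0L) return(numeric(0))
  o <- order(beta)
  b_s <- beta[o]
  w_s <- w[o]
  # runs of equal values along the sorted vector = tied groups
  grp <- cumsum(c(1L, b_s[-1L] != b_s[-n]))
  csum <- cumsum(w_s)
  sizes <- tabulate(grp)
  last <- cumsum(sizes)
  # total weight strictly below each group
  a_grp <- c(0, csum[last])[seq_along(sizes)]
  wbar_grp <- (csum[last] - a_grp) / sizes
  b_grp <- (sizes + 1) / 2 * wbar_grp
  r <- numeric(n)
  r[o] <- (a_grp + b_grp)[grp]
  r
}

#' Weighted Pearson correlation
#'
#' Pearson correlation with observation weights:
#' `sum(w (x - xbar)(y - ybar)) / sqrt(sum(w (x - xbar)^2) sum(w (y - ybar)^2))`
#' where `xbar`, `ybar` are weighted means. With uniform weights this equals
#' the ordinary Pearson coefficient.
#'
#' @param x,y Numeric vectors of equal length.
#' @param w Non-negative weights, same length, with positive total.
#' @return Correlation in `[-1, 1]`.
#' @export
weighted_pearson <- function(x, y, w) {
  if (length(x) != length(y) || length(x) != length(w)) {
    stop("x, y and w must have the same length", call. = FALSE)
  }
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  sw <- sum(w)
  if (sw <= 0) stop("weights sum to zero", call. = FALSE)
  xc <- x - sum(w * x) / sw
  yc <- y - sum(w * y) / sw
  vx <- sum(w * xc^2)
  vy <- sum(w * yc^2)
  if (vx <= 0 || vy <= 0) {
    stop("zero weighted variance; correlation undefined", call. = FALSE)
  }
  r <- sum(w * xc * yc) / sqrt(vx * vy)
  min(1, max(-1, r))
}

#' Weighted Spearman distance matrix between cells
#'
#' Each cell's gene-expression column is weighted-ranked
#' (see [weighted_rank()]) with the shared per-gene weights, then every pair
#' of rank vectors is compared with the weighted Pearson correlation and
#' converted to a distance `d = 1 - rho` (so distances lie in `[0, 2]`).
#' The diagonal is forced to 0.
#'
#' A cell whose ranks have zero weighted variance (all positively-weighted
#' genes tied) has no defined correlation; its distances to every other cell
#' are set to the maximum 2 with a warning.
#'
#' @param t Genes x cells log-expression matrix, >= 2 cells.
#' @param w Per-gene weights; defaults to [gene_weights()] of `t`.
#' @return Symmetric N x N distance matrix with zero diagonal.
#' @export
weighted_spearman_distance_matrix <- function(t, w = gene_weights(t)) {
  if (!is.matrix(t) || ncol(t) < 2L) {
    stop("need a matrix with at least 2 cells", call. = FALSE)
  }
  if (length(w) != nrow(t)) {
    stop("one weight per gene required", call. = FALSE)
  }
  if (any(w < 0) || sum(w) <= 0) {
    stop("weights must be non-negative with positive total", call. = FALSE)
  }
  n <- ncol(t)
  ranks <- apply(t, 2L, weighted_rank, w = w)
  sw <- sum(w)
  ctr <- sweep(ranks, 2L, colSums(w * ranks) / sw)      # weighted-centered
  a <- sqrt(w) * ctr                                    # so crossprod = w-cov
  ss <- colSums(a^2)
  bad <- ss <= 0
  ss[bad] <- 1
  rho <- crossprod(a) / sqrt(outer(ss, ss))
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  d <- 1 - rho
  if (any(bad)) {
    warning(sum(bad), " cell(s) with zero weighted rank variance; ",
            "distances set to the maximum 2", call. = FALSE)
    d[bad, ] <- 2
    d[, bad] <- 2
  }
  d <- (d + base::t(d)) / 2   # enforce exact symmetry
  diag(d) <- 0
  dimnames(d) <- list(colnames(t), colnames(t))
  d
}
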