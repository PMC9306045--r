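#' Algorithm parameters
#'
#' Bundles every tunable of the imputation pipeline with its default:
#'
#' * `threshold` (0.65): consensus entries below this are treated as noise and
#'   removed before voting; lower it for higher-quality clusterings.
#' * `max_subsets` (15): cap on the number of principal-component sub-datasets.
#' * `restarts_small` / `restarts_large` (1000 / 50): K-means random restarts
#'   for datasets with at most / more than `restart_cutoff` (2000) cells.
#' * `max_iter` (1e9): K-means iteration cap; convergence (stable assignments)
#'   normally occurs long before.
#' * `small_dataset_cutoff` (500): below this many cells the sub-dataset plan
#'   uses the fixed `[0.04 N, 0.07 N]` range (`small_range_lo` /
#'   `small_range_hi`); at or above it, the relative-variance thresholds
#'   `rel_var_start` (0.01) and `rel_var_stop` (0.008) apply.
#'
#' @param threshold Consensus threshold in `[0, 1]`.
#' @param max_subsets Positive integer.
#' @param restarts_small,restarts_large Positive integers.
#' @param restart_cutoff Cell count above which `restarts_large` applies.
#' @param max_iter K-means iteration cap.
#' @param small_dataset_cutoff Cell-count boundary for the sub-dataset rule.
#' @param small_range_lo,small_range_hi Fractions of N for the small-N range.
#' @param rel_var_start,rel_var_stop Relative-variance thresholds for the
#'   large-N range.
#' @return A named list of validated parameters.
#' @export
ccimpute_config <- function(threshold = 0.65,
                            max_subsets = 15L,
                            restarts_small = 1000L,
                            restarts_large = 50L,
                            restart_cutoff = 2000L,
                            max_iter = 1e9,
                            small_dataset_cutoff = 500L,
                            small_range_lo = 0.04,
                            small_range_hi = 0.07,
                            rel_var_start = 0.01,
                            rel_var_stop = 0.008) {
  cfg <- list(threshold = threshold, max_subsets = as.integer(max_subsets),
              restarts_small = as.integer(restarts_small),
              restarts_large = as.integer(restarts_large),
              restart_cutoff = as.integer(restart_cutoff),
              max_iter = max_iter,
              small_dataset_cutoff = as.integer(small_dataset_cutoff),
              small_range_lo = small_range_lo,
              small_range_hi = small_range_hi,
              rel_var_start = rel_var_start, rel_var_stop = rel_var_stop)
  stopifnot(cfg$threshold >= 0, cfg$threshold <= 1,
            cfg$max_subsets >= 1, cfg$restarts_small >= 1,
            cfg$restarts_large >= 1, cfg$restart_cutoff >= 1,
            cfg$max_iter >= 1, cfg$small_dataset_cutoff >= 1,
            cfg$small_range_lo > 0,
            cfg$small_range_hi >= cfg$small_range_lo,
            cfg$rel_var_start > 0, cfg$rel_var_stop > 0,
            cfg$rel_var_stop <= cfg$rel_var_start)
  cfg
}

#' Turn a consensus matrix into row-stochastic voting weights
#'
#' A cell's own influence (the diagonal) and all consensus entries below
#' `threshold` are removed; each remaining row is rescaled to sum to 1. Rows
#' left with no surviving entry become all-zero (such cells cast no votes and
#' receive no imputation).
#'
#' @param c N x N consensus matrix with entries in `[0, 1]`.
#' @param threshold Number in `[0, 1]`.
#' @return N x N weight matrix: zero diagonal, non-negative entries, every
#'   row summing to 1 or identically zero.
#' @export
process_consensus <- function(c, threshold = 0.65) {
  if (!is.matrix(c) || nrow(c) != ncol(c)) {
    stop("expected a square consensus matrix", call. = FALSE)
  }
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  p <- c
  diag(p) <- 0
  p[p < threshold] <- 0
  rs <- rowSums(p)
  keep <- rs > 0
  p[keep, ] <- p[keep, , drop = FALSE] / rs[keep]
  p[!keep, ] <- 0
  p
}

#' Classify zero entries as dropouts by weighted vote
#'
#' For each zero entry (gene g, cell i), every other cell j casts a vote of
#' magnitude `p[i, j]`: positive if cell j expresses gene g (`t[g, j] > 0`),
#' negative otherwise. The entry is a dropout when the vote sum is strictly
#' positive. Non-zero entries are never dropouts; cells with an all-zero
#' weight row never mark dropouts.
#'
#' @param t Genes x cells log-expression matrix.
#' @param p N x N row-stochastic weight matrix from [process_consensus()].
#' @return Genes x cells logical matrix, `TRUE` where a zero is judged a
#'   dropout.
#' @export
identify_dropouts <- function(t, p) {
  if (ncol(t) != nrow(p) || nrow(p) != ncol(p)) {
    stop("weight matrix must be N x N for N = ncol(t)", call. = FALSE)
  }
  expressed <- (t > 0) * 1
  # votes[g, i] = sum_j p[i,j] * (+1 if expressed, -1 otherwise)
  votes <- 2 * (expressed %*% base::t(p))
  votes <- sweep(votes, 2L, rowSums(p))
  mask <- (t == 0) & (votes > 0)
  dimnames(mask) <- dimnames(t)
  mask
}

#' Impute dropouts as consensus-weighted means via a linear system
#'
#' Each dropout value is the weighted mean of the same gene's values in the
#' voting cells. Because some of those values are themselves dropouts still
#' to be imputed, the per-gene problem is the linear system
#' `(I - P_DD) x_D = P_DO e_O`, with `P` the weight matrix restricted to
#' dropout (D) and observed (O) cells of that gene and `e_O` the observed
#' entries. Genes whose system is singular keep their dropouts at 0 (with a
#' warning count); negative numerical solutions are clamped to 0. All entries
#' not flagged in `mask` pass through bit-identical.
#'
#' @param t Genes x cells log-expression matrix.
#' @param p N x N weight matrix from [process_consensus()].
#' @param mask Logical dropout mask from [identify_dropouts()].
#' @return The imputed log-expression matrix.
#' @export
solve_imputation <- function(t, p, mask) {
  if (!all(dim(t) == dim(mask)) || ncol(t) != nrow(p)) {
    stop("inconsistent dimensions", call. = FALSE)
  }
  out <- t
  genes <- which(rowSums(mask) > 0)
  n_singular <- 0L
  for (g in genes) {
    dd <- which(mask[g, ])
    oo <- which(!mask[g, ])
    pd <- p[dd, , drop = FALSE]
    a <- diag(length(dd)) - pd[, dd, drop = FALSE]
    b <- pd[, oo, drop = FALSE] %*% t[g, oo]
    x <- tryCatch(solve(a, b), error = function(e) NULL)
    if (is.null(x)) {
      n_singular <- n_singular + 1L
      next
    }
    x[x < 0 | !is.finite(x)] <- 0
    out[g, dd] <- x
  }
  if (n_singular > 0L) {
    warning(n_singular, " gene(s) with a singular imputation system; their ",
            "dropouts were left at 0", call. = FALSE)
  }
  out
}

#' Consensus-clustering imputation of dropout events
#'
#' End-to-end imputation of a log-transformed expression matrix:
#' [build_consensus()] -> [process_consensus()] -> [identify_dropouts()] ->
#' [solve_imputation()]. Only zero entries judged to be dropouts change; all
#' non-zero input entries are bit-identical in the output, and the output is
#' non-negative. Deterministic given `seed`.
#'
#' @param t Genes x cells log-expression matrix (typically from
#'   [preprocess_counts()]).
#' @param k Number of cell clusters.
#' @param cfg Parameters from [ccimpute_config()].
#' @param seed Integer seed.
#' @param consensus Optional precomputed `"ccimpute_consensus"` object for
#'   `t` (skips the clustering stage).
#' @return An object of class `"ccimpute_fit"`: a list with `imputed`
#'   (the imputed log matrix), `mask` (dropout calls), `weights` (voting
#'   weight matrix), `consensus` (the [build_consensus()] result), `k`,
#'   `seed` and `cfg`.
#' @export
#' @examples
#' sim <- simulate_counts(sim_params(n_genes = 150, n_cells = 60), seed = 1)
#' t <- preprocess_counts(sim$counts)
#' fit <- ccimpute(t, k = 4, seed = 1)
#' fit
ccimpute <- function(t, k, cfg = ccimpute_config(), seed = 1L,
                     consensus = NULL) {
  if (is.null(consensus)) {
    consensus <- build_consensus(t, k, cfg = cfg, seed = seed)
  } else if (!inherits(consensus, "ccimpute_consensus")) {
    stop("consensus must come from build_consensus()", call. = FALSE)
  }
  p <- process_consensus(consensus$consensus, cfg$threshold)
  mask <- identify_dropouts(t, p)
  imputed <- solve_imputation(t, p, mask)
  structure(list(imputed = imputed, mask = mask, weights = p,
                 consensus = consensus, k = k, seed = seed, cfg = cfg),
            class = "ccimpute_fit")
}

#' @export
print.ccimpute_fit <- function(x, ...) {
  n_zero <- sum(x$imputed == 0) + sum(x$mask & x$imputed > 0)
  cat("ccimpute fit:", nrow(x$imputed), "genes x", ncol(x$imputed),
      "cells, k =", x$k, "\n")
  cat("dropouts imputed:", sum(x$mask), "of", n_zero,
      "zero entries (threshold", x$cfg$threshold, ")\n")
  invisible(x)
}

#' Back-transform an imputed log matrix to count space
#'
#' Inverts the `log2(CPM + 1)` transform (`2^x - 1`) and rescales each cell
#' by its original total count divided by the CPM scale factor, giving
#' imputed values on the scale of the raw counts.
#'
#' @param imputed Imputed log matrix (genes must match `counts` after
#'   filtering).
#' @param counts The raw count matrix the log matrix was derived from (used
#'   for per-cell totals).
#' @param scale CPM scale factor used during normalization.
#' @return Matrix of imputed values in count space.
#' @export
log_to_counts <- function(imputed, counts, scale = 1e6) {
  if (ncol(imputed) != ncol(counts)) {
    stop("cell dimensions disagree", call. = FALSE)
  }
  totals <- colSums(counts)
  sweep(2^imputed - 1, 2L, totals / scale, `*`)
}
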