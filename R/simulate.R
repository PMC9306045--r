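#' Simulation parameters
#'
#' Parameters of the Splatter-style generative model used to benchmark
#' imputation: gamma gene means, categorical group membership with uneven
#' probabilities, log-normal group differential-expression factors, log-normal
#' library sizes, gamma-Poisson (negative binomial) counts, and logistic
#' dropout applied to every cell.
#'
#' Defaults describe four unevenly sized cell populations
#' (probabilities 0.15, 0.20, 0.30, 0.35) of 500 cells by 2000 genes, with
#' differential expression strong enough to make the groups separable and a
#' dropout regime removing roughly a third to a half of non-zero entries.
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param group_probs Group membership probabilities (sum to 1).
#' @param mean_shape,mean_rate Gamma parameters for base gene means.
#' @param libsize_loc,libsize_scale Log-normal meanlog/sdlog of library sizes.
#' @param de_prob Fraction of genes differentially expressed per group.
#' @param de_factor_loc,de_factor_scale Log-normal meanlog/sdlog of the
#'   multiplicative differential-expression factors.
#' @param bcv Biological coefficient of variation; counts are negative
#'   binomial with dispersion `bcv^2`.
#' @param dropout_mid,dropout_shape Logistic dropout parameters: the
#'   probability of zeroing an entry with mean `lambda` is
#'   `plogis(dropout_shape * (log(lambda + 1) - dropout_mid))`. With a
#'   negative shape, lowly expressed entries drop out most. Set
#'   `dropout_mid = -Inf` (with negative shape) for no dropout.
#' @return Validated parameter list of class `"sim_params"`.
#' @export
sim_params <- function(n_genes = 2000L, n_cells = 500L,
                       group_probs = c(0.15, 0.20, 0.30, 0.35),
                       mean_shape = 0.6, mean_rate = 0.3,
                       libsize_loc = 11, libsize_scale = 0.2,
                       de_prob = 0.1,
                       de_factor_loc = 0.3, de_factor_scale = 0.4,
                       bcv = 0.2,
                       dropout_mid = 2.5, dropout_shape = -1) {
  p <- list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
            group_probs = group_probs, mean_shape = mean_shape,
            mean_rate = mean_rate, libsize_loc = libsize_loc,
            libsize_scale = libsize_scale, de_prob = de_prob,
            de_factor_loc = de_factor_loc,
            de_factor_scale = de_factor_scale, bcv = bcv,
            dropout_mid = dropout_mid, dropout_shape = dropout_shape)
  stopifnot(p$n_genes >= 1, p$n_cells >= 1,
            all(p$group_probs >= 0), abs(sum(p$group_probs) - 1) < 1e-8,
            p$mean_shape > 0, p$mean_rate > 0, p$libsize_scale > 0,
            p$de_prob >= 0, p$de_prob <= 1, p$de_factor_scale > 0,
            p$bcv > 0)
  class(p) <- "sim_params"
  p
}

#' Simulate scRNA-seq counts with known groups and a dropout mask
#'
#' Draws a genes x cells count matrix from the model in [sim_params()]:
#'
#' 1. base gene means ~ Gamma(`mean_shape`, rate = `mean_rate`);
#' 2. cell groups ~ Categorical(`group_probs`);
#' 3. per group, a random `de_prob` fraction of genes is scaled by a
#'    log-normal(`de_factor_loc`, `de_factor_scale`) factor;
#' 4. library sizes ~ log-normal(`libsize_loc`, `libsize_scale`);
#' 5. entry means `lambda[g, c] = libsize[c] * mu[g, group(c)] /
#'    sum_g mu[g, group(c)]`; counts ~ negative binomial with mean `lambda`
#'    and size `1 / bcv^2`;
#' 6. logistic dropout zeroes each entry independently with probability
#'    `plogis(dropout_shape * (log(lambda + 1) - dropout_mid))`; the mask
#'    records every non-zero true count that was zeroed.
#'
#' Deterministic given `seed`.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return A list of class `"sim_result"`: `counts` (post-dropout),
#'   `true_counts` (pre-dropout), `labels` (integer group per cell),
#'   `dropout_mask` (logical, `TRUE` where dropout zeroed a non-zero count).
#' @export
simulate_counts <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  g <- params$n_genes
  n <- params$n_cells
  n_groups <- length(params$group_probs)
  base_means <- stats::rgamma(g, shape = params$mean_shape,
                              rate = params$mean_rate)
  labels <- sample.int(n_groups, n, replace = TRUE,
                       prob = params$group_probs)
  # group-specific mean profiles
  group_means <- matrix(base_means, g, n_groups)
  n_de <- round(params$de_prob * g)
  for (grp in seq_len(n_groups)) {
    if (n_de == 0L) next
    de_genes <- sample.int(g, n_de)
    fac <- stats::rlnorm(n_de, meanlog = params$de_factor_loc,
                         sdlog = params$de_factor_scale)
    group_means[de_genes, grp] <- group_means[de_genes, grp] * fac
  }
  libsize <- stats::rlnorm(n, meanlog = params$libsize_loc,
                           sdlog = params$libsize_scale)
  profile <- sweep(group_means, 2L, colSums(group_means), `/`)
  lambda <- profile[, labels, drop = FALSE] *
    rep(libsize, each = g)
  true_counts <- matrix(
    stats::rnbinom(g * n, mu = lambda, size = 1 / params$bcv^2), g, n)
  drop_prob <- stats::plogis(
    params$dropout_shape * (log(lambda + 1) - params$dropout_mid))
  dropped <- matrix(stats::runif(g * n) < drop_prob, g, n)
  counts <- true_counts
  counts[dropped] <- 0
  mask <- dropped & true_counts > 0
  dimnames(counts) <- dimnames(true_counts) <- dimnames(mask) <-
    list(paste0("gene", seq_len(g)), paste0("cell", seq_len(n)))
  structure(list(counts = counts, true_counts = true_counts,
                 labels = labels, dropout_mask = mask, params = params,
                 seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("simulated scRNA-seq data:", nrow(x$counts), "genes x",
      ncol(x$counts), "cells,", length(x$params$group_probs), "groups\n")
  cat(sprintf("dropout rate: %.3f of non-zero true counts\n",
              dropout_rate(x)))
  invisible(x)
}

#' Fraction of non-zero true counts lost to dropout
#'
#' @param r A `"sim_result"` from [simulate_counts()].
#' @return Number in `[0, 1]`; 0 when the simulation had no dropout.
#' @export
dropout_rate <- function(r) {
  stopifnot(inherits(r, "sim_result"))
  nz <- sum(r$true_counts > 0)
  if (nz == 0L) return(0)
  sum(r$dropout_mask) / nz
}
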