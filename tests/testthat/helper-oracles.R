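# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the implementation.

# all permutations of a vector (n! rows) -- tiny n only
perms <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1L))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# weighted-rank oracle: for each tied group, enumerate every ordering of the
# tied units' weights, take the mean of the cumulative-weight rank vector
# (the shared rank of the group under that ordering), and average over
# orderings; add the total weight strictly below the group.
oracle_weighted_rank <- function(beta, w) {
  r <- numeric(length(beta))
  for (val in unique(beta)) {
    idx <- which(beta == val)
    a <- sum(w[beta < val])
    ords <- perms(w[idx])
    shared <- mean(apply(ords, 1L, function(o) mean(cumsum(o))))
    r[idx] <- a + shared
  }
  r
}

# adjusted Rand index from the four pair-agreement counts (no contingency
# table): ARI = 2 (n11 n00 - n10 n01) /
#              ((n11 + n10)(n10 + n00) + (n11 + n01)(n01 + n00))
oracle_ari <- function(x, y) {
  n <- length(x)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sx <- x[i] == x[j]
      sy <- y[i] == y[j]
      if (sx && sy) n11 <- n11 + 1
      else if (!sx && !sy) n00 <- n00 + 1
      else if (sx) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# fixed-point oracle for the per-gene imputation system:
# x <- P_DD x + P_DO e_O iterated from zero until convergence
oracle_impute_gene <- function(e, p, dropout_idx, tol = 1e-13,
                               max_iter = 100000L) {
  obs_idx <- setdiff(seq_along(e), dropout_idx)
  x <- rep(0, length(dropout_idx))
  pdd <- p[dropout_idx, dropout_idx, drop = FALSE]
  rhs <- p[dropout_idx, obs_idx, drop = FALSE] %*% e[obs_idx]
  for (i in seq_len(max_iter)) {
    x_new <- as.vector(pdd %*% x + rhs)
    if (max(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  x
}

# small labelled count matrix with planted groups, for fast pipeline tests
make_grouped_counts <- function(n_genes = 120L, n_cells = 60L, k = 3L,
                                seed = 42L, dropout = 0.3) {
  set.seed(seed)
  labels <- sort(rep_len(seq_len(k), n_cells))
  means <- matrix(rgamma(n_genes * k, 2, 0.5) * 5, n_genes, k)
  counts <- sapply(labels, function(g) rpois(n_genes, means[, g]))
  if (dropout > 0) {
    counts[matrix(runif(length(counts)) < dropout,
                  n_genes, n_cells)] <- 0
  }
  dimnames(counts) <- list(paste0("g", seq_len(n_genes)),
                           paste0("c", seq_len(n_cells)))
  list(counts = counts, labels = labels)
}

# random row-stochastic weight matrix with zero diagonal
make_weight_matrix <- function(n, seed = 1L, sparsity = 0.3) {
  set.seed(seed)
  p <- matrix(runif(n * n), n, n)
  p[matrix(runif(n * n) < sparsity, n, n)] <- 0
  diag(p) <- 0
  rs <- rowSums(p)
  keep <- rs > 0
  p[keep, ] <- p[keep, , drop = FALSE] / rs[keep]
  p
}
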