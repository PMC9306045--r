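test_that("ARI is 1 for identical partitions and 0 for the textbook case", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0)
  expect_error(adjusted_rand_index(1:3, 1:4), "same cells")
})

test_that("ARI agrees with the all-pairs oracle and mclust on random cases", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    ours <- adjusted_rand_index(x, y)
    expect_equal(ours, oracle_ari(x, y), tolerance = 1e-12)
    expect_equal(ours, mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})

test_that("ARI is symmetric, relabel-invariant, and near zero for noise", {
  set.seed(103)
  x <- sample(1:4, 60, replace = TRUE)
  y <- sample(1:4, 60, replace = TRUE)
  expect_equal(adjusted_rand_index(x, y), adjusted_rand_index(y, x))
  relab <- c(4, 1, 3, 2)[x]
  expect_equal(adjusted_rand_index(x, relab), 1)
  shuffles <- vapply(1:100, function(i) {
    adjusted_rand_index(x, sample(x))
  }, numeric(1))
  expect_lt(abs(mean(shuffles)), 0.05)
})

test_that("silhouette matches direct computation on two tight pairs", {
  data <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  labs <- c(1, 1, 2, 2)
  # every point: a = 0.1, b = (10 + 9.9) / 2 = 9.95 ... mean s ~ 0.99
  expect_equal(average_silhouette(data, labs), 0.98995, tolerance = 1e-4)
  expect_error(average_silhouette(data, rep(1, 4)), "single cluster")
})

test_that("silhouette agrees with the cluster package on random data", {
  set.seed(107)
  for (i in 1:10) {
    n <- sample(10:30, 1)
    data <- matrix(rnorm(n * 3), n, 3)
    labs <- sample(1:3, n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    ref <- mean(cluster::silhouette(labs, dist(data))[, "sil_width"])
    expect_equal(average_silhouette(data, labs), ref, tolerance = 1e-10)
  }
})

test_that("silhouette singleton rule and rigid-motion invariance hold", {
  data <- matrix(rnorm(12), 6, 2)
  expect_equal(average_silhouette(data, 1:6), 0)   # all singletons
  labs <- c(1, 1, 2, 2, 3, 3)
  base <- average_silhouette(data, labs)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  expect_equal(average_silhouette(data %*% rot + 5, labs), base,
               tolerance = 1e-10)
  # interleaved identical clusters cannot be separated
  inter <- rbind(data, data)
  expect_lte(average_silhouette(inter, rep(1:2, each = 6)), 0)
})

test_that("zero-change fraction counts rewritten zeros only", {
  orig <- matrix(c(0, 0, 0, 0, 0, 2, 3, 0, 0, 0), 2, 5)
  imp <- orig
  zeros <- which(orig == 0)
  imp[zeros[1:4]] <- c(0.6, 1.2, 0.5, 0.49)   # three at/above the cutoff
  expect_equal(zero_change_fraction(orig, imp), 3 / 8)
  expect_equal(zero_change_fraction(orig, orig), 0)
  imp2 <- orig; imp2[orig == 0] <- 1
  expect_equal(zero_change_fraction(orig, imp2), 1)
  expect_error(zero_change_fraction(matrix(1, 2, 2), matrix(1, 2, 2)),
               "no zero entries")
})

test_that("downstream clustering harness behaves at the two extremes", {
  sim <- simulate_counts(
    sim_params(n_genes = 300, n_cells = 150, de_factor_loc = 1.5,
               dropout_mid = -Inf), seed = 21)
  t0 <- preprocess_counts(sim$counts)
  ari <- downstream_ari(t0, sim$labels, "pca", k = 4, reps = 2, seed = 1,
                        restarts = 25)
  expect_gte(ari, 0.99)   # clean, well-separated: near-perfect recovery
  shuffled <- sample(sim$labels)
  ari0 <- downstream_ari(t0, shuffled, "pca", k = 4, reps = 2, seed = 1,
                         restarts = 25)
  expect_lt(abs(ari0), 0.05)
})

test_that("t-SNE harness runs when available and rejects high perplexity", {
  skip_if_not_installed("Rtsne")
  sim <- simulate_counts(
    sim_params(n_genes = 200, n_cells = 120, de_factor_loc = 1.5,
               dropout_mid = -Inf), seed = 22)
  t0 <- preprocess_counts(sim$counts)
  expect_error(
    downstream_ari(t0, sim$labels, "tsne", k = 4, perplexity = 50),
    "perplexity")
  ari <- downstream_ari(t0, sim$labels, "tsne", k = 4, reps = 1, seed = 2,
                        restarts = 10, perplexity = 15)
  expect_gt(ari, 0.8)
})

test_that("evaluate_imputation returns a complete one-row report", {
  dat <- make_grouped_counts(n_genes = 120, n_cells = 50, k = 3, seed = 15)
  t0 <- preprocess_counts(dat$counts)
  fit <- ccimpute(t0, k = 3, cfg = ccimpute_config(restarts_small = 10),
                  seed = 3)
  counts <- filter_unexpressed_genes(dat$counts)
  ev <- evaluate_imputation(t0, fit$imputed, counts, dat$labels, k = 3,
                            seed = 3, reps = 1, restarts = 10)
  expect_s3_class(ev, "data.frame")
  expect_identical(nrow(ev), 1L)
  expect_true(all(c("ari_before", "ari_after", "silhouette_before",
                    "silhouette_after", "zero_change_fraction")
                  %in% names(ev)))
  expect_true(ev$zero_change_fraction >= 0 && ev$zero_change_fraction <= 1)
  expect_true(abs(ev$ari_after) <= 1 && abs(ev$silhouette_after) <= 1)
})
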