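test_that("consensus post-processing yields row-stochastic voting weights", {
  cm <- rbind(c(1.0, 0.8, 0.3),
              c(0.8, 1.0, 0.4),
              c(0.3, 0.4, 1.0))
  p <- process_consensus(cm, 0.5)
  expect_equal(p[1, ], c(0, 1, 0))       # self + sub-threshold removed
  expect_equal(p[3, ], c(0, 0, 0))       # fully pruned row: all zero, no NaN
  cm2 <- rbind(c(1.0, 0.6, 0.6), c(0.6, 1, 0), c(0.6, 0, 1))
  expect_equal(process_consensus(cm2, 0.5)[1, ], c(0, 0.5, 0.5))
  expect_error(process_consensus(cm, 1.5), "threshold")
  # every row sums to exactly 0 or 1
  set.seed(77)
  big <- consensus_matrix(lapply(1:6, function(i) sample(1:3, 20, TRUE)))
  pb <- process_consensus(big, 0.4)
  rs <- rowSums(pb)
  expect_true(all(abs(rs - 1) < 1e-12 | rs == 0))
  expect_equal(unname(diag(pb)), rep(0, 20))
})

test_that("weighted votes split dropouts from true zeros", {
  # 1 gene, 3 cells; cell 3 has the zero under scrutiny
  t0 <- matrix(c(2, 4, 0), 1, 3)
  p_both <- rbind(c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  m <- identify_dropouts(t0, p_both)
  expect_true(m[1, 3])                    # both neighbors express: vote +1
  expect_false(any(m[1, 1:2]))            # nonzero entries never masked

  t0b <- matrix(c(0, 0, 0), 1, 3)
  expect_false(any(identify_dropouts(t0b, p_both)))  # all votes -1

  t0c <- matrix(c(3, 0, 0), 1, 3)
  p_c <- rbind(c(0, .6, .4), c(.6, 0, .4), c(.6, .4, 0))
  mc <- identify_dropouts(t0c, p_c)
  expect_true(mc[1, 2])                   # vote 0.6 - 0.4 = +0.2
  expect_true(mc[1, 3])

  # tie votes are not dropouts; zero-weight rows cast/receive nothing
  p_tie <- rbind(c(0, .5, .5), c(.5, 0, .5), c(0, 0, 0))
  t0d <- matrix(c(1, 0, 0), 1, 3)
  md <- identify_dropouts(t0d, p_tie)
  expect_false(md[1, 2])                  # +0.5 - 0.5 = 0, strict rule
  expect_false(md[1, 3])                  # all-zero weight row
})

test_that("voting is invariant to positive rescaling before normalization", {
  set.seed(79)
  cm <- consensus_matrix(lapply(1:5, function(i) sample(1:2, 12, TRUE)))
  t0 <- matrix(rpois(8 * 12, 1), 8, 12)
  p1 <- process_consensus(cm, 0.3)
  p2 <- process_consensus(cm * 1, 0.3)
  scaled <- p1 * 7        # rescale rows, then re-normalize
  rs <- rowSums(scaled)
  scaled[rs > 0, ] <- scaled[rs > 0, ] / rs[rs > 0]
  expect_equal(identify_dropouts(t0, scaled), identify_dropouts(t0, p2))
})

test_that("single dropout imputes to the plain weighted mean", {
  t0 <- matrix(c(1, 3, 0), 1, 3)
  p <- rbind(c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  mask <- matrix(c(FALSE, FALSE, TRUE), 1, 3)
  out <- solve_imputation(t0, p, mask)
  expect_equal(out[1, 3], 0.5 * 1 + 0.5 * 3)
  expect_identical(out[1, 1:2], t0[1, 1:2])
})

test_that("interdependent dropouts solve to the fixed point", {
  # cells 1, 2 dropouts leaning on each other and on observed cell 3
  t0 <- matrix(c(0, 0, 2), 1, 3)
  p <- rbind(c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  mask <- matrix(c(TRUE, TRUE, FALSE), 1, 3)
  out <- solve_imputation(t0, p, mask)
  expect_equal(out[1, 1], 2, tolerance = 1e-10)
  expect_equal(out[1, 2], 2, tolerance = 1e-10)
})

test_that("linear solve matches the fixed-point oracle on random instances", {
  set.seed(83)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    g <- sample(2:6, 1)
    p <- make_weight_matrix(n, seed = i)
    t0 <- matrix(rexp(g * n) * rbinom(g * n, 1, 0.6), g, n)
    mask <- t0 == 0 & matrix(runif(g * n) < 0.7, g, n)
    # rows with zero weights receive no imputation
    mask[, rowSums(p) == 0] <- FALSE
    out <- suppressWarnings(solve_imputation(t0, p, mask))
    for (gene in seq_len(g)) {
      dd <- which(mask[gene, ])
      if (!length(dd)) {
        expect_identical(out[gene, ], t0[gene, ])
        next
      }
      # the fixed point exists only when the dropout block is contractive
      pdd <- p[dd, dd, drop = FALSE]
      if (max(Mod(eigen(pdd, only.values = TRUE)$values)) >= 0.999) next
      oracle <- oracle_impute_gene(t0[gene, ], p, dd)
      expect_equal(out[gene, dd], pmax(oracle, 0), tolerance = 1e-8)
    }
  }
})

test_that("imputation never touches entries outside the mask", {
  set.seed(89)
  t0 <- matrix(rexp(50) * rbinom(50, 1, 0.5), 5, 10)
  p <- make_weight_matrix(10, seed = 4)
  mask <- identify_dropouts(t0, p)
  out <- suppressWarnings(solve_imputation(t0, p, mask))
  expect_identical(out[!mask], t0[!mask])
  expect_true(all(out >= 0))
})

test_that("end-to-end imputation preserves nonzero entries bit-for-bit", {
  dat <- make_grouped_counts(n_genes = 150, n_cells = 60, k = 3, seed = 6)
  t0 <- preprocess_counts(dat$counts)
  cfg <- ccimpute_config(restarts_small = 25)
  fit <- ccimpute(t0, k = 3, cfg = cfg, seed = 11)
  nz <- t0 != 0
  expect_identical(fit$imputed[nz], t0[nz])
  expect_true(all(fit$imputed >= 0))
  expect_false(any(fit$mask & nz))
  # a matrix with no zeros comes back identical
  t_dense <- t0 + 0.01
  fit_d <- ccimpute(t_dense, k = 3, cfg = cfg, seed = 11)
  expect_identical(fit_d$imputed, t_dense)
  expect_equal(sum(fit_d$mask), 0L)
})

test_that("ccimpute is deterministic given the seed", {
  dat <- make_grouped_counts(n_genes = 100, n_cells = 40, k = 2, seed = 9)
  t0 <- preprocess_counts(dat$counts)
  cfg <- ccimpute_config(restarts_small = 10)
  a <- ccimpute(t0, k = 2, cfg = cfg, seed = 5)
  b <- ccimpute(t0, k = 2, cfg = cfg, seed = 5)
  expect_identical(a$imputed, b$imputed)
  expect_identical(a$mask, b$mask)
})

test_that("count-space back-transform inverts preprocessing on nonzeros", {
  dat <- make_grouped_counts(n_genes = 80, n_cells = 30, k = 2, seed = 10)
  counts <- filter_unexpressed_genes(dat$counts)
  t0 <- log_transform(normalize_cpm(counts))
  back <- log_to_counts(t0, counts)
  expect_equal(back, counts, tolerance = 1e-9, ignore_attr = TRUE)
})
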