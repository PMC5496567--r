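test_that("Wisconsin double standardization matches hand arithmetic", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)  # rows (1,2), (3,4); col maxima 3, 4
  w <- wisconsin(m)
  expect_equal(w, matrix(c(0.4, 0.5, 0.6, 0.5), 2, 2))
  set.seed(1)
  r <- matrix(runif(60), 5, 12)
  expect_equal(unname(rowSums(wisconsin(r))), rep(1, 5))
  one_col <- matrix(c(2, 5, 9), 3, 1)
  expect_equal(unname(wisconsin(one_col)[, 1]), rep(1, 3))
  expect_error(wisconsin(matrix(c(1, 0, 2, 0), 2, 2, byrow = TRUE)),
               "all-zero")
  expect_error(wisconsin(matrix(c(-1, 2), 1, 2)), "non-negative")
})

test_that("Bray-Curtis distances obey their closed form and laws", {
  m <- rbind(c(1, 2), c(2, 1))
  expect_equal(bray_curtis(m)[1, 2], 1 / 3)
  same <- rbind(c(3, 1, 2), c(3, 1, 2))
  expect_equal(bray_curtis(same)[1, 2], 0)
  disjoint <- rbind(c(1, 0), c(0, 2))
  expect_equal(bray_curtis(disjoint)[1, 2], 1)
  set.seed(2)
  for (rep in 1:10) {
    x <- matrix(rexp(40), 5, 8)
    d <- bray_curtis(x)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
  }
  expect_warning(bray_curtis(rbind(c(0, 0), c(0, 0))), "all-zero")
})

test_that("pool-adjacent-violators reproduces hand-worked cases", {
  expect_equal(pava(c(3, 1, 2)), c(2, 2, 2))
  expect_equal(pava(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(pava(c(4, 3, 2, 1)), rep(2.5, 4))
  expect_equal(pava(c(1, 3, 2, 4)), c(1, 2.5, 2.5, 4))
  # weighted: block mean is the weighted mean
  expect_equal(pava(c(3, 1), w = c(1, 3)), c(1.5, 1.5))
  expect_equal(pava(numeric()), numeric())
  # output is always non-decreasing and preserves the weighted mean
  set.seed(3)
  for (rep in 1:20) {
    y <- rnorm(15)
    f <- pava(y)
    expect_true(all(diff(f) >= -1e-12))
    expect_equal(mean(f), mean(y))
  }
})

test_that("exactly embeddable 2-D distances reach near-zero stress", {
  set.seed(4)
  X <- matrix(rnorm(8), 4, 2)
  d <- as.matrix(dist(X))
  expect_warning(ord <- nmds(d, k = 2, n_restarts = 5, seed = 1),
                 "nearly.*zero")
  expect_lt(ord$stress, 1e-6)
  expect_gt(ord$linear_R2, 0.999999)
})

test_that("nmds is deterministic, centred and satisfies the R2 identity", {
  set.seed(5)
  x <- matrix(rexp(60), 12, 5)
  d <- bray_curtis(x)
  o1 <- nmds(d, n_restarts = 10, seed = 3)
  o2 <- nmds(d, n_restarts = 10, seed = 3)
  expect_identical(o1$scores, o2$scores)
  expect_equal(o1$nonmetric_R2, 1 - o1$stress^2, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(o1$scores))), 1e-10)
  expect_true(o1$stress >= 0 && o1$stress <= 1)
})

test_that("nmds recovers planted two-cluster structure", {
  set.seed(6)
  base1 <- rexp(8); base2 <- rexp(8) + 3
  rows <- rbind(
    t(replicate(6, base1 + runif(8, 0, 0.1))),
    t(replicate(6, base2 + runif(8, 0, 0.1))))
  ord <- suppressWarnings(nmds(bray_curtis(rows), n_restarts = 20, seed = 1))
  sc <- ord$scores
  within <- c(dist(sc[1:6, ]), dist(sc[7:12, ]))
  between <- as.vector(as.matrix(dist(sc))[1:6, 7:12])
  expect_gt(min(between), max(within))
})

test_that("stress agrees with an independent NMDS implementation", {
  skip_if_not_installed("vegan")
  set.seed(7)
  x <- matrix(rexp(72), 12, 6)
  d <- bray_curtis(x)
  ours <- nmds(d, n_restarts = 40, seed = 2)
  ref <- vegan::metaMDS(as.dist(d), k = 2, trymax = 40, trace = 0)
  # vegan reports stress on the same Kruskal stress-1 scale
  expect_equal(ours$stress, ref$stress, tolerance = 0.01)
})

test_that("envfit recovers a perfectly aligned variable", {
  set.seed(8)
  x <- matrix(rexp(72), 12, 6)
  ord <- nmds(bray_curtis(x), n_restarts = 10, seed = 1)
  fit <- envfit_vector(ord, ord$scores[, 1], n_perm = 199, seed = 1)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(abs(fit$dir1), 1, tolerance = 1e-6)
  expect_equal(fit$p_perm, 1 / 200)  # permutation lower bound
  expect_error(envfit_vector(ord, rep(1, 12)), "constant")
})

test_that("envfit r2 is invariant to rotation of the scores", {
  set.seed(9)
  x <- matrix(rexp(72), 12, 6)
  ord <- nmds(bray_curtis(x), n_restarts = 10, seed = 1)
  v <- rnorm(12)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  ord_rot <- ord
  ord_rot$scores <- ord$scores %*% R
  f1 <- envfit_vector(ord, v, n_perm = 99, seed = 2)
  f2 <- envfit_vector(ord_rot, v, n_perm = 99, seed = 2)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-10)
  expect_equal(f1$p_perm, f2$p_perm)
})

test_that("envfit agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(10)
  x <- matrix(rexp(72), 12, 6)
  ord <- nmds(bray_curtis(x), n_restarts = 10, seed = 1)
  v <- rnorm(12)
  ours <- envfit_vector(ord, v, n_perm = 999, seed = 3)
  ref <- vegan::envfit(ord$scores, data.frame(v = v), permutations = 999)
  expect_equal(ours$r2, unname(ref$vectors$r), tolerance = 1e-10)
})

test_that("within a restart the reported stress never increases", {
  # the optimizer keeps the best configuration; a degenerate all-equal
  # distance matrix must not crash and must give finite stress
  d <- matrix(0.5, 6, 6); diag(d) <- 0
  ord <- nmds(d, n_restarts = 5, seed = 1)
  expect_true(is.finite(ord$stress))
})
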