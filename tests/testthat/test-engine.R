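test_that("soft-thresholding keeps the largest entries, shrunk by the next one", {
  w <- c(3, -2, 1)
  expect_equal(sparsify_loading(w, 3), w / sqrt(sum(w^2)))         # no shrinkage
  expect_equal(sparsify_loading(w, 1), c(1, 0, 0))                 # lambda = 2
  expect_equal(sparsify_loading(w, 2), c(2, -1, 0) / sqrt(5))      # lambda = 1
  expect_error(sparsify_loading(w, 0), "keepX")
  expect_error(sparsify_loading(w, 4), "keepX")
  expect_warning(out <- sparsify_loading(c(0, 0, 0), 2), "all-zero")
  expect_equal(out, c(0, 0, 0))
})

test_that("soft-thresholding yields exactly keepX survivors, even under ties", {
  set.seed(4)
  for (i in 1:20) {
    w <- rnorm(15)
    k <- sample(1:15, 1)
    out <- sparsify_loading(w, k)
    expect_equal(sum(out != 0), k)
    expect_equal(sum(out^2), 1, tolerance = 1e-12)
  }
  # exact ties at the boundary: index order decides, count preserved
  out <- sparsify_loading(c(2, 2, 1), 1)
  expect_equal(sum(out != 0), 1)
  expect_equal(which(out != 0), 1L)
})

test_that("regression deflation leaves residuals orthogonal to the score", {
  set.seed(5)
  X <- matrix(rnorm(60), 12, 5)
  t <- rnorm(12)
  Xd <- deflate_block(X, t)
  expect_true(max(abs(crossprod(Xd, t))) < 1e-10)
  # rank-1 matrix deflated by its own score vanishes
  v <- rnorm(5)
  expect_true(max(abs(deflate_block(tcrossprod(t, v), t))) < 1e-12)
  expect_error(deflate_block(X, rep(0, 12)), "zero-norm")
})

test_that("one dense component recovers the first singular direction of X'Y", {
  set.seed(6)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- rep(c("A", "B"), each = 10)
  cmp <- fit_component(center_and_scale(omics_block(X)), encode_dummy(y))
  sv <- svd(crossprod(std(X), scaled_dummy(y)))
  expect_lt(align_sign(cmp$loadings[[1]], sv$u[, 1]), 1e-8)
  expect_true(cmp$converged)
})

test_that("two identical blocks give identical loadings", {
  set.seed(7)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rep(c("A", "B", "C"), each = 10)
  cmp <- fit_component(list(center_and_scale(omics_block(X)),
                            center_and_scale(omics_block(X))),
                       encode_dummy(y),
                       design = block_design(c("b1", "b2")))
  expect_lt(align_sign(cmp$loadings[[1]], cmp$loadings[[2]]), 1e-6)
})

test_that("every loading is unit norm and scores equal deflated-data projections", {
  d <- toy_da(seed = 8)
  m <- splsda(d$X, d$y, ncomp = 2, keepX = c(6, 4))
  R <- m$X[[1]]
  for (h in 1:2) {
    a <- m$loadings[[1]][, h]
    expect_equal(sum(a^2), 1, tolerance = 1e-10)
    expect_equal(unname(drop(R %*% a)), unname(m$scores[[1]][, h]),
                 tolerance = 1e-10)
    R <- R - tcrossprod(m$scores[[1]][, h], m$x_loadings[[1]][, h])
  }
})

test_that("dense multi-component fit matches an independent NIPALS-PLS2", {
  set.seed(9)
  X <- matrix(rnorm(25 * 12), 25, 12)
  y <- rep(c("A", "B", "C"), c(9, 8, 8))
  m <- plsda(X, y, ncomp = 2)
  orc <- oracle_nipals_pls2(std(X), scaled_dummy(y), 2)
  for (h in 1:2) {
    expect_lt(align_sign(m$scores[[1]][, h], orc$scores[, h]), 1e-6)
  }
})

test_that("scores are mutually orthogonal under regression deflation", {
  d <- toy_da(P = 40, seed = 10)
  m <- splsda(d$X, d$y, ncomp = 2, keepX = c(10, 10))
  G <- crossprod(m$scores[[1]])
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("nonzero loading counts equal keepX exactly", {
  d <- toy_da(P = 50, seed = 11)
  m <- splsda(d$X, d$y, ncomp = 2, keepX = c(7, 13))
  expect_equal(colSums(m$loadings[[1]] != 0), c(comp1 = 7, comp2 = 13))
})

test_that("refitting on identical input is bitwise deterministic", {
  d <- toy_da(seed = 12)
  m1 <- splsda(d$X, d$y, ncomp = 2, keepX = c(5, 5))
  m2 <- splsda(d$X, d$y, ncomp = 2, keepX = c(5, 5))
  expect_identical(m1$loadings, m2$loadings)
  expect_identical(m1$scores, m2$scores)
})

test_that("the sign convention makes each loading's largest entry positive", {
  d <- toy_da(seed = 13)
  m <- splsda(d$X, d$y, ncomp = 2, keepX = c(8, 8))
  for (h in 1:2) {
    a <- m$loadings[[1]][, h]
    expect_gt(a[which.max(abs(a))], 0)
  }
})

test_that("ncomp bounds are enforced", {
  d <- toy_da(N_per = 4, P = 9, seed = 14)
  expect_error(fit_model(d$X, encode_dummy(d$y), ncomp = 12), "samples")
  expect_error(fit_model(d$X, encode_dummy(d$y), ncomp = 9), "feature count")
})

test_that("sparse fits agree with an independent sPLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(15)
  X <- matrix(rnorm(30 * 20), 30, 20)
  y <- factor(rep(c("A", "B", "C"), each = 10))
  mo <- mixOmics::splsda(X, y, ncomp = 2, keepX = c(6, 4))
  mine <- splsda(X, y, ncomp = 2, keepX = c(6, 4))
  # stopping rules differ slightly between implementations, so agreement is
  # to convergence precision rather than machine precision
  for (h in 1:2) {
    expect_lt(align_sign(mine$loadings[[1]][, h], mo$loadings$X[, h]), 1e-3)
    expect_identical(unname(which(mine$loadings[[1]][, h] != 0)),
                     unname(which(mo$loadings$X[, h] != 0)))
  }
  mo_dense <- mixOmics::plsda(X, y, ncomp = 2)
  mine_dense <- plsda(X, y, ncomp = 2)
  for (h in 1:2) {
    expect_lt(align_sign(mine_dense$loadings[[1]][, h],
                         mo_dense$loadings$X[, h]), 1e-6)
  }
})
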