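test_that("self-projection reproduces training scores", {
  d <- toy_da(seed = 40)
  m <- splsda(d$X, d$y, ncomp = 2, keepX = c(6, 6))
  sc <- project_new(m, d$X)
  expect_equal(unname(sc), unname(m$scores[[1]]), tolerance = 1e-10)

  # a sample placed at a class centroid of X lands at that class's raw-score
  # centroid only for dense linear maps; check the smoke/dimension contract
  set.seed(40)
  Xnew <- matrix(rnorm(5 * ncol(d$X)), 5, ncol(d$X),
                 dimnames = list(NULL, colnames(d$X)))
  sc2 <- project_new(m, Xnew)
  expect_equal(dim(sc2), c(5, 2))
  expect_true(all(is.finite(sc2)))
})

test_that("feature name mismatches are reported", {
  d <- toy_da(seed = 41)
  m <- splsda(d$X, d$y, ncomp = 2)
  bad <- d$X[, 1:10]
  expect_error(project_new(m, bad), "lacks training feature")
})

test_that("predicted dummy values match explicit least squares on scores", {
  # 1-component toy: regression of scaled dummy on the training score
  set.seed(42)
  X <- matrix(rnorm(4 * 2), 4, 2)
  y <- c("A", "A", "B", "B")
  m <- splsda(X, y, ncomp = 1, keepX = 2)
  t1 <- m$scores[[1]][, 1]
  Ys <- scaled_dummy(y)
  beta <- drop(crossprod(Ys, t1) / sum(t1^2))
  pr <- predict(m, X)
  want <- outer(t1, beta)
  want <- sweep(sweep(want, 2, apply(encode_dummy(y)$indicator, 2, sd), "*"),
                2, colMeans(encode_dummy(y)$indicator), "+")
  expect_equal(unname(pr$dummy[[1]][, , 1]), unname(want), tolerance = 1e-10)
})

test_that("well-separated training data self-predicts dummy values near 0/1", {
  d <- toy_da(N_per = 15, K = 2, effect = 4, seed = 43)
  m <- plsda(d$X, d$y)
  pr <- predict(m, d$X)
  dm <- pr$dummy[[1]][, , m$ncomp]
  ind <- encode_dummy(d$y)$indicator
  expect_lt(max(abs(dm - ind)), 0.35)
  expect_identical(unname(predicted_classes(pr, "max")), d$y)
})

test_that("class assignment agrees with a brute-force reimplementation", {
  for (seed in 44:46) {
    d <- toy_da(N_per = 8, P = 20, K = 3, effect = 1, seed = seed)
    m <- splsda(d$X, d$y, ncomp = 2, keepX = c(8, 8))
    set.seed(seed)
    Xnew <- matrix(rnorm(12 * 20), 12, 20, dimnames = list(NULL, colnames(d$X)))
    pr <- predict(m, Xnew)
    for (dist in c("max", "centroid", "mahalanobis")) {
      got <- assign_class(m, pr, dist)[, 2]
      want <- oracle_assign(m$scores[[1]], m$outcome$y, pr$dummy[[1]][, , 2],
                            pr$scores[[1]], dist)
      expect_identical(unname(got), want)
    }
  }
})

test_that("mahalanobis equals centroid under identity score covariance", {
  d <- toy_da(seed = 47)
  m <- splsda(d$X, d$y, ncomp = 2, keepX = c(10, 10))
  # whiten the training scores so the pooled covariance is the identity
  y <- m$outcome$y
  W <- Reduce(`+`, lapply(levels(y), function(cl) {
    sc <- m$scores[[1]][y == cl, ]
    crossprod(sweep(sc, 2, colMeans(sc), "-"))
  })) / (nrow(d$X) - 3)
  R <- chol(solve(W))
  m$scores[[1]] <- m$scores[[1]] %*% t(R)
  pr <- list(scores = list(matrix(rnorm(20), 10, 2) %*% t(R)),
             dummy = list(array(0, c(10, 3, 2))))
  expect_identical(assign_class(m, pr, "centroid")[, 2],
                   assign_class(m, pr, "mahalanobis")[, 2])
})

test_that("majority vote picks the modal class and flags ties as NA", {
  expect_identical(combine_votes(list("A", "A", "B")), "A")
  expect_identical(combine_votes(list("A", "B")), NA_character_)
  expect_identical(combine_votes(list(c("A", "B"), c("A", "B"), c("A", "B"))),
                   c("A", "B"))
  # order-invariance
  labs <- list(c("A", "C"), c("B", "C"), c("B", "C"))
  expect_identical(combine_votes(labs), combine_votes(rev(labs)))
})

test_that("weighted vote follows the dominant block and breaks even splits", {
  labs <- list(c("A", "A"), c("B", "B"), c("B", "A"))
  expect_identical(weighted_vote(labs, c(0.99, 0.005, 0.005)), c("A", "A"))
  # equal weights reduce to majority behaviour with NA on exact ties
  expect_identical(weighted_vote(list("A", "B"), c(0.5, 0.5)), NA_character_)
  # discordant even split resolved by weights where majority ties
  labs2 <- list("A", "A", "B", "B")
  expect_identical(combine_votes(labs2), NA_character_)
  expect_identical(weighted_vote(labs2, c(0.3, 0.3, 0.4, 0.4)), "B")
})

test_that("label permutation of y permutes predictions consistently", {
  d <- toy_da(seed = 48)
  perm <- c(c1 = "zebra", c2 = "apple", c3 = "mango")
  m1 <- splsda(d$X, d$y, ncomp = 2, keepX = c(6, 6))
  m2 <- splsda(d$X, unname(perm[d$y]), ncomp = 2, keepX = c(6, 6))
  p1 <- predicted_classes(predict(m1, d$X), "centroid")
  p2 <- predicted_classes(predict(m2, d$X), "centroid")
  expect_identical(unname(perm[p1]), unname(p2))
})

test_that("self-prediction of separated data is error-free for all distances", {
  d <- toy_da(N_per = 12, P = 40, K = 3, effect = 4, seed = 49)
  m <- splsda(d$X, d$y, ncomp = 2, keepX = c(12, 12))
  pr <- predict(m, d$X)
  for (dist in c("max", "centroid", "mahalanobis")) {
    expect_equal(error_rate(d$y, predicted_classes(pr, dist)), 0)
  }
})

test_that("prediction regions cover the training samples and differ by distance", {
  d <- toy_da(N_per = 10, P = 30, K = 4, effect = 2, seed = 50)
  # anisotropic scores: stretch one class along comp 2
  m <- splsda(d$X, d$y, ncomp = 2, keepX = c(10, 10))
  regions <- lapply(c("max", "centroid", "mahalanobis"), function(dist) {
    prediction_region(m, dist, grid_n = 25)
  })
  sc <- m$scores[[1]]
  for (r in regions) {
    expect_true(all(sc[, 1] >= min(r$comp1) & sc[, 1] <= max(r$comp1)))
    expect_true(all(sc[, 2] >= min(r$comp2) & sc[, 2] <= max(r$comp2)))
  }
  expect_true(!identical(regions[[1]]$label, regions[[2]]$label) ||
              !identical(regions[[2]]$label, regions[[3]]$label))
})

test_that("max-distance regions of a 2-class model split at dummy 0.5", {
  d <- toy_da(N_per = 15, P = 20, K = 2, effect = 3, seed = 51)
  m <- plsda(d$X, d$y, ncomp = 2)
  r <- prediction_region(m, "max", grid_n = 30)
  # recompute the dummy value of class 1 on the grid; the argmax boundary in
  # a 2-class model is where the two dummy values cross, i.e. dummy = 0.5
  # only when the dummies sum to 1; verify the label equals the argmax rule
  Cm <- m$y_loadings[[1]][, 1:2]
  acc <- cbind(r$comp1, r$comp2) %*% t(Cm)
  dummy <- sweep(sweep(acc, 2, m$y_sds, "*"), 2, m$y_means, "+")
  want <- m$outcome$class_labels[max.col(dummy, ties.method = "first")]
  expect_identical(r$label, want)
  # the two dummy columns are complementary, so the split is at 0.5
  expect_equal(unname(rowSums(dummy)), rep(1, nrow(dummy)), tolerance = 1e-8)
  expect_identical(r$label == m$outcome$class_labels[1], dummy[, 1] > 0.5)
})

test_that("external studies are standardised by their own parameters when large", {
  sim <- gen_multistudy(sim_config(n_per_class = 8, p = 30, K = 3,
                                   n_informative = 10, m_studies = 3,
                                   batch_offset_sd = 3, seed = 52))
  keep <- sim$study != "study3"
  m <- mint_splsda(sim$X[keep, ], sim$y[keep], droplevels(sim$study[keep]),
                   ncomp = 2, keepX = c(10, 10))
  pr <- predict(m, sim$X[!keep, ], study_new = rep("new_study", sum(!keep)))
  acc <- mean(predicted_classes(pr, "centroid") == sim$y[!keep])
  expect_gt(acc, 0.8)
})
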