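test_that("overall error and BER match hand computations", {
  truth <- rep(c("a", "b"), c(10, 20))
  pred <- truth
  pred[1] <- "b"          # 1 error in class a (10)
  pred[11:13] <- "a"      # 3 errors in class b (20)
  expect_equal(error_rate(truth, pred), 4 / 30)
  expect_equal(ber(truth, pred), (0.1 + 0.15) / 2)
  expect_equal(error_rate(truth, truth), 0)
  expect_equal(ber(truth, truth), 0)
  # NA predictions count as errors
  pred2 <- truth
  pred2[1:2] <- NA
  expect_equal(error_rate(truth, pred2), 2 / 30)
})

test_that("BER equals the overall rate under balanced classes", {
  set.seed(60)
  truth <- rep(c("a", "b", "c"), each = 20)
  pred <- sample(c("a", "b", "c"), 60, replace = TRUE)
  expect_equal(ber(truth, pred), error_rate(truth, pred))
})

test_that("BER is invariant under class relabelling", {
  set.seed(61)
  truth <- sample(c("a", "b", "c"), 50, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  pred <- sample(c("a", "b", "c"), 50, replace = TRUE)
  map <- c(a = "x", b = "y", c = "z")
  expect_equal(ber(truth, pred), ber(map[truth], map[pred]))
})

test_that("stratified folds are balanced partitions", {
  y <- rep(c("BL", "EWS", "NB", "RMS"), c(8, 23, 12, 20))  # 63 samples
  plan <- make_folds(y, "stratified", nfolds = 5, nrepeats = 10, seed = 3)
  expect_equal(plan$nrepeats, 10)
  for (r in 1:10) {
    fold <- plan$assignments[[r]]
    expect_equal(sort(unique(fold)), 1:5)
    # partition: every sample in exactly one fold
    expect_equal(length(fold), 63)
    # per-fold class counts within +-1 of proportional
    for (cl in unique(y)) {
      counts <- tabulate(fold[y == cl], 5)
      expect_lte(max(counts) - min(counts), 1)
    }
  }
  # reproducible under the same seed
  plan2 <- make_folds(y, "stratified", nfolds = 5, nrepeats = 10, seed = 3)
  expect_identical(plan$assignments, plan2$assignments)
})

test_that("leave-one-group-out folds mirror study membership", {
  study <- rep(paste0("s", 1:4), c(10, 8, 12, 9))
  y <- rep(c("a", "b"), length.out = 39)
  plan <- make_folds(y, "logocv", study = study)
  expect_equal(plan$nfolds, 4)
  expect_equal(plan$nrepeats, 1)
  expect_identical(plan$assignments[[1]], as.integer(factor(study)))
})

test_that("component choice follows one-sided paired t-tests", {
  # flat curve: one component suffices
  flat <- matrix(0.3, 4, 8)
  expect_equal(choose_ncomp(flat), 1)
  # sharp drop at comp 2, flat after: choose 2
  set.seed(62)
  errs <- rbind(0.5 + rnorm(8, 0, 0.01),
                0.2 + rnorm(8, 0, 0.01),
                0.2 + rnorm(8, 0, 0.01))
  expect_equal(choose_ncomp(errs), 2)
  # oracle check against stats::t.test on the same rows
  p12 <- t.test(errs[2, ] - errs[1, ], alternative = "less")$p.value
  p23 <- t.test(errs[3, ] - errs[2, ], alternative = "less")$p.value
  expect_lt(p12, 0.05)
  expect_gte(p23, 0.05)
})

test_that("keepX ties resolve to the smallest value", {
  # all grid values reach identical CV error on perfectly separated data
  d <- toy_da(N_per = 10, P = 20, K = 2, effect = 5, seed = 63)
  tr <- tune_keepx(d$X, d$y, ncomp = 1, grid = c(5, 10, 15), nfolds = 3,
                   nrepeats = 2, seed = 64)
  expect_true(all(tr$error_surface[[1]]$mean == tr$error_surface[[1]]$mean[1]))
  expect_equal(tr$chosen_keepX$X, 5)
})

test_that("tuning recovers a planted support and is seed-reproducible", {
  cfg <- sim_config(n_per_class = 15, p = 120, K = 3, n_informative = 10,
                    effect = 1.5, seed = 65)
  sim <- gen_single(cfg)
  tr1 <- tune_keepx(sim$X, sim$y, ncomp = 1, grid = c(5, 10, 20, 40),
                    nfolds = 3, nrepeats = 2, seed = 66)
  tr2 <- tune_keepx(sim$X, sim$y, ncomp = 1, grid = c(5, 10, 20, 40),
                    nfolds = 3, nrepeats = 2, seed = 66)
  expect_identical(tr1$error_surface, tr2$error_surface)
  expect_identical(tr1$chosen_keepX, tr2$chosen_keepX)
  # chosen keepX in the neighbourhood of the true support size (10)
  expect_true(tr1$chosen_keepX$X %in% c(5, 10, 20))
  expect_error(tune_keepx(sim$X, sim$y, ncomp = 1, grid = c(10, 500)),
               "outside")
})

test_that("factorial multi-block grids break ties toward the smallest total", {
  d <- toy_da(N_per = 10, P = 15, K = 2, effect = 5, seed = 67)
  tr <- tune_keepx(list(b1 = d$X, b2 = d$X), d$y, ncomp = 1,
                   grid = list(b1 = c(4, 8), b2 = c(4, 8)),
                   nfolds = 3, nrepeats = 1, seed = 68)
  surf <- tr$error_surface[[1]]
  expect_equal(nrow(surf), 4)  # factorial candidates
  if (all(surf$mean == surf$mean[1])) {
    expect_equal(unname(c(tr$chosen_keepX$b1, tr$chosen_keepX$b2)), c(4, 4))
  }
})

test_that("fold-parallel evaluation leaves results unchanged", {
  d <- toy_da(N_per = 10, P = 30, K = 3, effect = 1.5, seed = 69)
  m <- splsda(d$X, d$y, ncomp = 2, keepX = c(8, 8))
  p1 <- perf(m, nfolds = 3, nrepeats = 2, seed = 70, cpus = 1)
  p2 <- perf(m, nfolds = 3, nrepeats = 2, seed = 70, cpus = 2)
  expect_equal(p1$error, p2$error, tolerance = 1e-12)
  expect_equal(p1$stability, p2$stability, tolerance = 1e-12)
})
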