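test_that("correlation-circle coordinates are correlations in the unit disk", {
  d <- toy_da(N_per = 12, P = 30, K = 3, effect = 2, seed = 100)
  m <- splsda(d$X, d$y, ncomp = 2, keepX = c(10, 10))
  cc <- correlation_circle(m)
  expect_true(all(cc$comp_x^2 + cc$comp_y^2 <= 1 + 1e-10))
  # a feature proportional to the first score sits at (1, 0)
  X2 <- cbind(d$X, synth = m$scores[[1]][, 1])
  m2 <- splsda(X2, d$y, ncomp = 2, keepX = c(31, 31))
  cc2 <- correlation_circle(m2)
  row <- cc2[cc2$feature == "synth", ]
  expect_equal(row$comp_x, 1, tolerance = 0.05)
  expect_lt(abs(row$comp_y), 0.15)
  # planted discriminant features sit near the rim
  strongest <- cc[order(-(cc$comp_x^2 + cc$comp_y^2))[1:3], ]
  expect_true(all(sqrt(strongest$comp_x^2 + strongest$comp_y^2) > 0.7))
})

test_that("feature similarities match a direct pairwise loop", {
  d <- toy_da(N_per = 10, P = 15, K = 3, effect = 2, seed = 101)
  m <- splsda(d$X, d$y, ncomp = 2, keepX = c(8, 6))
  edges <- feature_similarity(m, threshold = 0.3)
  sel <- unique(unlist(selected_features(m)))
  # brute-force oracle
  M <- cor(m$X[[1]][, sel], m$scores[[1]])
  for (r in seq_len(nrow(edges))) {
    i <- edges$feature_i[r]; j <- edges$feature_j[r]
    want <- sum(M[i, ] * M[j, ])
    expect_equal(edges$similarity[r], want, tolerance = 1e-12)
  }
  # symmetry / completeness: every pair above threshold appears once
  cnt <- 0
  for (i in seq_along(sel)) for (j in seq_along(sel)) {
    if (i < j && abs(sum(M[sel[i], ] * M[sel[j], ])) > 0.3) cnt <- cnt + 1
  }
  expect_equal(nrow(edges), cnt)
  expect_true(all(edges$feature_i != edges$feature_j))
  # an impossible threshold gives an empty edge set
  expect_equal(nrow(feature_similarity(m, threshold = 1.01)), 0)
  # duplicated features reach the self-similarity bound
  X2 <- cbind(d$X, dup = d$X[, 1] + rnorm(30, 0, 1e-8))
  m3 <- splsda(X2, d$y, ncomp = 2, keepX = c(16, 16))
  e3 <- feature_similarity(m3, threshold = 0.0)
  pair <- e3[(e3$feature_i == "f1" & e3$feature_j == "dup") |
             (e3$feature_i == "dup" & e3$feature_j == "f1"), ]
  self_sim <- sum(cor(m3$X[[1]][, "f1"], m3$scores[[1]])^2)
  expect_equal(pair$similarity, self_sim, tolerance = 1e-4)
})

test_that("clustered image map uses the depth-1 signature and groups duplicates", {
  d <- toy_da(N_per = 10, P = 30, K = 3, effect = 3, seed = 102)
  X <- d$X
  X[2, ] <- X[1, ]  # identical samples
  m <- splsda(X, d$y, ncomp = 2, keepX = c(10, 8))
  cd <- cim_data(m, comp_depth = 1)
  expect_equal(ncol(cd$matrix), 10)  # depth-1 signature size
  o <- cd$row_order
  expect_equal(abs(which(o == 1) - which(o == 2)), 1)  # adjacent leaves
  cd2 <- cim_data(m, comp_depth = 2)
  expect_equal(ncol(cd2$matrix), length(unique(unlist(selected_features(m)))))
  # class-pure clusters at the K-cut on the full signature
  ct <- cutree(cd2$row_hclust, k = 3)
  tab <- table(ct, d$y)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("loading display orders by importance and labels by class means", {
  d <- toy_da(N_per = 10, P = 20, K = 3, effect = 3, seed = 103)
  m <- splsda(d$X, d$y, ncomp = 2, keepX = c(9, 5))
  ld <- loading_display(m, comp = 1)
  expect_equal(nrow(ld), 9)
  expect_true(all(diff(abs(ld$weight)) >= 0))
  # f1..f3 are upregulated only in class c1
  expect_true(all(ld$class[ld$feature %in% c("f1", "f2", "f3")] == "c1"))
  ld_min <- loading_display(m, comp = 1, method = "min")
  expect_true(all(ld_min$class[ld_min$feature %in% c("f1", "f2", "f3")] != "c1"))
})

test_that("per-study loading labels agree on strong planted signals", {
  sim <- gen_multistudy(sim_config(n_per_class = 8, p = 40, K = 3,
                                   n_informative = 8, effect = 3,
                                   m_studies = 3, seed = 104))
  m <- mint_splsda(sim$X, sim$y, sim$study, ncomp = 2, keepX = c(8, 8))
  per_study <- lapply(levels(sim$study), function(s) {
    ld <- loading_display(m, comp = 1, study = s)
    ld$class[order(ld$feature)]
  })
  agree <- mean(per_study[[1]] == per_study[[2]] & per_study[[2]] == per_study[[3]])
  expect_gt(agree, 0.7)
})

test_that("arrows shrink as the class separation grows", {
  arrow_len <- function(effect, seed) {
    d <- toy_da(N_per = 12, P = 30, K = 3, effect = effect, seed = seed)
    m <- splsda(d$X, d$y, ncomp = 2, keepX = c(9, 9))
    ad <- arrow_data(m)
    expect_equal(nrow(ad), 36)
    mean(sqrt((ad$end_x - ad$start_x)^2 + (ad$end_y - ad$start_y)^2))
  }
  lens_weak <- mean(sapply(105:107, function(s) arrow_len(0.8, s)))
  lens_strong <- mean(sapply(105:107, function(s) arrow_len(4, s)))
  expect_lt(lens_strong, lens_weak)
})

test_that("sample plot data returns scores with calibrated ellipses", {
  d <- toy_da(N_per = 300, P = 10, K = 2, effect = 2, seed = 108)
  m <- plsda(d$X, d$y, ncomp = 2)
  sp <- sample_plot_data(m)
  expect_equal(sp$points$x, unname(m$scores[[1]][, 1]))
  # ~95% of a class's points fall inside its 95% normal ellipse
  cover <- sapply(levels(m$outcome$y), function(cl) {
    e <- sp$ellipses[[cl]]
    pts <- as.matrix(sp$points[sp$points$class == cl, c("x", "y")])
    d2 <- mahalanobis(pts, e$center, e$cov)
    mean(d2 <= e$radius^2)
  })
  expect_true(all(abs(cover - 0.95) < 0.04))
  # study splitting partitions rows exactly
  sim <- gen_multistudy(sim_config(n_per_class = 6, p = 20, K = 3,
                                   n_informative = 5, m_studies = 3, seed = 109))
  mm <- mint_plsda(sim$X, sim$y, sim$study, ncomp = 2)
  sps <- sample_plot_data(mm, by_study = TRUE)
  expect_equal(sort(unlist(lapply(sps$points, nrow), use.names = FALSE)),
               sort(unname(as.vector(table(sim$study)))))
})

test_that("similarity edges export to a readable GML graph", {
  d <- toy_da(N_per = 10, P = 15, K = 3, effect = 2, seed = 110)
  m <- splsda(d$X, d$y, ncomp = 2, keepX = c(8, 6))
  edges <- feature_similarity(m, threshold = 0.2)
  path <- tempfile(fileext = ".gml")
  g <- export_gml(edges, path)
  expect_true(file.exists(path))
  g2 <- igraph::read_graph(path, format = "gml")
  expect_equal(igraph::ecount(g2), nrow(edges))
  unlink(path)
})
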