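# Independent oracles used across the suite. These are deliberately naive
# (loops, closed forms, dense linear algebra) and share no code with the
# package's fitting path.

# classic two-matrix NIPALS PLS2, regression deflation
oracle_nipals_pls2 <- function(X, Y, ncomp) {
  Tm <- matrix(0, nrow(X), ncomp)
  W <- matrix(0, ncol(X), ncomp)
  for (h in seq_len(ncomp)) {
    u <- Y[, 1L]
    for (it in 1:1000) {
      w <- crossprod(X, u); w <- w / sqrt(sum(w^2))
      t <- drop(X %*% w)
      q <- crossprod(Y, t); q <- q / sqrt(sum(q^2))
      u_new <- drop(Y %*% q)
      if (max(abs(u_new - u)) < 1e-13) { u <- u_new; break }
      u <- u_new
    }
    t <- drop(X %*% w)
    p <- crossprod(X, t) / sum(t^2)
    cc <- crossprod(Y, t) / sum(t^2)
    X <- X - tcrossprod(t, p)
    Y <- Y - tcrossprod(t, cc)
    Tm[, h] <- t
    W[, h] <- w
  }
  list(scores = Tm, weights = W)
}

# brute-force class assignment by explicit loops over classes
oracle_assign <- function(train_scores, y, dummy_h, scores_h, distance) {
  labels <- levels(y)
  n <- nrow(scores_h)
  out <- character(n)
  if (distance == "max") {
    for (i in seq_len(n)) out[i] <- labels[which.max(dummy_h[i, ])]
    return(out)
  }
  cents <- lapply(labels, function(cl) colMeans(train_scores[y == cl, , drop = FALSE]))
  if (distance == "mahalanobis") {
    S <- matrix(0, ncol(train_scores), ncol(train_scores))
    for (cl in labels) {
      sc <- train_scores[y == cl, , drop = FALSE]
      sc <- sweep(sc, 2, colMeans(sc), "-")
      S <- S + t(sc) %*% sc
    }
    S <- S / (nrow(train_scores) - length(labels))
    Sinv <- solve(S)
  }
  for (i in seq_len(n)) {
    d <- sapply(seq_along(labels), function(k) {
      v <- scores_h[i, ] - cents[[k]]
      if (distance == "centroid") sum(v^2) else drop(t(v) %*% Sinv %*% v)
    })
    out[i] <- labels[which.min(d)]
  }
  out
}

# scaling with the same N-1 convention as the package
std <- function(X, scale = TRUE) {
  X <- scale(X, center = TRUE, scale = FALSE)
  if (scale) {
    sds <- apply(X, 2, sd)
    sds[sds == 0] <- 1
    X <- sweep(X, 2, sds, "/")
  }
  X
}

scaled_dummy <- function(y) {
  d <- encode_dummy(y)
  std(d$indicator)
}

# small deterministic classification problem with planted separation
toy_da <- function(N_per = 10, P = 30, K = 3, effect = 3, seed = 1) {
  set.seed(seed)
  y <- rep(paste0("c", seq_len(K)), each = N_per)
  X <- matrix(rnorm(N_per * K * P), N_per * K, P)
  for (k in seq_len(K)) {
    idx <- ((k - 1) * 3 + 1):(k * 3)  # 3 informative features per class
    X[y == paste0("c", k), idx] <- X[y == paste0("c", k), idx] + effect
  }
  colnames(X) <- paste0("f", seq_len(P))
  rownames(X) <- paste0("s", seq_len(nrow(X)))
  list(X = X, y = y)
}

align_sign <- function(a, b) min(max(abs(a - b)), max(abs(a + b)))
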