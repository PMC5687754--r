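l2norm <- function(x) sqrt(sum(x^2))

#' Soft-threshold a loading vector to a fixed number of features
#'
#' Keeps the `keepX` entries of largest absolute value, shrinks them toward
#' zero by the (keepX+1)-th largest absolute value (LASSO-style
#' soft-thresholding reparameterised by the number of features kept), zeroes
#' the rest, and renormalises to unit Euclidean norm. Ties at the selection
#' boundary are broken by feature index order so that exactly `keepX` entries
#' survive.
#'
#' @param w Numeric loading vector, length P.
#' @param keepX Integer number of entries to keep, `1 <= keepX <= P`.
#' @return Numeric vector of length P with exactly `keepX` nonzero entries
#'   and unit Euclidean norm (unless `w` is all zero, which is returned
#'   unchanged with a warning).
#' @export
sparsify_loading <- function(w, keepX) {
  P <- length(w)
  if (length(keepX) != 1L || is.na(keepX) || keepX < 1L || keepX > P) {
    stop("keepX must be a single integer in [1, ", P, "]")
  }
  keepX <- as.integer(keepX)
  if (all(w == 0)) {
    warning("all-zero loading vector; returned unchanged")
    return(w)
  }
  ord <- order(-abs(w), seq_along(w))
  kept <- ord[seq_len(keepX)]
  lambda <- if (keepX < P) abs(w[ord[keepX + 1L]]) else 0
  out <- numeric(P)
  shrunk <- abs(w[kept]) - lambda
  # boundary ties would otherwise shrink a kept entry to exactly zero;
  # nudge it so the keepX invariant holds while leaving untied cases exact
  shrunk[shrunk <= 0] <- max(lambda, max(abs(w))) * 1e-9
  out[kept] <- sign(w[kept]) * shrunk
  nrm <- l2norm(out)
  if (nrm > 0) out <- out / nrm
  names(out) <- names(w)
  out
}

# deterministic sign convention: largest-|entry| positive, ties -> lowest index
sign_flip <- function(a) {
  i <- order(-abs(a), seq_along(a))[1L]
  if (a[i] < 0) -1 else 1
}

#' Remove a component's contribution from a data matrix
#'
#' Regression deflation: `X <- X - t (t'X) / (t't)`, leaving the residual
#' orthogonal to the score `t`.
#'
#' @param X Numeric matrix (N x P), or an `omics_block`.
#' @param score Numeric score vector of length N with nonzero norm.
#' @return Object of the same type as `X`, deflated.
#' @export
deflate_block <- function(X, score) {
  if (inherits(X, "omics_block")) {
    X$values <- deflate_block(X$values, score)
    return(X)
  }
  if (length(score) != nrow(X)) stop("score length != nrow(X)")
  ss <- sum(score^2)
  if (ss == 0) stop("zero-norm score; cannot deflate")
  X - tcrossprod(score, crossprod(X, score) / ss)
}

# Alternating Horst-type update for one component of the multi-block sparse
# objective, with the (scaled) outcome dummy treated as one more connected
# block. Xs: list of standardized (deflated) matrices; Ys: scaled (deflated)
# outcome matrix; C: (B+1)x(B+1) design, last row/col = outcome.
engine_component <- function(Xs, Ys, C, keepX, tol = 1e-6, max_iter = 100L) {
  B <- length(Xs)
  N <- nrow(Ys)
  a <- vector("list", B)
  tmat <- matrix(0, N, B)
  for (b in seq_len(B)) {
    M <- crossprod(Xs[[b]], Ys)
    a0 <- svd(M, nu = 1L, nv = 0L)$u[, 1L]
    a[[b]] <- a0 / l2norm(a0)
    tmat[, b] <- Xs[[b]] %*% a[[b]]
  }
  e <- crossprod(Ys, rowMeans(tmat))
  if (l2norm(e) == 0) e <- rep(1, ncol(Ys))
  e <- e / l2norm(e)
  u <- drop(Ys %*% e)

  delta <- Inf
  iter <- 0L
  while (iter < max_iter && delta > tol) {
    iter <- iter + 1L
    a_old <- a
    e_old <- e
    for (b in seq_len(B)) {
      z <- u * C[b, B + 1L]
      for (b2 in seq_len(B)) {
        if (b2 != b && C[b, b2] != 0) z <- z + C[b, b2] * tmat[, b2]
      }
      w <- drop(crossprod(Xs[[b]], z))
      if (all(w == 0)) next  # degenerate target: keep previous direction
      w <- sparsify_loading(w, keepX[b])
      a[[b]] <- w
      tmat[, b] <- Xs[[b]] %*% w
    }
    zy <- rowSums(sweep(tmat, 2L, C[B + 1L, seq_len(B)], "*"))
    e_new <- drop(crossprod(Ys, zy))
    if (l2norm(e_new) > 0) e <- e_new / l2norm(e_new)
    u <- drop(Ys %*% e)
    delta <- max(abs(unlist(a) - unlist(a_old)), abs(e - e_old))
  }
  converged <- delta <= tol
  if (!converged) {
    warning(sprintf("component did not converge in %d iterations (change %.2e)",
                    max_iter, delta))
  }
  for (b in seq_len(B)) {
    s <- sign_flip(a[[b]])
    a[[b]] <- s * a[[b]]
    tmat[, b] <- s * tmat[, b]
  }
  s <- sign_flip(e)
  e <- s * e
  u <- s * u
  list(loadings = a, scores = tmat, y_weight = drop(e), y_score = u,
       iterations = iter, final_change = delta, converged = converged)
}

#' Fit a single component of the multi-block sparse discriminant model
#'
#' One round of the alternating soft-thresholded least-squares scheme: each
#' block's loading is recomputed from the design-weighted sum of the other
#' connected blocks' scores (the outcome's score included as a connected
#' block), sparsified to its `keepX`, and unit-normalised, until the maximum
#' absolute loading change falls below `tol`.
#'
#' @param blocks List of standardized `omics_block`s (or matrices) with equal N.
#' @param Y An `outcome_dummy` (its indicator is centred/scaled internally).
#' @param design B x B design matrix from [block_design()] (outcome
#'   connections are fixed at 1 internally).
#' @param keepX Integer vector, number of features kept per block.
#' @param tol,max_iter Convergence tolerance on the maximum absolute loading
#'   change, and iteration cap.
#' @return List with per-block `loadings` (unit-norm, exactly keepX nonzero),
#'   per-block `scores`, the outcome `y_weight` and `y_score`, plus
#'   `iterations`, `final_change`, `converged`.
#' @export
fit_component <- function(blocks, Y, design = NULL, keepX = NULL,
                          tol = 1e-6, max_iter = 100L) {
  if (inherits(blocks, "omics_block") || is.matrix(blocks)) blocks <- list(blocks)
  Xs <- lapply(blocks, function(b) {
    b <- as_omics_block(b)
    if (!isTRUE(b$standardized)) stop("blocks must be standardized first")
    b$values
  })
  ns <- vapply(Xs, nrow, 1L)
  if (length(unique(ns)) != 1L) stop("blocks have inconsistent sample counts")
  if (!inherits(Y, "outcome_dummy")) Y <- encode_dummy(Y)
  if (nrow(Y$indicator) != ns[1L]) stop("outcome length != number of samples")
  Ys <- scale_dummy(Y$indicator)$Ys
  B <- length(Xs)
  if (is.null(keepX)) keepX <- vapply(Xs, ncol, 1L)
  if (is.null(design)) design <- block_design(paste0("block", seq_len(B)))
  C <- full_design(design, B)
  engine_component(Xs, Ys, C, keepX, tol = tol, max_iter = max_iter)
}

# centre and scale the dummy indicator (sd denominator N-1)
scale_dummy <- function(ind) {
  mu <- colMeans(ind)
  Ys <- sweep(ind, 2L, mu, "-")
  sds <- apply(Ys, 2L, stats::sd)
  sds[is.na(sds) | sds == 0] <- 1
  Ys <- sweep(Ys, 2L, sds, "/")
  list(Ys = Ys, y_means = mu, y_sds = sds)
}

# embed the B x B block design into the (B+1) x (B+1) design including the
# outcome block, connected to every X block with weight 1
full_design <- function(design, B) {
  C <- matrix(0, B + 1L, B + 1L)
  C[seq_len(B), seq_len(B)] <- design
  C[B + 1L, seq_len(B)] <- 1
  C[seq_len(B), B + 1L] <- 1
  C
}

#' Fit the full multi-component sparse projection model
#'
#' The generic engine behind every supervised method in the package: loops
#' [fit_component()] and regression deflation `ncomp` times, recording all
#' quantities needed to project new samples. With a `study` vector the blocks
#' are standardised within each study first (multi-group / P-integration
#' fit); otherwise globally.
#'
#' @param blocks Named list of `omics_block`s or matrices (samples x features,
#'   equal N, aligned rows). A single block may be passed directly.
#' @param Y An `outcome_dummy`, a categorical vector (encoded internally), or
#'   a numeric matrix for a continuous-response fit.
#' @param design B x B design matrix (default [block_design()] with weight
#'   0.1); outcome connections fixed at 1.
#' @param ncomp Number of components H (`H < N` and `H < min P_b`).
#' @param keepX List (per block) of integer vectors of length `ncomp`, or a
#'   single vector for one block; default keeps all features.
#' @param study Optional study membership vector for P-integration.
#' @param scale Scale columns to unit variance (default TRUE).
#' @param tol,max_iter Convergence control passed to each component.
#' @return An object of class `latent_model`.
#' @export
fit_model <- function(blocks, Y, design = NULL, ncomp = 2L, keepX = NULL,
                      study = NULL, scale = TRUE, tol = 1e-6, max_iter = 100L) {
  single <- inherits(blocks, "omics_block") || is.matrix(blocks) || is.data.frame(blocks)
  if (single) blocks <- list(X = blocks)
  if (is.null(names(blocks)) || any(!nzchar(names(blocks)))) {
    names(blocks) <- paste0("block", seq_along(blocks))
  }
  B <- length(blocks)
  blocks <- lapply(blocks, as_omics_block)
  ns <- vapply(blocks, function(b) nrow(b$values), 1L)
  if (length(unique(ns)) != 1L) stop("blocks have inconsistent sample counts")
  N <- ns[[1L]]
  sid <- blocks[[1L]]$sample_ids
  for (b in blocks) {
    if (!identical(b$sample_ids, sid)) stop("sample ids differ across blocks")
  }

  X_raw <- lapply(blocks, `[[`, "values")

  is_da <- inherits(Y, "outcome_dummy") || is.factor(Y) ||
    is.character(Y) || (is.atomic(Y) && !is.matrix(Y) && !is.numeric(Y))
  if (is.numeric(Y) && !is.matrix(Y)) {
    # a bare numeric vector is a continuous response unless factor-coded
    Y <- matrix(Y, ncol = 1L, dimnames = list(NULL, "Y"))
  }
  if (is_da) {
    if (!inherits(Y, "outcome_dummy")) Y <- encode_dummy(Y)
    if (nrow(Y$indicator) != N) stop("outcome length != number of samples")
    sc <- scale_dummy(Y$indicator)
    outcome <- Y
  } else {
    if (nrow(Y) != N) stop("response rows != number of samples")
    sc <- scale_dummy(Y)  # same centring/scaling path for continuous Y
    outcome <- NULL
  }
  Ys <- sc$Ys
  K <- ncol(Ys)

  ncomp <- as.integer(ncomp)
  Pmin <- min(vapply(blocks, function(b) ncol(b$values), 1L))
  if (ncomp < 1L) stop("ncomp must be >= 1")
  if (ncomp >= N) stop("ncomp must be smaller than the number of samples")
  if (ncomp >= Pmin && Pmin > 1L) stop("ncomp must be smaller than every block's feature count")

  if (!is.null(study)) {
    study <- as.factor(study)
    blocks <- lapply(blocks, mint_standardise, study = study, scale = scale)
  } else {
    blocks <- lapply(blocks, function(b) {
      if (isTRUE(b$standardized)) b else center_and_scale(b, scale = scale)
    })
  }
  Xs <- lapply(blocks, `[[`, "values")
  Ps <- vapply(Xs, ncol, 1L)

  keepX <- normalise_keepx(keepX, Ps, ncomp, names(blocks))
  if (is.null(design)) design <- block_design(names(blocks))
  C <- full_design(design, B)

  loadings <- lapply(Ps, function(p) matrix(0, p, ncomp))
  x_loadings <- lapply(Ps, function(p) matrix(0, p, ncomp))
  scores <- lapply(seq_len(B), function(b) matrix(0, N, ncomp))
  y_loadings <- lapply(seq_len(B), function(b) matrix(0, K, ncomp))
  y_weights <- matrix(0, K, ncomp)
  y_scores <- matrix(0, N, ncomp)
  expl_var <- lapply(seq_len(B), function(b) numeric(ncomp))
  convergence <- data.frame(component = seq_len(ncomp), iterations = NA_integer_,
                            final_change = NA_real_, converged = NA)

  curX <- Xs
  curY <- Ys
  totvar <- vapply(Xs, function(x) sum(x^2), 1)
  wy <- C[B + 1L, seq_len(B)]
  for (h in seq_len(ncomp)) {
    kx <- vapply(keepX, function(k) as.integer(k[h]), integer(1))
    cmp <- engine_component(curX, curY, C, kx, tol = tol, max_iter = max_iter)
    for (b in seq_len(B)) {
      t_b <- cmp$scores[, b]
      ss <- sum(t_b^2)
      loadings[[b]][, h] <- cmp$loadings[[b]]
      scores[[b]][, h] <- t_b
      x_loadings[[b]][, h] <- crossprod(curX[[b]], t_b) / ss
      # regression of the (scaled) response on this block's orthogonal scores
      y_loadings[[b]][, h] <- crossprod(Ys, t_b) / ss
      expl_var[[b]][h] <- ss * sum(x_loadings[[b]][, h]^2) / totvar[b]
    }
    y_weights[, h] <- cmp$y_weight
    y_scores[, h] <- cmp$y_score
    convergence$iterations[h] <- cmp$iterations
    convergence$final_change[h] <- cmp$final_change
    convergence$converged[h] <- cmp$converged
    # deflate each block by its own score; the response by the design-weighted
    # mean of the block scores (regression mode)
    for (b in seq_len(B)) curX[[b]] <- curX[[b]] - tcrossprod(cmp$scores[, b], x_loadings[[b]][, h])
    ty <- drop(cmp$scores %*% (wy / sum(wy)))
    curY <- deflate_block(curY, ty)
  }

  for (b in seq_len(B)) {
    rownames(loadings[[b]]) <- blocks[[b]]$feature_ids
    rownames(x_loadings[[b]]) <- blocks[[b]]$feature_ids
    rownames(scores[[b]]) <- sid
    colnames(loadings[[b]]) <- colnames(x_loadings[[b]]) <-
      colnames(scores[[b]]) <- paste0("comp", seq_len(ncomp))
  }

  structure(list(
    method = "fit_model", is_da = is_da, mode = "regression",
    block_names = names(blocks), ncomp = ncomp,
    X = Xs, X_raw = X_raw, Ys = Ys, y_means = sc$y_means, y_sds = sc$y_sds,
    outcome = outcome, design = design,
    keepX = keepX, loadings = loadings, x_loadings = x_loadings,
    scores = scores, y_loadings = y_loadings, y_weights = y_weights,
    y_scores = y_scores, explained_variance = expl_var,
    col_means = lapply(blocks, `[[`, "col_means"),
    col_sds = lapply(blocks, `[[`, "col_sds"),
    study = if (is.null(study)) NULL else study,
    study_params = if (is.null(study)) NULL else lapply(blocks, `[[`, "study_params"),
    scale = scale, tol = tol, max_iter = max_iter,
    convergence = convergence
  ), class = "latent_model")
}

normalise_keepx <- function(keepX, Ps, ncomp, block_names) {
  B <- length(Ps)
  if (is.null(keepX)) {
    keepX <- lapply(Ps, function(p) rep(p, ncomp))
  } else if (!is.list(keepX)) {
    if (B != 1L) stop("keepX must be a list with one vector per block")
    keepX <- list(keepX)
  }
  if (length(keepX) != B) stop("keepX must have one entry per block")
  keepX <- lapply(seq_len(B), function(b) {
    k <- as.integer(keepX[[b]])
    if (length(k) == 1L) k <- rep(k, ncomp)
    if (length(k) != ncomp) stop("keepX[[", b, "]] must have length ncomp")
    if (any(k < 1L | k > Ps[b])) {
      stop("keepX for block ", block_names[b], " out of [1, ", Ps[b], "]")
    }
    k
  })
  names(keepX) <- block_names
  keepX
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("<latent_model: %s> %d block(s), %d component(s)%s\n",
              x$method, length(x$block_names), x$ncomp,
              if (x$is_da) sprintf(", %d classes", length(x$outcome$class_labels)) else ""))
  for (b in seq_along(x$block_names)) {
    cat(sprintf("  %s: %d features, keepX = %s\n", x$block_names[b],
                nrow(x$loadings[[b]]), paste(x$keepX[[b]], collapse = "/")))
  }
  invisible(x)
}
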