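#' Principal component analysis
#'
#' PCA via NIPALS (see [nipals_pca()]), so missing values are tolerated.
#'
#' @param X Matrix or `omics_block` (N x P).
#' @param ncomp Number of components (default 2).
#' @param center,scale Column standardisation (default centre only, the usual
#'   PCA convention).
#' @return A `latent_pca`.
#' @export
pca <- function(X, ncomp = 2L, center = TRUE, scale = FALSE) {
  m <- nipals_pca(X, ncomp = ncomp, center = center, scale = scale)
  m$method <- "pca"
  m
}

#' Sparse principal component analysis
#'
#' Iterative power scheme with soft-thresholding of the loading to `keepX`
#' features per component; with `keepX = P` it reduces to PCA.
#'
#' @inheritParams pca
#' @param keepX Integer vector (length `ncomp`, recycled from length 1) of
#'   features kept per component; default all.
#' @param tol,max_iter Convergence control.
#' @return A `latent_pca` with an extra `keepX` element.
#' @export
spca <- function(X, ncomp = 2L, keepX = NULL, center = TRUE, scale = FALSE,
                 tol = 1e-9, max_iter = 500L) {
  blk <- as_omics_block(X)
  if (!isTRUE(blk$standardized) && (center || scale)) {
    blk <- center_and_scale(blk, scale = scale)
  }
  R <- blk$values
  N <- nrow(R); P <- ncol(R)
  ncomp <- min(as.integer(ncomp), N - 1L, P)
  if (is.null(keepX)) keepX <- rep(P, ncomp)
  if (length(keepX) == 1L) keepX <- rep(keepX, ncomp)
  if (length(keepX) != ncomp) stop("keepX must have length ncomp")
  if (any(keepX < 1L | keepX > P)) stop("keepX out of [1, ", P, "]")
  totvar <- sum(R^2)
  scores <- matrix(0, N, ncomp)
  loadings <- matrix(0, P, ncomp)
  expl <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    v <- svd(R, nu = 0L, nv = 1L)$v[, 1L]
    delta <- Inf; iter <- 0L
    while (iter < max_iter && delta > tol) {
      iter <- iter + 1L
      t <- drop(R %*% v)
      v_new <- sparsify_loading(drop(crossprod(R, t)), keepX[h])
      delta <- max(abs(v_new - v))
      v <- v_new
    }
    s <- sign_flip(v)
    v <- s * v
    t <- drop(R %*% v)
    scores[, h] <- t
    loadings[, h] <- v
    ss <- sum(t^2)
    proj <- crossprod(R, t) / ss
    expl[h] <- ss * sum(proj^2) / totvar
    R <- R - tcrossprod(t, proj)
  }
  dimnames(scores) <- list(blk$sample_ids, paste0("PC", seq_len(ncomp)))
  dimnames(loadings) <- list(blk$feature_ids, paste0("PC", seq_len(ncomp)))
  structure(list(method = "spca", scores = scores, loadings = loadings,
                 explained_variance = expl, ncomp = ncomp, keepX = keepX,
                 col_means = blk$col_means, col_sds = blk$col_sds,
                 center = center, scale = scale),
            class = "latent_pca")
}

default_ncomp_da <- function(y, blocks_pmin, N) {
  K <- length(unique(as.character(y)))
  max(1L, min(K - 1L, N - 1L, blocks_pmin - 1L))
}

#' Partial least squares regression (PLS)
#'
#' Two-matrix projection to latent structures in regression mode.
#'
#' @param X Predictor matrix or `omics_block`.
#' @param Y Numeric response matrix (N x Q) or vector.
#' @param ncomp Number of components (default 2).
#' @param keepX Optional integer vector of features kept per component
#'   ([spls()] sets it; `pls` keeps all).
#' @param scale Scale columns to unit variance (default TRUE).
#' @param ... Passed to [fit_model()].
#' @return A `latent_model`.
#' @export
pls <- function(X, Y, ncomp = 2L, scale = TRUE, ...) {
  if (is.factor(Y) || is.character(Y)) stop("Y must be continuous; use plsda for a categorical outcome")
  m <- fit_model(X, Y, ncomp = ncomp, scale = scale, ...)
  m$method <- "pls"
  m
}

#' Sparse PLS regression
#' @inheritParams pls
#' @export
spls <- function(X, Y, ncomp = 2L, keepX = NULL, scale = TRUE, ...) {
  if (is.factor(Y) || is.character(Y)) stop("Y must be continuous; use splsda for a categorical outcome")
  m <- fit_model(X, Y, ncomp = ncomp, keepX = keepX, scale = scale, ...)
  m$method <- "spls"
  m
}

#' PLS discriminant analysis
#'
#' The categorical outcome is dummy-encoded and the model fitted in
#' regression mode; equivalent to [splsda()] with all features kept.
#'
#' @param X Matrix or `omics_block`.
#' @param y Categorical outcome, length N.
#' @param ncomp Number of components; default K - 1 (one fewer than the
#'   number of classes).
#' @param scale Scale columns (default TRUE).
#' @param ... Passed to [fit_model()].
#' @return A `latent_model`.
#' @export
plsda <- function(X, y, ncomp = NULL, scale = TRUE, ...) {
  m <- splsda(X, y, ncomp = ncomp, keepX = NULL, scale = scale, ...)
  m$method <- "plsda"
  m
}

#' Sparse PLS discriminant analysis
#'
#' @inheritParams plsda
#' @param keepX Integer vector: number of features selected on each
#'   component (recycled from length 1); default all features (dense PLS-DA).
#' @return A `latent_model` whose loadings have exactly `keepX` nonzero
#'   entries per component.
#' @export
splsda <- function(X, y, ncomp = NULL, keepX = NULL, scale = TRUE, ...) {
  blk <- as_omics_block(X)
  Yd <- if (inherits(y, "outcome_dummy")) y else encode_dummy(y)
  if (is.null(ncomp)) {
    ncomp <- default_ncomp_da(Yd$y, ncol(blk$values), nrow(blk$values))
  }
  m <- fit_model(blk, Yd, ncomp = ncomp, keepX = keepX, scale = scale, ...)
  m$method <- "splsda"
  m
}

#' Multi-block PLS-DA (N-integration, dense)
#'
#' @param X_list Named list of blocks measured on the same samples.
#' @param y Categorical outcome.
#' @param design B x B design matrix (see [block_design()]).
#' @param ncomp Number of components; default K - 1.
#' @param scale Scale columns (default TRUE).
#' @param ... Passed to [fit_model()].
#' @return A `latent_model` with per-block scores and loadings.
#' @export
block_plsda <- function(X_list, y, design = NULL, ncomp = NULL, scale = TRUE, ...) {
  m <- block_splsda(X_list, y, design = design, ncomp = ncomp, keepX = NULL,
                    scale = scale, ...)
  m$method <- "block_plsda"
  m
}

#' Multi-block sparse PLS-DA (N-integration with feature selection)
#'
#' Joint supervised fit of several omics blocks measured on the same N
#' samples, selecting `keepX` features per block per component. The design
#' matrix sets how strongly pairs of blocks are tied; every block is tied to
#' the outcome with weight 1.
#'
#' @inheritParams block_plsda
#' @param keepX_list Named list (per block) of integer vectors of length
#'   `ncomp`; default all features.
#' @export
block_splsda <- function(X_list, y, design = NULL, ncomp = NULL,
                         keepX_list = NULL, scale = TRUE, ...) {
  if (inherits(X_list, "omics_block") || is.matrix(X_list)) X_list <- list(X = X_list)
  X_list <- lapply(X_list, as_omics_block)
  Yd <- if (inherits(y, "outcome_dummy")) y else encode_dummy(y)
  if (is.null(ncomp)) {
    pmin_ <- min(vapply(X_list, function(b) ncol(b$values), 1L))
    ncomp <- default_ncomp_da(Yd$y, pmin_, nrow(X_list[[1L]]$values))
  }
  m <- fit_model(X_list, Yd, design = design, ncomp = ncomp, keepX = keepX_list,
                 scale = scale, ...)
  m$method <- "block_splsda"
  m
}

#' Multi-group PLS-DA across independent studies (P-integration, dense)
#'
#' @param X Matrix or `omics_block` stacking all studies.
#' @param y Categorical outcome.
#' @param study Study membership vector, length N.
#' @param ncomp Number of components; default K - 1.
#' @param scale Scale within study (default TRUE).
#' @param ... Passed to [fit_model()].
#' @export
mint_plsda <- function(X, y, study, ncomp = NULL, scale = TRUE, ...) {
  m <- mint_splsda(X, y, study, ncomp = ncomp, keepX = NULL, scale = scale, ...)
  m$method <- "mint_plsda"
  m
}

#' Multi-group sparse PLS-DA across independent studies
#'
#' Each feature is centred/scaled within each study before a single joint
#' fit, removing additive and multiplicative study batch effects in one step.
#' Loadings are global; scores are available globally and per study.
#'
#' @inheritParams mint_plsda
#' @param keepX Integer vector of features selected per component.
#' @export
mint_splsda <- function(X, y, study, ncomp = NULL, keepX = NULL, scale = TRUE, ...) {
  blk <- as_omics_block(X)
  Yd <- if (inherits(y, "outcome_dummy")) y else encode_dummy(y)
  if (is.null(ncomp)) {
    ncomp <- default_ncomp_da(Yd$y, ncol(blk$values), nrow(blk$values))
  }
  m <- fit_model(blk, Yd, ncomp = ncomp, keepX = keepX, study = study,
                 scale = scale, ...)
  m$method <- "mint_splsda"
  m
}

#' Per-study scores of a multi-group model
#'
#' @param model A `latent_model` fitted with a `study` vector.
#' @param block Block index or name (default 1).
#' @return Named list of score matrices, one per study.
#' @export
study_scores <- function(model, block = 1L) {
  if (is.null(model$study)) stop("model was not fitted with study information")
  sc <- model$scores[[block]]
  lapply(split(seq_along(model$study), model$study),
         function(i) sc[i, , drop = FALSE])
}

#' Features selected on each component
#'
#' @param model A `latent_model` or `latent_pca`.
#' @param block Block index or name (default 1).
#' @param comp Component index, or `NULL` for all components (union kept per
#'   component in a list).
#' @return Character vector (single comp) or list of character vectors.
#' @export
selected_features <- function(model, block = 1L, comp = NULL) {
  L <- if (inherits(model, "latent_pca")) model$loadings else model$loadings[[block]]
  pick <- function(h) rownames(L)[L[, h] != 0]
  if (is.null(comp)) lapply(seq_len(ncol(L)), pick) else pick(comp)
}
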