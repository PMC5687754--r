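#' Principal component analysis by NIPALS, tolerant to missing values
#'
#' Components are extracted by the NIPALS power loop with regression
#' deflation. Missing cells are handled by expectation-maximisation: they
#' are initialised at the column mean, the NIPALS fit is run on the
#' completed matrix, the missing cells are re-imputed from the rank-`ncomp`
#' reconstruction, and the cycle repeats until the imputations stabilise.
#' On complete data a single pass runs and the result coincides with the
#' truncated SVD (up to the package's sign convention).
#'
#' @param X An `omics_block` or numeric matrix, possibly with `NA` entries
#'   (no all-missing row or column).
#' @param ncomp Number of components.
#' @param center,scale Standardise columns first (means/sds computed over
#'   observed cells).
#' @param tol,max_iter Convergence control for each component's power loop.
#' @param em_iter Maximum number of imputation sweeps (ignored on complete
#'   data); the sweep stops when the largest imputed-cell change falls
#'   below 1e-6.
#' @return Object of class `latent_pca`: scores (N x H), loadings (P x H,
#'   unit norm), explained_variance (fraction of total variance per
#'   component), centring/scaling parameters.
#' @export
nipals_pca <- function(X, ncomp = 2L, center = TRUE, scale = FALSE,
                       tol = 1e-9, max_iter = 1000L, em_iter = 100L) {
  blk <- as_omics_block(X, allow_missing = TRUE)
  V <- blk$values
  if (any(rowSums(!is.na(V)) == 0L)) stop("all-missing row present")
  if (any(colSums(!is.na(V)) == 0L)) stop("all-missing column present")
  N <- nrow(V); P <- ncol(V)
  ncomp <- min(as.integer(ncomp), N - 1L, P)
  obs <- !is.na(V)

  sds <- rep(1, P)
  if (scale) {
    sds <- apply(V, 2L, stats::sd, na.rm = TRUE)
    sds[is.na(sds) | sds == 0] <- 1
  }
  Vs <- sweep(V, 2L, sds, "/")

  if (all(obs)) {
    mu <- if (center) colMeans(Vs) else rep(0, P)
    fit <- nipals_core(sweep(Vs, 2L, mu, "-"), ncomp, tol, max_iter)
  } else {
    imp <- Vs
    mu0 <- colMeans(Vs, na.rm = TRUE)
    if (!center) mu0 <- rep(0, P)
    imp[!obs] <- matrix(mu0, N, P, byrow = TRUE)[!obs]
    mu <- mu0
    for (s in seq_len(max(em_iter, 1L))) {
      mu <- if (center) colMeans(imp) else rep(0, P)
      fit <- nipals_core(sweep(imp, 2L, mu, "-"), ncomp, tol, max_iter)
      rec <- sweep(tcrossprod(fit$scores, fit$loadings), 2L, mu, "+")
      delta <- max(abs(rec[!obs] - imp[!obs]))
      imp[!obs] <- rec[!obs]
      if (delta < 1e-6) break
    }
    if (delta >= 1e-6) warning("imputation sweeps did not stabilise; result is approximate")
  }

  scores <- fit$scores
  loadings <- fit$loadings
  dimnames(scores) <- list(blk$sample_ids, paste0("PC", seq_len(ncomp)))
  dimnames(loadings) <- list(blk$feature_ids, paste0("PC", seq_len(ncomp)))
  structure(list(method = "pca", scores = scores, loadings = loadings,
                 explained_variance = fit$explained_variance, ncomp = ncomp,
                 col_means = stats::setNames(mu * sds, blk$feature_ids),
                 col_sds = stats::setNames(sds, blk$feature_ids),
                 center = center, scale = scale),
            class = "latent_pca")
}

# classic NIPALS on a complete, centred matrix
nipals_core <- function(R, ncomp, tol, max_iter) {
  N <- nrow(R); P <- ncol(R)
  totvar <- sum(R^2)
  scores <- matrix(0, N, ncomp)
  loadings <- matrix(0, P, ncomp)
  expl <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    t <- R[, which.max(colSums(R^2))]
    p <- numeric(P)
    delta <- Inf; iter <- 0L
    while (iter < max_iter && delta > tol) {
      iter <- iter + 1L
      p_new <- drop(crossprod(R, t)) / sum(t^2)
      p_new <- p_new / l2norm(p_new)
      t <- drop(R %*% p_new)
      delta <- max(abs(p_new - p))
      p <- p_new
    }
    if (delta > tol) {
      warning(sprintf("NIPALS component %d did not converge in %d iterations", h, max_iter))
    }
    s <- sign_flip(p)
    p <- s * p
    t <- s * t
    scores[, h] <- t
    loadings[, h] <- p
    expl[h] <- sum(t^2) / totvar
    R <- R - tcrossprod(t, p)
  }
  list(scores = scores, loadings = loadings, explained_variance = expl)
}

#' Reconstruct data from a fitted PCA
#'
#' Rank-H reconstruction on the standardized scale, `T %*% t(P)`. Add back
#' `col_means / col_sds` to return to the raw scale.
#'
#' @param pca A `latent_pca`.
#' @param ncomp Number of components to use (default all fitted).
#' @return N x P matrix.
#' @export
pca_reconstruct <- function(pca, ncomp = pca$ncomp) {
  ncomp <- min(ncomp, pca$ncomp)
  tcrossprod(pca$scores[, seq_len(ncomp), drop = FALSE],
             pca$loadings[, seq_len(ncomp), drop = FALSE])
}

#' @export
print.latent_pca <- function(x, ...) {
  cat(sprintf("<latent_pca> %d components; explained variance: %s\n", x$ncomp,
              paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", ")))
  invisible(x)
}
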