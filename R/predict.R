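#' Project new samples onto a fitted model
#'
#' Applies the training standardisation (study-wise for multi-group models,
#' see Details) and the training deflation sequence to compute the predicted
#' scores of new samples on every component of one block.
#'
#' For multi-group (P-integration) models, each new study is standardised by
#' the stored parameters of the matching training study when its name is
#' known; an unseen study with at least 3 samples is standardised by its own
#' means/sds; smaller unseen batches fall back to the global training
#' parameters.
#'
#' @param model A `latent_model`.
#' @param Xnew Matrix of new samples; columns must cover the block's
#'   training features (matched by name when named, by position otherwise).
#' @param block Block index or name (default 1).
#' @param study_new Optional study membership of the new samples.
#' @return N_new x H matrix of predicted scores.
#' @export
project_new <- function(model, Xnew, block = 1L, study_new = NULL) {
  Xs <- standardise_new(model, Xnew, block, study_new)
  H <- model$ncomp
  A <- model$loadings[[block]]
  P <- model$x_loadings[[block]]
  scores <- matrix(0, nrow(Xs), H, dimnames = list(rownames(Xnew), colnames(A)))
  R <- Xs
  for (h in seq_len(H)) {
    t_new <- drop(R %*% A[, h])
    scores[, h] <- t_new
    R <- R - tcrossprod(t_new, P[, h])
  }
  scores
}

standardise_new <- function(model, Xnew, block = 1L, study_new = NULL) {
  Xnew <- as.matrix(Xnew)
  feats <- rownames(model$loadings[[block]])
  if (!is.null(colnames(Xnew))) {
    missing <- setdiff(feats, colnames(Xnew))
    if (length(missing)) {
      stop("new data lacks training feature(s): ",
           paste(utils::head(missing, 5L), collapse = ", "),
           if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L))
    }
    Xnew <- Xnew[, feats, drop = FALSE]
  } else if (ncol(Xnew) != length(feats)) {
    stop("new data has ", ncol(Xnew), " columns; training block has ", length(feats))
  }
  if (anyNA(Xnew) || any(is.infinite(Xnew))) stop("new data contains NA/Inf")
  if (is.null(model$study)) {
    return(apply_standardisation(model$col_means[[block]], model$col_sds[[block]], Xnew))
  }
  if (is.null(study_new)) {
    # no study given: treat the whole batch as one external study if large
    study_new <- rep("..external", nrow(Xnew))
  }
  study_new <- as.character(study_new)
  out <- Xnew
  sp <- model$study_params[[block]]
  for (s in unique(study_new)) {
    idx <- which(study_new == s)
    if (!is.null(sp[[s]])) {
      out[idx, ] <- apply_standardisation(sp[[s]]$col_means, sp[[s]]$col_sds,
                                          Xnew[idx, , drop = FALSE])
    } else if (length(idx) >= 3L) {
      mu <- colMeans(Xnew[idx, , drop = FALSE])
      sds <- apply(Xnew[idx, , drop = FALSE], 2L, stats::sd)
      sds[is.na(sds) | sds == 0] <- 1
      if (!model$scale) sds <- rep(1, ncol(Xnew))
      out[idx, ] <- apply_standardisation(mu, sds, Xnew[idx, , drop = FALSE])
    } else {
      out[idx, ] <- apply_standardisation(model$col_means[[block]],
                                          model$col_sds[[block]],
                                          Xnew[idx, , drop = FALSE])
    }
  }
  out
}

#' Predicted response (dummy) values from predicted scores
#'
#' Applies the training-time regression of the (scaled) response on the
#' block's orthogonal scores, cumulatively for each depth h = 1..H, and maps
#' back to the original dummy scale.
#'
#' @param model A `latent_model`.
#' @param predicted_scores N_new x H matrix from [project_new()].
#' @param block Block index or name.
#' @return N_new x K x H array: predictions built from components 1..h.
#' @export
predict_dummy <- function(model, predicted_scores, block = 1L) {
  H <- model$ncomp
  K <- ncol(model$Ys)
  Cm <- model$y_loadings[[block]]  # K x H
  n <- nrow(predicted_scores)
  out <- array(0, dim = c(n, K, H),
               dimnames = list(rownames(predicted_scores), colnames(model$Ys),
                               paste0("comp", seq_len(H))))
  acc <- matrix(0, n, K)
  for (h in seq_len(H)) {
    acc <- acc + tcrossprod(predicted_scores[, h], Cm[, h])
    out[, , h] <- sweep(sweep(acc, 2L, model$y_sds, "*"), 2L, model$y_means, "+")
  }
  out
}

# classify predicted scores/dummies at one depth
classify_depth <- function(train_scores, y, dummy_h, scores_h, distance) {
  labels <- levels(y)
  if (distance == "max") {
    return(labels[max.col(dummy_h, ties.method = "first")])
  }
  cents <- do.call(rbind, lapply(labels, function(cl) {
    colMeans(train_scores[y == cl, , drop = FALSE])
  }))
  if (distance == "centroid") {
    d2 <- outer(rowSums(scores_h^2), rowSums(cents^2), "+") -
      2 * tcrossprod(scores_h, cents)
  } else {  # mahalanobis, pooled within-class covariance of training scores
    W <- Reduce(`+`, lapply(labels, function(cl) {
      sc <- train_scores[y == cl, , drop = FALSE]
      crossprod(sweep(sc, 2L, colMeans(sc), "-"))
    })) / (nrow(train_scores) - length(labels))
    Winv <- tryCatch(solve(W), error = function(e) NULL)
    if (is.null(Winv)) {
      warning("singular within-class covariance; falling back to centroid distance")
      return(classify_depth(train_scores, y, dummy_h, scores_h, "centroid"))
    }
    d2 <- t(vapply(seq_len(nrow(scores_h)), function(i) {
      diffs <- sweep(cents, 2L, scores_h[i, ], "-")
      rowSums((diffs %*% Winv) * diffs)
    }, numeric(nrow(cents))))
  }
  labels[apply(d2, 1L, which.min)]
}

#' Assign classes to predicted samples with a prediction distance
#'
#' * `max`: argmax over the K predicted dummy values;
#' * `centroid`: nearest training class centroid of the latent scores
#'   (Euclidean);
#' * `mahalanobis`: nearest centroid under the pooled within-class
#'   covariance of the training scores (falls back to centroid with a
#'   warning when that covariance is singular).
#'
#' @param model A `latent_model`.
#' @param prediction Result of [predict.latent_model()] (or a list with
#'   `scores` and `dummy` for the chosen block).
#' @param distance One of `"max"`, `"centroid"`, `"mahalanobis"`.
#' @param block Block index or name.
#' @return N_new x H character matrix of predicted labels, one column per
#'   component depth.
#' @export
assign_class <- function(model, prediction, distance = c("max", "centroid", "mahalanobis"),
                         block = 1L) {
  distance <- match.arg(distance)
  if (!model$is_da) stop("class assignment requires a discriminant model")
  scores_new <- prediction$scores[[block]]
  dummy_new <- prediction$dummy[[block]]
  y <- model$outcome$y
  H <- model$ncomp
  out <- matrix(NA_character_, nrow(scores_new), H,
                dimnames = list(rownames(scores_new), paste0("comp", seq_len(H))))
  for (h in seq_len(H)) {
    dh <- dummy_new[, , h, drop = FALSE]
    dim(dh) <- dim(dummy_new)[1:2]
    out[, h] <- classify_depth(model$scores[[block]][, seq_len(h), drop = FALSE],
                               y, dh,
                               scores_new[, seq_len(h), drop = FALSE], distance)
  }
  out
}

#' Majority vote across blocks
#'
#' The class predicted most often across blocks; ties are reported as `NA`.
#'
#' @param per_block_labels List (or N x B matrix) of per-block label vectors.
#' @return Character vector with `NA` at ties.
#' @export
combine_votes <- function(per_block_labels) {
  M <- if (is.list(per_block_labels)) do.call(cbind, per_block_labels) else as.matrix(per_block_labels)
  apply(M, 1L, function(v) {
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) NA_character_ else names(tab)[1L]
  })
}

#' Block weights for the weighted vote
#'
#' Each block's weight is the mean over components of the absolute
#' correlation between the block's training scores and the outcome variate.
#'
#' @param model A multi-block `latent_model`.
#' @return Named numeric vector of weights, one per block.
#' @export
block_weights <- function(model) {
  w <- vapply(seq_along(model$block_names), function(b) {
    mean(abs(diag(stats::cor(model$scores[[b]], model$y_scores))))
  }, numeric(1))
  stats::setNames(w, model$block_names)
}

#' Weighted vote across blocks
#'
#' Each block votes for its predicted class with the block's weight (see
#' [block_weights()]); the class accumulating the highest total weight wins.
#' Exact weight ties are reported as `NA`.
#'
#' @param per_block_labels List or N x B matrix of per-block label vectors.
#' @param weights Numeric vector of block weights (e.g. [block_weights()]).
#' @return Character vector with `NA` at exact ties.
#' @export
weighted_vote <- function(per_block_labels, weights) {
  M <- if (is.list(per_block_labels)) do.call(cbind, per_block_labels) else as.matrix(per_block_labels)
  if (length(weights) != ncol(M)) stop("one weight per block required")
  apply(M, 1L, function(v) {
    sc <- tapply(weights, v, sum)
    sc <- sort(sc, decreasing = TRUE)
    if (length(sc) > 1L && abs(sc[1L] - sc[2L]) < 1e-12) NA_character_ else names(sc)[1L]
  })
}

#' Predict method for fitted models
#'
#' Computes predicted scores, predicted dummy (or continuous response)
#' values at every component depth, and -- for discriminant models -- class
#' assignments under the three prediction distances, with majority and
#' weighted votes across blocks for multi-block models.
#'
#' @param object A `latent_model`.
#' @param newdata Matrix (single block) or named list of matrices.
#' @param study_new Optional study membership of new samples (multi-group
#'   models).
#' @param ... Unused.
#' @return Object of class `latent_prediction` with elements `scores`,
#'   `dummy` (per block, N x K x H), `dummy_combined` (average over blocks),
#'   `class` (per distance: per-block N x H label matrices plus
#'   `majority`/`weighted` for B > 1), `weights`.
#' @export
predict.latent_model <- function(object, newdata, study_new = NULL, ...) {
  B <- length(object$block_names)
  if (!is.list(newdata) || is.data.frame(newdata)) newdata <- list(newdata)
  if (length(newdata) != B) stop("newdata must supply all ", B, " block(s)")
  if (!is.null(names(newdata)) && all(nzchar(names(newdata))) &&
      setequal(names(newdata), object$block_names)) {
    newdata <- newdata[object$block_names]
  }
  scores <- lapply(seq_len(B), function(b) {
    project_new(object, as.matrix(newdata[[b]]), block = b, study_new = study_new)
  })
  dummy <- lapply(seq_len(B), function(b) predict_dummy(object, scores[[b]], block = b))
  names(scores) <- names(dummy) <- object$block_names
  dummy_combined <- Reduce(`+`, dummy) / B
  pred <- list(scores = scores, dummy = dummy, dummy_combined = dummy_combined)
  if (object$is_da) {
    weights <- block_weights(object)
    pred$weights <- weights
    pred$class <- list()
    for (d in c("max", "centroid", "mahalanobis")) {
      per_block <- lapply(seq_len(B), function(b) assign_class(object, pred, d, block = b))
      names(per_block) <- object$block_names
      entry <- per_block
      if (B > 1L) {
        H <- object$ncomp
        maj <- wtd <- matrix(NA_character_, nrow(per_block[[1L]]), H)
        for (h in seq_len(H)) {
          lab_h <- lapply(per_block, function(m) m[, h])
          maj[, h] <- combine_votes(lab_h)
          wtd[, h] <- weighted_vote(lab_h, weights)
        }
        colnames(maj) <- colnames(wtd) <- paste0("comp", seq_len(H))
        entry$majority <- maj
        entry$weighted <- wtd
      }
      pred$class[[d]] <- entry
    }
  }
  structure(pred, class = "latent_prediction")
}

#' Headline class predictions at full depth
#'
#' @param prediction A `latent_prediction` from a discriminant model.
#' @param distance Prediction distance.
#' @param vote For multi-block models, `"majority"` or `"weighted"`.
#' @return Character vector of predicted labels (`NA` at vote ties).
#' @export
predicted_classes <- function(prediction, distance = "centroid", vote = "majority") {
  cl <- prediction$class[[distance]]
  if (is.null(cl)) stop("unknown distance: ", distance)
  blocks <- setdiff(names(cl), c("majority", "weighted"))
  M <- if (length(blocks) > 1L) cl[[vote]] else cl[[1L]]
  M[, ncol(M)]
}

#' Prediction-area grid over the first two components
#'
#' Classifies a rectangular grid spanning the component-1/2 score range
#' (plus a 10% margin) with the chosen prediction distance, the numeric
#' backend of the prediction-area overlay on sample plots.
#'
#' @param model A discriminant `latent_model` with `ncomp >= 2`.
#' @param distance Prediction distance.
#' @param grid_n Grid resolution per axis.
#' @param block Block index or name.
#' @return data.frame with columns `comp1`, `comp2`, `label`.
#' @export
prediction_region <- function(model, distance = c("max", "centroid", "mahalanobis"),
                              grid_n = 50L, block = 1L) {
  distance <- match.arg(distance)
  if (!model$is_da) stop("prediction regions require a discriminant model")
  if (model$ncomp < 2L) stop("prediction regions need at least 2 components")
  sc <- model$scores[[block]][, 1:2, drop = FALSE]
  pad <- 0.1
  rx <- range(sc[, 1L]); ry <- range(sc[, 2L])
  rx <- rx + c(-1, 1) * pad * diff(rx)
  ry <- ry + c(-1, 1) * pad * diff(ry)
  gx <- seq(rx[1L], rx[2L], length.out = grid_n)
  gy <- seq(ry[1L], ry[2L], length.out = grid_n)
  grid <- as.matrix(expand.grid(comp1 = gx, comp2 = gy))
  # dummy values of a grid point from the two displayed components
  Cm <- model$y_loadings[[block]][, 1:2, drop = FALSE]
  acc <- tcrossprod(grid[, 1L], Cm[, 1L]) + tcrossprod(grid[, 2L], Cm[, 2L])
  dummy_h <- sweep(sweep(acc, 2L, model$y_sds, "*"), 2L, model$y_means, "+")
  lab <- classify_depth(sc, model$outcome$y, dummy_h, grid, distance)
  data.frame(comp1 = grid[, 1L], comp2 = grid[, 2L], label = lab,
             stringsAsFactors = FALSE)
}
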