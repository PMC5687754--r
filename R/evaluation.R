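#' Cross-validated performance of a fitted model
#'
#' Refits the model inside each training fold (the sparse selection is
#' repeated per fold with the model's keepX), predicts the held-out fold at
#' every component depth and under all three prediction distances, and
#' aggregates the overall and balanced error rates over repeats. The
#' per-fold selected features are recorded for stability assessment, and
#' one-vs-all AUC is averaged over the CV.
#'
#' @param model A discriminant `latent_model`.
#' @param folds Optional `fold_plan`; otherwise stratified
#'   `nfolds x nrepeats` folds are built (leave-one-group-out when the model
#'   carries a study vector).
#' @param nfolds,nrepeats,seed Fold construction when `folds` is NULL.
#' @param cpus Number of workers for the fold loop (results are identical
#'   for any value).
#' @return Object of class `perf_report`: `error` (array distance x measure
#'   x depth of means over repeats) and `error_sd`; `error_per_repeat`;
#'   `stability` (per block, per component: named selection frequencies);
#'   `auc` (class x depth, averaged over repeats); `folds`.
#' @export
perf <- function(model, folds = NULL, nfolds = 5L, nrepeats = 1L, seed = 1L,
                 cpus = 1L) {
  if (!inherits(model, "latent_model") || !model$is_da) {
    stop("perf requires a fitted discriminant latent_model")
  }
  y <- model$outcome$y
  blocks <- model$X_raw
  study <- model$study
  if (is.null(folds)) {
    folds <- if (!is.null(study)) {
      make_folds(y, "logocv", study = study, seed = seed)
    } else {
      make_folds(y, "stratified", nfolds = nfolds, nrepeats = nrepeats, seed = seed)
    }
  }
  fitter <- function(tr_blocks, y_tr, st_tr) {
    fit_model(tr_blocks, encode_dummy(y_tr), design = model$design,
              ncomp = model$ncomp, keepX = model$keepX, study = st_tr,
              scale = model$scale, tol = model$tol, max_iter = model$max_iter)
  }
  distances <- c("max", "centroid", "mahalanobis")
  reps <- cv_run(blocks, y, study, folds, fitter, distances = distances, cpus = cpus)

  H <- model$ncomp
  measures <- c("overall", "ber")
  R <- length(reps)
  err_rep <- array(NA_real_, dim = c(length(distances), length(measures), H, R),
                   dimnames = list(distances, measures, paste0("comp", seq_len(H)), NULL))
  for (r in seq_len(R)) {
    for (d in distances) {
      for (h in seq_len(H)) {
        err_rep[d, "overall", h, r] <- error_rate(y, reps[[r]]$labels[[d]][, h])
        err_rep[d, "ber", h, r] <- ber(y, reps[[r]]$labels[[d]][, h])
      }
    }
  }
  err_mean <- apply(err_rep, 1:3, mean)
  err_sd <- apply(err_rep, 1:3, stats::sd)

  # stability: selection frequency across all fold refits
  all_sel <- unlist(lapply(reps, `[[`, "selected"), recursive = FALSE)
  stability <- lapply(seq_along(model$block_names), function(b) {
    feats <- rownames(model$loadings[[b]])
    sel_b <- lapply(all_sel, `[[`, b)
    selection_stability(sel_b, feats)
  })
  names(stability) <- model$block_names

  # one-vs-all AUC from the pooled CV dummy predictions, averaged over repeats
  classes <- model$outcome$class_labels
  auc_rep <- array(NA_real_, dim = c(length(classes), H, R),
                   dimnames = list(classes, paste0("comp", seq_len(H)), NULL))
  for (r in seq_len(R)) {
    for (h in seq_len(H)) {
      sc <- reps[[r]]$dummy[, , h]
      auc_rep[, h, r] <- roc_auc(sc, y)$auc
    }
  }
  structure(list(error = err_mean, error_sd = err_sd, error_per_repeat = err_rep,
                 stability = stability, auc = apply(auc_rep, 1:2, mean),
                 auc_per_repeat = auc_rep, folds = folds),
            class = "perf_report")
}

#' Feature-selection stability across CV refits
#'
#' @param fold_selections List over fold refits; each element is a list (per
#'   component) of selected feature identifiers.
#' @param features Character vector of all feature identifiers.
#' @return List per component of named selection frequencies in `[0, 1]`.
#' @export
selection_stability <- function(fold_selections, features) {
  ncomp <- length(fold_selections[[1L]])
  nfit <- length(fold_selections)
  lapply(seq_len(ncomp), function(h) {
    counts <- table(factor(unlist(lapply(fold_selections, `[[`, h)), levels = features))
    stats::setNames(as.numeric(counts) / nfit, features)
  })
}

#' One-vs-all ROC curves and AUC
#'
#' For each class, the predicted dummy value of that class is swept over all
#' thresholds against the class-vs-rest truth. AUC is computed by the
#' rank/trapezoid rule, with ties averaged.
#'
#' @param scores N x K matrix of per-class scores (e.g. predicted dummy
#'   values); column names identify the classes.
#' @param truth Length-N vector of true labels.
#' @return List with `auc` (named per-class vector) and `roc` (per class, a
#'   data.frame of `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, truth) {
  scores <- as.matrix(scores)
  truth <- as.character(truth)
  classes <- colnames(scores)
  if (is.null(classes)) classes <- paste0("class", seq_len(ncol(scores)))
  auc <- stats::setNames(numeric(length(classes)), classes)
  roc <- list()
  for (k in seq_along(classes)) {
    s <- scores[, k]
    pos <- truth == classes[k]
    ok <- !is.na(s)
    s <- s[ok]; p <- pos[ok]
    n1 <- sum(p); n0 <- sum(!p)
    if (n1 == 0L || n0 == 0L) {
      auc[k] <- NA_real_
      next
    }
    r <- rank(s, ties.method = "average")
    auc[k] <- (sum(r[p]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    thr <- sort(unique(s), decreasing = TRUE)
    tpr <- vapply(thr, function(t) mean(s[p] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(s[!p] >= t), numeric(1))
    roc[[classes[k]]] <- data.frame(threshold = c(Inf, thr),
                                    fpr = c(0, fpr), tpr = c(0, tpr))
  }
  list(auc = auc, roc = roc)
}

#' @export
print.perf_report <- function(x, ...) {
  H <- dim(x$error)[3L]
  cat(sprintf("<perf_report> %d component depth(s)\n", H))
  cat("BER at full depth:\n")
  for (d in dimnames(x$error)[[1L]]) {
    cat(sprintf("  %-12s %.3f\n", d, x$error[d, "ber", H]))
  }
  invisible(x)
}
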