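#' Overall misclassification error rate
#'
#' `NA` predictions (vote ties) count as errors.
#'
#' @param truth,predicted Label vectors of equal length.
#' @return Fraction of misclassified samples in `[0, 1]`.
#' @export
error_rate <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  mean(is.na(predicted) | predicted != truth)
}

#' Balanced error rate (BER)
#'
#' Unweighted mean of the per-class misclassification proportions, so
#' minority classes count as much as majority classes. `NA` predictions
#' count as errors.
#'
#' @inheritParams error_rate
#' @return BER in `[0, 1]`.
#' @export
ber <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  err <- is.na(predicted) | predicted != truth
  mean(tapply(err, truth, mean))
}

#' Build cross-validation fold assignments
#'
#' Stratified M-fold (class proportions preserved within one sample per
#' fold), repeated `nrepeats` times, or leave-one-group-out where each study
#' is a fold.
#'
#' @param y Outcome labels (stratification variable).
#' @param scheme `"stratified"` or `"logocv"`.
#' @param nfolds Number of folds (stratified scheme).
#' @param nrepeats Number of repeats (stratified scheme).
#' @param seed Integer seed making the plan reproducible.
#' @param study Study membership (required for `"logocv"`).
#' @return Object of class `fold_plan`: list with `assignments` (one integer
#'   vector per repeat), `scheme`, `nfolds`, `nrepeats`, `seed`,
#'   `fold_names`.
#' @export
make_folds <- function(y, scheme = c("stratified", "logocv"), nfolds = 5L,
                       nrepeats = 1L, seed = 1L, study = NULL) {
  scheme <- match.arg(scheme)
  N <- length(y)
  if (scheme == "logocv") {
    if (is.null(study)) stop("logocv requires a study vector")
    study <- as.factor(study)
    assignments <- list(as.integer(study))
    return(structure(list(assignments = assignments, scheme = scheme,
                          nfolds = nlevels(study), nrepeats = 1L, seed = seed,
                          fold_names = levels(study)),
                     class = "fold_plan"))
  }
  y <- as.factor(y)
  if (nfolds < 2L || nfolds > N) stop("nfolds must be in [2, N]")
  if (any(table(y) < 1L)) stop("empty class")
  rng <- local({
    set.seed(as.integer(seed))
    lapply(seq_len(nrepeats), function(r) sample.int(.Machine$integer.max, 1L))
  })
  assignments <- lapply(seq_len(nrepeats), function(r) {
    set.seed(rng[[r]])
    fold <- integer(N)
    offset <- 0L
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      # continue the fold cycle across classes so totals stay balanced too
      ids <- ((offset + seq_along(idx) - 1L) %% nfolds) + 1L
      fold[idx] <- ids
      offset <- offset + length(idx)
    }
    fold
  })
  structure(list(assignments = assignments, scheme = scheme, nfolds = nfolds,
                 nrepeats = nrepeats, seed = seed,
                 fold_names = paste0("fold", seq_len(nfolds))),
            class = "fold_plan")
}

# Run cross-validation for a model-fitting closure.
# fitter(blocks_train, y_train, study_train) -> latent_model
# Returns per repeat: labels per distance (N x H, majority vote for B > 1),
# dummy (N x K x H combined), and per-fold selected features per component.
cv_run <- function(blocks, y, study, plan, fitter,
                   distances = c("max", "centroid", "mahalanobis"), cpus = 1L) {
  y <- as.factor(y)
  N <- length(y)
  run_fold <- function(r, f) {
    fold <- plan$assignments[[r]]
    test <- which(fold == f)
    train <- which(fold != f)
    tr_blocks <- lapply(blocks, function(X) X[train, , drop = FALSE])
    te_blocks <- lapply(blocks, function(X) X[test, , drop = FALSE])
    tr_study <- if (is.null(study)) NULL else droplevels(as.factor(study)[train])
    te_study <- if (is.null(study)) NULL else as.character(study)[test]
    m <- fitter(tr_blocks, y[train], tr_study)
    pr <- predict(m, te_blocks, study_new = te_study)
    B <- length(m$block_names)
    labels <- lapply(distances, function(d) {
      cl <- pr$class[[d]]
      if (B > 1L) cl$majority else cl[[1L]]
    })
    names(labels) <- distances
    sel <- lapply(seq_along(m$block_names), function(b) selected_features(m, block = b))
    names(sel) <- m$block_names
    list(test = test, labels = labels, dummy = pr$dummy_combined, selected = sel)
  }
  jobs <- expand.grid(f = seq_len(plan$nfolds), r = seq_len(plan$nrepeats))
  runner <- function(i) run_fold(jobs$r[i], jobs$f[i])
  res <- if (cpus > 1L) {
    parallel::mclapply(seq_len(nrow(jobs)), runner, mc.cores = cpus)
  } else {
    lapply(seq_len(nrow(jobs)), runner)
  }
  # assemble per repeat
  H <- ncol(res[[1L]]$labels[[1L]])
  K <- dim(res[[1L]]$dummy)[2L]
  repeats <- lapply(seq_len(plan$nrepeats), function(r) {
    labels <- lapply(distances, function(d) matrix(NA_character_, N, H))
    names(labels) <- distances
    dn <- dimnames(res[[1L]]$dummy)
    dummy <- array(NA_real_, dim = c(N, K, H),
                   dimnames = list(NULL, dn[[2L]], dn[[3L]]))
    sel <- list()
    for (i in which(jobs$r == r)) {
      for (d in distances) labels[[d]][res[[i]]$test, ] <- res[[i]]$labels[[d]]
      dummy[res[[i]]$test, , ] <- res[[i]]$dummy
      sel[[length(sel) + 1L]] <- res[[i]]$selected
    }
    list(labels = labels, dummy = dummy, selected = sel)
  })
  repeats
}

measure_fun <- function(measure) if (measure == "ber") ber else error_rate

#' Tune the number of selected features by cross-validation
#'
#' Grid search over `keepX`, one component at a time: the component-1 value
#' is fixed at its CV-optimal value before component 2 is tuned, and so on.
#' For multi-block models per-block grids are evaluated factorially. Ties
#' are resolved toward the smallest keepX (smallest total, then
#' lexicographic, for factorial grids) to favour minimal signatures.
#'
#' @param X Matrix (or `omics_block`), or named list of matrices for
#'   multi-block tuning.
#' @param y Categorical outcome.
#' @param ncomp Number of components to tune.
#' @param grid Integer vector of candidate keepX values, or named list of
#'   vectors (one per block).
#' @param study Optional study vector; triggers the multi-group fit and, by
#'   default, leave-one-group-out folds.
#' @param design Optional design matrix for multi-block fits.
#' @param folds Optional `fold_plan`; built from `nfolds`/`nrepeats`/`seed`
#'   when omitted (LOGOCV when `study` is given).
#' @param distance Prediction distance used during tuning.
#' @param measure `"ber"` (default) or `"overall"`.
#' @param nfolds,nrepeats,seed Fold-plan construction when `folds` is NULL.
#' @param alpha Significance level of the one-sided t-tests used to pick the
#'   number of components.
#' @param scale,cpus Passed through to the fits / CV loop.
#' @return Object of class `tune_result`: `chosen_keepX` (list per block),
#'   `chosen_ncomp`, `error_surface` (per component: candidates with mean/sd
#'   error over repeats), `error_by_ncomp` (depth x repeat matrix at the
#'   chosen keepX), `measure`, `distance`, `grid`, `folds`.
#' @export
tune_keepx <- function(X, y, ncomp = 2L, grid, study = NULL, design = NULL,
                       folds = NULL, distance = c("centroid", "max", "mahalanobis"),
                       measure = c("ber", "overall"), nfolds = 5L, nrepeats = 1L,
                       seed = 1L, alpha = 0.05, scale = TRUE, cpus = 1L) {
  distance <- match.arg(distance)
  measure <- match.arg(measure)
  single <- !is.list(X) || is.data.frame(X) || inherits(X, "omics_block")
  blocks <- if (single) list(X = as.matrix(as_omics_block(X)$values)) else
    lapply(X, function(b) as.matrix(as_omics_block(b)$values))
  if (is.null(names(blocks)) || any(!nzchar(names(blocks)))) {
    names(blocks) <- paste0("block", seq_along(blocks))
  }
  B <- length(blocks)
  if (!is.list(grid)) grid <- stats::setNames(rep(list(as.integer(grid)), B), names(blocks))
  grid <- lapply(grid, function(g) sort(unique(as.integer(g))))
  for (b in seq_len(B)) {
    if (any(grid[[b]] < 1L | grid[[b]] > ncol(blocks[[b]]))) {
      stop("grid values for block ", names(blocks)[b],
           " outside [1, ", ncol(blocks[[b]]), "]")
    }
  }
  y <- as.factor(y)
  if (is.null(folds)) {
    folds <- if (!is.null(study)) {
      make_folds(y, "logocv", study = study, seed = seed)
    } else {
      make_folds(y, "stratified", nfolds = nfolds, nrepeats = nrepeats, seed = seed)
    }
  }
  mfun <- measure_fun(measure)

  # candidate combinations, ordered so the tie rule = first minimum
  combos <- as.matrix(expand.grid(grid, KEEP.OUT.ATTRS = FALSE))
  colnames(combos) <- names(blocks)
  ord <- do.call(order, c(list(rowSums(combos)), lapply(seq_len(B), function(b) combos[, b])))
  combos <- combos[ord, , drop = FALSE]

  chosen <- lapply(seq_len(B), function(b) integer(0))
  names(chosen) <- names(blocks)
  surfaces <- list()
  err_by_ncomp <- matrix(NA_real_, ncomp, folds$nrepeats)

  for (h in seq_len(ncomp)) {
    err_mean <- err_sd <- numeric(nrow(combos))
    err_reps <- matrix(NA_real_, nrow(combos), folds$nrepeats)
    for (ci in seq_len(nrow(combos))) {
      keepX_h <- lapply(seq_len(B), function(b) c(chosen[[b]], combos[ci, b]))
      names(keepX_h) <- names(blocks)
      fitter <- function(tr_blocks, y_tr, st_tr) {
        fit_model(tr_blocks, encode_dummy(y_tr), design = design, ncomp = h,
                  keepX = keepX_h, study = st_tr, scale = scale)
      }
      reps <- cv_run(blocks, y, study, folds, fitter, distances = distance,
                     cpus = cpus)
      err_reps[ci, ] <- vapply(reps, function(rr) mfun(y, rr$labels[[distance]][, h]),
                               numeric(1))
    }
    err_mean <- rowMeans(err_reps)
    err_sd <- apply(err_reps, 1L, stats::sd)
    best <- which(err_mean == min(err_mean))[1L]
    for (b in seq_len(B)) chosen[[b]] <- c(chosen[[b]], unname(combos[best, b]))
    err_by_ncomp[h, ] <- err_reps[best, ]
    surfaces[[h]] <- data.frame(combos, mean = err_mean, sd = err_sd,
                                check.names = FALSE)
  }
  chosen_ncomp <- choose_ncomp(err_by_ncomp, alpha = alpha)
  structure(list(chosen_keepX = chosen, chosen_ncomp = chosen_ncomp,
                 error_surface = surfaces, error_by_ncomp = err_by_ncomp,
                 measure = measure, distance = distance, grid = grid,
                 folds = folds),
            class = "tune_result")
}

#' Choose the number of components from CV error curves
#'
#' Starting from one component, a one-sided paired t-test across CV repeats
#' asks whether adding the next component still lowers the error; the
#' smallest depth at which the gain stops being significant (at `alpha`) is
#' returned. With a single repeat the test degenerates to requiring a
#' strict error decrease.
#'
#' @param cv_errors H x R matrix of error rates (component depth x repeat).
#' @param alpha Significance level (default 0.05).
#' @return Integer, the chosen number of components.
#' @export
choose_ncomp <- function(cv_errors, alpha = 0.05) {
  cv_errors <- as.matrix(cv_errors)
  H <- nrow(cv_errors)
  if (H == 1L) return(1L)
  for (h in seq_len(H - 1L)) {
    d <- cv_errors[h + 1L, ] - cv_errors[h, ]
    if (length(d) < 2L) {
      if (d >= 0) return(h) else next
    }
    if (stats::sd(d) == 0) {
      if (all(d < 0)) next else return(h)
    }
    p <- stats::t.test(d, alternative = "less")$p.value
    if (p >= alpha) return(h)
  }
  H
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("<tune_result> measure=%s distance=%s, chosen ncomp=%d\n",
              x$measure, x$distance, x$chosen_ncomp))
  for (b in names(x$chosen_keepX)) {
    cat(sprintf("  keepX[%s] = %s\n", b, paste(x$chosen_keepX[[b]], collapse = "/")))
  }
  invisible(x)
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %s, %d fold(s) x %d repeat(s)\n",
              x$scheme, x$nfolds, x$nrepeats))
  invisible(x)
}
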