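#' Construct an omics data block
#'
#' An omics block is a samples-by-features numeric matrix carrying sample and
#' feature identifiers plus, once standardised, the column means and standard
#' deviations needed to project new samples onto a fitted model.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param sample_ids Character vector of unique sample identifiers. Defaults
#'   to the row names of `values`, or `sample1..sampleN`.
#' @param feature_ids Character vector of unique feature identifiers. Defaults
#'   to the column names of `values`, or `feature1..featureP`.
#' @param allow_missing Logical; when `FALSE` (default) `NA` entries are an
#'   error. Only missing-tolerant consumers (NIPALS PCA) should set `TRUE`.
#'
#' @return An object of class `omics_block`: a list with elements `values`,
#'   `sample_ids`, `feature_ids`, `standardized`, `col_means`, `col_sds`.
#' @export
omics_block <- function(values, sample_ids = NULL, feature_ids = NULL,
                        allow_missing = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("block values must be numeric")
  if (nrow(values) < 2L) stop("an omics block needs at least 2 samples")
  if (ncol(values) < 1L) stop("an omics block needs at least 1 feature")
  if (any(is.infinite(values))) stop("block contains infinite entries")
  if (!allow_missing && anyNA(values)) {
    stop("block contains missing values; only NIPALS PCA accepts them")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("feature", seq_len(ncol(values)))
  }
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values)) stop("sample_ids length != nrow(values)")
  if (length(feature_ids) != ncol(values)) stop("feature_ids length != ncol(values)")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(values = values, sample_ids = sample_ids, feature_ids = feature_ids,
         standardized = FALSE, col_means = NULL, col_sds = NULL),
    class = "omics_block"
  )
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("<omics_block> %d samples x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (isTRUE(x$standardized)) " (standardized)" else ""))
  invisible(x)
}

as_omics_block <- function(x, allow_missing = FALSE) {
  if (inherits(x, "omics_block")) x else omics_block(x, allow_missing = allow_missing)
}

#' Centre (and scale) the columns of an omics block
#'
#' Columns are centred to mean zero and, when `scale = TRUE`, divided by
#' their standard deviation (denominator N - 1). Constant columns are left at
#' zero after centring and their sd is recorded as 1 so projection of new
#' samples never divides by zero. The centring/scaling parameters are stored
#' on the returned block for later projection.
#'
#' @param block An `omics_block` (or bare matrix).
#' @param scale Logical; divide by column sds as well as centring.
#' @return A standardized `omics_block` with `col_means`/`col_sds` recorded.
#' @export
center_and_scale <- function(block, scale = TRUE) {
  block <- as_omics_block(block, allow_missing = TRUE)
  if (isTRUE(block$standardized)) stop("block is already standardized")
  X <- block$values
  n_obs <- colSums(!is.na(X))
  if (any(n_obs == 0L)) {
    stop("column(s) entirely missing: ",
         paste(block$feature_ids[n_obs == 0L], collapse = ", "))
  }
  mu <- colMeans(X, na.rm = TRUE)
  Xc <- sweep(X, 2L, mu, "-")
  sds <- rep(1, ncol(X))
  if (scale) {
    sds <- apply(Xc, 2L, stats::sd, na.rm = TRUE)
    sds[is.na(sds) | sds == 0] <- 1  # constant columns: scale-protected
    Xc <- sweep(Xc, 2L, sds, "/")
  }
  block$values <- Xc
  block$standardized <- TRUE
  block$col_means <- stats::setNames(mu, block$feature_ids)
  block$col_sds <- stats::setNames(sds, block$feature_ids)
  block
}

#' Apply stored standardisation parameters to new samples
#'
#' @param block A standardized `omics_block` whose parameters to reuse.
#' @param newdata Matrix of new samples with the same features.
#' @return Matrix of standardized new samples.
#' @keywords internal
apply_standardisation <- function(col_means, col_sds, newdata) {
  newdata <- sweep(newdata, 2L, col_means, "-")
  sweep(newdata, 2L, col_sds, "/")
}

#' Study-wise standardisation for multi-study (P-integration) data
#'
#' Each feature is centred (and scaled) within each study separately, so that
#' additive and multiplicative study-level batch effects are removed before a
#' joint fit. Per-study parameters are stored for projecting new samples.
#'
#' @param block An `omics_block` (or matrix) holding all studies stacked.
#' @param study Factor/vector of study membership, length N.
#' @param scale Logical; scale within study as well as centring.
#' @return A standardized `omics_block` with an extra `study_params` element
#'   (per-study lists of `col_means`, `col_sds`) and `study` stored.
#' @export
mint_standardise <- function(block, study, scale = TRUE) {
  block <- as_omics_block(block)
  study <- as.factor(study)
  if (length(study) != nrow(block$values)) stop("study length != number of samples")
  sizes <- table(study)
  if (any(sizes < 2L)) {
    stop("every study needs >= 2 samples for within-study centring")
  }
  if (scale && any(sizes < 3L)) {
    stop("a study has < 3 samples; scaling is unstable, use scale = FALSE")
  }
  X <- block$values
  raw_mu <- colMeans(X)
  raw_sd <- rep(1, ncol(X))
  if (scale) {
    raw_sd <- apply(X, 2L, stats::sd)
    raw_sd[is.na(raw_sd) | raw_sd == 0] <- 1
  }
  params <- list()
  for (s in levels(study)) {
    idx <- which(study == s)
    mu <- colMeans(X[idx, , drop = FALSE])
    Xs <- sweep(X[idx, , drop = FALSE], 2L, mu, "-")
    sds <- rep(1, ncol(X))
    if (scale) {
      sds <- apply(Xs, 2L, stats::sd)
      sds[is.na(sds) | sds == 0] <- 1
      Xs <- sweep(Xs, 2L, sds, "/")
    }
    X[idx, ] <- Xs
    params[[s]] <- list(col_means = stats::setNames(mu, block$feature_ids),
                        col_sds = stats::setNames(sds, block$feature_ids))
  }
  block$values <- X
  block$standardized <- TRUE
  # raw global params retained as fallback for tiny external test studies
  block$col_means <- stats::setNames(raw_mu, block$feature_ids)
  block$col_sds <- stats::setNames(raw_sd, block$feature_ids)
  block$study_params <- params
  block$study <- study
  block
}

#' Encode a categorical outcome as a dummy indicator matrix
#'
#' Each column of the indicator corresponds to one outcome class (sorted
#' label order); row i has a single 1 in the column of sample i's class.
#'
#' @param y Categorical outcome, length N, with at least 2 distinct values.
#' @return An object of class `outcome_dummy`: list with `indicator` (N x K
#'   binary matrix), `class_labels`, `y` (as factor with sorted levels).
#' @export
encode_dummy <- function(y) {
  y <- factor(as.character(y), levels = sort(unique(as.character(y))))
  if (nlevels(y) < 2L) stop("outcome must have at least 2 classes")
  counts <- table(y)
  if (any(counts == 0L)) {
    stop("class(es) with 0 samples: ",
         paste(names(counts)[counts == 0L], collapse = ", "))
  }
  ind <- stats::model.matrix(~ y - 1)
  colnames(ind) <- levels(y)
  rownames(ind) <- NULL
  attr(ind, "assign") <- NULL
  attr(ind, "contrasts") <- NULL
  structure(list(indicator = ind, class_labels = levels(y), y = y),
            class = "outcome_dummy")
}

#' Block-connection design matrix for multi-block models
#'
#' Returns the B x B symmetric design governing which block pairs' covariance
#' the multi-block objective maximises. The default links every pair of omics
#' blocks with a weak weight of 0.1 (a compromise between maximising
#' cross-block correlation and discriminating the outcome); the connection of
#' each block to the outcome is always 1 and is handled internally.
#'
#' @param block_names Character vector of block names.
#' @param weight Off-diagonal block-block weight in `[0, 1]`.
#' @param design Optional full B x B matrix overriding the default.
#' @return Symmetric B x B matrix with zero diagonal, dimnames = block names.
#' @export
block_design <- function(block_names, weight = 0.1, design = NULL) {
  B <- length(block_names)
  if (is.null(design)) {
    D <- matrix(weight, B, B)
  } else {
    D <- as.matrix(design)
    if (!all(dim(D) == B)) stop("design must be ", B, " x ", B)
    if (max(abs(D - t(D))) > 1e-12) stop("design must be symmetric")
    if (any(D < 0 | D > 1)) stop("design weights must lie in [0, 1]")
  }
  diag(D) <- 0
  dimnames(D) <- list(block_names, block_names)
  D
}
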