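#' Correlation-circle coordinates of selected features
#'
#' Each selected feature is placed at its correlations with the two
#' displayed latent components, so strongly contributing features lie near
#' the unit circle and features near the origin contribute little.
#'
#' @param model A `latent_model`.
#' @param block Block index or name.
#' @param comps Length-2 integer vector of component indices.
#' @return data.frame with `feature`, `block`, the two correlation
#'   coordinates `comp_x`/`comp_y`, and `selected_on` (first component the
#'   feature was selected on).
#' @export
correlation_circle <- function(model, block = 1L, comps = c(1L, 2L)) {
  X <- model$X[[block]]
  sc <- model$scores[[block]]
  sel <- selected_features(model, block = block)
  feats <- unique(unlist(sel[comps]))
  if (!length(feats)) stop("no selected features on the requested components")
  first_comp <- vapply(feats, function(f) {
    which(vapply(sel, function(s) f %in% s, logical(1)))[1L]
  }, numeric(1))
  cors <- stats::cor(X[, feats, drop = FALSE], sc[, comps, drop = FALSE])
  data.frame(feature = feats,
             block = model$block_names[if (is.numeric(block)) block else match(block, model$block_names)],
             comp_x = cors[, 1L], comp_y = cors[, 2L],
             selected_on = first_comp, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pairwise feature similarities via the latent components
#'
#' The similarity between two selected features is the inner product of
#' their correlations with the retained latent components (each feature is
#' correlated with its own block's components), the component-based proxy
#' used by relevance networks and circos plots. Edges with
#' `|similarity| > threshold` are returned.
#'
#' @param model A `latent_model`.
#' @param comps Components retained in the sum (default all).
#' @param threshold Absolute-similarity cutoff (default 0.7).
#' @param between_only Keep only edges joining different blocks.
#' @return data.frame of class `similarity_edges`: `feature_i`, `block_i`,
#'   `feature_j`, `block_j`, `similarity`, `sign`.
#' @export
feature_similarity <- function(model, comps = seq_len(model$ncomp),
                               threshold = 0.7, between_only = FALSE) {
  tags <- list()
  cors <- list()
  for (b in seq_along(model$block_names)) {
    sel <- unique(unlist(selected_features(model, block = b)[comps]))
    if (!length(sel)) next
    cc <- stats::cor(model$X[[b]][, sel, drop = FALSE],
                     model$scores[[b]][, comps, drop = FALSE])
    cors[[length(cors) + 1L]] <- cc
    tags[[length(tags) + 1L]] <- data.frame(feature = sel,
                                            block = model$block_names[b],
                                            stringsAsFactors = FALSE)
  }
  M <- do.call(rbind, cors)
  tag <- do.call(rbind, tags)
  S <- tcrossprod(M)
  n <- nrow(S)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  keep <- abs(S[idx]) > threshold
  if (between_only) keep <- keep & tag$block[idx[, 1L]] != tag$block[idx[, 2L]]
  idx <- idx[keep, , drop = FALSE]
  out <- data.frame(feature_i = tag$feature[idx[, 1L]],
                    block_i = tag$block[idx[, 1L]],
                    feature_j = tag$feature[idx[, 2L]],
                    block_j = tag$block[idx[, 2L]],
                    similarity = S[idx],
                    sign = ifelse(S[idx] >= 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  class(out) <- c("similarity_edges", "data.frame")
  out
}

#' Clustered image map backend
#'
#' Standardised values of the features selected up to `comp_depth`, with
#' hierarchical clusterings (Euclidean distance, complete linkage) of
#' samples and features and the corresponding leaf orders.
#'
#' @param model A `latent_model`.
#' @param comp_depth Components whose signatures are shown (default 1).
#' @param blocks Block indices/names to include (default all).
#' @return List: `matrix` (samples x selected features), `row_order`,
#'   `col_order`, `row_hclust`, `col_hclust`, `feature_block`.
#' @export
cim_data <- function(model, comp_depth = 1L, blocks = seq_along(model$block_names)) {
  mats <- list(); fb <- character(0)
  for (b in blocks) {
    sel <- unique(unlist(selected_features(model, block = b)[seq_len(comp_depth)]))
    if (!length(sel)) next
    mats[[length(mats) + 1L]] <- model$X[[b]][, sel, drop = FALSE]
    fb <- c(fb, rep(model$block_names[if (is.numeric(b)) b else match(b, model$block_names)],
                    length(sel)))
  }
  M <- do.call(cbind, mats)
  rh <- stats::hclust(stats::dist(M, method = "euclidean"), method = "complete")
  ch <- stats::hclust(stats::dist(t(M), method = "euclidean"), method = "complete")
  list(matrix = M, row_order = rh$order, col_order = ch$order,
       row_hclust = rh, col_hclust = ch, feature_block = fb)
}

#' Loading barplot backend
#'
#' Selected features of one component ordered by increasing absolute weight
#' (bottom-to-top of the pyramid barplot), each labelled with the class
#' whose mean (standardised) value is maximal -- or minimal -- for that
#' feature.
#'
#' @param model A discriminant `latent_model`.
#' @param comp Component index.
#' @param block Block index or name.
#' @param study Optional study name: means are computed within that study.
#' @param method `"max"` (default) or `"min"` class-mean labelling.
#' @return data.frame `feature`, `weight`, `class`, ordered by `|weight|`.
#' @export
loading_display <- function(model, comp = 1L, block = 1L, study = NULL,
                            method = c("max", "min")) {
  method <- match.arg(method)
  if (!model$is_da) stop("loading display labels require a discriminant model")
  sel <- selected_features(model, block = block)[[comp]]
  w <- model$loadings[[block]][sel, comp]
  X <- model$X[[block]][, sel, drop = FALSE]
  y <- model$outcome$y
  if (!is.null(study)) {
    keep <- model$study == study
    if (!any(keep)) stop("unknown study: ", study)
    X <- X[keep, , drop = FALSE]
    y <- droplevels(y[keep])
  }
  cls <- vapply(seq_along(sel), function(j) {
    m <- tapply(X[, j], y, mean)
    names(m)[if (method == "max") which.max(m) else which.min(m)]
  }, character(1))
  out <- data.frame(feature = sel, weight = w, class = cls,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(abs(out$weight)), , drop = FALSE]
}

#' Arrow plot backend
#'
#' Each sample is drawn from its position in the predictor latent space
#' (averaged over blocks for multi-block fits) to its position in the
#' outcome latent space. Both coordinate sets are scaled to unit variance
#' per component, so arrows shrink as the agreement between the predictor
#' and outcome representations grows.
#'
#' @param model A `latent_model`.
#' @param comps Length-2 components to display.
#' @return data.frame `sample`, `start_x`, `start_y`, `end_x`, `end_y`,
#'   `class` (discriminant models).
#' @export
arrow_data <- function(model, comps = c(1L, 2L)) {
  if (model$ncomp < max(comps)) stop("model has fewer components than requested")
  Tm <- Reduce(`+`, model$scores) / length(model$scores)
  U <- model$y_scores
  unit <- function(M) {
    sweep(M, 2L, pmax(apply(M, 2L, stats::sd), .Machine$double.eps), "/")
  }
  Ts <- unit(Tm[, comps, drop = FALSE])
  Us <- unit(U[, comps, drop = FALSE])
  data.frame(sample = rownames(model$scores[[1L]]),
             start_x = Ts[, 1L], start_y = Ts[, 2L],
             end_x = Us[, 1L], end_y = Us[, 2L],
             class = if (model$is_da) as.character(model$outcome$y) else NA_character_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sample plot backend
#'
#' Latent-score coordinates with class labels and 95% normal confidence
#' ellipses per class (bivariate normal contour from each class's mean and
#' covariance), optionally split by study.
#'
#' @param model A `latent_model`.
#' @param comps Length-2 components.
#' @param block Block index or name.
#' @param by_study Split the points by study (multi-group models).
#' @param level Ellipse coverage level (default 0.95).
#' @return List with `points` (data.frame `sample`, `x`, `y`, `class`,
#'   `study`) or a per-study list thereof, and `ellipses` (per class:
#'   `center`, `cov`, `radius`).
#' @export
sample_plot_data <- function(model, comps = c(1L, 2L), block = 1L,
                             by_study = FALSE, level = 0.95) {
  sc <- model$scores[[block]][, comps, drop = FALSE]
  pts <- data.frame(sample = rownames(sc), x = sc[, 1L], y = sc[, 2L],
                    class = if (model$is_da) as.character(model$outcome$y) else NA_character_,
                    study = if (is.null(model$study)) NA_character_ else as.character(model$study),
                    row.names = NULL, stringsAsFactors = FALSE)
  ellipses <- NULL
  if (model$is_da) {
    r <- sqrt(stats::qchisq(level, df = 2))
    ellipses <- lapply(split(seq_len(nrow(sc)), model$outcome$y), function(i) {
      list(center = colMeans(sc[i, , drop = FALSE]),
           cov = stats::cov(sc[i, , drop = FALSE]),
           radius = r, level = level)
    })
  }
  if (by_study) {
    if (is.null(model$study)) stop("model has no study information")
    pts <- split(pts, pts$study)
  }
  list(points = pts, ellipses = ellipses)
}

#' Export similarity edges as a GML graph
#'
#' @param edges A `similarity_edges` data.frame from [feature_similarity()].
#' @param path Output file path (GML format).
#' @return The igraph object, invisibly.
#' @export
export_gml <- function(edges, path) {
  nodes <- unique(data.frame(
    name = c(edges$feature_i, edges$feature_j),
    block = c(edges$block_i, edges$block_j),
    stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(
    edges[, c("feature_i", "feature_j", "similarity", "sign")],
    directed = FALSE, vertices = nodes)
  igraph::write_graph(g, path, format = "gml")
  invisible(g)
}
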