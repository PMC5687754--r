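#' Configuration for the synthetic multi-omics generators
#'
#' The generators plant class-discriminative mean shifts on a subset of
#' features, optional cross-block correlation through shared latent factors,
#' and optional per-study batch effects, on top of unit-variance noise --
#' the structure the supervised projection methods assume.
#'
#' Class-mean profiles are built on an orthonormal basis of class contrasts
#' (scaled to unit maximum offset) with geometrically decaying weights
#' (1, 0.5, 0.25, ...): every informative feature carries the full primary
#' contrast (random sign) plus weaker higher-order contrasts, so all K
#' classes are mutually separated while a dominant discriminative axis
#' exists. `effect` is the largest class offset along the primary contrast,
#' in noise-sd units.
#'
#' @param n_per_class Samples per class (scalar or length-K vector). For
#'   multi-study generation this is per class per study.
#' @param p Features per block (vector of length B for multi-block data).
#' @param K Number of classes.
#' @param n_informative Informative features (per block).
#' @param effect Mean-shift amplitude in noise-sd units.
#' @param shared_strength Strength of the cross-block shared latent factors
#'   (multi-block); the factor loading is `2.2 * shared_strength`, scaled so
#'   strength 1 yields cross-block correlations around 0.7-0.75 among paired
#'   informative features.
#' @param n_factors Number of shared latent factors.
#' @param m_studies Number of studies (multi-study generation).
#' @param batch_offset_sd Sd of the per-study, per-feature additive offsets.
#' @param batch_scale_sd Sd (log scale) of per-study multiplicative factors.
#' @param missing_rate Fraction of cells set missing, in `[0, 1)`.
#' @param noise `"gaussian"` (default) or `"t3"` (heavy-tailed, t with 3 df
#'   scaled to unit variance).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_class = 20L, p = 500L, K = 3L, n_informative = 20L,
                       effect = 1.5, shared_strength = 1, n_factors = 2L,
                       m_studies = 4L, batch_offset_sd = 2, batch_scale_sd = 0.2,
                       missing_rate = 0, noise = c("gaussian", "t3"), seed = 1L) {
  noise <- match.arg(noise)
  if (K < 2L) stop("K must be >= 2")
  if (any(p < 1L) || any(n_per_class < 1L)) stop("counts must be positive")
  if (any(n_informative > p)) stop("n_informative must be <= p")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  structure(list(n_per_class = as.integer(n_per_class), p = as.integer(p),
                 K = as.integer(K), n_informative = as.integer(n_informative),
                 effect = effect, shared_strength = shared_strength,
                 n_factors = as.integer(n_factors), m_studies = as.integer(m_studies),
                 batch_offset_sd = batch_offset_sd, batch_scale_sd = batch_scale_sd,
                 missing_rate = missing_rate, noise = noise, seed = as.integer(seed)),
            class = "sim_config")
}

# orthonormal class contrasts scaled to unit maximum absolute offset
class_contrasts <- function(K) {
  Cm <- stats::contr.helmert(K)
  Cm <- sweep(Cm, 2L, apply(abs(Cm), 2L, max), "/")
  Cm
}

rnoise <- function(n, noise) {
  if (noise == "t3") stats::rt(n, df = 3) / sqrt(3) else stats::rnorm(n)
}

# class-mean matrix (K x n_informative) for one block
make_class_means <- function(K, n_inf, effect) {
  Cm <- class_contrasts(K)
  M <- max(1L, min(K - 1L, 3L))
  lambda <- 0.5^(seq_len(M) - 1L)
  mu <- matrix(0, K, n_inf)
  for (m in seq_len(M)) {
    s <- sample(c(-1, 1), n_inf, replace = TRUE)
    mu <- mu + effect * lambda[m] * outer(Cm[, m], s)
  }
  mu
}

#' Generate one synthetic omics block with planted discriminative features
#'
#' @param cfg A [sim_config()].
#' @return List: `X` (N x P matrix with ids), `y` (factor), `truth` (list
#'   with `informative` ids, `informative_idx`, `class_means`).
#' @export
gen_single <- function(cfg) {
  set.seed(cfg$seed)
  out <- gen_block_set(cfg, B = 1L)
  X <- out$blocks[[1L]]
  if (cfg$missing_rate > 0) {
    X <- inject_missing(X, cfg$missing_rate, seed = cfg$seed + 1L)
  }
  list(X = X, y = out$y, truth = out$truth[[1L]])
}

#' Generate multiple blocks with cross-block correlated informative features
#'
#' Shared latent factors load on paired informative features across blocks
#' (pairing by rank within each block's informative set), inducing the
#' cross-block correlation structure that N-integration exploits; class-mean
#' sign patterns are drawn independently per block.
#'
#' @param cfg A [sim_config()] whose `p` and `n_informative` may be vectors
#'   (one entry per block).
#' @return List: `blocks` (named list of matrices), `y`, `truth` (per
#'   block).
#' @export
gen_multiblock <- function(cfg) {
  set.seed(cfg$seed)
  B <- length(cfg$p)
  out <- gen_block_set(cfg, B = B)
  list(blocks = out$blocks, y = out$y, truth = out$truth)
}

gen_block_set <- function(cfg, B) {
  K <- cfg$K
  npc <- rep(cfg$n_per_class, length.out = K)
  N <- sum(npc)
  y <- factor(rep(paste0("class", seq_len(K)), npc))
  p <- rep(cfg$p, length.out = B)
  n_inf <- rep(cfg$n_informative, length.out = B)
  Z <- matrix(stats::rnorm(N * cfg$n_factors), N, cfg$n_factors)
  gamma <- 2.2 * cfg$shared_strength
  blocks <- truth <- vector("list", B)
  for (b in seq_len(B)) {
    X <- matrix(rnoise(N * p[b], cfg$noise), N, p[b])
    inf_idx <- sort(sample.int(p[b], n_inf[b]))
    mu <- make_class_means(K, n_inf[b], cfg$effect)
    X[, inf_idx] <- X[, inf_idx] + mu[as.integer(y), , drop = FALSE]
    if (B > 1L && gamma > 0 && cfg$n_factors > 0L) {
      fac <- ((seq_len(n_inf[b]) - 1L) %% cfg$n_factors) + 1L
      sgn <- rep(1, n_inf[b])  # shared-factor loading sign fixed across blocks
      X[, inf_idx] <- X[, inf_idx] + sweep(Z[, fac, drop = FALSE], 2L, gamma * sgn, "*")
    }
    dimnames(X) <- list(paste0("sample", seq_len(N)),
                        sprintf("b%d_feature%d", b, seq_len(p[b])))
    blocks[[b]] <- X
    truth[[b]] <- list(informative = colnames(X)[inf_idx],
                       informative_idx = inf_idx, class_means = mu,
                       factor = if (B > 1L) ((seq_len(n_inf[b]) - 1L) %% max(cfg$n_factors, 1L)) + 1L else NULL)
  }
  names(blocks) <- names(truth) <- paste0("block", seq_len(B))
  list(blocks = blocks, y = y, truth = truth)
}

#' Generate multi-study data with batch effects
#'
#' The class signal (informative features and class means) is identical in
#' every study; each study applies its own per-feature multiplicative factor
#' and additive offset to all features, emulating between-study batch
#' effects.
#'
#' @param cfg A [sim_config()]; `m_studies`, `batch_offset_sd`,
#'   `batch_scale_sd` control the studies.
#' @return List: `X`, `y`, `study` (factor), `truth`.
#' @export
gen_multistudy <- function(cfg) {
  set.seed(cfg$seed)
  K <- cfg$K
  M <- cfg$m_studies
  npc <- rep(cfg$n_per_class, length.out = K)
  n_study <- sum(npc)
  N <- n_study * M
  y <- factor(rep(rep(paste0("class", seq_len(K)), npc), M))
  study <- factor(rep(paste0("study", seq_len(M)), each = n_study))
  P <- cfg$p[1L]
  n_inf <- cfg$n_informative[1L]
  X <- matrix(rnoise(N * P, cfg$noise), N, P)
  inf_idx <- sort(sample.int(P, n_inf))
  mu <- make_class_means(K, n_inf, cfg$effect)
  X[, inf_idx] <- X[, inf_idx] + mu[as.integer(y), , drop = FALSE]
  for (s in seq_len(M)) {
    idx <- which(study == levels(study)[s])
    scl <- exp(stats::rnorm(P, 0, cfg$batch_scale_sd))
    off <- stats::rnorm(P, 0, cfg$batch_offset_sd)
    X[idx, ] <- sweep(sweep(X[idx, , drop = FALSE], 2L, scl, "*"), 2L, off, "+")
  }
  dimnames(X) <- list(paste0("sample", seq_len(N)), paste0("feature", seq_len(P)))
  list(X = X, y = y, study = study,
       truth = list(informative = colnames(X)[inf_idx], informative_idx = inf_idx,
                    class_means = mu))
}

#' Set a fraction of cells missing, avoiding empty rows/columns
#'
#' @param X Numeric matrix.
#' @param rate Fraction of cells to set `NA`, in `[0, 1)`.
#' @param seed Integer seed.
#' @return Matrix with `floor(rate * length(X))` missing cells (a cell is
#'   kept observed when masking it would empty its row or column).
#' @export
inject_missing <- function(X, rate, seed = 1L) {
  if (rate == 0) return(X)
  set.seed(as.integer(seed))
  n_miss <- floor(rate * length(X))
  cells <- sample.int(length(X), n_miss)
  M <- X
  M[cells] <- NA
  # guard: restore cells in all-missing rows/columns
  bad_col <- which(colSums(!is.na(M)) == 0L)
  for (j in bad_col) {
    i <- sample.int(nrow(M), 1L)
    M[i, j] <- X[i, j]
  }
  bad_row <- which(rowSums(!is.na(M)) == 0L)
  for (i in bad_row) {
    j <- sample.int(ncol(M), 1L)
    M[i, j] <- X[i, j]
  }
  M
}

#' Preset generator configurations shaped like classic benchmark studies
#'
#' * `"srbct-like"`: 63 samples in 4 unbalanced classes (8/23/12/20),
#'   2,308 features -- a single-block microarray shape;
#' * `"tcga-like"`: 150 samples, 3 classes (75/30/45), three blocks of
#'   200/184/142 features -- a multi-omics shape;
#' * `"stemcells-like"`: 4 studies of ~31 samples, 3 classes, 400 features
#'   -- a multi-study shape.
#'
#' @param preset Preset name.
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
preset_config <- function(preset = c("srbct-like", "tcga-like", "stemcells-like"),
                          seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    "srbct-like" = sim_config(n_per_class = c(8L, 23L, 12L, 20L), p = 2308L,
                              K = 4L, n_informative = 60L, effect = 1.5,
                              seed = seed),
    "tcga-like" = sim_config(n_per_class = c(75L, 30L, 45L), p = c(200L, 184L, 142L),
                             K = 3L, n_informative = c(20L, 20L, 15L),
                             effect = 1.5, shared_strength = 1, seed = seed),
    "stemcells-like" = sim_config(n_per_class = c(10L, 10L, 11L), p = 400L, K = 3L,
                                  n_informative = 30L, effect = 1.5,
                                  m_studies = 4L, seed = seed)
  )
}
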