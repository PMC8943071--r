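# linear-interpolation weight matrix mapping a length-nz profile to length
# target (rows sum to 1); applied as profiles %*% t(W) for whole cubes
resample_weights <- function(nz, target) {
  if (nz == 1L) return(matrix(1, target, 1L))
  xout <- seq(1, nz, length.out = target)
  lo <- pmin(floor(xout), nz - 1L)
  frac <- xout - lo
  W <- matrix(0, target, nz)
  W[cbind(seq_len(target), lo)] <- 1 - frac
  W[cbind(seq_len(target), lo + 1L)] <- W[cbind(seq_len(target), lo + 1L)] + frac
  W
}

#' Unfold reflectivity cubes into a point-by-depth matrix
#'
#' Stage-1 unfolding of the 3D-PCA: every lateral point `(i, j)` of every
#' lesion contributes one row holding its depth profile, resampled to a
#' common length so that cubes truncated at different penetration depths
#' align.
#'
#' @param cubes List of `reflectivity_cube`s sharing one lateral shape.
#' @param target_depth_samples Common depth length after linear resampling.
#' @return List with `matrix` (`(lesions * lateral points) x depth`) and
#'   `index` (data frame mapping each row to `lesion`, `i`, `j`).
#' @export
unfold_cubes <- function(cubes, target_depth_samples = 20L) {
  stopifnot(length(cubes) >= 1L, target_depth_samples >= 2L)
  dims <- lapply(cubes, function(cb) dim(cb$values))
  lat <- dims[[1]][1:2]
  if (!all(vapply(dims, function(d) all(d[1:2] == lat), logical(1))))
    stop("all cubes must share the same lateral shape")
  n_pts <- prod(lat)
  wcache <- list()
  rows <- vector("list", length(cubes))
  for (l in seq_along(cubes)) {
    v <- cubes[[l]]$values
    nz <- dim(v)[3]
    key <- as.character(nz)
    if (is.null(wcache[[key]]))
      wcache[[key]] <- resample_weights(nz, target_depth_samples)
    # rows of the per-cube block are lateral points in column-major order
    profiles <- matrix(aperm(v, c(3L, 1L, 2L)), nrow = nz)
    rows[[l]] <- t(wcache[[key]] %*% profiles)
  }
  index <- data.frame(
    lesion = rep(seq_along(cubes), each = n_pts),
    i = rep(rep(seq_len(lat[1]), times = lat[2]), length(cubes)),
    j = rep(rep(seq_len(lat[2]), each = lat[1]), length(cubes))
  )
  list(matrix = do.call(rbind, rows), index = index, lateral = lat)
}

#' Refold an unfolded matrix back into cubes
#'
#' Inverse of [unfold_cubes()] via its index map (for cubes whose depth
#' already equals the target length the round trip is exact).
#'
#' @param unfolded Result of [unfold_cubes()].
#' @param depth_pitch_mm Depth pitch to stamp on the rebuilt cubes.
#' @return List of `reflectivity_cube`s.
#' @export
refold_cubes <- function(unfolded, depth_pitch_mm = 1) {
  lat <- unfolded$lateral
  nz <- ncol(unfolded$matrix)
  lapply(unique(unfolded$index$lesion), function(l) {
    sel <- unfolded$index$lesion == l
    v <- array(0, dim = c(lat[1], lat[2], nz))
    rows <- which(sel)
    for (r in seq_along(rows)) {
      i <- unfolded$index$i[rows[r]]
      j <- unfolded$index$j[rows[r]]
      v[i, j, ] <- unfolded$matrix[rows[r], ]
    }
    structure(list(values = v, lateral_pitch_mm = 1,
                   depth_pitch_mm = depth_pitch_mm, settings = list()),
              class = "reflectivity_cube")
  })
}

#' Fit a principal component analysis by singular value decomposition
#'
#' Column-mean-centers the matrix and takes the SVD; the explained-variance
#' ratios are the normalized squared singular values, ordered from highest
#' to lowest. For determinism across platforms each loading column is
#' sign-fixed so that its largest-magnitude element is positive.
#'
#' @param x Numeric matrix (>= 2 rows) with variables in columns.
#' @return Object of class `pca_model`: `mean`, `loadings` (variables x
#'   components, orthonormal columns), `ratios` (nonincreasing, summing
#'   to <= 1), `scores` of the training rows.
#' @export
fit_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  total <- sum(xc^2)
  if (total <= .Machine$double.eps * length(xc))
    stop("matrix has zero variance; PCA undefined")
  sv <- svd(xc)
  # deterministic sign: largest |loading| element positive per column
  flip <- vapply(seq_len(ncol(sv$v)), function(k) {
    col <- sv$v[, k]
    sign(col[which.max(abs(col))]) < 0
  }, logical(1))
  v <- sv$v
  v[, flip] <- -v[, flip]
  u <- sv$u
  u[, flip] <- -u[, flip]
  structure(
    list(mean = mu, loadings = v, ratios = sv$d^2 / sum(sv$d^2),
         scores = u %*% diag(sv$d, length(sv$d))),
    class = "pca_model"
  )
}

#' Number of components needed to exceed an explained-variance threshold
#'
#' The smallest `k` whose first `k` explained-variance ratios sum to a value
#' strictly greater than `threshold` (the variance-explained criterion; 80%
#' by default).
#'
#' @param model A `pca_model`, or a numeric vector of ratios.
#' @param threshold Cumulative-ratio threshold in (0, 1).
#' @return Integer `k >= 1`.
#' @export
select_components <- function(model, threshold = 0.80) {
  stopifnot(threshold > 0, threshold < 1)
  ratios <- if (inherits(model, "pca_model")) model$ratios else model
  cum <- cumsum(ratios)
  k <- which(cum > threshold)
  if (length(k) == 0L) length(ratios) else k[1]
}

# project rows onto a fitted model's first k components
pca_scores <- function(model, x, k) {
  sweep(as.matrix(x), 2L, model$mean) %*% model$loadings[, seq_len(k), drop = FALSE]
}

#' Extract per-lesion features by two-stage 3D-PCA
#'
#' Stage 1 fits a PCA on the unfolded point-by-depth matrix and retains the
#' `k1` depth modes selected by the explained-variance criterion; each
#' lesion's per-point stage-1 scores are concatenated into a single row.
#' Stage 2 fits a PCA across lesions on those rows and retains `k_final`
#' components, giving one `k_final`-dimensional feature vector per lesion.
#' A one-stage variant (`scheme = "flat"`) applies a single PCA to fully
#' flattened cubes for comparison.
#'
#' @param cubes List of `reflectivity_cube`s (>= 3).
#' @param k_final Number of final feature components.
#' @param threshold Explained-variance threshold for the stage-1 selection.
#' @param target_depth_samples Common depth length for unfolding.
#' @param scheme `"two_stage"` (default) or `"flat"`.
#' @return Object of class `pca3d_model` with the fitted stage models and
#'   `features` (`lesions x k_final` score matrix).
#' @export
extract_features <- function(cubes, k_final = 6L, threshold = 0.80,
                             target_depth_samples = 20L,
                             scheme = c("two_stage", "flat")) {
  scheme <- match.arg(scheme)
  stopifnot(length(cubes) >= 3L, k_final >= 1L)
  unf <- unfold_cubes(cubes, target_depth_samples)
  n_pts <- prod(unf$lateral)
  if (scheme == "flat") {
    flat <- t(vapply(seq_along(cubes), function(l) {
      as.vector(unf$matrix[unf$index$lesion == l, ])
    }, numeric(n_pts * ncol(unf$matrix))))
    m2 <- fit_pca(flat)
    rank2 <- sum(m2$ratios > 1e-12)
    if (k_final > rank2)
      stop(sprintf("k_final = %d exceeds available rank %d", k_final, rank2))
    feats <- m2$scores[, seq_len(k_final), drop = FALSE]
    return(structure(list(scheme = scheme, stage2 = m2, k_final = k_final,
                          target_depth_samples = target_depth_samples,
                          lateral = unf$lateral, features = feats),
                     class = "pca3d_model"))
  }
  m1 <- fit_pca(unf$matrix)
  k1 <- select_components(m1, threshold)
  s1 <- pca_scores(m1, unf$matrix, k1)
  rows <- t(vapply(seq_along(cubes), function(l) {
    as.vector(t(s1[unf$index$lesion == l, , drop = FALSE]))
  }, numeric(n_pts * k1)))
  m2 <- fit_pca(rows)
  rank2 <- sum(m2$ratios > 1e-12)
  if (k_final > rank2)
    stop(sprintf("k_final = %d exceeds available rank %d", k_final, rank2))
  feats <- m2$scores[, seq_len(k_final), drop = FALSE]
  structure(
    list(scheme = scheme, stage1 = m1, k1 = k1, stage2 = m2,
         k_final = k_final, target_depth_samples = target_depth_samples,
         lateral = unf$lateral, features = feats),
    class = "pca3d_model"
  )
}

#' Project new cubes onto a fitted 3D-PCA model
#'
#' Applies the training means and loadings only (never refits), exactly as
#' held-out lesions are scored during cross-validation.
#'
#' @param model A `pca3d_model` from [extract_features()].
#' @param cubes List of new `reflectivity_cube`s with the training lateral
#'   shape.
#' @return Feature matrix (`length(cubes) x k_final`).
#' @export
project_features <- function(model, cubes) {
  stopifnot(inherits(model, "pca3d_model"))
  unf <- unfold_cubes(cubes, model$target_depth_samples)
  if (!all(unf$lateral == model$lateral))
    stop("cube lateral shape does not match the fitted model")
  n_pts <- prod(unf$lateral)
  if (model$scheme == "flat") {
    flat <- t(vapply(seq_along(cubes), function(l) {
      as.vector(unf$matrix[unf$index$lesion == l, ])
    }, numeric(n_pts * ncol(unf$matrix))))
    return(pca_scores(model$stage2, flat, model$k_final))
  }
  s1 <- pca_scores(model$stage1, unf$matrix, model$k1)
  rows <- t(vapply(seq_along(cubes), function(l) {
    as.vector(t(s1[unf$index$lesion == l, , drop = FALSE]))
  }, numeric(n_pts * model$k1)))
  pca_scores(model$stage2, rows, model$k_final)
}
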