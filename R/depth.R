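# the n_columns depth columns nearest a lateral spot, deterministic order
region_columns <- function(cube, spot, n_columns) {
  dims <- dim(cube$values)
  if (spot[1] < 1 || spot[1] > dims[1] || spot[2] < 1 || spot[2] > dims[2])
    stop("spot lies outside the cube's lateral extent")
  total <- dims[1] * dims[2]
  if (total < n_columns)
    stop(sprintf("only %d depth columns available, %d required (deficit %d)",
                 total, n_columns, n_columns - total))
  ij <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]))
  d2 <- (ij$i - spot[1])^2 + (ij$j - spot[2])^2
  sel <- order(d2, ij$i, ij$j)[seq_len(n_columns)]
  # depth x n_columns matrix of reflectivity profiles
  vapply(sel, function(s) cube$values[ij$i[s], ij$j[s], ],
         numeric(dims[3]))
}

# depth of one region: mean profile over the columns, thresholded at its own
# depth-mean; depth = deepest sample down to which the profile stays >= T
region_depth <- function(cols, depth_pitch_mm, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  p <- if (aggregate == "mean") rowMeans(cols) else rowSums(cols)
  thr <- mean(p)
  below <- which(p < thr)
  n_keep <- if (length(below) == 0L) length(p) else below[1] - 1L
  list(depth_mm = n_keep * depth_pitch_mm, threshold = thr, profile = p)
}

#' Estimate usable penetration depth of a reflectivity cube
#'
#' Two-region thresholding: around a central and a marginal lateral spot,
#' the `n_columns` nearest depth columns are aggregated into a mean depth
#' profile; the profile's own depth-average serves as the threshold, and the
#' region depth is the deepest point down to which the profile stays at or
#' above that threshold. The two region depths are averaged. Because the
#' threshold is derived from the same values, the estimate is invariant to
#' scaling the cube by a positive constant, and a constant cube keeps its
#' full depth.
#'
#' @param cube A `reflectivity_cube`.
#' @param center_spot,margin_spot Lateral indices `c(i, j)` of the lesion
#'   center and margin regions.
#' @param n_columns Number of depth columns per region.
#' @param aggregate Aggregate the columns by per-depth `"mean"` (default) or
#'   `"sum"`; the two give identical depths since the threshold scales with
#'   the profile, and both are kept for transparency.
#' @return Object of class `depth_estimate` with `center_mm`, `margin_mm`,
#'   `depth_mm` (their mean), thresholds, and the profiles.
#' @export
estimate_depth <- function(cube, center_spot, margin_spot, n_columns = 30L,
                           aggregate = c("mean", "sum")) {
  stopifnot(inherits(cube, "reflectivity_cube"))
  ctr <- region_depth(region_columns(cube, center_spot, n_columns),
                      cube$depth_pitch_mm, aggregate)
  mar <- region_depth(region_columns(cube, margin_spot, n_columns),
                      cube$depth_pitch_mm, aggregate)
  structure(
    list(center_mm = ctr$depth_mm, margin_mm = mar$depth_mm,
         depth_mm = (ctr$depth_mm + mar$depth_mm) / 2,
         thresholds = c(center = ctr$threshold, margin = mar$threshold),
         profiles = list(center = ctr$profile, margin = mar$profile),
         depth_pitch_mm = cube$depth_pitch_mm),
    class = "depth_estimate"
  )
}

#' Truncate a cube at its estimated penetration depth
#'
#' Crops the depth axis at the averaged penetration depth (rounded up to
#' whole samples); at least one depth sample is always retained.
#'
#' @param cube A `reflectivity_cube`.
#' @param estimate A [estimate_depth()] result for the same cube (or a depth
#'   in mm).
#' @return The cropped `reflectivity_cube`.
#' @export
truncate_to_depth <- function(cube, estimate) {
  stopifnot(inherits(cube, "reflectivity_cube"))
  depth_mm <- if (inherits(estimate, "depth_estimate")) estimate$depth_mm
              else as.numeric(estimate)
  nz <- dim(cube$values)[3]
  n_keep <- ceiling(depth_mm / cube$depth_pitch_mm - 1e-9)
  if (n_keep < 1L) {
    warning("zero penetration depth; retaining a single depth slice")
    n_keep <- 1L
  }
  n_keep <- min(n_keep, nz)
  cube$values <- cube$values[, , seq_len(n_keep), drop = FALSE]
  cube
}

#' Default depth-estimation spots for a lesion scan
#'
#' Center spot at the lateral index nearest the lesion center; margin spot
#' at the lesion boundary along x (clamped to the cube).
#'
#' @param ds A `scan_dataset` with lesion metadata.
#' @return List with `center` and `margin` index pairs.
#' @export
default_spots <- function(ds) {
  geom <- ds$geometry
  les <- ds$meta$lesion
  ctr_xy <- if (is.null(les)) c(0, 0) else les$center_mm
  to_idx <- function(x, n) {
    min(max(round(x / geom$increment_mm + (n + 1) / 2), 1L), n)
  }
  center <- c(to_idx(ctr_xy[1], geom$m), to_idx(ctr_xy[2], geom$n))
  mar_x <- ctr_xy[1] + if (is.null(les)) geom$increment_mm else les$radius_mm
  margin <- c(to_idx(mar_x, geom$m), to_idx(ctr_xy[2], geom$n))
  list(center = center, margin = margin)
}
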