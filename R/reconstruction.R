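# spectral window applied before focusing
spectral_window <- function(nf, window = c("hann", "none")) {
  window <- match.arg(window)
  if (window == "none") rep(1, nf)
  else 0.5 - 0.5 * cos(2 * pi * (seq_len(nf) - 1) / (nf - 1))
}

# assemble the nf x np spectrum matrix and aperture coordinates from a list
# of uwb_signals carrying (row, col) positions
signal_matrix <- function(signals, geometry) {
  if (length(signals) == 0L) stop("no signals supplied")
  freq <- signals[[1]]$freq_ghz
  if (any(diff(freq) <= 0)) stop("frequencies must be strictly increasing")
  S <- vapply(signals, function(s) {
    if (length(s$s11) != length(freq) ||
        any(abs(s$freq_ghz - freq) > 1e-9))
      stop("all signals must share one frequency grid")
    s$s11
  }, complex(length(freq)))
  pos <- t(vapply(signals, function(s) as.numeric(s$position), numeric(2)))
  inc <- geometry$increment_mm
  xy <- cbind((pos[, 1] - (geometry$m + 1) / 2) * inc,
              (pos[, 2] - (geometry$n + 1) / 2) * inc)
  list(freq = freq, S = matrix(S, nrow = length(freq)), pos = pos, xy = xy)
}

# two-segment straight-ray path lengths from each antenna to each voxel:
# antenna at (x, y, -standoff), voxel at (xv, yv, z >= 0); the ray is split
# proportionally into its free-space and in-tissue parts
path_lengths <- function(xy, standoff_mm, vox_xy, vox_z) {
  np <- nrow(xy); nv <- nrow(vox_xy) * length(vox_z)
  d_air <- matrix(0, np, nv)
  d_tiss <- matrix(0, np, nv)
  nv_lat <- nrow(vox_xy)
  for (iz in seq_along(vox_z)) {
    z <- vox_z[iz]
    cols <- (iz - 1L) * nv_lat + seq_len(nv_lat)
    dx <- outer(xy[, 1], vox_xy[, 1], "-")
    dy <- outer(xy[, 2], vox_xy[, 2], "-")
    L <- sqrt(dx^2 + dy^2 + (standoff_mm + z)^2)
    if (standoff_mm + z > 0) {
      d_air[, cols] <- L * (standoff_mm / (standoff_mm + z))
      d_tiss[, cols] <- L * (z / (standoff_mm + z))
    }
  }
  list(d_air = d_air, d_tiss = d_tiss)
}

# collapse (position, voxel) path pairs to a unique table plus index map
unique_paths <- function(paths) {
  key <- paste(signif(paths$d_air, 12), signif(paths$d_tiss, 12))
  uq <- !duplicated(key)
  uidx <- match(key, key[uq])
  list(d_air_u = paths$d_air[uq], d_tiss_u = paths$d_tiss[uq],
       uidx = matrix(uidx, nrow = nrow(paths$d_air)))
}

# default depth pitch: half the range resolution c/(2 B sqrt(eps')), i.e.
# 2x oversampling of the point response
default_depth_pitch <- function(freq, eps_real_mid) {
  bw <- freq[length(freq)] - freq[1]
  C_MM_GHZ / (4 * bw * sqrt(eps_real_mid))
}

#' Reconstruct a 3-D reflectivity cube by dispersive back-propagation
#'
#' Frequency-domain matched-filter focusing: each voxel accumulates
#' `sum_p sum_f S(f, p) exp(+2 i k(f) d(p, v))` over the aperture, where the
#' wavenumber is the free-space `k0 = 2 pi f / c` along the standoff segment
#' and the complex, dispersive `k(f) = 2 pi f sqrt(eps(f)) / c` of `medium`
#' inside the tissue. The output voxel value is the accumulated magnitude.
#' Lateral voxels sit at the scan positions; depth samples start at the skin
#' surface.
#'
#' @param signals List of `uwb_signal`s over the aperture (calibrated, so the
#'   standoff phase has been removed; see `standoff_mm`).
#' @param medium [debye_medium()] used for in-tissue propagation.
#' @param geometry The [scan_geometry()] of the aperture.
#' @param depth_samples Number of depth samples (>= 2).
#' @param depth_pitch_mm Depth pitch; default `c / (4 B sqrt(eps'))`, twice
#'   oversampled relative to the range resolution of bandwidth `B`.
#' @param window Spectral window before accumulation (`"hann"` suppresses
#'   range sidelobes; `"none"` preserves the closed-form point response).
#' @param standoff_mm Residual free-space path between the signal reference
#'   plane and the surface; 0 for metal-plate-calibrated signals.
#' @param attenuation_compensation If `TRUE`, the imaginary part of the
#'   tissue wavenumber enters the focusing exponent, so deep voxels receive
#'   exponential gain that offsets tissue loss. Off by default: at
#'   millimeter-wave skin attenuation the gain amplifies deep noise and
#'   clutter faster than signal, so phase-only focusing (real part of `k`)
#'   yields the physically expected reflectivity decay with depth.
#' @return Object of class `reflectivity_cube`: nonnegative `values` array
#'   `(m, n, depth)`, `lateral_pitch_mm`, `depth_pitch_mm`, settings.
#' @export
reconstruct_cube <- function(signals, medium, geometry = scan_geometry(),
                             depth_samples = 20L, depth_pitch_mm = NULL,
                             window = c("hann", "none"), standoff_mm = 0,
                             attenuation_compensation = FALSE) {
  stopifnot(inherits(medium, "debye_medium"), depth_samples >= 2L)
  sm <- signal_matrix(signals, geometry)
  eps <- debye_permittivity(medium, sm$freq)
  n_idx <- refractive_index(eps)
  k0 <- 2 * pi * sm$freq / C_MM_GHZ
  kt <- k0 * n_idx
  mid <- Re(eps[ceiling(length(eps) / 2)])
  if (is.null(depth_pitch_mm)) depth_pitch_mm <- default_depth_pitch(sm$freq, mid)
  stopifnot(depth_pitch_mm > 0)

  inc <- geometry$increment_mm
  vox_xy <- as.matrix(position_coords(geometry)[, c("x_mm", "y_mm")])
  vox_z <- (seq_len(depth_samples) - 0.5) * depth_pitch_mm
  paths <- path_lengths(sm$xy, standoff_mm, vox_xy, vox_z)

  w <- spectral_window(length(sm$freq), window)
  Sw <- sm$S * w
  kt_im <- if (attenuation_compensation) Im(kt) else numeric(length(kt))
  up <- unique_paths(paths)
  acc <- backproject_cpp(Sw, k0, Re(kt), kt_im, up$d_air_u, up$d_tiss_u,
                         up$uidx)
  vals <- array(Mod(acc) / (length(sm$freq) * ncol(sm$S)),
                dim = c(geometry$m, geometry$n, depth_samples))
  structure(
    list(values = vals, lateral_pitch_mm = inc,
         depth_pitch_mm = depth_pitch_mm,
         settings = list(window = match.arg(window),
                         standoff_mm = standoff_mm,
                         bandwidth_ghz = sm$freq[length(sm$freq)] - sm$freq[1],
                         eps_mid = mid)),
    class = "reflectivity_cube"
  )
}

#' Delay-and-sum reference reconstruction
#'
#' Independent time-domain implementation used to cross-check
#' [reconstruct_cube()]: each spectrum is transformed to a finely sampled
#' complex time trace by direct inverse discrete Fourier transform, then
#' time-shifted to every voxel's two-way delay (constant real permittivity
#' `epsilon`) with linear interpolation and summed over the aperture.
#'
#' @param signals List of `uwb_signal`s over the aperture.
#' @param epsilon Constant real relative permittivity of the medium (>= 1).
#' @param geometry Scan geometry.
#' @param depth_samples,depth_pitch_mm,window,standoff_mm As in
#'   [reconstruct_cube()].
#' @return A `reflectivity_cube`.
#' @export
das_reference <- function(signals, epsilon = 1, geometry = scan_geometry(),
                          depth_samples = 20L, depth_pitch_mm = NULL,
                          window = c("hann", "none"), standoff_mm = 0) {
  stopifnot(epsilon >= 1, depth_samples >= 2L)
  sm <- signal_matrix(signals, geometry)
  if (is.null(depth_pitch_mm))
    depth_pitch_mm <- default_depth_pitch(sm$freq, epsilon)
  vox_xy <- as.matrix(position_coords(geometry)[, c("x_mm", "y_mm")])
  vox_z <- (seq_len(depth_samples) - 0.5) * depth_pitch_mm
  paths <- path_lengths(sm$xy, standoff_mm, vox_xy, vox_z)
  # two-way delay in ns
  v_tiss <- C_MM_GHZ / sqrt(epsilon)
  tau <- 2 * (paths$d_air / C_MM_GHZ + paths$d_tiss / v_tiss)

  w <- spectral_window(length(sm$freq), window)
  Sw <- sm$S * w
  fmax <- sm$freq[length(sm$freq)]
  dt <- 1 / (8 * fmax)
  tgrid <- seq(0, max(tau) * 1.05 + 4 * dt, by = dt)
  # direct inverse DFT onto the fine time grid (handles non-uniform grids)
  E <- exp(2i * pi * outer(tgrid, sm$freq))
  traces <- (E %*% Sw) / length(sm$freq)    # nt x np

  np <- ncol(Sw); nv <- ncol(tau)
  acc <- complex(nv)
  for (p in seq_len(np)) {
    re <- approx(tgrid, Re(traces[, p]), xout = tau[p, ], rule = 2)$y
    im <- approx(tgrid, Im(traces[, p]), xout = tau[p, ], rule = 2)$y
    acc <- acc + complex(real = re, imaginary = im)
  }
  vals <- array(Mod(acc) / np,
                dim = c(geometry$m, geometry$n, depth_samples))
  structure(
    list(values = vals, lateral_pitch_mm = geometry$increment_mm,
         depth_pitch_mm = depth_pitch_mm,
         settings = list(window = match.arg(window),
                         standoff_mm = standoff_mm, epsilon = epsilon)),
    class = "reflectivity_cube"
  )
}

#' Ideal point-scatterer aperture signals
#'
#' Synthetic monostatic response of a single isotropic point scatterer for
#' reconstruction tests: `S(f, p) = A exp(-2 i k R_p)` with `R_p` the
#' antenna-to-target distance in a homogeneous medium of permittivity
#' `epsilon`.
#'
#' @param geometry Scan geometry giving the aperture positions.
#' @param freq_ghz Frequency grid.
#' @param target_mm Target location `c(x, y, z)` (z >= 0, into the medium).
#' @param epsilon Real relative permittivity of the homogeneous medium.
#' @param amplitude Scattering amplitude.
#' @param standoff_mm Antenna plane height above the z = 0 reference (the
#'   medium must be homogeneous, so this simply lengthens the path).
#' @return List of `uwb_signal`s, one per aperture position.
#' @export
simulate_point_target <- function(geometry, freq_ghz, target_mm,
                                  epsilon = 1, amplitude = 1,
                                  standoff_mm = 0) {
  stopifnot(length(target_mm) == 3L, target_mm[3] >= 0, epsilon >= 1)
  pos <- position_coords(geometry)
  k <- 2 * pi * freq_ghz * sqrt(epsilon) / C_MM_GHZ
  lapply(seq_len(nrow(pos)), function(p) {
    R <- sqrt((pos$x_mm[p] - target_mm[1])^2 +
              (pos$y_mm[p] - target_mm[2])^2 +
              (target_mm[3] + standoff_mm)^2)
    structure(
      list(freq_ghz = freq_ghz, s11 = amplitude * exp(-2i * k * R),
           position = c(row = pos$row[p], col = pos$col[p]),
           span_ghz = freq_ghz[length(freq_ghz)] - freq_ghz[1]),
      class = "uwb_signal"
    )
  })
}

#' Index of the peak voxel of a cube
#' @param cube A `reflectivity_cube`.
#' @return Integer vector `c(i, j, k)` of the maximum-magnitude voxel.
#' @export
peak_voxel <- function(cube) {
  stopifnot(inherits(cube, "reflectivity_cube"))
  which(cube$values == max(cube$values), arr.ind = TRUE)[1, ]
}
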