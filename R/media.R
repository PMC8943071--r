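#' Single-pole Debye dielectric medium
#'
#' Describes one tissue type by its frequency-dependent complex relative
#' permittivity under the single-relaxation Debye model with a static
#' conductivity term. The time-harmonic convention is `e^{+i omega t}`, so the
#' imaginary part of the permittivity of a lossy medium is negative.
#'
#' @param eps_inf High-frequency relative permittivity (dimensionless, >= 1).
#' @param delta_eps Dispersion magnitude, the drop from the static to the
#'   high-frequency permittivity (dimensionless, >= 0).
#' @param tau_ps Relaxation time in picoseconds (> 0).
#' @param sigma_s Static conductivity in S/m (>= 0).
#' @param label Optional name for the medium.
#' @return An object of class `debye_medium`.
#' @examples
#' skin <- debye_medium(4.0, 32.0, 6.9, 0.9, label = "dermis")
#' debye_permittivity(skin, 60)
#' @export
debye_medium <- function(eps_inf, delta_eps, tau_ps, sigma_s, label = NULL) {
  stopifnot(is.numeric(eps_inf), length(eps_inf) == 1L, eps_inf >= 1,
            is.numeric(delta_eps), length(delta_eps) == 1L, delta_eps >= 0,
            is.numeric(tau_ps), length(tau_ps) == 1L, tau_ps > 0,
            is.numeric(sigma_s), length(sigma_s) == 1L, sigma_s >= 0)
  structure(
    list(eps_inf = eps_inf, delta_eps = delta_eps, tau_ps = tau_ps,
         sigma_s = sigma_s, label = label),
    class = "debye_medium"
  )
}

#' @export
print.debye_medium <- function(x, ...) {
  cat(sprintf("Debye medium%s: eps_inf=%g, delta_eps=%g, tau=%g ps, sigma_s=%g S/m\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$eps_inf, x$delta_eps, x$tau_ps, x$sigma_s))
  invisible(x)
}

#' Complex relative permittivity of a Debye medium
#'
#' Evaluates `eps(f) = eps_inf + delta_eps / (1 + i 2 pi f tau) -
#' i sigma_s / (2 pi f eps0)` under the `e^{+i omega t}` convention, so
#' `Im(eps) <= 0` for passive media.
#'
#' @param medium A [debye_medium()].
#' @param f_ghz Frequency (or vector of frequencies) in GHz; must be > 0.
#' @return Complex relative permittivity, same length as `f_ghz`.
#' @export
debye_permittivity <- function(medium, f_ghz) {
  stopifnot(inherits(medium, "debye_medium"), is.numeric(f_ghz))
  if (any(f_ghz <= 0)) stop("frequency must be positive (GHz)")
  omega <- 2 * pi * f_ghz * 1e9                     # rad/s
  wt <- omega * medium$tau_ps * 1e-12               # omega * tau
  medium$eps_inf + medium$delta_eps / (1 + 1i * wt) -
    1i * medium$sigma_s / (omega * EPS0)
}

# principal square root keeping Im <= 0 for Im(eps) <= 0 (decaying wave under
# e^{+i omega t} with propagation factor e^{-ikz})
refractive_index <- function(eps) {
  n <- sqrt(eps)
  flip <- Im(n) > 0
  n[flip] <- -n[flip]
  n
}

#' Normal-incidence reflection from a layered half-space
#'
#' Computes the complex plane-wave reflection coefficient of a stack of
#' homogeneous dielectric layers seen from air at normal incidence, using the
#' transmission-line impedance recursion. The final layer is treated as
#' semi-infinite. An air standoff between the antenna reference plane and the
#' first interface adds the free-space round-trip phase
#' `exp(-2 i k0 standoff)`.
#'
#' @param stack List of layers; each layer is `list(medium = <debye_medium>,
#'   thickness_mm = <mm>)`. The last layer's thickness is ignored
#'   (semi-infinite). A bare `debye_medium` is accepted as a one-layer stack.
#' @param f_ghz Frequencies in GHz (vectorized).
#' @param standoff_mm Air gap between the reference plane and the surface, mm.
#' @return Complex reflection coefficient, one value per frequency;
#'   `abs()` is <= 1 for passive media.
#' @examples
#' dermis <- debye_medium(4.0, 32.0, 6.9, 0.9)
#' layered_reflection(list(list(medium = dermis)), f_ghz = c(20, 60, 100))
#' @export
layered_reflection <- function(stack, f_ghz, standoff_mm = 0) {
  if (inherits(stack, "debye_medium")) stack <- list(list(medium = stack))
  if (!is.list(stack) || length(stack) == 0L)
    stop("stack must contain at least one layer")
  if (any(f_ghz <= 0)) stop("frequency must be positive (GHz)")
  nl <- length(stack)
  thick <- vapply(stack, function(l) {
    d <- l$thickness_mm
    if (is.null(d)) Inf else as.numeric(d)
  }, numeric(1))
  if (nl > 1L && any(thick[-nl] <= 0)) stop("layer thicknesses must be > 0")

  # relative wave impedance of each layer, eta = 1/sqrt(eps) (air = 1)
  eps <- lapply(stack, function(l) debye_permittivity(l$medium, f_ghz))
  n_idx <- lapply(eps, refractive_index)

  # impedance recursion from the semi-infinite bottom layer upward
  z <- 1 / n_idx[[nl]]
  if (nl > 1L) {
    for (j in seq(nl - 1L, 1L)) {
      eta <- 1 / n_idx[[j]]
      kd <- (2 * pi * f_ghz / C_MM_GHZ) * n_idx[[j]] * thick[j]
      t_kd <- tan(kd)
      z <- eta * (z + 1i * eta * t_kd) / (eta + 1i * z * t_kd)
    }
  }
  gamma <- (z - 1) / (z + 1)
  if (standoff_mm != 0) {
    k0 <- 2 * pi * f_ghz / C_MM_GHZ
    gamma <- gamma * exp(-2i * k0 * standoff_mm)
  }
  gamma
}

#' Default skin tissue media
#'
#' A set of Debye media representing the layered structure of human skin at
#' millimeter-wave frequencies, with parameter values in the range reported
#' for skin in the published dielectric-spectroscopy literature. Malignant
#' lesion tissue is modeled as dermis-like tissue with a fractional increase
#' of `contrast` in both the dispersion magnitude and static conductivity,
#' reflecting the higher water and biochemical content of tumors.
#'
#' @param contrast Fractional malignant-versus-benign increase applied to
#'   `delta_eps` and `sigma_s` (>= 0).
#' @return Named list of `debye_medium` objects: `epidermis`, `dermis`,
#'   `fat`, `benign`, `malignant`.
#' @export
skin_media <- function(contrast = 0.3) {
  if (contrast < 0) stop("contrast must be >= 0")
  benign <- debye_medium(4.0, 30.0, 6.9, 0.8, label = "benign lesion")
  list(
    epidermis = debye_medium(3.5, 25.0, 6.9, 0.5, label = "epidermis"),
    dermis    = debye_medium(4.0, 32.0, 6.9, 0.9, label = "dermis"),
    fat       = debye_medium(2.5, 5.0, 8.0, 0.05, label = "subcutaneous fat"),
    benign    = benign,
    malignant = debye_medium(benign$eps_inf,
                             benign$delta_eps * (1 + contrast),
                             benign$tau_ps,
                             benign$sigma_s * (1 + contrast),
                             label = "malignant lesion")
  )
}
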