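#' Uniform frequency grid
#'
#' @param start_ghz,stop_ghz Band edges in GHz, `start < stop`.
#' @param n Number of points (>= 2), uniformly spaced.
#' @return Object of class `frequency_grid` with a `freq_ghz` vector.
#' @export
frequency_grid <- function(start_ghz, stop_ghz, n = 128L) {
  stopifnot(start_ghz < stop_ghz, n >= 2L)
  structure(
    list(start_ghz = start_ghz, stop_ghz = stop_ghz, n = as.integer(n),
         freq_ghz = seq(start_ghz, stop_ghz, length.out = n)),
    class = "frequency_grid"
  )
}

#' Default measurement sub-bands
#'
#' The two antenna sub-bands, 12-51 GHz and 51-110 GHz, which together span
#' the synthetic ultra-wide bandwidth of 98 GHz.
#'
#' @param n Points per sub-band.
#' @return List of two [frequency_grid()]s.
#' @export
default_subbands <- function(n = 128L) {
  list(frequency_grid(12, 51, n), frequency_grid(51, 110, n))
}

#' Rectangular scan-aperture geometry
#'
#' Monostatic raster scan over an `m x n` rectangular grid of antenna
#' positions. Rows run along x with the first field-of-view extent, columns
#' along y with the second; the aperture is centered on the origin.
#'
#' @param m,n Grid dimensions (positions along x and y).
#' @param increment_mm Spacing between consecutive scan positions, mm.
#' @param fov_mm Antenna field of view on the skin, `c(x_extent, y_extent)` mm.
#' @param standoff_mm Constant distance between the antenna phase center and
#'   the skin surface, mm.
#' @return Object of class `scan_geometry`.
#' @export
scan_geometry <- function(m = 8L, n = 6L, increment_mm = 1.5,
                          fov_mm = c(4, 8), standoff_mm = 20) {
  if (increment_mm <= 0) stop("scan increment must be > 0")
  stopifnot(m >= 1L, n >= 1L, length(fov_mm) == 2L, all(fov_mm > 0),
            standoff_mm >= 0)
  structure(
    list(m = as.integer(m), n = as.integer(n), increment_mm = increment_mm,
         fov_mm = fov_mm, standoff_mm = standoff_mm),
    class = "scan_geometry"
  )
}

# centered lateral coordinates of every scan position (column-major over rows)
position_coords <- function(geometry) {
  rows <- rep(seq_len(geometry$m), times = geometry$n)
  cols <- rep(seq_len(geometry$n), each = geometry$m)
  data.frame(
    row = rows, col = cols,
    x_mm = (rows - (geometry$m + 1) / 2) * geometry$increment_mm,
    y_mm = (cols - (geometry$n + 1) / 2) * geometry$increment_mm
  )
}

#' Layered skin phantom with an embedded lesion
#'
#' A laterally homogeneous layer stack (epidermis, dermis, fat by default)
#' with a cylindrical lesion region: inside a lateral disc, the top of the
#' dermis is replaced by lesion tissue down to the lesion depth.
#'
#' @param media Named media list as from [skin_media()].
#' @param lesion `NULL` for no lesion, or a list with `center_mm` (length-2
#'   lateral center), `radius_mm`, `depth_mm`, and `medium` (a
#'   [debye_medium()]).
#' @param class Lesion class label, `"benign"` or `"malignant"`.
#' @param subtype Diagnosis subtype label.
#' @param site Body-site class label.
#' @param epidermis_mm,dermis_mm Layer thicknesses, mm.
#' @return Object of class `skin_phantom`.
#' @export
skin_phantom <- function(media = skin_media(), lesion = NULL,
                         class = "benign", subtype = NA_character_,
                         site = NA_character_,
                         epidermis_mm = 0.1, dermis_mm = 1.5) {
  stopifnot(epidermis_mm > 0, dermis_mm > 0)
  if (!is.null(lesion)) {
    stopifnot(length(lesion$center_mm) == 2L, lesion$radius_mm > 0,
              lesion$depth_mm > 0, inherits(lesion$medium, "debye_medium"))
  }
  structure(
    list(media = media, lesion = lesion, class = class, subtype = subtype,
         site = site, epidermis_mm = epidermis_mm, dermis_mm = dermis_mm),
    class = "skin_phantom"
  )
}

# background stack: epidermis / dermis / semi-infinite fat
background_stack <- function(phantom) {
  list(
    list(medium = phantom$media$epidermis, thickness_mm = phantom$epidermis_mm),
    list(medium = phantom$media$dermis, thickness_mm = phantom$dermis_mm),
    list(medium = phantom$media$fat)
  )
}

# lesion stack: lesion tissue replaces the top of the dermis
lesion_stack <- function(phantom) {
  les <- phantom$lesion
  stack <- list(
    list(medium = phantom$media$epidermis, thickness_mm = phantom$epidermis_mm),
    list(medium = les$medium, thickness_mm = les$depth_mm)
  )
  remaining <- phantom$dermis_mm - les$depth_mm
  if (remaining > 0)
    stack <- c(stack, list(list(medium = phantom$media$dermis,
                                thickness_mm = remaining)))
  c(stack, list(list(medium = phantom$media$fat)))
}

# does the antenna footprint (FOV rectangle centered at x,y) overlap the
# lesion disc?
footprint_overlaps <- function(x, y, lesion, fov_mm) {
  dx <- pmax(0, abs(lesion$center_mm[1] - x) - fov_mm[1] / 2)
  dy <- pmax(0, abs(lesion$center_mm[2] - y) - fov_mm[2] / 2)
  dx^2 + dy^2 <= lesion$radius_mm^2
}

#' Simulate a two-sub-band monostatic scan of a phantom
#'
#' At each scan position the reflection sweep is the plane-wave layered
#' response of the local stack: lesion tissue where the antenna footprint
#' overlaps the lesion disc, background elsewhere. Additive circular complex
#' Gaussian noise with standard deviation `noise_level` times the mean
#' reflection magnitude is applied per band.
#'
#' @param phantom A [skin_phantom()].
#' @param grids List of the two sub-band [frequency_grid()]s.
#' @param geometry A [scan_geometry()].
#' @param noise_level Relative noise standard deviation (>= 0).
#' @param seed Integer seed for the noise; `NULL` uses the current RNG stream.
#' @return Object of class `scan_dataset`: per-band complex `n_freq x
#'   n_positions` matrices plus geometry and phantom metadata.
#' @export
simulate_scan <- function(phantom, grids = default_subbands(),
                          geometry = scan_geometry(), noise_level = 0.02,
                          seed = NULL) {
  stopifnot(inherits(phantom, "skin_phantom"), length(grids) == 2L,
            noise_level >= 0)
  if (geometry$increment_mm <= 0) stop("scan increment must be > 0")
  run <- function() {
    pos <- position_coords(geometry)
    over <- if (is.null(phantom$lesion)) rep(FALSE, nrow(pos)) else
      footprint_overlaps(pos$x_mm, pos$y_mm, phantom$lesion, geometry$fov_mm)
    bg <- background_stack(phantom)
    les <- if (any(over)) lesion_stack(phantom) else NULL
    bands <- lapply(grids, function(g) {
      f <- g$freq_ghz
      sweep_bg <- layered_reflection(bg, f, geometry$standoff_mm)
      s11 <- matrix(sweep_bg, nrow = length(f), ncol = nrow(pos))
      if (any(over)) {
        sweep_les <- layered_reflection(les, f, geometry$standoff_mm)
        s11[, over] <- sweep_les
      }
      if (noise_level > 0) {
        sd_n <- noise_level * mean(abs(s11)) / sqrt(2)
        s11 <- s11 + complex(
          real = rnorm(length(s11), 0, sd_n),
          imaginary = rnorm(length(s11), 0, sd_n)
        )
      }
      list(grid = g, s11 = s11)
    })
    structure(
      list(bands = bands, geometry = geometry,
           meta = list(class = phantom$class, subtype = phantom$subtype,
                       site = phantom$site, lesion = phantom$lesion),
           artifacts = FALSE, dips = NULL),
      class = "scan_dataset"
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Extract one sub-band sweep from a scan dataset
#'
#' @param ds A `scan_dataset`.
#' @param row,col Scan position indices.
#' @param band Sub-band identifier (1 or 2).
#' @return Object of class `subband_sweep` with `freq_ghz`, complex `s11`,
#'   `band`, and `position`.
#' @export
get_sweep <- function(ds, row, col, band = 1L) {
  stopifnot(inherits(ds, "scan_dataset"), band %in% c(1L, 2L),
            row >= 1L, row <= ds$geometry$m, col >= 1L, col <= ds$geometry$n)
  p <- (col - 1L) * ds$geometry$m + row
  structure(
    list(freq_ghz = ds$bands[[band]]$grid$freq_ghz,
         s11 = ds$bands[[band]]$s11[, p],
         band = as.integer(band), position = c(row = row, col = col)),
    class = "subband_sweep"
  )
}

#' Construct a sub-band sweep from raw vectors
#' @param freq_ghz Frequencies in GHz, strictly increasing.
#' @param s11 Complex reflection coefficients, same length.
#' @param band Sub-band identifier.
#' @param position Scan position index `c(row, col)`.
#' @return Object of class `subband_sweep`.
#' @export
subband_sweep <- function(freq_ghz, s11, band = 1L, position = c(1L, 1L)) {
  stopifnot(length(freq_ghz) == length(s11), all(diff(freq_ghz) > 0),
            all(is.finite(abs(s11))))
  structure(list(freq_ghz = freq_ghz, s11 = as.complex(s11),
                 band = as.integer(band), position = position),
            class = "subband_sweep")
}

#' Inject narrow interference notches into a scan dataset
#'
#' Emulates the accidental-interference spectral dips that invalidate a
#' measurement: narrow multiplicative notches at random band/position/
#' frequency locations. A triangular notch window of `width` samples scaled
#' by `depth_fraction` multiplies the spectrum (center magnitude reduced to
#' `1 - depth_fraction`).
#'
#' @param ds A `scan_dataset`.
#' @param n_dips Number of notches (>= 0; 0 returns the dataset unchanged).
#' @param depth_fraction Notch depth, 0 < depth <= 1 (1 = magnitude reaches 0).
#' @param width Notch width in samples (odd).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return The dataset with notches applied and `artifacts = TRUE`.
#' @export
inject_interference_dips <- function(ds, n_dips = 3L, depth_fraction = 0.9,
                                     width = 3L, seed = NULL) {
  stopifnot(inherits(ds, "scan_dataset"))
  if (n_dips < 0) stop("n_dips must be >= 0")
  if (depth_fraction <= 0 || depth_fraction > 1)
    stop("depth_fraction must be in (0, 1]")
  if (n_dips == 0L) return(ds)
  half <- (width - 1L) %/% 2L
  tri <- 1 - abs(seq(-half, half)) / (half + 1L)   # triangular window
  run <- function() {
    dips <- vector("list", n_dips)
    for (d in seq_len(n_dips)) {
      band <- sample(1:2, 1L)
      nf <- length(ds$bands[[band]]$grid$freq_ghz)
      np <- ncol(ds$bands[[band]]$s11)
      p <- sample(np, 1L)
      ctr <- sample((half + 1L):(nf - half), 1L)
      idx <- (ctr - half):(ctr + half)
      ds$bands[[band]]$s11[idx, p] <<- ds$bands[[band]]$s11[idx, p] *
        (1 - depth_fraction * tri)
      dips[[d]] <- list(band = band, position = p,
                        freq_ghz = ds$bands[[band]]$grid$freq_ghz[ctr])
    }
    dips
  }
  dips <- if (is.null(seed)) run() else with_seed(seed, run())
  ds$artifacts <- TRUE
  ds$dips <- dips
  ds
}

#' Study cohort composition of validated lesions
#'
#' Counts of the nine diagnosis subtypes among the 136 validated lesions:
#' 93 benign (melanocytic nevus 22, seborrheic keratosis 25, solar lentigo
#' 24, angioma/angiokeratoma 12, dermatofibroma 10) and 43 malignant or
#' premalignant (melanoma 5, basal cell carcinoma 10, squamous cell carcinoma
#' 8, actinic keratosis 20).
#'
#' @return Data frame with columns `subtype`, `class`, `count`.
#' @export
table1_composition <- function() {
  data.frame(
    subtype = c("melanocytic nevus", "seborrheic keratosis", "solar lentigo",
                "angioma/angiokeratoma", "dermatofibroma",
                "melanoma", "basal cell carcinoma",
                "squamous cell carcinoma", "actinic keratosis"),
    class = c(rep("benign", 5L), rep("malignant", 4L)),
    count = c(22L, 25L, 24L, 12L, 10L, 5L, 10L, 8L, 20L),
    stringsAsFactors = FALSE
  )
}

# body-site class distribution per lesion class (counts among validated
# lesions: non-glabrous 43/22, palmoplantar 12/1, facial 28/15, scalp 10/5)
site_distribution <- function() {
  list(
    sites = c("non-glabrous common skin", "palmoplantar skin",
              "facial skin", "hairbearing scalp"),
    benign = c(43, 12, 28, 10) / 93,
    malignant = c(22, 1, 15, 5) / 43
  )
}

#' Generate a synthetic lesion cohort with scan data
#'
#' Builds one [skin_phantom()] and one simulated [simulate_scan()] dataset
#' per lesion. The valid part of the cohort follows `composition` exactly;
#' `n_invalid` additional lesions (subtypes drawn from the composition
#' proportions) receive injected interference notches and are flagged
#' invalid. Per-lesion dielectric variability is lognormal jitter around the
#' class medium; malignant media carry a fractional increase of `contrast`
#' in dispersion magnitude and conductivity.
#'
#' @param composition Data frame of `subtype`, `class`, `count` rows;
#'   defaults to [table1_composition()].
#' @param contrast Malignant-versus-benign dielectric contrast (>= 0).
#' @param n_invalid Number of extra artifact-bearing lesions.
#' @param noise_level Relative measurement noise standard deviation.
#' @param seed Integer seed; the whole cohort is deterministic given the seed.
#' @param grids Sub-band frequency grids.
#' @param geometry Scan geometry.
#' @param n_subjects Number of subjects lesions are attributed to.
#' @param jitter_sd Lognormal sd of per-lesion dielectric jitter.
#' @return Object of class `mmwi_cohort`: `table` (one row per lesion:
#'   `lesion_id`, `subject_id`, `class`, `subtype`, `site`, `valid_truth`,
#'   `scan_id`) and `scans` (list of `scan_dataset`s).
#' @export
generate_cohort <- function(composition = table1_composition(),
                            contrast = 0.3, n_invalid = 10L,
                            noise_level = 0.02, seed = 1L,
                            grids = default_subbands(),
                            geometry = scan_geometry(),
                            n_subjects = 71L, jitter_sd = 0.05) {
  if (contrast < 0) stop("contrast must be >= 0")
  stopifnot(all(composition$count >= 0), n_invalid >= 0)
  n_valid <- sum(composition$count)
  total <- n_valid + n_invalid
  if (total < 1L) stop("cohort must contain at least one lesion")
  if (n_invalid > total) stop("n_invalid exceeds cohort size")
  media <- skin_media(contrast)
  sites <- site_distribution()

  with_seed(seed, {
    subtype <- rep(composition$subtype, composition$count)
    class <- rep(composition$class, composition$count)
    valid <- rep(TRUE, n_valid)
    if (n_invalid > 0L) {
      extra <- sample(nrow(composition), n_invalid, replace = TRUE,
                      prob = composition$count / max(1L, n_valid))
      subtype <- c(subtype, composition$subtype[extra])
      class <- c(class, composition$class[extra])
      valid <- c(valid, rep(FALSE, n_invalid))
    }
    ord <- sample(total)
    subtype <- subtype[ord]; class <- class[ord]; valid <- valid[ord]

    site <- character(total)
    for (cl in c("benign", "malignant")) {
      idx <- which(class == cl)
      if (length(idx))
        site[idx] <- sample(sites$sites, length(idx), replace = TRUE,
                            prob = sites[[cl]])
    }

    n_subj <- min(n_subjects, total)
    subject <- sample(c(seq_len(n_subj),
                        if (total > n_subj)
                          sample(n_subj, total - n_subj, replace = TRUE)))

    scans <- vector("list", total)
    for (i in seq_len(total)) {
      base <- media[[class[i]]]
      jit <- exp(rnorm(2, 0, jitter_sd))
      lesion_medium <- debye_medium(base$eps_inf, base$delta_eps * jit[1],
                                    base$tau_ps, base$sigma_s * jit[2],
                                    label = class[i])
      lesion <- list(center_mm = runif(2, -1.5, 1.5),
                     radius_mm = runif(1, 2.5, 4),
                     depth_mm = runif(1, 0.6, 1.4),
                     medium = lesion_medium)
      ph <- skin_phantom(media = media, lesion = lesion, class = class[i],
                         subtype = subtype[i], site = site[i])
      ds <- simulate_scan(ph, grids = grids, geometry = geometry,
                          noise_level = noise_level, seed = NULL)
      if (!valid[i])
        ds <- inject_interference_dips(ds, n_dips = 3L, seed = NULL)
      scans[[i]] <- ds
    }

    structure(
      list(
        table = data.frame(
          lesion_id = sprintf("L%03d", seq_len(total)),
          subject_id = sprintf("S%02d", subject),
          class = class, subtype = subtype, site = site,
          valid_truth = valid, scan_id = seq_len(total),
          stringsAsFactors = FALSE
        ),
        scans = scans,
        params = list(contrast = contrast, n_invalid = n_invalid,
                      noise_level = noise_level, seed = seed)
      ),
      class = "mmwi_cohort"
    )
  })
}
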