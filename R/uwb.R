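#' Calibrate a raw sweep to reflectivity
#'
#' Reflectivity is the ratio of the reflected to the incident field; with a
#' known reference target (e.g. a metal plate, reflection -1 at the surface)
#' the pointwise complex ratio `raw / reference` removes the incident-field
#' and standoff contributions.
#'
#' @param raw,reference `subband_sweep`s on identical frequency grids;
#'   all reference magnitudes must be nonzero.
#' @return A `subband_sweep` with the calibrated spectrum.
#' @export
calibrate_reflectivity <- function(raw, reference) {
  stopifnot(inherits(raw, "subband_sweep"), inherits(reference, "subband_sweep"))
  if (length(raw$freq_ghz) != length(reference$freq_ghz) ||
      any(abs(raw$freq_ghz - reference$freq_ghz) > 1e-9))
    stop("frequency grids of raw and reference sweeps do not match")
  zero <- abs(reference$s11) == 0
  if (any(zero))
    stop(sprintf("reference magnitude is zero at %g GHz",
                 raw$freq_ghz[which(zero)[1]]))
  out <- raw
  out$s11 <- raw$s11 / reference$s11
  out
}

#' Ideal metal-plate reference sweep
#'
#' The reflection of a perfect conductor at the target surface seen through
#' the air standoff: `-exp(-2 i k0 standoff)`.
#'
#' @param freq_ghz Frequencies in GHz.
#' @param standoff_mm Air standoff in mm.
#' @param band,position Passed through to the sweep.
#' @return A `subband_sweep`.
#' @export
metal_plate_reference <- function(freq_ghz, standoff_mm,
                                  band = 1L, position = c(1L, 1L)) {
  k0 <- 2 * pi * freq_ghz / C_MM_GHZ
  subband_sweep(freq_ghz, -exp(-2i * k0 * standoff_mm), band, position)
}

#' Synthesize an ultra-wideband spectrum from two sub-band sweeps
#'
#' Places the two sub-band spectra adjacent to each other in the frequency
#' domain. The bands must share their junction frequency (51 GHz for the
#' default bands); the two samples at the junction are averaged, so the
#' merged grid carries a single value there and the covered span equals the
#' sum of the sub-band spans.
#'
#' @param band1,band2 `subband_sweep`s; `band1` must end where `band2`
#'   starts (within one grid step).
#' @return Object of class `uwb_signal` with the merged `freq_ghz` grid and
#'   complex `s11`.
#' @export
synthesize_uwb <- function(band1, band2) {
  stopifnot(inherits(band1, "subband_sweep"), inherits(band2, "subband_sweep"))
  f1 <- band1$freq_ghz; f2 <- band2$freq_ghz
  step <- max(f1[length(f1)] - f1[length(f1) - 1], f2[2] - f2[1])
  gap <- f2[1] - f1[length(f1)]
  if (gap < -1e-9)
    stop("sub-band ranges overlap; bands must be adjacent")
  if (gap > step + 1e-9)
    stop("gap between sub-bands exceeds one grid step")
  if (abs(gap) <= 1e-9) {
    # shared junction sample: average the two band endpoint values
    freq <- c(f1, f2[-1])
    s11 <- c(band1$s11[-length(f1)],
             (band1$s11[length(f1)] + band2$s11[1]) / 2,
             band2$s11[-1])
  } else {
    freq <- c(f1, f2)
    s11 <- c(band1$s11, band2$s11)
  }
  structure(
    list(freq_ghz = freq, s11 = s11, position = band1$position,
         span_ghz = freq[length(freq)] - freq[1]),
    class = "uwb_signal"
  )
}

#' Synthesize UWB signals for every position of a scan dataset
#'
#' Optionally calibrates each sub-band sweep against the ideal metal-plate
#' reference (removing the standoff phase) before merging.
#'
#' @param ds A `scan_dataset`.
#' @param calibrate If `TRUE`, divide by the metal-plate reference first.
#' @return List of `uwb_signal`s, one per scan position (column-major).
#' @export
uwb_signals <- function(ds, calibrate = TRUE) {
  stopifnot(inherits(ds, "scan_dataset"))
  geom <- ds$geometry
  refs <- lapply(1:2, function(b) {
    if (!calibrate) return(NULL)
    metal_plate_reference(ds$bands[[b]]$grid$freq_ghz, geom$standoff_mm, b)
  })
  np <- geom$m * geom$n
  lapply(seq_len(np), function(p) {
    row <- (p - 1L) %% geom$m + 1L
    col <- (p - 1L) %/% geom$m + 1L
    sw <- lapply(1:2, function(b) {
      s <- subband_sweep(ds$bands[[b]]$grid$freq_ghz, ds$bands[[b]]$s11[, p],
                         b, c(row = row, col = col))
      if (calibrate) calibrate_reflectivity(s, refs[[b]]) else s
    })
    synthesize_uwb(sw[[1]], sw[[2]])
  })
}

#' Maximum scan spacing satisfying the Nyquist criterion
#'
#' Free-space half wavelength `c / (2 f_ref)` at the reference frequency. At
#' the default reference of 100 GHz this is 1.499 mm, matching the 1.5 mm
#' scan increment; at the band edge of 110 GHz the half wavelength is
#' 1.363 mm, slightly below the increment, which is why the criterion is
#' only approximately satisfied there (a warning notes this when the
#' reference is at or above 110 GHz equivalents of the increment in use).
#'
#' @param f_ref_ghz Reference frequency in GHz (> 0).
#' @return Spacing in mm.
#' @export
max_nyquist_spacing <- function(f_ref_ghz = 100) {
  if (f_ref_ghz <= 0) stop("reference frequency must be positive")
  C_MM_GHZ / (2 * f_ref_ghz)
}

#' Lateral extent illuminated by a scan
#'
#' `(n_positions - 1) * increment + fov_extent`: the span of scan positions
#' plus the antenna field of view.
#'
#' @param n_positions Number of positions along the axis (>= 1).
#' @param increment_mm Scan increment, mm (> 0).
#' @param fov_extent_mm Field-of-view extent along the axis, mm (> 0).
#' @return Illuminated extent in mm.
#' @examples
#' illuminated_extent(8, 1.5, 4)  # 14.5 mm
#' illuminated_extent(6, 1.5, 8)  # 15.5 mm
#' @export
illuminated_extent <- function(n_positions, increment_mm, fov_extent_mm) {
  stopifnot(n_positions >= 1, increment_mm > 0, fov_extent_mm > 0)
  (n_positions - 1) * increment_mm + fov_extent_mm
}

# scan one magnitude spectrum for narrow dips below a running-median baseline
find_dips <- function(freq_ghz, mag, dip_depth_db, dip_width,
                      baseline_window = 11L) {
  baseline <- runmed(mag, baseline_window, endrule = "median")
  depth_db <- 20 * log10(pmax(baseline, .Machine$double.xmin) /
                           pmax(mag, .Machine$double.xmin))
  deep <- depth_db > dip_depth_db          # strict: at-threshold is not a dip
  if (!any(deep)) return(numeric(0))
  r <- rle(deep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hits <- which(r$values & r$lengths < dip_width)
  unlist(lapply(hits, function(h) {
    idx <- starts[h]:ends[h]
    freq_ghz[idx[which.max(depth_db[idx])]]
  }))
}

#' Flag a lesion invalid if its spectra contain narrow interference dips
#'
#' A lesion is invalidated when any of its position spectra contains a local
#' magnitude minimum deeper than `dip_depth_db` relative to a running-median
#' baseline and narrower than `dip_width` samples — the signature of
#' accidental interference rather than tissue response. Both comparisons are
#' strict, so a dip exactly at the depth threshold does not invalidate.
#'
#' @param signals List of `uwb_signal`s for one lesion (>= 1).
#' @param dip_depth_db Depth threshold in dB below the baseline.
#' @param dip_width Width threshold in samples.
#' @return List with `valid` (logical) and `dips` (data frame of offending
#'   position/frequency pairs).
#' @export
validity_filter <- function(signals, dip_depth_db = 6, dip_width = 5L) {
  if (length(signals) == 0L) stop("no signals supplied")
  rows <- list()
  for (p in seq_along(signals)) {
    sig <- signals[[p]]
    f <- find_dips(sig$freq_ghz, abs(sig$s11), dip_depth_db, dip_width)
    if (length(f))
      rows[[length(rows) + 1L]] <- data.frame(position = p, freq_ghz = f)
  }
  dips <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), freq_ghz = numeric(0))
  list(valid = nrow(dips) == 0L, dips = dips)
}

#' Apply the validity filter to every lesion of a cohort
#'
#' @param cohort An `mmwi_cohort` from [generate_cohort()].
#' @param dip_depth_db,dip_width Thresholds passed to [validity_filter()].
#' @param calibrate Passed to [uwb_signals()].
#' @return The cohort table with a logical `valid` column appended.
#' @export
cohort_validity <- function(cohort, dip_depth_db = 6, dip_width = 5L,
                            calibrate = TRUE) {
  stopifnot(inherits(cohort, "mmwi_cohort"))
  valid <- vapply(cohort$scans, function(ds) {
    validity_filter(uwb_signals(ds, calibrate = calibrate),
                    dip_depth_db, dip_width)$valid
  }, logical(1))
  tab <- cohort$table
  tab$valid <- valid[tab$scan_id]
  tab
}
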