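#' Write a one-port sweep as a Touchstone .s1p file
#'
#' Standard Touchstone v1 one-port format: option line `# GHz S RI R 50`,
#' one `frequency real imaginary` triple per line.
#'
#' @param sweep A `subband_sweep` or `uwb_signal`.
#' @param path Output file path (conventionally `.s1p`).
#' @export
write_touchstone <- function(sweep, path) {
  stopifnot(!is.null(sweep$freq_ghz), !is.null(sweep$s11))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("! one-port reflection sweep", "# GHz S RI R 50"), con)
  writeLines(sprintf("%.9g %.12g %.12g", sweep$freq_ghz,
                     Re(sweep$s11), Im(sweep$s11)), con)
  invisible(path)
}

#' Read a Touchstone .s1p file
#'
#' Supports the RI (real/imaginary) and MA (linear magnitude/angle in
#' degrees) formats with a GHz/MHz/Hz frequency unit.
#'
#' @param path File path.
#' @param band,position Metadata attached to the returned sweep.
#' @return A `subband_sweep`.
#' @export
read_touchstone <- function(path, band = 1L, position = c(1L, 1L)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  opt <- lines[startsWith(lines, "#")]
  fmt <- "RI"; unit <- 1
  if (length(opt)) {
    toks <- toupper(strsplit(opt[1], "\\s+")[[1]])
    if ("MA" %in% toks) fmt <- "MA"
    if ("HZ" %in% toks) unit <- 1e-9
    if ("MHZ" %in% toks) unit <- 1e-3
  }
  dat <- lines[!startsWith(lines, "!") & !startsWith(lines, "#")]
  m <- do.call(rbind, lapply(strsplit(dat, "\\s+"), as.numeric))
  if (ncol(m) < 3L) stop("malformed one-port Touchstone file")
  s11 <- if (fmt == "RI") complex(real = m[, 2], imaginary = m[, 3])
         else m[, 2] * exp(1i * m[, 3] * pi / 180)
  subband_sweep(m[, 1] * unit, s11, band = band, position = position)
}

#' Write a cohort's metadata and scans to a directory
#'
#' `cohort.csv` holds one row per lesion (`lesion_id`, `subject_id`,
#' `class`, `subtype`, `site`, `valid_truth`, `scan_id`, `path`); each scan
#' position/band sweep goes to `scans/<lesion>/bN_rR_cC.s1p`.
#'
#' @param cohort An `mmwi_cohort`.
#' @param dir Output directory.
#' @param max_scans Cap on the number of scans written (all by default).
#' @export
write_cohort <- function(cohort, dir, max_scans = Inf) {
  stopifnot(inherits(cohort, "mmwi_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- cohort$table
  tab$path <- file.path("scans", tab$lesion_id)
  n_write <- min(nrow(tab), max_scans)
  for (r in seq_len(n_write)) {
    ds <- cohort$scans[[tab$scan_id[r]]]
    sub <- file.path(dir, tab$path[r])
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    for (b in 1:2) for (col in seq_len(ds$geometry$n))
      for (row in seq_len(ds$geometry$m)) {
        sw <- get_sweep(ds, row, col, b)
        write_touchstone(sw, file.path(sub,
                                       sprintf("b%d_r%d_c%d.s1p", b, row, col)))
      }
  }
  write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}
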