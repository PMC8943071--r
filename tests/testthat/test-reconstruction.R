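geom <- scan_geometry(m = 8L, n = 6L, increment_mm = 1.5, standoff_mm = 0)
fgrid <- seq(12, 110, length.out = 127)
air <- debye_medium(1, 0, 1, 0)

zero_signals <- function(freq = fgrid, g = geom) {
  lapply(seq_len(g$m * g$n), function(p) {
    structure(list(freq_ghz = freq, s11 = rep(0+0i, length(freq)),
                   position = c(row = (p - 1) %% g$m + 1,
                                col = (p - 1) %/% g$m + 1)),
              class = "uwb_signal")
  })
}

test_that("zero spectra reconstruct to zero cubes in both methods", {
  sig <- zero_signals()
  a <- reconstruct_cube(sig, air, geom, depth_samples = 8L)
  b <- das_reference(sig, 1, geom, depth_samples = 8L)
  expect_true(all(a$values == 0))
  expect_true(all(b$values == 0))
  expect_error(reconstruct_cube(list(), air, geom), "no signals")
})

test_that("a free-space point scatterer focuses at its true voxel in both methods", {
  pitch <- 0.75
  target <- c(0.75, 0.75, 5.5 * pitch)      # on-grid laterally, z slice 6
  sig <- simulate_point_target(geom, fgrid, target)
  fd <- reconstruct_cube(sig, air, geom, depth_samples = 16L,
                         depth_pitch_mm = pitch)
  td <- das_reference(sig, 1, geom, depth_samples = 16L,
                      depth_pitch_mm = pitch)
  pk_fd <- peak_voxel(fd); pk_td <- peak_voxel(td)
  # true voxel: x=0.75 -> row 5, y=0.75 -> col 4 (centered grid), z slice 6
  expect_true(all(abs(pk_fd - c(5, 4, 6)) <= 1))
  expect_equal(unname(pk_fd), unname(pk_td))
})

test_that("reconstruction is linear in the signal amplitude", {
  sig <- simulate_point_target(geom, fgrid, c(0, 0, 2))
  sig2 <- lapply(sig, function(s) { s$s11 <- 2 * s$s11; s })
  a <- reconstruct_cube(sig, air, geom, depth_samples = 8L)
  b <- reconstruct_cube(sig2, air, geom, depth_samples = 8L)
  expect_equal(b$values, 2 * a$values, tolerance = 1e-12)
})

test_that("shifting the scatterer one scan increment shifts the peak one voxel", {
  pitch <- 0.75
  z <- 5.5 * pitch
  s0 <- simulate_point_target(geom, fgrid, c(-0.75, 0.75, z))
  s1 <- simulate_point_target(geom, fgrid, c(0.75, 0.75, z))
  p0 <- peak_voxel(reconstruct_cube(s0, air, geom, depth_samples = 12L,
                                    depth_pitch_mm = pitch))
  p1 <- peak_voxel(reconstruct_cube(s1, air, geom, depth_samples = 12L,
                                    depth_pitch_mm = pitch))
  expect_equal(unname(p1 - p0), c(1, 0, 0))
})

test_that("dispersionless Debye media reproduce the constant-permittivity image", {
  eps <- 3
  med <- debye_medium(eps, 0, 1, 0)
  # finer scan increment keeps the lateral sampling below the in-medium
  # half wavelength (no grating lobes)
  g2 <- scan_geometry(increment_mm = 0.75, standoff_mm = 0)
  target <- c(0.375, 0.375, 2)
  sig <- simulate_point_target(g2, fgrid, target, epsilon = eps)
  fd <- reconstruct_cube(sig, med, g2, depth_samples = 12L,
                         depth_pitch_mm = 0.5)
  td <- das_reference(sig, eps, g2, depth_samples = 12L,
                      depth_pitch_mm = 0.5)
  pk_fd <- peak_voxel(fd); pk_td <- peak_voxel(td)
  expect_true(all(abs(pk_fd - pk_td) <= 1))
  expect_gt(cor(fd$values[pk_fd[1], pk_fd[2], ], td$values[pk_fd[1], pk_fd[2], ]),
            0.95)
})

test_that("depth resolution approximates c/(2 B sqrt(eps))", {
  # unwindowed point response; FWHM of the focal peak along depth. The
  # closed form assumes near-paraxial geometry, so the aperture stands off
  # 20 mm from the reference plane.
  pitch <- 0.1
  z0 <- 4
  sig <- simulate_point_target(geom, fgrid, c(0, 0, z0), standoff_mm = 20)
  cube <- reconstruct_cube(sig, air, geom, depth_samples = 80L,
                           depth_pitch_mm = pitch, window = "none",
                           standoff_mm = 20)
  pk <- peak_voxel(cube)
  prof <- cube$values[pk[1], pk[2], ]
  half <- max(prof) / 2
  above <- which(prof >= half)
  fwhm <- (max(above) - min(above) + 1) * pitch
  expected <- 299.792458 / (2 * 98)
  expect_lt(abs(fwhm - expected) / expected, 0.30)
})

test_that("two scatterers beyond twice the range resolution are resolved", {
  res_mm <- 299.792458 / (2 * 98)
  sep <- 2.2 * res_mm
  pitch <- 0.25
  sig1 <- simulate_point_target(geom, fgrid, c(0, 0, 2), standoff_mm = 20)
  sig2 <- simulate_point_target(geom, fgrid, c(0, 0, 2 + sep),
                                standoff_mm = 20)
  both <- Map(function(a, b) { a$s11 <- a$s11 + b$s11; a }, sig1, sig2)
  cube <- das_reference(both, 1, geom, depth_samples = 40L,
                        depth_pitch_mm = pitch, window = "none",
                        standoff_mm = 20)
  pk <- peak_voxel(cube)
  prof <- cube$values[pk[1], pk[2], ]
  # count strict local maxima above half the global peak
  locmax <- which(diff(sign(diff(prof))) == -2) + 1
  expect_gte(sum(prof[locmax] > 0.5 * max(prof)), 2)
})
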