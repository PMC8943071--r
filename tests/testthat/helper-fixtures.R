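# shared fixtures, all generated in code

# small two-subtype cohort composition
two_class_comp <- function(nb = 6L, nm = 6L) {
  data.frame(subtype = c("melanocytic nevus", "basal cell carcinoma"),
             class = c("benign", "malignant"), count = c(nb, nm),
             stringsAsFactors = FALSE)
}

# cube-based feature source from a small simulated cohort
small_cohort_source <- function(contrast = 0.3, seed = 1L, nb = 6L, nm = 6L,
                                n_freq = 64L, depth_samples = 16L,
                                k_final = 4L) {
  co <- generate_cohort(two_class_comp(nb, nm), contrast = contrast,
                        n_invalid = 0L, seed = seed,
                        grids = default_subbands(n_freq))
  cc <- cohort_cubes(co, depth_samples = depth_samples)
  feature_source(labels = co$table$class, cubes = cc$cubes,
                 ids = co$table$lesion_id, subtypes = co$table$subtype,
                 sites = co$table$site, k_final = k_final)
}

# deterministic synthetic cube with a given mean depth profile
profile_cube <- function(profile, m = 8L, n = 6L, pitch = 0.25) {
  v <- array(rep(profile, each = m * n), dim = c(m, n, length(profile)))
  structure(list(values = v, lateral_pitch_mm = 1.5,
                 depth_pitch_mm = pitch, settings = list()),
            class = "reflectivity_cube")
}

# random nonnegative cube (fixed seed supplied by caller)
random_cube <- function(m = 4L, n = 3L, nz = 10L, pitch = 0.3) {
  v <- array(abs(rnorm(m * n * nz)) + 0.1, dim = c(m, n, nz))
  structure(list(values = v, lateral_pitch_mm = 1.5,
                 depth_pitch_mm = pitch, settings = list()),
            class = "reflectivity_cube")
}

# brute-force geometric bounce-series reflection of a single slab over a
# semi-infinite backing (independent oracle for layered_reflection)
bounce_series_gamma <- function(eps1, eps2, d_mm, f_ghz, n_bounce = 50L) {
  c_mm <- 299.792458
  n1 <- sqrt(eps1); n1 <- ifelse(Im(n1) > 0, -n1, n1)
  n2 <- sqrt(eps2); n2 <- ifelse(Im(n2) > 0, -n2, n2)
  r01 <- (1 - n1) / (1 + n1)
  r12 <- (n1 - n2) / (n1 + n2)
  ph <- exp(-2i * (2 * pi * f_ghz / c_mm) * n1 * d_mm)
  g <- r01
  for (m in 0:n_bounce)
    g <- g + (1 - r01^2) * r12 * ph * (-r01 * r12 * ph)^m
  g
}

expect_complex_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
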