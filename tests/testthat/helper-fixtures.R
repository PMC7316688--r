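# Shared fixtures: small deterministic objects built in code.

# A tiny cube with hand-set band vectors per pixel.
# `pixels` is a list of numeric band vectors, filled row-major into an
# n1 x n2 grid.
toy_cube <- function(pixels, n1, n2, exposure_ms = NULL) {
  nb <- length(pixels[[1]])
  arr <- array(0, dim = c(n1, n2, nb))
  k <- 1
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    arr[i, j, ] <- pixels[[k]]; k <- k + 1
  }
  spectral_cube(arr, exposure_ms = exposure_ms)
}

# Small fast camera for simulation tests: fewer bands, coarse grid.
test_camera <- function(...) {
  camera_model(grid = wavelength_grid(450, 720, 6), n_bands = 8,
               centers = seq(470, 630, length.out = 8), ...)
}

# Small scene with reduced spatial size for speed; defaults otherwise.
test_scene <- function(illuminant, camera, ...) {
  dichromatic_scene(illuminant, camera, width = 48, height = 48,
                    n_highlights = 5, n_sheen = 1, ...)
}

expect_spectrum_sums_to_one <- function(s) {
  expect_true(all(s >= 0))
  expect_equal(sum(s), 1, tolerance = 1e-9)
}
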