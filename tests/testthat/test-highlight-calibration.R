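test_that("valid mask requires every band strictly inside the thresholds", {
  thr <- validity_thresholds(30, 950)
  allok <- spectral_cube(array(500, dim = c(3, 3, 4)))
  expect_true(all(compute_valid_mask(allok, thr)))
  # one saturated band invalidates the pixel
  cube <- toy_cube(list(c(100, 960), c(500, 500)), 1, 2)
  expect_equal(as.vector(compute_valid_mask(cube, thr)), c(FALSE, TRUE))
  # boundary values are excluded (strict inequalities)
  edge <- toy_cube(list(c(30, 500), c(31, 949), c(500, 950)), 1, 3)
  expect_equal(as.vector(compute_valid_mask(edge, thr)), c(FALSE, TRUE, FALSE))
  expect_error(validity_thresholds(950, 950), class = "speclight_error_config")
})

test_that("highlight selection takes brightest valid pixels with deterministic tie-breaks", {
  lf <- matrix(c(5, 9, 9, 1), 2, 2, byrow = TRUE)
  all_valid <- matrix(TRUE, 2, 2)
  sel <- select_highlight_pixels(lf, all_valid, n_p = 2)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$row, c(1L, 2L))  # ties: row ascending
  expect_equal(sel$col, c(2L, 1L))
  expect_equal(sel$lightness, c(9, 9))
  # n_p = 1 returns the argmax
  lf2 <- matrix(1:12, 3, 4)
  s1 <- select_highlight_pixels(lf2, matrix(TRUE, 3, 4), n_p = 1)
  expect_equal(c(s1$row, s1$col), c(3L, 4L))
  # clamping when fewer valid pixels than n_p
  sparse <- matrix(FALSE, 3, 4); sparse[1, 1] <- sparse[2, 2] <- sparse[3, 3] <- TRUE
  expect_equal(nrow(select_highlight_pixels(lf2, sparse, n_p = 100)), 3)
  expect_error(select_highlight_pixels(lf2, matrix(FALSE, 3, 4), 5),
               class = "speclight_error_no_highlights")
})

test_that("illuminant estimate is the mean of per-pixel L1-normalized spectra", {
  cube <- toy_cube(list(c(1, 0), c(0, 1), c(4, 4), c(9, 9)), 2, 2)
  sel <- tibble::tibble(row = c(1L, 1L), col = c(1L, 2L),
                        lightness = c(0.5, 0.5))
  est <- estimate_illuminant(cube, sel)
  expect_equal(as.numeric(est), c(0.5, 0.5))
  expect_spectrum_sums_to_one(est)
  # pixels proportional to a common spectrum recover it exactly
  L <- c(0.2, 0.3, 0.5)
  cube2 <- toy_cube(list(10 * L, 40 * L, 7 * L, 90 * L), 2, 2)
  sel2 <- tibble::tibble(row = c(1L, 2L), col = c(1L, 2L), lightness = c(1, 1))
  expect_equal(as.numeric(estimate_illuminant(cube2, sel2)), L, tolerance = 1e-12)
  # dark subtraction removes a flat offset exactly
  cube3 <- toy_cube(lapply(list(10 * L, 40 * L), function(p) p + 6), 1, 2)
  sel3 <- tibble::tibble(row = c(1L, 1L), col = c(1L, 2L), lightness = c(1, 1))
  expect_equal(as.numeric(estimate_illuminant(cube3, sel3, dark_level = 6)), L,
               tolerance = 1e-12)
  # all-zero pixel errors
  cube4 <- toy_cube(list(c(0, 0), c(1, 1)), 1, 2)
  sel4 <- tibble::tibble(row = 1L, col = 1L, lightness = 0)
  expect_error(estimate_illuminant(cube4, sel4),
               class = "speclight_error_degenerate_input")
})

test_that("goodness is the median relative excess over the dark level", {
  sel <- tibble::tibble(row = 1:3, col = 1:3, lightness = c(110, 210, 310))
  expect_equal(goodness(sel, 10), 20)  # median of {10, 20, 30}
  sel0 <- tibble::tibble(row = 1L, col = 1L, lightness = 7)
  expect_equal(goodness(sel0, 7), 0)
  # ratio invariance under joint rescaling
  expect_equal(goodness(dplyr::mutate(sel, lightness = lightness * 3.5), 35),
               goodness(sel, 10))
  expect_error(goodness(sel, 0), class = "speclight_error_config")
})

test_that("exposure selection maximizes G with shorter-exposure tie-breaks", {
  cam <- test_camera()
  # constructed profile: middle exposure has the brightest valid highlights
  mk <- function(v, t) {
    arr <- array(40, dim = c(4, 4, cam$n_bands))
    arr[1, 1, ] <- v
    spectral_cube(arr, exposure_ms = t, band_ids = cam$band_ids)
  }
  dark <- tibble::tibble(exposure_ms = c(10, 20, 30),
                         dark_mean = c(10, 10, 10), dark_std = c(0.5, 0.5, 0.5))
  series <- exposure_series(list(mk(110, 10), mk(850, 20), mk(300, 30)), dark)
  sel <- select_exposure(series, i_max = 950, n_p = 1)
  expect_equal(sel$exposure_ms, 20)
  expect_equal(nrow(sel$profile), 3)
  expect_true(all(diff(sel$profile$exposure_ms) > 0))
  # single-entry series returns that exposure
  s1 <- exposure_series(list(mk(500, 10)), dark[1, ])
  expect_equal(select_exposure(s1, n_p = 1)$exposure_ms, 10)
  # exact G ties resolve to the shorter exposure
  tie <- exposure_series(list(mk(110, 10), mk(110, 20)), dark[1:2, ])
  expect_equal(select_exposure(tie, n_p = 1)$exposure_ms, 10)
  # exposures whose pixels all saturate are never selected
  sat <- exposure_series(list(mk(500, 10), mk(990, 20)), dark[1:2, ])
  arr <- sat$cubes[[2]]$data; arr[] <- 990
  sat$cubes[[2]]$data <- arr
  expect_equal(select_exposure(sat, n_p = 1)$exposure_ms, 10)
})

test_that("calibrate on identical cubes matches the single-cube estimate", {
  cam <- test_camera()
  ill <- reference_illuminants(cam$grid)
  scene <- test_scene(ill$ls2, cam, sigma_w = 0, seed = 9)
  cam_dark <- dark_statistics(cam, c(10, 20), seed = 1)
  cube <- generate_scene(scene, 10, seed = 2)$cube
  cube2 <- cube; cube2$exposure_ms <- 20
  # same pixel data at both "exposures", same dark stats rows
  eq_dark <- tibble::tibble(exposure_ms = c(10, 20),
                            dark_mean = rep(cam_dark$dark_mean[1], 2),
                            dark_std = rep(cam_dark$dark_std[1], 2))
  series <- exposure_series(list(cube, cube2), eq_dark)
  cal <- calibrate(series)
  thr <- validity_thresholds(eq_dark$dark_mean[1] + 3 * eq_dark$dark_std[1], 950)
  sel <- select_highlight_pixels(lightness(cube), compute_valid_mask(cube, thr), 100)
  single <- estimate_illuminant(cube, sel, dark_level = eq_dark$dark_mean[1])
  expect_equal(as.numeric(cal$estimate), as.numeric(single), tolerance = 1e-12)
  expect_equal(cal$exposure_ms, 10)  # tie broken toward shorter exposure
})

test_that("estimate is invariant to global scaling that keeps the mask fixed", {
  cam <- test_camera()
  ill <- reference_illuminants(cam$grid)
  scene <- test_scene(ill$ls5, cam, sigma_w = 0, seed = 21)
  cube <- generate_scene(scene, 5, seed = 3)$cube
  thr <- validity_thresholds(25, 950)
  mask <- compute_valid_mask(cube, thr)
  sel <- select_highlight_pixels(lightness(cube), mask, 50)
  e1 <- estimate_illuminant(cube, sel)
  scaled <- spectral_cube(cube$data * 1.01, exposure_ms = cube$exposure_ms)
  sel2 <- select_highlight_pixels(lightness(scaled),
                                  compute_valid_mask(scaled, thr), 50)
  # verify like-for-like selection before comparing
  if (identical(sel$row, sel2$row) && identical(sel$col, sel2$col)) {
    e2 <- estimate_illuminant(scaled, sel2)
    expect_equal(as.numeric(e1), as.numeric(e2), tolerance = 1e-6)
  }
  # exact invariance when the selection is fixed
  e3 <- estimate_illuminant(scaled, sel)
  expect_equal(as.numeric(e1), as.numeric(e3), tolerance = 1e-12)
})

test_that("tidy and glance methods expose calibration results as tibbles", {
  cam <- test_camera()
  ill <- reference_illuminants(cam$grid)
  scene <- test_scene(ill$ls1, cam, seed = 31)
  series <- generate_exposure_series(scene, exposures = c(5, 10, 20), seed = 32)
  cal <- calibrate(series)
  td <- generics::tidy(cal)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("band", "value"))
  expect_equal(sum(td$value), 1, tolerance = 1e-9)
  gl <- generics::glance(cal)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_exposures, 3)
  expect_s3_class(autoplot(cal), "ggplot")
})
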