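test_that("tissue sampling is reproducible and respects the stated ranges", {
  a <- sample_tissue(50, seed = 7)
  b <- sample_tissue(50, seed = 7)
  expect_identical(a, b)
  big <- sample_tissue(10000, seed = 8)
  rng <- tissue_ranges()
  for (l in 1:3) {
    expect_true(all(big[[paste0("thickness_um_", l)]] >= rng$thickness_um[1] &
                    big[[paste0("thickness_um_", l)]] <= rng$thickness_um[2]))
    expect_true(all(big[[paste0("bvf_", l)]] >= 0 & big[[paste0("bvf_", l)]] <= 0.3))
    expect_true(all(big[[paste0("sox_", l)]] >= 0 & big[[paste0("sox_", l)]] <= 1))
  }
  expect_true(all(big$mus500 > 0))
  expect_error(sample_tissue(0), class = "speclight_error_config")
})

test_that("absorption is linear in bvf/sox with the right endpoints", {
  grid <- wavelength_grid()
  tab <- chromophore_table(grid)
  expect_equal(absorption_coefficient(0, 0.5, grid, tab, background = 0),
               rep(0, length(grid)))
  # sox = 1 gives bvf * mua_oxy + background exactly
  got <- absorption_coefficient(0.2, 1, grid, tab, background = 0.3)
  expect_equal(got, 0.2 * tab$mua_oxy + 0.3, tolerance = 1e-12)
  # at an isosbestic crossing of the packaged table, mua is sox-independent
  d <- tab$mua_oxy - tab$mua_deoxy
  k <- which(d[-1] * d[-length(d)] < 0)[1]  # sign change between k, k+1
  expect_true(!is.na(k))
  lam <- grid[k] + (grid[k + 1] - grid[k]) * d[k] / (d[k] - d[k + 1])
  m0 <- absorption_coefficient(0.25, 0, lam, tab)
  m1 <- absorption_coefficient(0.25, 1, lam, tab)
  expect_equal(m0, m1, tolerance = 1e-6 * m0)
  expect_error(absorption_coefficient(0.5, 0.5, 500, tab),
               class = "speclight_error_config")
})

test_that("layered reflectance is deterministic, bounded, and monotone in absorption", {
  grid <- wavelength_grid()
  tab <- chromophore_table(grid)
  s <- sample_tissue(5, seed = 3)
  r1 <- reflectance_spectrum(s, grid, tab)
  r2 <- reflectance_spectrum(s, grid, tab)
  expect_identical(r1, r2)
  expect_true(all(r1 >= 0 & r1 <= 1))
  # no absorption anywhere -> constant r_max = 0.85
  s0 <- s[1, ]
  s0[paste0("bvf_", 1:3)] <- 0
  s0$mua_background <- 0
  expect_equal(as.numeric(reflectance_spectrum(s0, grid, tab)),
               rep(0.85, length(grid)), tolerance = 1e-12)
  # increasing first-layer bvf strictly decreases reflectance where blood absorbs
  sA <- s[2, ]; sA$thickness_um_1 <- 1500
  sB <- sA; sA$bvf_1 <- 0.05; sB$bvf_1 <- 0.25
  rA <- as.numeric(reflectance_spectrum(sA, grid, tab))
  rB <- as.numeric(reflectance_spectrum(sB, grid, tab))
  strong <- tab$mua_oxy > 5 | tab$mua_deoxy > 5
  expect_true(all(rB[strong] < rA[strong]))
})

test_that("band integration matches the closed-form rectangle case and is linear", {
  # xi = 1 on [500, 600], r = 1, L = 1 -> integral = 100
  grid <- seq(500, 600, by = 2)
  cam <- camera_model(grid = grid, n_bands = 2,
                      centers = c(525, 575), fwhm = 20)
  cam$response[1, ] <- 1  # overwrite band 1 with the flat response
  out <- band_integrate(rep(1, length(grid)), rep(1, length(grid)), cam)
  expect_equal(unname(out[1, 1]), 100, tolerance = 1e-12)
  # linear in alpha
  r <- runif(length(grid))
  L <- runif(length(grid))
  b1 <- band_integrate(r, L, cam, alpha = 1)
  b2 <- band_integrate(r, L, cam, alpha = 2)
  expect_equal(b2, 2 * b1, tolerance = 1e-12)
  # sigma_w = 0 is deterministic; fixed seed reproduces noise
  n1 <- band_integrate(r, L, cam, sigma_w = 0.1, seed = 5)
  n2 <- band_integrate(r, L, cam, sigma_w = 0.1, seed = 5)
  expect_identical(n1, n2)
  expect_error(band_integrate(r[-1], L, cam),
               class = "speclight_error_dimension_mismatch")
})

test_that("flat reflectance makes normalized bands equal the normalized illuminant", {
  # the dichromatic fact behind the whole method: spectrally flat (specular)
  # pixels carry pure illuminant information
  cam <- test_camera()
  ill <- reference_illuminants(cam$grid)
  for (L in ill) {
    flat <- band_integrate(rep(0.4, length(cam$grid)), L, cam)
    pure <- band_integrate(rep(1, length(cam$grid)), L, cam)
    expect_equal(l1_normalize(as.numeric(flat)), l1_normalize(as.numeric(pure)),
                 tolerance = 1e-12)
  }
})

test_that("pseudo-hemoglobin mode works without the packaged fixture", {
  grid <- wavelength_grid()
  tab <- chromophore_table(grid, source = "pseudo")
  expect_true(all(tab$mua_oxy > 0) && all(tab$mua_deoxy > 0))
  r <- reflectance_spectrum(sample_tissue(3, seed = 1), grid, tab)
  expect_true(all(r >= 0 & r <= 1))
})
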