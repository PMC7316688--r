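#' Model-based baseline illuminant estimators
#'
#' Four classical single-image color-constancy estimators extended to
#' multispectral cubes, used as comparison baselines for the
#' specular-highlight method:
#'
#' * `max_rgb()` — per-band maximum over the considered pixels (white-patch
#'   assumption: some pixel reflects the illuminant maximally in each band).
#' * `gray_world()` — per-band mean (the scene average is achromatic).
#' * `shades_of_gray()` — per-band Minkowski mean of order `p`
#'   (`p = 1` is gray-world, `p = Inf` is max-band; default `p = 6`).
#' * `gray_edge()` — Minkowski mean of the Gaussian-smoothed
#'   gradient-magnitude image per band (the average reflectance *derivative*
#'   is achromatic).
#'
#' All outputs are L1-normalized spectra and invariant to global positive
#' rescaling of the cube. The optional `mask` restricts the pixels considered
#' (e.g. to the valid-pixel set of the specular-highlight method) so
#' comparisons at a given exposure are like-for-like; the default considers
#' every pixel, the convention in the color-constancy literature.
#'
#' @param cube A [spectral_cube()].
#' @param mask Optional logical matrix of pixels to consider (default: all).
#' @param p Minkowski order, `>= 1` or `Inf`.
#' @param sigma Gaussian smoothing standard deviation in pixels (gray-edge).
#' @return An `illuminant_spectrum` (sums to 1).
#' @name baseline_estimators
NULL

considered_pixels <- function(cube, mask) {
  d <- dim(cube$data)
  flat <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  if (is.null(mask)) return(flat)
  if (!all(dim(mask) == d[1:2])) stop_dimension("Mask and cube shapes differ.")
  keep <- as.vector(mask)
  if (!any(keep)) stop_degenerate("Mask selects no pixels.")
  flat[keep, , drop = FALSE]
}

minkowski_mean <- function(m, p) {
  if (is.infinite(p)) return(apply(m, 2, max))
  if (p < 1) stop_config("Minkowski order p must be >= 1 (or Inf).")
  # scale each band by its own maximum so large p cannot underflow a band
  s <- apply(m, 2, max)
  s[s <= 0] <- 1
  scaled <- sweep(m, 2, s, "/")
  (colMeans(scaled^p))^(1 / p) * s
}

#' @rdname baseline_estimators
#' @export
max_rgb <- function(cube, mask = NULL) {
  m <- considered_pixels(cube, mask)
  illuminant_spectrum(l1_normalize(apply(m, 2, max)), band_ids = cube$band_ids,
                      normalize = FALSE)
}

#' @rdname baseline_estimators
#' @export
gray_world <- function(cube, mask = NULL) {
  m <- considered_pixels(cube, mask)
  illuminant_spectrum(l1_normalize(colMeans(m)), band_ids = cube$band_ids,
                      normalize = FALSE)
}

#' @rdname baseline_estimators
#' @export
shades_of_gray <- function(cube, mask = NULL, p = 6) {
  m <- considered_pixels(cube, mask)
  illuminant_spectrum(l1_normalize(minkowski_mean(m, p)), band_ids = cube$band_ids,
                      normalize = FALSE)
}

# Separable Gaussian smoothing with reflection padding.
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

reflect_index <- function(n, r) {
  # indices -r+1 .. n+r mapped by reflection (edge duplicated)
  idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
  idx[idx < 1] <- 1; idx[idx > n] <- n
  idx
}

smooth_band <- function(img, kernel) {
  r <- (length(kernel) - 1L) / 2L
  n1 <- nrow(img); n2 <- ncol(img)
  pad <- img[reflect_index(n1, r), reflect_index(n2, r), drop = FALSE]
  # rows then cols
  a <- apply(pad, 2, function(cl) as.numeric(stats::filter(cl, kernel, sides = 2)))
  a <- a[(r + 1):(r + n1), , drop = FALSE]
  b <- t(apply(a, 1, function(rw) as.numeric(stats::filter(rw, kernel, sides = 2))))
  b[, (r + 1):(r + n2), drop = FALSE]
}

gradient_magnitude <- function(img) {
  n1 <- nrow(img); n2 <- ncol(img)
  di <- (img[c(2:n1, n1), ] - img[c(1, 1:(n1 - 1)), ]) / 2
  dj <- (img[, c(2:n2, n2)] - img[, c(1, 1:(n2 - 1))]) / 2
  sqrt(di^2 + dj^2)
}

#' @rdname baseline_estimators
#' @export
gray_edge <- function(cube, mask = NULL, p = 6, sigma = 2) {
  d <- dim(cube$data)
  if (d[1] < 3 || d[2] < 3) stop_dimension("gray_edge needs at least 3 x 3 pixels.")
  if (!is.numeric(sigma) || sigma <= 0) stop_config("`sigma` must be > 0.")
  kern <- gaussian_kernel(sigma)
  border <- max(1L, ceiling(3 * sigma))
  interior <- matrix(FALSE, d[1], d[2])
  if (d[1] > 2 * border && d[2] > 2 * border) {
    interior[(border + 1):(d[1] - border), (border + 1):(d[2] - border)] <- TRUE
  } else {
    interior[2:(d[1] - 1), 2:(d[2] - 1)] <- TRUE
  }
  keep <- if (is.null(mask)) interior else (mask & interior)
  if (!any(keep)) stop_degenerate("Mask leaves no interior pixels.")
  grads <- vapply(seq_len(d[3]), function(k) {
    g <- gradient_magnitude(smooth_band(cube$data[, , k], kern))
    g[keep]
  }, numeric(sum(keep)))
  if (sum(grads^2) < 1e-12) {
    stop_degenerate("No gradient energy in any band (uniform image).")
  }
  est <- minkowski_mean(grads, p)
  illuminant_spectrum(l1_normalize(est), band_ids = cube$band_ids, normalize = FALSE)
}
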