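#' Multispectral image cube
#'
#' A lightweight container for a `rows x cols x bands` stack of intensities in
#' ADC counts, optionally tagged with the exposure time it was recorded at.
#' Axis order is fixed as (row, col, band).
#'
#' @param data Numeric array of dimension `rows x cols x bands` (at least two
#'   bands), all values finite and non-negative.
#' @param exposure_ms Optional exposure time in milliseconds (> 0).
#' @param band_ids Optional character vector of band labels, one per band;
#'   defaults to `"b01"`, `"b02"`, ...
#' @return An object of class `spectral_cube`.
#' @examples
#' cube <- spectral_cube(array(1, dim = c(4, 4, 3)), exposure_ms = 10)
#' dim(cube$data)
#' @export
spectral_cube <- function(data, exposure_ms = NULL, band_ids = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3) {
    stop_dimension("`data` must be a 3-d array (rows x cols x bands).")
  }
  d <- dim(data)
  if (d[1] < 1 || d[2] < 1 || d[3] < 2) {
    stop_dimension("Cube needs >= 1 row, >= 1 column and >= 2 bands.")
  }
  if (anyNA(data) || any(!is.finite(data)) || any(data < 0)) {
    stop_degenerate("Cube intensities must be finite and >= 0.")
  }
  if (!is.null(exposure_ms)) {
    if (!is.numeric(exposure_ms) || length(exposure_ms) != 1 || exposure_ms <= 0) {
      stop_config("`exposure_ms` must be a single positive number.")
    }
    exposure_ms <- as.numeric(exposure_ms)
  }
  if (is.null(band_ids)) band_ids <- sprintf("b%02d", seq_len(d[3]))
  if (length(band_ids) != d[3]) stop_dimension("One band id per band required.")
  structure(
    list(data = data, exposure_ms = exposure_ms, band_ids = as.character(band_ids)),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<spectral_cube> %d x %d px, %d bands%s, range [%g, %g]\n",
    d[1], d[2], d[3],
    if (is.null(x$exposure_ms)) "" else sprintf(", %g ms", x$exposure_ms),
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

n_bands <- function(cube) dim(cube$data)[3]

#' Angular error between two spectra
#'
#' The Euclidean angle between two spectra treated as vectors, in degrees.
#' Scale-invariant: multiplying either argument by a positive constant leaves
#' the angle unchanged.
#'
#' @param u,v Numeric vectors of equal length, neither all-zero.
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' angular_error(c(1, 1), c(1, 0)) # 45
#' @export
angular_error <- function(u, v) {
  if (length(u) != length(v)) stop_dimension("Spectra must have equal length.")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop_degenerate("Angular error undefined for zero vectors.")
  ct <- sum(u * v) / (nu * nv)
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

#' L1-normalize a spectrum
#'
#' @param s Non-negative numeric vector with positive sum.
#' @return A vector proportional to `s` summing to 1.
#' @export
l1_normalize <- function(s) {
  if (anyNA(s) || any(s < 0)) stop_degenerate("Spectrum entries must be >= 0.")
  tot <- sum(s)
  if (tot <= 0) stop_degenerate("Cannot normalize an all-zero spectrum.")
  s / tot
}

#' Per-pixel lightness of a cube
#'
#' Lightness is the mean intensity across bands at each pixel.
#'
#' @param cube A [spectral_cube()].
#' @return A `rows x cols` numeric matrix.
#' @export
lightness <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  rowMeans(matrix(cube$data, nrow = d[1] * d[2], ncol = d[3]), na.rm = FALSE) |>
    matrix(nrow = d[1], ncol = d[2])
}

#' Project spectra onto the principal plane of a reference set
#'
#' Fits a (centered, unscaled) PCA basis on the reference spectra only and
#' projects both references and query spectra onto the first two components.
#' The sign of each component is fixed by making its largest-magnitude loading
#' positive, so coordinates are reproducible.
#'
#' @param spectra Matrix (rows = spectra) or list of query spectra.
#' @param references Matrix (rows = spectra) or list of at least two reference
#'   spectra of the same length as the queries.
#' @return A tibble with columns `id`, `role` ("reference" or "query"),
#'   `pc1`, `pc2`.
#' @export
pca_project <- function(spectra, references) {
  as_mat <- function(x) {
    if (is.list(x)) x <- do.call(rbind, x)
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    x
  }
  q <- as_mat(spectra); r <- as_mat(references)
  if (nrow(r) < 2) stop_config("At least two reference spectra are required.")
  if (ncol(q) != ncol(r)) stop_dimension("Query and reference spectra lengths differ.")
  fit <- prcomp(r, center = TRUE, scale. = FALSE, rank. = 2)
  rot <- fit$rotation
  if (ncol(rot) < 2) rot <- cbind(rot, 0)  # rank-1 reference set
  for (j in 1:2) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) rot[, j] <- -rot[, j]
  }
  proj <- function(m) sweep(m, 2, fit$center) %*% rot[, 1:2]
  pr <- proj(r); pq <- proj(q)
  tibble::tibble(
    id = c(
      if (!is.null(rownames(r))) rownames(r) else sprintf("ref%d", seq_len(nrow(r))),
      if (!is.null(rownames(q))) rownames(q) else sprintf("query%d", seq_len(nrow(q)))
    ),
    role = rep(c("reference", "query"), c(nrow(r), nrow(q))),
    pc1 = c(pr[, 1], pq[, 1]),
    pc2 = c(pr[, 2], pq[, 2])
  )
}
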