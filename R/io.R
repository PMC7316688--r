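#' Write a cube to disk
#'
#' Multi-page TIFF (one 16-bit page per band, lossless for integer ADC
#' counts) or ENVI (flat binary + `.hdr` text header, band-sequential
#' uint16). A JSON sidecar (`<path>.json`) records exposure, band ids and the
#' scale used, so [read_cube()] restores the cube bit-exactly.
#'
#' @param cube A [spectral_cube()] with integer-valued counts.
#' @param path Output path; format from extension (`.tif`/`.tiff` or
#'   `.envi`/`.raw`) or the `format` argument.
#' @param format `"tiff"` or `"envi"` (default: from extension).
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = NULL, overwrite = FALSE) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (file.exists(path) && !overwrite) {
    stop_io(paste0("File exists (use overwrite = TRUE): ", path))
  }
  if (is.null(format)) {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "envi"
  }
  d <- dim(cube$data)
  mx <- 65535
  if (any(cube$data != round(cube$data)) || max(cube$data) > mx) {
    stop_format("Cube must hold integer counts within 16 bits for storage.")
  }
  if (format == "tiff") {
    pages <- lapply(seq_len(d[3]), function(k) cube$data[, , k] / mx)
    ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
    if (!isTRUE(ok) && !is.numeric(ok)) stop_io("TIFF write failed.")
  } else {
    hdr <- sub("\\.[A-Za-z]+$", "", path)
    writeLines(c(
      "ENVI",
      paste0("samples = ", d[2]),
      paste0("lines = ", d[1]),
      paste0("bands = ", d[3]),
      "header offset = 0",
      "file type = ENVI Standard",
      "data type = 12",
      "interleave = bsq",
      "byte order = 0"
    ), paste0(hdr, ".hdr"))
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    # bsq: band-major, row-major within band
    for (k in seq_len(d[3])) {
      writeBin(as.integer(t(cube$data[, , k])), con, size = 2, endian = "little")
    }
  }
  jsonlite::write_json(
    list(exposure_ms = cube$exposure_ms, band_ids = cube$band_ids,
         rows = d[1], cols = d[2], bands = d[3], scale = mx, format = format),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' Read a cube from disk
#'
#' Reads TIFF stacks or ENVI cubes written by [write_cube()]. Exposure comes
#' from the JSON sidecar when present, else from a `*_<ms>ms.<ext>` filename
#' convention.
#'
#' @param path Cube path.
#' @return A [spectral_cube()].
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop_not_found(paste0("No such file: ", path))
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else NULL
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2) stop_format("Cube file must hold at least two bands.")
    scale <- if (!is.null(side)) side$scale else 65535
    data <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) data[, , k] <- round(pages[[k]] * scale)
  } else {
    if (is.null(side)) {
      hdr_path <- paste0(sub("\\.[A-Za-z]+$", "", path), ".hdr")
      if (!file.exists(hdr_path)) stop_format("ENVI cube needs a .hdr or sidecar.")
      hdr <- readLines(hdr_path)
      grab <- function(key) {
        ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
        as.integer(sub(".*= *", "", ln[1]))
      }
      dims <- c(grab("lines"), grab("samples"), grab("bands"))
    } else {
      dims <- c(side$rows, side$cols, side$bands)
    }
    if (dims[3] < 2) stop_format("Cube file must hold at least two bands.")
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    data <- array(0, dim = dims)
    for (k in seq_len(dims[3])) {
      v <- readBin(con, "integer", n = dims[1] * dims[2], size = 2,
                   signed = FALSE, endian = "little")
      data[, , k] <- t(matrix(v, nrow = dims[2]))
    }
  }
  exposure <- NULL
  if (!is.null(side) && !is.null(side$exposure_ms)) {
    exposure <- side$exposure_ms
  } else {
    m <- regmatches(path, regexec("_([0-9.]+)ms\\.[A-Za-z]+$", path))[[1]]
    if (length(m) == 2) exposure <- as.numeric(m[2])
  }
  band_ids <- if (!is.null(side)) unlist(side$band_ids) else NULL
  spectral_cube(data, exposure_ms = exposure, band_ids = band_ids)
}

#' Read a delimited table of labeled spectra
#'
#' Expects columns `id`, `band` (or `wavelength`), `value`; groups rows by
#' `id` and validates that every group has the same length and non-negative
#' values.
#'
#' @param path CSV path.
#' @return Named list of numeric spectra.
#' @export
read_spectra_table <- function(path) {
  if (!file.exists(path)) stop_not_found(paste0("No such file: ", path))
  d <- read.csv(path)
  axis <- intersect(c("band", "wavelength"), names(d))
  if (!("id" %in% names(d)) || length(axis) == 0 || !("value" %in% names(d))) {
    stop_format("Need columns id, band (or wavelength), value.")
  }
  if (any(d$value < 0)) stop_format("Spectrum values must be >= 0.")
  sp <- split(d, d$id)
  lens <- vapply(sp, nrow, integer(1))
  if (length(unique(lens)) != 1) stop_format("Ragged spectra groups.")
  lapply(sp, function(g) setNames(g$value, g[[axis[1]]]))
}

#' Write an illuminant spectrum as CSV
#'
#' @param spectrum An `illuminant_spectrum` (or named numeric vector).
#' @param path Output CSV (`band_id`, `value` columns).
#' @param overwrite Refuse to clobber unless `TRUE`.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop_io(paste0("File exists (use overwrite = TRUE): ", path))
  }
  ids <- if (is.null(names(spectrum))) sprintf("b%02d", seq_along(spectrum)) else
    names(spectrum)
  write.csv(data.frame(band_id = ids, value = as.numeric(spectrum)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read/write dark-current statistics
#'
#' CSV with columns `exposure_ms`, `dark_mean`, `dark_std` as consumed by
#' [exposure_series()].
#'
#' @param path CSV path.
#' @return Tibble of dark statistics.
#' @export
read_dark_stats <- function(path) {
  if (!file.exists(path)) stop_not_found(paste0("No such file: ", path))
  d <- tibble::as_tibble(read.csv(path))
  need <- c("exposure_ms", "dark_mean", "dark_std")
  if (!all(need %in% names(d))) stop_format("Need exposure_ms, dark_mean, dark_std.")
  d
}

#' @rdname read_dark_stats
#' @param stats Dark statistics data frame.
#' @param overwrite Refuse to clobber unless `TRUE`.
#' @export
write_dark_stats <- function(stats, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop_io(paste0("File exists (use overwrite = TRUE): ", path))
  }
  write.csv(stats, path, row.names = FALSE)
  invisible(path)
}

#' Read an exposure series from a directory
#'
#' Expects cube files named `*_<ms>ms.tif` (or `.envi`/`.raw`) plus a
#' `dark_stats.csv` table.
#'
#' @param dir Directory path.
#' @return An [exposure_series()].
#' @export
read_exposure_series <- function(dir) {
  if (!dir.exists(dir)) stop_not_found(paste0("No such directory: ", dir))
  files <- list.files(dir, pattern = "_[0-9.]+ms\\.(tiff?|envi|raw)$",
                      full.names = TRUE)
  if (length(files) == 0) stop_not_found("No cube files found in directory.")
  cubes <- lapply(files, read_cube)
  ord <- order(vapply(cubes, function(x) x$exposure_ms, numeric(1)))
  dark <- read_dark_stats(file.path(dir, "dark_stats.csv"))
  exposure_series(cubes[ord], dark)
}

#' Write an exposure series to a directory
#'
#' @param series An [exposure_series()].
#' @param dir Output directory (created if needed).
#' @param format `"tiff"` or `"envi"`.
#' @param overwrite Refuse to clobber unless `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_exposure_series <- function(series, dir, format = "tiff", overwrite = FALSE) {
  stopifnot(inherits(series, "exposure_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "tiff") "tif" else "envi"
  for (cube in series$cubes) {
    write_cube(cube, file.path(dir, sprintf("cube_%gms.%s", cube$exposure_ms, ext)),
               format = format, overwrite = overwrite)
  }
  write_dark_stats(series$dark_stats, file.path(dir, "dark_stats.csv"),
                   overwrite = overwrite)
  invisible(dir)
}
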