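#' @importFrom rlang abort .data
#' @importFrom stats approx median prcomp predict quantile rnorm runif sd setNames spline
#' @importFrom utils read.csv write.csv
NULL

# Condition helpers: every error raised by the package carries a
# "speclight_error_<category>" class so callers (and the CLI) can dispatch.
stop_speclight <- function(message, category, ...) {
  abort(message, class = c(paste0("speclight_error_", category), "speclight_error"), ...)
}

stop_degenerate <- function(message) stop_speclight(message, "degenerate_input")
stop_dimension  <- function(message) stop_speclight(message, "dimension_mismatch")
stop_config     <- function(message) stop_speclight(message, "config")
stop_no_highlights <- function(message) stop_speclight(message, "no_highlights")
stop_format     <- function(message) stop_speclight(message, "format")
stop_not_found  <- function(message) stop_speclight(message, "not_found")
stop_io         <- function(message) stop_speclight(message, "io")

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream; seed = NULL runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop_config("`seed` must be a single finite number or NULL.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive k reproducible child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, k)))
}

# Trapezoidal quadrature weights for an (increasing) grid.
trapezoid_weights <- function(x) {
  n <- length(x)
  if (n < 2) stop_dimension("Need at least two grid points for quadrature.")
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}
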