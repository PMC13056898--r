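#' Wrap angles into (-180, 180]
#'
#' Signed angles are used throughout the package with counterclockwise
#' positive. `wrap_angle()` maps any angle in degrees onto the half-open
#' interval (-180, 180], so that e.g. 190 becomes -170 and -180 becomes 180.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped to (-180, 180].
#' @examples
#' wrap_angle(c(0, 190, -180, 360, 725))
#' @export
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  # %% maps -180 to -180; the interval is half-open at the bottom
  w[w == -180] <- 180
  w
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Moving average with shrinking windows at the series ends, so every output
# sample is the mean of the available samples within +/- (k-1)/2 positions.
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
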