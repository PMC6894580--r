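# Circular statistics on hue angles. Internal math in radians; every
# user-facing value in degrees.

#' Wrap angles to (-180, 180] degrees
#'
#' @param x Angles in degrees.
#' @return Wrapped angles; the convention maps 180 to +180 (not -180), so a
#'   reported 350 vs a true 10 gives an error of -20, never +340.
#' @export
wrap_angle_deg <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180 & !is.na(w)] <- 180
  w
}

# mean resultant length of angles in degrees
.resultant_length <- function(deg) {
  th <- deg * pi / 180
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

.circ_mean_deg <- function(deg) {
  th <- deg * pi / 180
  wrap_angle_deg(atan2(mean(sin(th)), mean(cos(th))) * 180 / pi)
}

#' Angular deviation of a sample of angles
#'
#' The circular spread \eqn{\sqrt{2(1 - R)}} (in degrees), where R is the mean
#' resultant length. For uniform angles it tends to \eqn{\sqrt 2} rad
#' (about 81.03 degrees).
#'
#' @param deg Angles in degrees.
#' @return Angular deviation in degrees.
#' @export
angular_deviation_deg <- function(deg) {
  sqrt(2 * (1 - .resultant_length(deg))) * 180 / pi
}

#' Circular summary of report errors
#'
#' Computes the wrapped error (reported minus true), its circular mean via the
#' resultant vector, the circular variance (1 - R) and the angular deviation
#' \eqn{\sqrt{2(1-R)}} in degrees.
#'
#' @param reported_deg Reported hues in degrees, or (if `true_deg` is `NULL`)
#'   precomputed errors.
#' @param true_deg True hues in degrees.
#' @return A list of class `ib_circular`: `circular_mean_deg`,
#'   `angular_deviation_deg`, `circular_variance`, `resultant_length`, `n`,
#'   and the wrapped `errors_deg`.
#' @export
#' @examples
#' circular_error_summary(c(350, 30), c(10, 20))$circular_mean_deg
circular_error_summary <- function(reported_deg, true_deg = NULL) {
  err <- if (is.null(true_deg)) reported_deg else reported_deg - true_deg
  err <- wrap_angle_deg(err[!is.na(err)])
  if (length(err) == 0) stop("no non-missing errors to summarise")
  R <- .resultant_length(err)
  structure(
    list(
      circular_mean_deg = .circ_mean_deg(err),
      angular_deviation_deg = sqrt(2 * (1 - R)) * 180 / pi,
      circular_variance = 1 - R,
      resultant_length = R,
      n = length(err),
      errors_deg = err
    ),
    class = "ib_circular"
  )
}

#' @export
print.ib_circular <- function(x, ...) {
  cat(sprintf(
    "circular mean %.1f deg (angular deviation = %.1f), n = %d\n",
    x$circular_mean_deg, x$angular_deviation_deg, x$n))
  invisible(x)
}

#' von Mises random angles
#'
#' Best--Fisher rejection sampler for the von Mises distribution; `kappa = 0`
#' falls back to uniform angles.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction in degrees.
#' @param kappa Concentration (>= 0).
#' @return Angles in degrees, wrapped to (-180, 180] around 0 then shifted to
#'   `[0, 360)` positions on the hue circle.
#' @export
rvonmises_deg <- function(n, mu_deg = 0, kappa = 1) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, theta)
  }
  (mu_deg + out[seq_len(n)] * 180 / pi) %% 360
}
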