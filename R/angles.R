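#' Wrap an angle in degrees to (-180, 180]
#'
#' All user-facing angles in fovadapt are signed degrees with the clockwise
#' direction positive (the direction of a "rightward" rotation of the
#' vehicle's motion relative to the fish's heading). This helper maps any
#' angle onto the principal range.
#'
#' @param deg numeric vector of angles in degrees.
#' @return numeric vector in (-180, 180].
#' @examples
#' wrap_angle(c(0, 180, -180, 270, 361))
#' @export
wrap_angle <- function(deg) {
  out <- ((deg + 180) %% 360) - 180
  # %% maps 180 -> -180; keep the convention that +180 is the representative
  out[out == -180] <- 180
  out
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' Draw von Mises distributed angles
#'
#' Circular noise model for simulated fish headings. Uses the
#' Best-Fisher (1979) acceptance-rejection algorithm; `kappa = 0` gives the
#' uniform distribution on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction, degrees.
#' @param kappa concentration (>= 0); larger is tighter. For large `kappa`
#'   the distribution approaches a normal with sd `1/sqrt(kappa)` radians.
#' @return numeric vector of `n` angles in degrees, wrapped to (-180, 180].
#' @export
rvonmises <- function(n, mu = 0, kappa = 20) {
  stopifnot(length(n) == 1L, n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(wrap_angle(runif(n, -180, 180)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      theta <- sign(u[3] - 0.5) * acos(f)
      out[i] <- theta
      i <- i + 1L
    }
  }
  wrap_angle(mu + rad2deg(out))
}
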