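# Geometry constants used throughout: ideal tetrahedral angle between
# successive rotation axes, and the H-C bond angle to the methyl axis.
TETRA_DEG <- 109.4712206344907  # acos(-1/3), degrees
HC_AXIS_DEG <- 110.5            # H-C bond to methyl rotation axis, degrees
GAS_R <- 8.314                  # J mol^-1 K^-1

#' Second Legendre polynomial
#'
#' @param x Numeric vector, typically a cosine of an angle.
#' @return `(3 x^2 - 1) / 2`.
#' @keywords internal
#' @noRd
p2 <- function(x) (3 * x^2 - 1) / 2

#' Wrap angles into (-180, 180]
#' @noRd
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Circular standard deviation (degrees) of an angle series
#' @noRd
circ_sd_deg <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  rad2deg(sqrt(-2 * log(rbar)))
}

#' Circular mean (degrees)
#' @noRd
circ_mean_deg <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  rad2deg(atan2(mean(sin(th)), mean(cos(th))))
}

# Rotation of an n x 3 matrix about z by per-row angles (radians)
rot_z_rows <- function(v, phi) {
  cp <- cos(phi); sp <- sin(phi)
  cbind(cp * v[, 1] - sp * v[, 2],
        sp * v[, 1] + cp * v[, 2],
        v[, 3])
}

# Fixed rotation about y by angle (radians), applied to n x 3 matrix
rot_y_fixed <- function(v, ang) {
  ca <- cos(ang); sa <- sin(ang)
  cbind(ca * v[, 1] + sa * v[, 3],
        v[, 2],
        -sa * v[, 1] + ca * v[, 3])
}

#' Log-spaced lag indices
#'
#' Roughly `per_decade` unique integer lags per decade from 0 up to
#' `max_lag`, always including 0 and 1.
#' @noRd
log_lags <- function(max_lag, per_decade = 50) {
  if (max_lag < 1) return(0L)
  raw <- 10^seq(0, log10(max_lag), by = 1 / per_decade)
  sort(unique(c(0L, 1L, as.integer(round(raw)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
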