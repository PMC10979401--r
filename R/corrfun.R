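#' Orientation trajectory
#'
#' Container for a time series of unit bond vectors (for example the
#' methyl H-C bond) sampled at a fixed timestep.
#'
#' @param vectors Numeric matrix with one row per frame and three columns
#'   (x, y, z). Every row must be a unit vector to within `tol`.
#' @param dt Timestep in seconds between successive rows; must be > 0.
#' @param label Optional site label.
#' @param tol Tolerance on the vector norms (default `1e-8`).
#'
#' @return An object of class `orientation_trajectory`: a list with
#'   elements `vectors`, `dt` and `label`.
#' @export
#' @examples
#' v <- matrix(rep(c(0, 0, 1), 5), ncol = 3, byrow = TRUE)
#' orientation_trajectory(v, dt = 1e-12)
orientation_trajectory <- function(vectors, dt, label = NULL, tol = 1e-8) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2) stop("need at least 2 time points")
  if (ncol(vectors) != 3) stop("vectors must have 3 columns")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(abs(nrm - 1) > tol)) {
    stop("non-unit vectors beyond tolerance (max |norm - 1| = ",
         signif(max(abs(nrm - 1)), 3), ")")
  }
  structure(list(vectors = vectors, dt = dt, label = label),
            class = "orientation_trajectory")
}

new_corr_fn <- function(lag, value, dt = NA_real_, S2 = NA_real_,
                        label = NULL) {
  out <- tibble::tibble(lag = lag, value = value)
  structure(out, class = c("corr_fn", class(out)),
            dt = dt, S2 = S2, label = label)
}

#' Rank-2 reorientational correlation function
#'
#' Computes `C(t) = < P2(u(tau) . u(tau + t)) >_tau`, the rank-2
#' autocorrelation of a unit-vector time series, averaged over all start
#' times with valid endpoints. This is the correlation function whose
#' plateau is the squared order parameter S2 and whose decay drives
#' dipolar NMR relaxation.
#'
#' @param traj An [orientation_trajectory()], or a plain n x 3 matrix of
#'   unit vectors (then `dt` must be given).
#' @param lags Integer lag indices (in frames). Default: log-spaced,
#'   about 50 per decade, up to half the trajectory length.
#' @param dt Timestep in seconds when `traj` is a bare matrix.
#' @param linear Logical; if `TRUE` use every lag up to `max_lag`
#'   instead of log spacing.
#' @param max_lag Largest lag index considered (default `n - 1` for
#'   explicit `lags`, `floor(n/2)` otherwise).
#'
#' @return A `corr_fn` tibble with columns `lag` (seconds) and `value`,
#'   carrying attributes `dt` and `S2` (plateau estimate: mean of C over
#'   the final decade of lags).
#' @export
#' @examples
#' v <- matrix(rep(c(0, 0, 1), 100), ncol = 3, byrow = TRUE)
#' cf <- rank2_correlation(orientation_trajectory(v, dt = 1e-12))
#' all(cf$value == 1)
rank2_correlation <- function(traj, lags = NULL, dt = NULL,
                              linear = FALSE, max_lag = NULL) {
  if (inherits(traj, "orientation_trajectory")) {
    v <- traj$vectors
    dt <- traj$dt
    label <- traj$label
  } else {
    v <- as.matrix(traj)
    if (is.null(dt)) stop("dt required when traj is a bare matrix")
    label <- NULL
  }
  n <- nrow(v)
  if (n < 2) stop("empty or too-short trajectory")
  if (is.null(lags)) {
    mx <- max_lag %||% (n %/% 2)
    lags <- if (linear) 0:mx else log_lags(mx)
  }
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 0) || any(lags >= n)) {
    stop("requested lags must lie in [0, trajectory length)")
  }
  vals <- vapply(lags, function(k) {
    if (k == 0) return(1)
    d <- rowSums(v[seq_len(n - k), , drop = FALSE] *
                   v[(k + 1):n, , drop = FALSE])
    mean(p2(d))
  }, numeric(1))
  S2 <- plateau_estimate(lags * dt, vals)
  new_corr_fn(lags * dt, vals, dt = dt, S2 = S2, label = label)
}

# Plateau estimate: mean of C over the last decade of (positive) lags.
plateau_estimate <- function(lag_s, value) {
  pos <- lag_s > 0
  if (!any(pos)) return(NA_real_)
  tmax <- max(lag_s[pos])
  mean(value[pos & lag_s >= tmax / 10])
}

#' Multi-exponential model correlation function
#'
#' Evaluates `C(t) = S2 + (1 - S2) * sum_i A_i exp(-t / tau_i)`, the
#' standard partition of the decay amplitude `1 - S2` over discrete
#' correlation times.
#'
#' @param S2 Plateau (squared order parameter), in `[0, 1]`.
#' @param A Amplitudes, non-negative, summing to 1 (tolerance 1e-9).
#' @param tau Correlation times in seconds, positive, same length as `A`.
#' @param lags Lag times in seconds at which to evaluate.
#'
#' @return A `corr_fn` tibble.
#' @export
#' @examples
#' model_corrfn(1 / 9, 1, 1e-9, c(0, 1e-9))
model_corrfn <- function(S2, A, tau, lags) {
  if (length(A) != length(tau)) stop("A and tau lengths differ")
  if (any(A < 0)) stop("amplitudes must be >= 0")
  if (abs(sum(A) - 1) > 1e-9) stop("amplitudes must sum to 1")
  if (any(tau <= 0)) stop("tau must be > 0")
  if (S2 < 0 || S2 > 1) stop("S2 must lie in [0, 1]")
  vals <- vapply(lags, function(t) {
    S2 + (1 - S2) * sum(A * exp(-t / tau))
  }, numeric(1))
  new_corr_fn(as.numeric(lags), vals, S2 = S2)
}

#' Log-timescale distribution of correlation times
#'
#' A density `theta(z)` on `z = log10(tau / s)`, normalised to unit
#' trapezoid integral, together with the total decay amplitude `1 - S2`.
#'
#' @param z Uniform grid of `log10(tau / s)` values.
#' @param theta Non-negative density values on `z`.
#' @param amplitude Total amplitude `1 - S2`, in `[0, 1]`.
#' @param normalize If `TRUE` (default) rescale `theta` to unit integral.
#'
#' @return An object of class `timescale_distribution`.
#' @export
timescale_distribution <- function(z, theta, amplitude, normalize = TRUE) {
  if (length(z) != length(theta)) stop("z and theta lengths differ")
  if (any(theta < 0)) stop("theta must be >= 0")
  if (amplitude < 0 || amplitude > 1) stop("amplitude must lie in [0, 1]")
  tot <- pracma::trapz(z, theta)
  if (normalize && tot > 0) theta <- theta / tot
  tot <- pracma::trapz(z, theta)
  if (abs(tot - 1) > 1e-6) stop("theta does not integrate to 1")
  structure(list(z = z, theta = theta, amplitude = amplitude),
            class = "timescale_distribution")
}

#' Delta-like timescale distribution at one correlation time
#'
#' Convenience constructor: all density concentrated at the grid point
#' nearest `log10(tau)`, represented as a narrow triangle so the
#' trapezoid integral is exactly 1.
#'
#' @param tau Correlation time, seconds.
#' @param z Grid of `log10(tau / s)`.
#' @param amplitude `1 - S2`.
#' @return A [timescale_distribution()].
#' @export
delta_distribution <- function(tau, z, amplitude) {
  k <- which.min(abs(z - log10(tau)))
  th <- numeric(length(z))
  dz <- z[2] - z[1]
  th[k] <- 1 / dz  # triangle of base 2*dz, trapezoid integral 1
  timescale_distribution(z, th, amplitude, normalize = TRUE)
}

#' @export
print.corr_fn <- function(x, ...) {
  cat("<corr_fn> ", nrow(x), " lags",
      if (!is.na(attr(x, "S2"))) paste0(", plateau S2 ~ ",
                                        signif(attr(x, "S2"), 4)), "\n",
      sep = "")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.corr_fn <- function(x, ...) {
  tibble::tibble(lag = x$lag, value = x$value)
}

#' @export
glance.corr_fn <- function(x, ...) {
  tibble::tibble(n_lags = nrow(x), S2 = attr(x, "S2"),
                 dt = attr(x, "dt"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.corr_fn <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$lag > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lag time (s)", y = "C(t)") +
    ggplot2::theme_minimal()
}

#' Write / read a correlation function as delimited text
#'
#' Plain two-column whitespace-delimited text with `#`-prefixed metadata
#' header lines (dt, S2, label).
#'
#' @param x A `corr_fn`.
#' @param path File path.
#' @return `write_corrfn` returns `path` invisibly; `read_corrfn`
#'   returns a `corr_fn`.
#' @export
write_corrfn <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# dt ", format(attr(x, "dt") %||% NA, digits = 17)),
    paste0("# S2 ", format(attr(x, "S2") %||% NA, digits = 17)),
    paste0("# label ", attr(x, "label") %||% "NA"),
    "lag value"), con)
  utils::write.table(format(as.data.frame(x)[, c("lag", "value")],
                            digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_corrfn
#' @export
read_corrfn <- function(path) {
  ln <- readLines(path)
  meta <- ln[startsWith(ln, "#")]
  getm <- function(key) {
    m <- meta[grepl(paste0("^# ", key, " "), meta)]
    if (!length(m)) return(NA)
    sub(paste0("^# ", key, " "), "", m[1])
  }
  d <- utils::read.table(text = ln[!startsWith(ln, "#")], header = TRUE)
  lab <- getm("label")
  new_corr_fn(d$lag, d$value,
              dt = suppressWarnings(as.numeric(getm("dt"))),
              S2 = suppressWarnings(as.numeric(getm("S2"))),
              label = if (identical(lab, "NA")) NULL else lab)
}
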