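#' Librational order parameter of a methyl H-C bond
#'
#' The rank-2 order parameter of small-angle rotational fluctuation
#' about the methyl axis: `S_lib^2 = E[ P2( u(phi1) . u(phi2) ) ]` for
#' a unit vector at 110.5 degrees to the axis, rotated by independent
#' Gaussian angles `phi1, phi2 ~ N(0, sigma^2)`. With
#' `delta = phi1 - phi2 ~ N(0, 2 sigma^2)` and
#' `u(phi1) . u(phi2) = sin^2(beta) cos(delta) + cos^2(beta)`, the
#' Gaussian moments `E[cos delta] = exp(-sigma^2)` and
#' `E[cos 2 delta] = exp(-4 sigma^2)` give the exact value
#'
#'   `S_lib^2 = (3 (a^2 (1 + e^{-4 s^2}) / 2 + 2 a b e^{-s^2} + b^2) - 1) / 2`
#'
#' with `a = sin^2 beta`, `b = cos^2 beta`, `s = sigma`. Decreases
#' monotonically from 1 (sigma = 0) to `P2(cos beta)^2 ~ 1/9`
#' (free rotation).
#'
#' @param sigma Librational circular standard deviation(s), radians.
#' @param beta_deg Bond-to-axis angle in degrees (default 110.5).
#' @return `S_lib^2`, same length as `sigma`.
#' @export
#' @examples
#' libration_order_parameter(0)      # 1
#' libration_order_parameter(10)     # about 1/9
libration_order_parameter <- function(sigma, beta_deg = HC_AXIS_DEG) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  b <- cos(deg2rad(beta_deg))^2
  a <- 1 - b
  (3 * (a^2 * (1 + exp(-4 * sigma^2)) / 2 +
          2 * a * b * exp(-sigma^2) + b^2) - 1) / 2
}

#' Fit the methyl hop-time / libration line
#'
#' Both the methyl hopping time and the librational amplitude are set
#' by the rotation barrier, making `log10(tau_met)` approximately
#' linear in `sigma_libr^-2`. Ordinary least squares with a single
#' outlier-rejection pass: points deviating by more than 2 residual
#' standard deviations from the preliminary fit are excluded and the
#' line refitted.
#'
#' @param pairs Data frame with columns `tau` (seconds) and `sigma`
#'   (radians), one row per methyl site; at least 4 rows.
#' @return A `methyl_line` object: `intercept` (log10 s), `slope`
#'   (log10 s rad^2), `excluded` (row indices), `sigma_fit` (residual
#'   SD of the final fit) and the input data.
#' @export
#' @examples
#' d <- data.frame(sigma = c(0.1, 0.15, 0.2, 0.3))
#' d$tau <- 10^(-11 + 0.02 / d$sigma^2)
#' fit_methyl_line(d)
fit_methyl_line <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("tau", "sigma") %in% names(pairs)))
  if (nrow(pairs) < 4) stop("need at least 4 sites")
  if (any(pairs$tau <= 0) || any(pairs$sigma <= 0)) {
    stop("tau and sigma must be > 0")
  }
  x <- pairs$sigma^-2
  y <- log10(pairs$tau)
  fit0 <- stats::lm(y ~ x)
  res <- stats::residuals(fit0)
  s0 <- stats::sd(res)
  excluded <- if (s0 > 0) which(abs(res) > 2 * s0) else integer(0)
  keep <- setdiff(seq_along(x), excluded)
  if (length(keep) < 3) stop("fewer than 3 points survive outlier rejection")
  fit <- stats::lm(y[keep] ~ x[keep])
  co <- unname(stats::coef(fit))
  structure(list(intercept = co[1], slope = co[2],
                 excluded = excluded,
                 sigma_fit = stats::sd(stats::residuals(fit)),
                 data = tibble::tibble(tau = pairs$tau,
                                       sigma = pairs$sigma,
                                       excluded = seq_along(x) %in%
                                         excluded)),
            class = "methyl_line")
}

#' @export
print.methyl_line <- function(x, ...) {
  cat("<methyl_line> log10(tau) = ", signif(x$intercept, 4), " + ",
      signif(x$slope, 4), " / sigma^2  (", length(x$excluded),
      " excluded)\n", sep = "")
  invisible(x)
}

#' @export
tidy.methyl_line <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.methyl_line <- function(x, ...) {
  tibble::tibble(sigma_fit = x$sigma_fit, n_excluded = length(x$excluded),
                 n_used = nrow(x$data) - length(x$excluded))
}

#' @export
autoplot.methyl_line <- function(object, ...) {
  d <- object$data
  d$x <- d$sigma^-2
  d$y <- log10(d$tau)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$excluded)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope) +
    ggplot2::labs(x = expression(sigma[libr]^-2),
                  y = expression(log[10](tau[met] / s))) +
    ggplot2::theme_minimal()
}

# sigma on the line for a given tau: log10(tau) = a + b / sigma^2
line_sigma <- function(line, tau) {
  lx <- log10(tau) - line$intercept
  if (line$slope > 0) {
    ifelse(lx > 0, sqrt(line$slope / lx), Inf)
  } else {
    ifelse(lx < 0, sqrt(line$slope / lx), Inf)
  }
}

#' Model detector responses for methyl hopping plus libration
#'
#' Responses of the methyl model
#' `C(t) = S_lib^2 (1/9 + (8/9) exp(-t / tau))` with the fast
#' librational amplitude `1 - S_lib^2` placed at the fastest grid
#' point: evaluates each detector at the two timescales.
#'
#' @param tau Methyl hopping correlation time, seconds.
#' @param sigma Librational SD in radians (give either `sigma` or a
#'   `line` from which it is interpolated).
#' @param det A `detector_set`.
#' @param line Optional `methyl_line` used to slave `sigma` to `tau`.
#' @return Numeric vector of model responses, one per detector.
#' @export
methyl_model_responses <- function(tau, det, sigma = NULL, line = NULL) {
  if (is.null(sigma)) {
    if (is.null(line)) stop("give sigma or a methyl_line")
    sigma <- line_sigma(line, tau)
  }
  s2l <- libration_order_parameter(sigma)
  rho_at <- function(zq) {
    apply(det$rho, 1, function(r) {
      stats::approx(det$z, r, xout = zq, rule = 2)$y
    })
  }
  (1 - s2l) * rho_at(min(det$z)) + s2l * (8 / 9) * rho_at(log10(tau))
}

#' Extract methyl hopping time and librational amplitude from detector
#' responses
#'
#' One-dimensional fit over tau: the methyl model
#' `C(t) = S_lib^2(sigma(tau)) (1/9 + (8/9) e^{-t/tau})`, with sigma
#' slaved to tau through the fitted line, is matched to the
#' methyl-dominated detector responses (the two fastest windows by
#' default) by least squares on a log10(tau) grid refined by golden
#' section.
#'
#' @param responses A `detector_responses` (or numeric vector, one per
#'   detector).
#' @param det The `detector_set`.
#' @param line A `methyl_line` relating tau and sigma.
#' @param use Indices (0-based detector ids) entering the fit; default
#'   `c(0, 1)`.
#' @param tau_range Search range in seconds (default 1e-14 to 1e-8).
#'
#' @return A `methyl_params` object: `tau_met` (s), `sigma_libr`
#'   (radians), `sigma_libr_deg`, `source`, `objective` and a
#'   `boundary` flag set when the optimum sits at the edge of the
#'   search range.
#' @export
extract_methyl_params <- function(responses, det, line, use = c(0, 1),
                                  tau_range = c(1e-14, 1e-8)) {
  resp <- if (inherits(responses, "detector_responses")) {
    responses$response
  } else {
    as.numeric(responses)
  }
  idx <- use + 1L
  if (any(idx > length(resp))) stop("responses must include the used windows")
  target <- resp[idx]
  if (all(abs(target) < 1e-12)) {
    stop("zero-amplitude responses: methyl fit is undefined")
  }
  obj <- function(l10tau) {
    m <- methyl_model_responses(10^l10tau, det, line = line)
    sum((m[idx] - target)^2)
  }
  # coarse scan (the objective need not be unimodal), then refine
  lo <- log10(tau_range)
  grid <- seq(lo[1], lo[2], length.out = 121)
  ov <- vapply(grid, obj, numeric(1))
  i0 <- which.min(ov)
  bracket <- c(grid[max(1, i0 - 1)], grid[min(length(grid), i0 + 1)])
  opt <- stats::optimize(obj, bracket, tol = 1e-6)
  if (ov[i0] < opt$objective) {
    opt <- list(minimum = grid[i0], objective = ov[i0])
  }
  boundary <- min(opt$minimum - lo[1], lo[2] - opt$minimum) < 1e-2
  if (boundary) {
    warning("methyl fit optimum at the edge of the tau search range")
  }
  tau <- 10^opt$minimum
  sigma <- line_sigma(line, tau)
  structure(list(tau_met = tau, sigma_libr = sigma,
                 sigma_libr_deg = rad2deg(sigma), source = "total-fit",
                 objective = opt$objective, boundary = boundary),
            class = "methyl_params")
}

#' @export
print.methyl_params <- function(x, ...) {
  cat("<methyl_params> tau_met = ", signif(x$tau_met, 4), " s, sigma_libr = ",
      signif(x$sigma_libr_deg, 4), " deg (", x$source, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.methyl_params <- function(x, ...) {
  tibble::tibble(tau_met = x$tau_met, sigma_libr = x$sigma_libr,
                 sigma_libr_deg = x$sigma_libr_deg, source = x$source)
}

#' Factor methyl hopping and libration out of detector responses
#'
#' Subtracts the methyl-model responses (fixed at the supplied
#' parameters) from the total responses; because the detector fit is
#' linear in the measurements, this equals refitting the
#' measurement-space data with the methyl contribution removed. The
#' remaining (non-methyl) responses report slower side-chain motion,
#' whose amplitude in the total correlation function is scaled by the
#' methyl plateau `S_lib^2 / 9`; the `rescaled` column multiplies the
#' residual by `9 / S_lib^2` to undo that factor, matching the
#' convention of multiplying methyl hopping by 9 when comparing it
#' with chi1/chi2 hopping. The fastest window is ambiguous between
#' fast and slow motion, so its residual amplitude is optionally split
#' in half across both sides.
#'
#' @param responses Total `detector_responses` (or numeric vector).
#' @param det The `detector_set`.
#' @param params A `methyl_params` object.
#' @param split_rho0 Halve the first window's residual across a fast
#'   and a slow entry (default `TRUE`).
#' @return A tibble with columns `detector`, `side`, `residual`,
#'   `rescaled`; negative residuals beyond 3 sigma of the response
#'   uncertainty trigger an error.
#' @export
factor_out_methyl <- function(responses, det, params, split_rho0 = TRUE) {
  if (inherits(responses, "detector_responses")) {
    resp <- responses$response
    sd <- responses$sd
  } else {
    resp <- as.numeric(responses)
    sd <- rep(0, length(resp))
  }
  model <- methyl_model_responses(params$tau_met, det,
                                  sigma = params$sigma_libr)
  res <- resp - model
  tolv <- pmax(3 * sd, 0.02)
  if (any(res < -tolv)) {
    stop("methyl parameters inconsistent with responses: residual ",
         signif(min(res), 3), " below -3 sigma")
  }
  s2l <- libration_order_parameter(params$sigma_libr)
  out <- tibble::tibble(detector = seq_along(res) - 1L,
                        side = "slow",
                        residual = res,
                        rescaled = res * 9 / s2l)
  if (split_rho0) {
    r0 <- out[1, ]
    out <- out[-1, ]
    half <- r0
    half$residual <- r0$residual / 2
    half$rescaled <- r0$rescaled / 2
    fast <- half
    fast$side <- "fast"
    out <- dplyr::bind_rows(fast, half, out)
  }
  out
}
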