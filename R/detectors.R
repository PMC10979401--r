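#' Optimise timescale-specific detector windows
#'
#' Recombines the leading singular vectors of a sensitivity matrix into
#' `n` non-negative, timescale-localised windows rho_n(z) ("detectors").
#' Each window is obtained by bound-constrained least squares on the
#' grid values: the linear objective `integral rho(z) (z - z0)^2 dz` is
#' minimised subject to rho >= 0, rho(z0) = 1 and a quadratic penalty
#' keeping rho in the span of the top-`n` singular vectors; anchor
#' positions are initialised at quantiles of the covered grid region and
#' updated to the sensitivity-weighted mean over a few passes. Windows
#' are returned ordered by ascending centre. The completed set
#' approximately partitions unity over the region where the
#' truncated-SVD subspace can represent a constant.
#'
#' @param sens A `sensitivity_set` from [nmr_sensitivities()] or
#'   [md_sensitivities()].
#' @param n Number of detectors; at most the number of measurements.
#' @param mode Normalisation: `"max1"` (each window's maximum is 1; the
#'   response then reports amplitude within the window) or `"integral"`
#'   (each window integrates to 1; the response then estimates
#'   `(1 - S2) theta(z)` at the window centre).
#' @param anchors Optional explicit anchor positions on z (length `n`).
#'
#' @return A `detector_set`: grid `z`, matrix `rho` (detector x grid),
#'   centres `z0`, the SVD basis and coefficients used for response
#'   fitting, and the normalisation mode and per-detector scale.
#' @export
#' @examples
#' det <- optimize_detectors(md_sensitivities(10^seq(-10, -7, 0.25)), 3)
#' det$z0
optimize_detectors <- function(sens, n, mode = c("max1", "integral"),
                               anchors = NULL) {
  mode <- match.arg(mode)
  m <- nrow(sens$R)
  if (n < 1) stop("n must be >= 1")
  if (n > m) stop("n exceeds the number of measurements")
  z <- sens$z
  k <- length(z)
  dz <- z[2] - z[1]
  Rn <- sens$R / sens$scale          # row-normalised sensitivities
  sv <- svd(Rn)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (n > rank) {
    warning("n exceeds numerical rank (", rank, "); reduced")
    n <- rank
  }
  B <- sv$v[, seq_len(n), drop = FALSE]          # k x n z-space basis

  # covered region: where the subspace can represent the constant 1
  one_proj <- as.numeric(B %*% crossprod(B, rep(1, k)))
  covered <- abs(one_proj - 1) < 0.05
  if (!any(covered)) covered <- one_proj > 0.5 * max(one_proj)

  if (is.null(anchors)) {
    # equal partition of the subspace leverage diag(B B^T): anchors sit
    # where the truncated basis has resolving power
    lev <- rowSums(B^2)
    cl <- cumsum(lev) / sum(lev)
    anchors <- vapply(seq_len(n), function(i) {
      z[which.min(abs(cl - (i - 0.5) / n))]
    }, numeric(1))
  }
  if (length(anchors) != n) stop("need one anchor per detector")
  min_sep <- max(2 * dz, diff(range(z[covered])) / (2 * n))
  anchors <- spread_anchors(sort(anchors), min_sep = min_sep,
                            lo = min(z), hi = max(z))

  rho <- optimize_windows(B, z, anchors)
  # one refinement pass with anchors at the realised window peaks
  a2 <- sort(vapply(seq_len(n), function(i) z[which.max(rho[i, ])],
                    numeric(1)))
  a2 <- spread_anchors(a2, min_sep = min_sep, lo = min(z), hi = max(z))
  if (max(abs(a2 - anchors)) > dz) rho <- optimize_windows(B, z, a2)
  rho[rho < 0 & rho > -1e-9] <- 0
  ctr <- apply(rho, 1, function(r) sum(pmax(r, 0) * z) / sum(pmax(r, 0)))
  ord <- order(ctr)
  rho <- rho[ord, , drop = FALSE]

  scale <- switch(mode,
                  max1 = apply(rho, 1, max),
                  integral = apply(rho, 1, function(r) pracma::trapz(z, r)))
  rho_n <- rho / scale
  z0 <- apply(rho_n, 1, function(r) sum(pmax(r, 0) * z) / sum(pmax(r, 0)))
  structure(list(z = z, rho = rho_n, rho_raw = rho, z0 = z0, mode = mode,
                 scale = scale, basis = B, covered = covered,
                 sens_kind = sens$kind),
            class = "detector_set")
}

# Push sorted anchor positions apart to at least min_sep, clamped to
# the grid range.
spread_anchors <- function(a, min_sep, lo, hi) {
  n <- length(a)
  if (n == 1) return(a)
  for (pass in 1:10) {
    moved <- FALSE
    for (i in 2:n) {
      if (a[i] - a[i - 1] < min_sep) {
        mid <- (a[i] + a[i - 1]) / 2
        a[i - 1] <- mid - min_sep / 2
        a[i] <- mid + min_sep / 2
        moved <- TRUE
      }
    }
    a <- pmin(pmax(a, lo), hi)
    if (!moved) break
  }
  a
}

# Joint window optimisation: all n shapes at once, bound-constrained
# (rho >= 0) least squares with a linear width objective
# sum_i rho_i(z) (z - a_i)^2, a quadratic penalty towards span(B) and a
# quadratic partition-of-unity penalty sum_z (sum_i rho_i(z) - P1(z))^2,
# where P1 is the subspace projection of the constant. Convex;
# L-BFGS-B with analytic gradient, then an exact projection into the
# span so responses live in the measurable subspace.
optimize_windows <- function(B, z, anchors, l_span = 5e3, l_one = 5e3) {
  k <- length(z)
  n <- length(anchors)
  W <- t(vapply(anchors, function(a) {
    w <- (z - a)^2
    w / max(w)
  }, numeric(k)))
  one_proj <- as.numeric(B %*% crossprod(B, rep(1, k)))
  eps <- (z[2] - z[1]) / 2
  init <- t(vapply(seq_len(n), function(i) {
    a <- anchors[i]
    left <- if (i == 1) min(z) - 1 else anchors[i - 1]
    right <- if (i == n) max(z) + 1 else anchors[i + 1]
    h <- ifelse(z < a, (z - left) / max(a - left, eps),
                (right - z) / max(right - a, eps))
    pmax(pmin(h, 1), 0)
  }, numeric(k)))
  fn <- function(p) {
    Rho <- matrix(p, n, k)
    span_resid <- Rho - Rho %*% B %*% t(B)
    s <- colSums(Rho) - one_proj
    sum(W * Rho) / k + l_span * sum(span_resid^2) / k +
      l_one * sum(s^2) / k
  }
  gr <- function(p) {
    Rho <- matrix(p, n, k)
    span_resid <- Rho - Rho %*% B %*% t(B)
    s <- colSums(Rho) - one_proj
    as.numeric(W / k + 2 * l_span * span_resid / k +
                 2 * l_one * matrix(s, n, k, byrow = TRUE) / k)
  }
  opt <- stats::optim(as.numeric(init), fn, gr, method = "L-BFGS-B",
                      lower = 0, control = list(maxit = 2000))
  matrix(opt$par, n, k) %*% B %*% t(B)
}

#' @export
print.detector_set <- function(x, ...) {
  cat("<detector_set> ", nrow(x$rho), " detectors (", x$mode,
      " normalisation), centres z0 = ",
      paste(round(x$z0, 2), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.detector_set <- function(x, ...) {
  n <- nrow(x$rho)
  tibble::tibble(
    detector = rep(seq_len(n) - 1L, each = length(x$z)),
    z = rep(x$z, n),
    rho = as.numeric(t(x$rho)))
}

#' @export
glance.detector_set <- function(x, ...) {
  tibble::tibble(n_detectors = nrow(x$rho), mode = x$mode,
                 z0_min = min(x$z0), z0_max = max(x$z0))
}

#' @export
autoplot.detector_set <- function(object, ...) {
  d <- tidy(object)
  d$detector <- factor(d$detector)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z, y = .data$rho,
                                  colour = .data$detector)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(log[10](tau / s)), y = expression(rho[n](z)),
                  colour = "detector") +
    ggplot2::theme_minimal()
}

#' Detector responses of a timescale distribution
#'
#' Evaluates `rho_n = (1 - S2) integral theta(z) rho_n(z) dz` by the
#' trapezoid rule: the amplitude of motion each window reports for a
#' known distribution of correlation times.
#'
#' @param dist A [timescale_distribution()], on the same grid as `det`.
#' @param det A `detector_set`.
#' @return A `detector_responses` tibble with columns `detector`,
#'   `response`, `sd` (zero here: no measurement noise).
#' @export
responses_from_distribution <- function(dist, det) {
  if (length(dist$z) != length(det$z) ||
      max(abs(dist$z - det$z)) > 1e-9) {
    stop("distribution grid does not match detector grid")
  }
  resp <- apply(det$rho, 1, function(r) {
    dist$amplitude * pracma::trapz(det$z, dist$theta * r)
  })
  new_detector_responses(resp, rep(0, length(resp)), det)
}

new_detector_responses <- function(response, sd, det, extra = NULL) {
  out <- tibble::tibble(detector = seq_along(response) - 1L,
                        response = as.numeric(response),
                        sd = as.numeric(sd))
  structure(out, class = c("detector_responses", class(out)),
            detector_set = det, extra = extra)
}

#' @export
tidy.detector_responses <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("detector", "response", "sd")])
}

#' @export
autoplot.detector_responses <- function(object, ...) {
  d <- tidy(object)
  det <- attr(object, "detector_set")
  d$z0 <- det$z0[d$detector + 1L]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z0, y = .data$response)) +
    ggplot2::geom_col(width = 0.3, fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$response - .data$sd,
                                        ymax = .data$response + .data$sd),
                           width = 0.1) +
    ggplot2::labs(x = expression(z[0] == log[10](tau / s)),
                  y = "detector response") +
    ggplot2::theme_minimal()
}

# Back-calculation design matrix G mapping detector responses to
# (row-normalised) measurements: m = G x within the truncated subspace.
detector_design <- function(sens, det) {
  z <- det$z
  k <- length(z)
  wtz <- rep(z[2] - z[1], k)
  wtz[c(1, k)] <- wtz[1] / 2          # trapezoid weights
  B <- det$basis
  # subspace coefficients a: responses x = Mx a, measurements m = H a
  Mx <- det$rho %*% (wtz * B)                  # n x n
  H <- (sens$R / sens$scale) %*% (wtz * B)     # m x n
  H %*% solve(Mx)
}

#' Back-calculate measurements from detector responses
#'
#' @param responses A `detector_responses` object.
#' @param sens The `sensitivity_set` the detectors were built from.
#' @param det The `detector_set`.
#' @param S2 Optional plateau added to MD lag measurements.
#' @return Numeric vector of measurements in the original units
#'   (s^-1 for rates, dimensionless for correlation values).
#' @export
backcalc_measurements <- function(responses, sens, det, S2 = 0) {
  G <- detector_design(sens, det)
  m <- as.numeric(G %*% responses$response) * sens$scale
  if (sens$kind == "md") m <- m + S2
  m
}

#' Fit detector responses to measured data
#'
#' Weighted least squares in the truncated-SVD subspace: finds the
#' responses whose back-calculated measurements minimise chi^2, with 1
#' sigma uncertainties propagated from the covariance. If any response
#' is negative, a non-negative refit is reported alongside the
#' unconstrained covariance (soft constraint).
#'
#' @param data Numeric vector of measured rates (s^-1) or correlation
#'   values, one per measurement in `sens`.
#' @param sigma Measurement standard deviations (same length; default
#'   uniform).
#' @param sens The `sensitivity_set` describing the measurements.
#' @param det The `detector_set` to fit.
#' @param fit_plateau For MD lag data: also fit the long-time plateau S2
#'   as an extra offset parameter (default `TRUE` for kind `"md"`).
#' @param nonneg Apply the soft non-negativity refit (default `TRUE`).
#'
#' @return A `detector_responses` tibble; attribute `extra` holds the
#'   fitted plateau (if any) and chi^2.
#' @export
fit_responses <- function(data, sigma = NULL, sens, det,
                          fit_plateau = identical(sens$kind, "md"),
                          nonneg = TRUE) {
  m <- nrow(sens$R)
  if (length(data) != m) stop("data length must equal measurement count")
  sigma <- sigma %||% rep(1, m)
  if (any(sigma <= 0)) stop("sigma must be > 0")
  G <- detector_design(sens, det)
  y <- data / sens$scale
  sig <- sigma / sens$scale
  X <- G
  if (fit_plateau) X <- cbind(G, 1 / sens$scale)
  Xw <- X / sig
  yw <- y / sig
  qx <- qr(Xw)
  if (qx$rank < ncol(Xw)) warning("singular design; minimum-norm solution")
  beta <- qr.coef(qx, yw)
  beta[is.na(beta)] <- 0
  cov <- tryCatch(solve(crossprod(Xw)), error = function(e) {
    MASSish <- svd(crossprod(Xw))
    d <- ifelse(MASSish$d > max(MASSish$d) * 1e-12, 1 / MASSish$d, 0)
    MASSish$v %*% (d * t(MASSish$u))
  })
  se <- sqrt(pmax(diag(cov), 0))
  nresp <- nrow(det$rho)
  resp <- beta[seq_len(nresp)]
  if (nonneg && any(resp < 0)) {
    beta_nn <- nnls_fit(Xw, yw)
    resp <- beta_nn[seq_len(nresp)]
    beta <- beta_nn
  }
  chi2 <- sum((yw - Xw %*% beta)^2)
  extra <- list(chi2 = chi2)
  if (fit_plateau) extra$S2 <- unname(beta[nresp + 1])
  new_detector_responses(resp, se[seq_len(nresp)], det, extra = extra)
}

#' Write / read a detector set as delimited text
#'
#' @param x A `detector_set`.
#' @param path File path.
#' @export
write_detectors <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# mode ", x$mode),
               paste0("# kind ", x$sens_kind),
               paste0("# z0 ", paste(format(x$z0, digits = 17),
                                     collapse = " ")),
               paste0("# scale ", paste(format(x$scale, digits = 17),
                                        collapse = " ")),
               paste0("# z ", paste(format(x$z, digits = 17),
                                    collapse = " "))), con)
  utils::write.table(format(t(rbind(x$rho, t(x$basis))), digits = 17),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_detectors
#' @export
read_detectors <- function(path) {
  ln <- readLines(path)
  meta <- ln[startsWith(ln, "#")]
  get1 <- function(key) sub(paste0("^# ", key, " "), "",
                            meta[grepl(paste0("^# ", key, " "), meta)][1])
  z <- as.numeric(strsplit(get1("z"), " +")[[1]])
  z0 <- as.numeric(strsplit(get1("z0"), " +")[[1]])
  scale <- as.numeric(strsplit(get1("scale"), " +")[[1]])
  M <- t(as.matrix(utils::read.table(text = ln[!startsWith(ln, "#")])))
  n <- length(z0)
  rho <- M[seq_len(n), , drop = FALSE]
  basis <- t(M[-seq_len(n), , drop = FALSE])
  dimnames(rho) <- NULL
  structure(list(z = z, rho = rho, rho_raw = rho * scale, z0 = z0,
                 mode = get1("mode"),
                 scale = scale, basis = basis,
                 covered = rep(TRUE, length(z)),
                 sens_kind = get1("kind")),
            class = "detector_set")
}
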