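#' Assign rotamer states with hysteresis
#'
#' Nearest-centre assignment of a dihedral series to the staggered
#' wells, recording a transition only once the angle comes within a
#' margin (default 30 degrees) of a new centre. The hysteresis keeps
#' libration from inflating hop counts.
#'
#' @param dihedral Angle series in degrees, wrapped to (-180, 180].
#' @param centers State centres in degrees (default -60, 60, 180).
#' @param margin Capture radius in degrees for switching state.
#' @param dt Timestep in seconds.
#' @return A `state_trajectory`: list with integer `state` series,
#'   `dt`, `centers` and `n_states`.
#' @export
#' @examples
#' st <- assign_states(c(-60, -50, 70, 60), dt = 1e-12)
#' st$state
assign_states <- function(dihedral, centers = c(-60, 60, 180),
                          margin = 30, dt) {
  dihedral <- wrap_deg(dihedral)
  dmat <- abs(wrap_deg(outer(dihedral, centers, "-")))
  nearest <- max.col(-dmat)
  within <- dmat[cbind(seq_along(dihedral), nearest)] <= margin
  state <- integer(length(dihedral))
  state[1] <- nearest[1]
  # switch only when captured inside a *different* well's margin
  cur <- nearest[1]
  for (i in seq_along(dihedral)[-1]) {
    if (nearest[i] != cur && within[i]) cur <- nearest[i]
    state[i] <- cur
  }
  structure(list(state = state, dt = dt, centers = centers,
                 n_states = length(centers)),
            class = "state_trajectory")
}

#' Joint two-dihedral state trajectory
#'
#' Combines chi1 and chi2 state series into joint labels
#' `(chi1 - 1) * 3 + chi2` on 1..9.
#'
#' @param chi1,chi2 `state_trajectory` objects with equal length and dt.
#' @return A `state_trajectory` with 9 states.
#' @export
joint_states <- function(chi1, chi2) {
  stopifnot(length(chi1$state) == length(chi2$state),
            chi1$dt == chi2$dt)
  structure(list(state = (chi1$state - 1L) * chi2$n_states + chi2$state,
                 dt = chi1$dt, centers = NULL,
                 n_states = chi1$n_states * chi2$n_states),
            class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat("<state_trajectory> ", length(x$state), " frames, ",
      x$n_states, " states, dt = ", x$dt, " s\n", sep = "")
  invisible(x)
}

#' Binned hop rates and state occupancies
#'
#' Splits a state trajectory into consecutive bins, counting
#' transitions per bin (rate = hops / bin duration) and the fraction
#' of frames spent in each state. The study's default binning is 200
#' bins of 50 ns.
#'
#' @param states A `state_trajectory`.
#' @param bin_duration Bin length in seconds (>= 10 dt).
#' @return A `hop_rate_series` tibble: `bin`, `rate` (s^-1) and one
#'   occupancy column `p<i>` per state.
#' @export
binned_hop_rates <- function(states, bin_duration) {
  dt <- states$dt
  if (bin_duration < 10 * dt) stop("bin duration must be >= 10 dt")
  per_bin <- as.integer(round(bin_duration / dt))
  bin_duration <- per_bin * dt       # effective duration on the grid
  n <- length(states$state)
  n_bins <- n %/% per_bin
  if (n_bins < 1) stop("trajectory shorter than one bin")
  s <- states$state[seq_len(n_bins * per_bin)]
  bin <- rep(seq_len(n_bins), each = per_bin)
  hops <- c(0L, as.integer(s[-1] != s[-length(s)]))
  # a hop across a bin boundary is credited to the later bin
  rate <- as.numeric(tapply(hops, bin, sum)) / bin_duration
  occ <- vapply(seq_len(states$n_states), function(i) {
    as.numeric(tapply(s == i, bin, mean))
  }, numeric(n_bins))
  colnames(occ) <- paste0("p", seq_len(states$n_states))
  out <- tibble::tibble(bin = seq_len(n_bins), rate = rate)
  out <- dplyr::bind_cols(out, tibble::as_tibble(occ))
  structure(out, class = c("hop_rate_series", class(out)),
            bin_duration = bin_duration, dt = dt)
}

#' Rank-2 order parameter of tetrahedral 3-site exchange
#'
#' `S^2 = sum_ij p_i p_j P2(cos beta_ij)` with `beta_ii = 0` and
#' `beta_ij = 109.47` degrees between distinct wells; reduces to
#' `1 - (8/3)(p1 p2 + p1 p3 + p2 p3)`. Equal populations give the
#' tetrahedral floor 1/9 (total hopping amplitude 8/9).
#'
#' @param p Numeric vector of three populations summing to 1 (order
#'   irrelevant).
#' @return `S^2` in `[1/9, 1]`.
#' @export
#' @examples
#' order_param_3site(c(1, 1, 1) / 3)  # 1/9
order_param_3site <- function(p) {
  if (length(p) != 3) stop("need three populations")
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-9) {
    stop("populations must be non-negative and sum to 1")
  }
  1 - (8 / 3) * (p[1] * p[2] + p[1] * p[3] + p[2] * p[3])
}

#' Rotamer populations from a dipolar order parameter
#'
#' Inverts [order_param_3site()] for the measured |S| of a
#' methyl-bearing site under one of three population models:
#' `p3 = 0` (valid for S^2 in \[1/3, 1\]), `p2 = p3` (S^2 in
#' \[1/9, 1\]) or `p1 = p2` (S^2 in \[1/9, 1/3\]). Measured methyl |S|
#' values are optionally rescaled by the fast methyl-rotation factor
#' |P2(cos 110.5 deg)| ~ 1/3 before inversion.
#'
#' @param S Measured |S| (dimensionless).
#' @param model `"p3=0"`, `"p2=p3"` or `"p1=p2"`.
#' @param rescale Divide |S| by |P2(cos 110.5 deg)| first (default
#'   `FALSE`: |S| already refers to the hopping frame).
#' @return Sorted populations `c(p1, p2, p3)` with `p1 >= p2 >= p3`.
#' @export
#' @examples
#' populations_from_S(1, "p3=0")           # (1, 0, 0)
#' populations_from_S(1 / 3, "p2=p3")      # equal thirds
populations_from_S <- function(S, model = c("p3=0", "p2=p3", "p1=p2"),
                               rescale = FALSE) {
  model <- match.arg(model)
  if (rescale) S <- S / abs(p2(cos(deg2rad(HC_AXIS_DEG))))
  s2 <- S^2
  if (s2 < 1 / 9 - 1e-9) stop("|S| below the tetrahedral floor 1/3")
  s2 <- max(s2, 1 / 9)
  eps <- 1e-9
  pops <- switch(
    model,
    "p3=0" = {
      if (s2 < 1 / 3 - eps) stop("model {p3=0} invalid: S^2 < 1/3")
      q <- 3 * (1 - s2) / 8          # p1 p2
      p1 <- (1 + sqrt(max(1 - 4 * q, 0))) / 2
      c(p1, 1 - p1, 0)
    },
    "p2=p3" = {
      disc <- 256 / 9 - 32 * (1 - s2)
      p2s <- (16 / 3 - sqrt(max(disc, 0))) / 16
      c(1 - 2 * p2s, p2s, p2s)
    },
    "p1=p2" = {
      if (s2 > 1 / 3 + eps) stop("model {p1=p2} invalid: S^2 > 1/3")
      disc <- 256 / 9 - 32 * (1 - s2)
      p1 <- (16 / 3 + sqrt(max(disc, 0))) / 16
      c(p1, p1, 1 - 2 * p1)
    })
  sort(pmin(pmax(pops, 0), 1), decreasing = TRUE)
}

#' Select the population model for a measured |S|
#'
#' Among the models valid for the given |S|, picks the one whose
#' inverted populations lie closest (Euclidean) to a reference — in
#' practice populations observed in simulation.
#'
#' @param S Measured |S|.
#' @param reference Numeric reference populations (sorted or not).
#' @param rescale Passed to [populations_from_S()].
#' @return A list with `model`, `populations` and `distance`.
#' @export
select_model <- function(S, reference, rescale = FALSE) {
  reference <- sort(reference, decreasing = TRUE)
  models <- c("p3=0", "p2=p3", "p1=p2")
  cand <- lapply(models, function(m) {
    tryCatch(populations_from_S(S, m, rescale = rescale),
             error = function(e) NULL)
  })
  ok <- !vapply(cand, is.null, logical(1))
  if (!any(ok)) stop("no population model is valid for |S| = ", S)
  d <- vapply(cand[ok], function(p) sqrt(sum((p - reference)^2)),
              numeric(1))
  best <- which(ok)[which.min(d)]
  list(model = models[best], populations = cand[[best]],
       distance = min(d))
}

#' State-dependent hop rates from binned data
#'
#' Fits `<R_hop>_bin = sum_i R_hop^i p_bin^i` across bins by
#' non-negative least squares: the per-state rates that best predict
#' each bin's mean hopping rate from its state occupancies. The
#' Pearson correlation between observed and back-calculated bin rates
#' measures how much of the rate variability the current state
#' explains; a flat prediction with low correlation signals hidden
#' (state-external) modulation.
#'
#' @param series A `hop_rate_series` from [binned_hop_rates()].
#' @return A `state_rates` object: `rates` (s^-1 per state),
#'   `predicted` per bin, `correlation` (NA when undefined, with a
#'   `flag`), and the input series.
#' @export
fit_state_rates <- function(series) {
  pcols <- grep("^p[0-9]+$", names(series), value = TRUE)
  P <- as.matrix(series[pcols])
  y <- series$rate
  if (nrow(P) < ncol(P)) stop("need at least as many bins as states")
  qrP <- qr(P)
  flag <- NULL
  if (qrP$rank < ncol(P)) {
    flag <- "occupancy matrix rank-deficient; minimum-norm solution"
    warning(flag)
  }
  rates <- nnls_fit(P, y)
  pred <- as.numeric(P %*% rates)
  correlation <- if (stats::sd(pred) == 0 || stats::sd(y) == 0) {
    flag <- c(flag, "correlation undefined (constant series)")
    NA_real_
  } else {
    stats::cor(y, pred)
  }
  structure(list(rates = rates, predicted = pred, observed = y,
                 correlation = correlation, flag = flag,
                 series = series),
            class = "state_rates")
}

#' @export
print.state_rates <- function(x, ...) {
  cat("<state_rates> R_hop per state (s^-1): ",
      paste(signif(x$rates, 4), collapse = ", "),
      "; r = ", signif(x$correlation, 3), "\n", sep = "")
  if (!is.null(x$flag)) cat(" note: ", paste(x$flag, collapse = "; "),
                            "\n", sep = "")
  invisible(x)
}

#' @export
tidy.state_rates <- function(x, ...) {
  tibble::tibble(state = seq_along(x$rates), rate = x$rates)
}

#' @export
glance.state_rates <- function(x, ...) {
  tibble::tibble(correlation = x$correlation,
                 n_bins = length(x$predicted))
}

#' @export
autoplot.state_rates <- function(object, ...) {
  d <- tibble::tibble(bin = seq_along(object$observed),
                      observed = object$observed,
                      predicted = object$predicted)
  d <- tidyr::pivot_longer(d, -"bin", names_to = "series",
                           values_to = "rate")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$rate,
                                  linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "bin", y = expression(R[hop] ~ (s^-1))) +
    ggplot2::theme_minimal()
}
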