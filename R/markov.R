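# Ideal orientations of the rotamer states for the outer bond: one
# unit vector per state, wells 120 degrees apart on a cone tilted
# 109.47 degrees from the rotation axis; for 9 joint states the outer
# bond orientation composes the chi1 and chi2 rotations.
state_orientations <- function(n_states, centers = c(-60, 60, 180)) {
  if (n_states == 3) {
    return(cone_vectors(centers, TETRA_DEG))
  }
  if (n_states == 9) {
    grid <- expand.grid(chi2 = centers, chi1 = centers)
    # joint label (chi1-1)*3 + chi2 -> row order chi1-major
    grid <- grid[order(rep(seq_len(3), each = 3)), ]
    u <- cone_vectors(grid$chi2, TETRA_DEG)
    u <- rot_y_fixed(u, deg2rad(TETRA_DEG))
    u <- rot_z_rows(u, deg2rad(grid$chi1))
    return(u)
  }
  stop("state orientations defined for 3 or 9 states")
}

#' Build a rotamer Markov model
#'
#' Estimates a row-stochastic transition matrix from transition counts
#' at the chosen lag (counts symmetrised so detailed balance holds),
#' the stationary distribution from its leading left eigenvector, and
#' the exchange (rate) matrix as `(T - I) / lag`. States never visited
#' are dropped with a warning.
#'
#' @param states A `state_trajectory`.
#' @param lag Lag time in seconds; must be a multiple of dt (default
#'   dt).
#' @return A `markov_model`: `T` (transition matrix), `pi`
#'   (equilibrium), `exchange`, `lag`, `P2` (state-orientation
#'   overlaps `P2(u_i . u_j)` from ideal geometry), `states_kept`.
#' @export
build_markov <- function(states, lag = NULL) {
  dt <- states$dt
  lag <- lag %||% dt
  steps <- lag / dt
  if (abs(steps - round(steps)) > 1e-9) {
    stop("lag must be a multiple of dt")
  }
  steps <- as.integer(round(steps))
  s <- states$state
  n <- states$n_states
  from <- s[seq_len(length(s) - steps)]
  to <- s[-seq_len(steps)]
  tab <- table(factor(from, levels = 1:n), factor(to, levels = 1:n))
  C <- matrix(as.numeric(tab), n, n)
  C <- (C + t(C)) / 2               # detailed balance by symmetrisation
  visited <- rowSums(C) > 0
  if (!all(visited)) {
    warning("state(s) never visited: ",
            paste(which(!visited), collapse = ", "), " (dropped)")
  }
  keep <- which(visited)
  Ck <- C[keep, keep, drop = FALSE]
  T_ <- Ck / rowSums(Ck)
  ev <- eigen(t(T_))
  i1 <- which.min(abs(ev$values - 1))
  pi_ <- Re(ev$vectors[, i1])
  pi_ <- pi_ / sum(pi_)
  u <- state_orientations(n, states$centers %||% c(-60, 60, 180))
  uk <- u[keep, , drop = FALSE]
  P2m <- p2(tcrossprod(uk))
  structure(list(T = T_, pi = pi_, exchange = (T_ - diag(nrow(T_))) / lag,
                 lag = lag, P2 = P2m, states_kept = keep,
                 n_states = n, dt = dt),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("<markov_model> ", nrow(x$T), " states, lag ", x$lag, " s, pi = ",
      paste(signif(x$pi, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.markov_model <- function(x, ...) {
  n <- nrow(x$T)
  tibble::tibble(from = rep(x$states_kept, each = n),
                 to = rep(x$states_kept, n),
                 probability = as.numeric(t(x$T)))
}

#' @export
glance.markov_model <- function(x, ...) {
  tibble::tibble(n_states = nrow(x$T), lag = x$lag,
                 relaxation_rate = -sort(Re(eigen(x$exchange)$values))[2])
}

#' Correlation function of rotamer-state dynamics
#'
#' Markov mode: `C(n lag) = sum_ij pi_i [T^n]_ij P2(u_i . u_j)` — the
#' correlation function implied by the fitted Markov model and the
#' ideal state geometry. Empirical mode: the same quantity computed
#' directly from the observed state series (each frame mapped to its
#' ideal orientation) without the Markov assumption. Disagreement
#' between the two is the diagnostic for hidden-variable (non-Markov)
#' dynamics.
#'
#' @param model A `markov_model` (markov mode) or `state_trajectory`
#'   (empirical mode).
#' @param lags Markov mode: lag times in seconds, multiples of the
#'   model lag. Empirical mode: integer frame lags (default
#'   log-spaced).
#' @param mode `"markov"` or `"empirical"` (chosen automatically from
#'   the class of `model`).
#' @return A `corr_fn`.
#' @export
markov_corrfn <- function(model, lags = NULL,
                          mode = c("auto", "markov", "empirical")) {
  mode <- match.arg(mode)
  if (mode == "auto") {
    mode <- if (inherits(model, "markov_model")) "markov" else "empirical"
  }
  if (mode == "markov") {
    stopifnot(inherits(model, "markov_model"))
    lags <- lags %||% (model$lag * log_lags(1000))
    steps <- lags / model$lag
    if (any(abs(steps - round(steps)) > 1e-6)) {
      stop("lags must be multiples of the model lag")
    }
    steps <- round(steps)
    # T^n via eigen-decomposition (detailed balance makes T
    # diagonalisable with real spectrum)
    ed <- eigen(model$T)
    Q <- ed$vectors
    Qi <- solve(Q)
    lam <- Re(ed$values)
    vals <- vapply(steps, function(k) {
      Tn <- Re(Q %*% (lam^k * Qi))
      sum((model$pi * Tn) * model$P2)
    }, numeric(1))
    return(new_corr_fn(lags, vals, dt = model$lag))
  }
  stopifnot(inherits(model, "state_trajectory"))
  u <- state_orientations(model$n_states,
                          model$centers %||% c(-60, 60, 180))
  v <- u[model$state, , drop = FALSE]
  rank2_correlation(v, lags = lags, dt = model$dt)
}
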