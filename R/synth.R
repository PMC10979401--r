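#' Ornstein-Uhlenbeck series
#'
#' Exact discretisation of an OU process with stationary standard
#' deviation `sd` and relaxation time `tau`, started from the
#' stationary distribution.
#'
#' @param n Number of samples.
#' @param dt Timestep, seconds.
#' @param tau Relaxation time, seconds.
#' @param sd Stationary standard deviation.
#' @return Numeric series of length `n`.
#' @export
ou_series <- function(n, dt, tau, sd) {
  if (sd == 0) return(numeric(n))
  a <- exp(-dt / tau)
  e <- stats::rnorm(n, sd = sd * sqrt(1 - a^2))
  e[1] <- stats::rnorm(1, sd = sd)
  as.numeric(stats::filter(e, a, method = "recursive", init = 0))
}

#' Side-chain simulation specification
#'
#' Ground-truth parameters for [simulate_sidechain()]: the processes
#' emulate three-site methyl hopping, chi1/chi2 rotamer exchange with
#' per-state rates, Gaussian (OU) libration within wells, and an
#' optional slow collective ("breathing") mode log-modulating all hop
#' rates.
#'
#' @param restype `"Ala"`, `"Val"`, `"Leu"` or `"Ile"`.
#' @param tau_met Methyl hopping correlation time, seconds (the decay
#'   time of the 3-site exchange eigenmode; the pairwise jump rate is
#'   `1 / (3 tau_met)`).
#' @param chi1_rates,chi2_rates 3 x 3 generator matrices (off-diagonal
#'   jump rates in s^-1, rows summing to 0), or a single number for
#'   symmetric exchange with that pairwise rate.
#' @param sigma_libr Librational SD in radians (recycled per axis).
#' @param tau_libr Libration OU timescale, seconds.
#' @param breathing_amp Log-rate modulation per unit mode displacement
#'   (0 disables).
#' @param tau_breathing Breathing OU timescale, seconds.
#' @return A `sidechain_spec` list.
#' @export
sidechain_spec <- function(restype = "Ile", tau_met = 50e-12,
                           chi1_rates = NULL, chi2_rates = NULL,
                           sigma_libr = deg2rad(10), tau_libr = 1e-12,
                           breathing_amp = 0, tau_breathing = 350e-9) {
  as_gen <- function(x) {
    if (is.null(x)) return(NULL)
    if (length(x) == 1) {
      G <- matrix(x, 3, 3)
      diag(G) <- 0
      diag(G) <- -rowSums(G)
      return(G)
    }
    G <- as.matrix(x)
    if (any(G[row(G) != col(G)] < 0)) stop("jump rates must be >= 0")
    if (max(abs(rowSums(G))) > 1e-6 * max(abs(G))) {
      stop("generator rows must sum to 0")
    }
    G
  }
  structure(list(restype = restype, tau_met = tau_met,
                 chi1 = as_gen(chi1_rates), chi2 = as_gen(chi2_rates),
                 sigma_libr = rep(sigma_libr, length.out = 3),
                 tau_libr = tau_libr,
                 breathing_amp = breathing_amp,
                 tau_breathing = tau_breathing),
            class = "sidechain_spec")
}

# Continuous-time Markov jumps on 1..3 with generator G, optionally
# thinned against a slow log-rate modulation series m(t) (rates scaled
# by exp(m)). Returns the state at each of n dt-steps.
simulate_ctmc <- function(G, n, dt, modulation = NULL) {
  duration <- n * dt
  esc <- -diag(G)
  if (all(esc == 0)) return(rep(1L, n))
  pops <- rep(1 / 3, 3)  # start uniform over states
  state0 <- sample.int(3, 1, prob = pops)
  mmax <- if (is.null(modulation)) 0 else max(modulation)
  lam_max <- max(esc) * exp(mmax)
  n_cand <- stats::rpois(1, lam_max * duration)
  t_cand <- sort(stats::runif(n_cand, 0, duration))
  u_acc <- stats::runif(n_cand)
  u_dest <- stats::runif(n_cand)
  jump_t <- numeric(n_cand)
  jump_s <- integer(n_cand)
  nj <- 0L
  cur <- state0
  mod_at <- if (is.null(modulation)) rep(0, n_cand) else {
    modulation[pmin(n, 1L + as.integer(t_cand / dt))]
  }
  for (i in seq_len(n_cand)) {
    rate <- esc[cur] * exp(mod_at[i])
    if (u_acc[i] < rate / lam_max) {
      w <- G[cur, ]
      w[cur] <- 0
      cs <- cumsum(w) / sum(w)
      cur <- which(u_dest[i] <= cs + 1e-15)[1]
      nj <- nj + 1L
      jump_t[nj] <- t_cand[i]
      jump_s[nj] <- cur
    }
  }
  idx <- findInterval((seq_len(n) - 1) * dt, jump_t[seq_len(nj)])
  c(state0, jump_s[seq_len(nj)])[idx + 1L]
}

#' Simulate a methyl-bearing side chain
#'
#' Continuous-time Markov hopping per axis (thinning algorithm when a
#' breathing mode modulates the rates), OU libration within wells,
#' dihedral series assembled as state centre + libration, and the H-C
#' unit-vector series composed with ideal tetrahedral geometry. Fully
#' reproducible from the seed.
#'
#' @param spec A [sidechain_spec()].
#' @param duration Total time, seconds.
#' @param dt Timestep, seconds.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `synth_result`: tibble `dihedrals` (time, methyl, chi1,
#'   chi2 as available, degrees), matrix `vectors` (H-C unit vectors),
#'   list `states` of true `state_trajectory`s, `breathing` series (or
#'   NULL), and `spec`/`dt` metadata.
#' @export
simulate_sidechain <- function(spec, duration, dt, seed) {
  stopifnot(inherits(spec, "sidechain_spec"))
  min_ts <- min(c(spec$tau_met,
                  if (any(spec$sigma_libr > 0)) spec$tau_libr),
                na.rm = TRUE)
  if (dt > min_ts / 5) {
    warning("dt larger than min timescale / 5; dynamics under-resolved")
  }
  set.seed(seed)
  n <- as.integer(floor(duration / dt + 1e-6))
  centers <- c(-60, 60, 180)

  b <- NULL
  modul <- NULL
  if (spec$breathing_amp != 0) {
    b <- ou_series(n, dt, spec$tau_breathing, 1)
    modul <- spec$breathing_amp * b
  }

  k_met <- 1 / (3 * spec$tau_met)
  Gm <- matrix(k_met, 3, 3)
  diag(Gm) <- 0
  diag(Gm) <- -rowSums(Gm)

  axes <- list(methyl = Gm)
  if (spec$restype %in% c("Val", "Leu", "Ile")) {
    axes$chi1 <- spec$chi1 %||% {
      G <- matrix(0, 3, 3)
      G  # frozen chi1 unless rates given
    }
  }
  if (spec$restype %in% c("Leu", "Ile")) {
    axes$chi2 <- spec$chi2 %||% matrix(0, 3, 3)
  }

  states <- list()
  dihedrals <- tibble::tibble(time = (seq_len(n) - 1) * dt)
  for (i in seq_along(axes)) {
    ax <- names(axes)[i]
    st <- simulate_ctmc(axes[[i]], n, dt, modulation = modul)
    libr <- ou_series(n, dt, spec$tau_libr,
                      rad2deg(spec$sigma_libr[i]))
    dihedrals[[ax]] <- wrap_deg(centers[st] + libr)
    states[[ax]] <- structure(list(state = st, dt = dt,
                                   centers = centers, n_states = 3L),
                              class = "state_trajectory")
  }

  vectors <- compose_hc_vectors(
    dihedrals$methyl,
    chi1 = if ("chi1" %in% names(dihedrals)) dihedrals$chi1 else NULL,
    chi2 = if ("chi2" %in% names(dihedrals)) dihedrals$chi2 else NULL)
  structure(list(dihedrals = dihedrals, vectors = vectors,
                 states = states, breathing = b, spec = spec,
                 dt = dt, seed = seed),
            class = "synth_result")
}

#' @export
print.synth_result <- function(x, ...) {
  cat("<synth_result> ", x$spec$restype, ", ", nrow(x$dihedrals),
      " frames at dt = ", x$dt, " s\n", sep = "")
  invisible(x)
}

#' Simulate coupled side chains with excluded joint states
#'
#' Joint continuous-time Markov chain on the product rotamer space of
#' several residues, with listed joint states removed (hard steric
#' exclusion): transitions change one residue at a time at its own
#' rate, and moves into forbidden configurations are disallowed.
#'
#' @param rates Named list (one per residue) of pairwise symmetric
#'   exchange rates (s^-1) or 3 x 3 generators.
#' @param forbidden Data frame / matrix with one row per forbidden
#'   joint state and one column per residue, or NULL.
#' @param duration,dt,seed As in [simulate_sidechain()].
#' @return A tibble of per-frame joint states, one column per residue,
#'   with attribute `dt`.
#' @export
simulate_coupled_set <- function(rates, forbidden = NULL, duration, dt,
                                 seed) {
  set.seed(seed)
  nres <- length(rates)
  res <- names(rates) %||% paste0("res", seq_len(nres))
  gens <- lapply(rates, function(x) {
    if (length(x) == 1) {
      G <- matrix(x, 3, 3)
      diag(G) <- 0
      diag(G) <- -rowSums(G)
      G
    } else as.matrix(x)
  })
  grid <- as.matrix(expand.grid(rep(list(1:3), nres)))
  colnames(grid) <- res
  allowed <- rep(TRUE, nrow(grid))
  if (!is.null(forbidden) && nrow(forbidden) > 0) {
    fb <- as.matrix(forbidden)
    for (i in seq_len(nrow(fb))) {
      allowed <- allowed & rowSums(grid == matrix(fb[i, ], nrow(grid),
                                                  nres, byrow = TRUE)) < nres
    }
  }
  if (!any(allowed)) stop("no allowed joint state")
  gstates <- grid[allowed, , drop = FALSE]
  ns <- nrow(gstates)
  key <- apply(gstates, 1, paste, collapse = "|")
  # generator on the allowed joint space: single-residue moves
  G <- matrix(0, ns, ns)
  for (a in seq_len(ns)) {
    for (r in seq_len(nres)) {
      for (to in 1:3) {
        if (to == gstates[a, r]) next
        tgt <- gstates[a, ]
        tgt[r] <- to
        bidx <- match(paste(tgt, collapse = "|"), key)
        if (!is.na(bidx)) G[a, bidx] <- G[a, bidx] +
            gens[[r]][gstates[a, r], to]
      }
    }
  }
  diag(G) <- -rowSums(G)
  n <- as.integer(floor(duration / dt + 1e-6))
  esc <- -diag(G)
  cur0 <- sample.int(ns, 1)
  cur <- cur0
  jump_t <- numeric(0)
  jump_s <- integer(0)
  t_now <- 0
  repeat {
    if (esc[cur] == 0) break
    t_now <- t_now + stats::rexp(1, esc[cur])
    if (t_now >= n * dt) break
    w <- G[cur, ]
    w[cur] <- 0
    cur <- sample.int(ns, 1, prob = w)
    jump_t <- c(jump_t, t_now)
    jump_s <- c(jump_s, cur)
  }
  idx <- findInterval((seq_len(n) - 1) * dt, jump_t)
  path <- c(cur0, jump_s)[idx + 1L]
  out <- tibble::as_tibble(as.data.frame(gstates[path, , drop = FALSE]))
  names(out) <- res
  attr(out, "dt") <- dt
  out
}

#' Simulate a breathing backbone
#'
#' Coordinates `ref + b(t) * shape + noise` with `b(t)` an OU process
#' of relaxation time `tau_B` and stationary standard deviation
#' `amplitude`: a single slow collective mode on top of isotropic
#' positional noise, the minimal model of fibril breathing.
#'
#' @param n_atoms Number of atoms.
#' @param mode_shape Numeric vector of length `3 n_atoms` (need not be
#'   normalised).
#' @param tau_B Mode relaxation time, seconds.
#' @param amplitude Stationary standard deviation of the mode
#'   displacement (length units).
#' @param duration,dt,seed As in [simulate_sidechain()].
#' @param ref Reference coordinates (length `3 n_atoms`); default a
#'   reproducible random cloud of ~10 length-unit extent.
#' @param noise_sd Isotropic per-coordinate noise SD (default 0.05).
#' @return A list: `coords` (frames x 3N), `b` (mode displacement
#'   series), `mode` (unit mode shape), `ref`.
#' @export
simulate_breathing_backbone <- function(n_atoms, mode_shape, tau_B,
                                        amplitude, duration, dt, seed,
                                        ref = NULL, noise_sd = 0.05) {
  if (length(mode_shape) != 3 * n_atoms) {
    stop("mode shape must have length 3 n_atoms")
  }
  set.seed(seed)
  n <- as.integer(floor(duration / dt + 1e-6))
  shape <- mode_shape / sqrt(sum(mode_shape^2))
  ref <- ref %||% stats::rnorm(3 * n_atoms, sd = 10)
  b <- if (amplitude > 0) ou_series(n, dt, tau_B, amplitude) else numeric(n)
  coords <- outer(b, shape) +
    matrix(ref, n, 3 * n_atoms, byrow = TRUE) +
    matrix(stats::rnorm(n * 3 * n_atoms, sd = noise_sd), n)
  list(coords = coords, b = b, mode = shape, ref = ref)
}
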