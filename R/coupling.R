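plugin_entropy <- function(labels) {
  p <- table(labels) / length(labels)
  -GAS_R * sum(p * log(p))
}

#' Rotameric entropy report
#'
#' Plug-in (observed-frequency) entropies `dS = -R sum p ln p` over
#' rotamer states, using the gas constant R = 8.314 J mol^-1 K^-1 and
#' natural logarithms: per-residue marginal entropies, the total
#' entropy of the simultaneous configuration of all side chains, the
#' maximum possible entropy `sum_res R ln(n_states)`, and the
#' leave-one-out change `d(dS_total)` — how much total entropy is lost
#' when a residue is marginalised out, i.e. how independently it
#' samples its states given its neighbours.
#'
#' @param states Data frame or tibble, one column per residue, one row
#'   per frame, integer (or factor) rotamer states; no missing values.
#' @param n_states Named integer vector of state-space sizes per
#'   residue (default: 3 for <= 3 observed states, else 9).
#' @return An `entropy_report`: tibble `per_residue` (`residue`,
#'   `dS_res`, `dS_loo`), scalars `dS_total`, `dS_max`.
#' @export
#' @examples
#' st <- data.frame(a = rep(1:3, 30), b = rep(1:3, each = 30))
#' entropy_report(st)$dS_total
entropy_report <- function(states, n_states = NULL) {
  states <- as.data.frame(states)
  if (nrow(states) == 0) stop("empty state table")
  if (anyNA(states)) stop("state table has missing values")
  res <- names(states)
  if (is.null(n_states)) {
    n_states <- vapply(states, function(s) {
      if (length(unique(s)) <= 3) 3L else 9L
    }, integer(1))
  }
  dS_res <- vapply(states, plugin_entropy, numeric(1))
  joint_of <- function(cols) {
    plugin_entropy(do.call(paste, c(states[cols], sep = "|")))
  }
  dS_total <- if (length(res) == 1) dS_res[[1]] else joint_of(res)
  dS_loo <- vapply(res, function(r) {
    others <- setdiff(res, r)
    if (!length(others)) return(dS_total)
    dS_total - joint_of(others)
  }, numeric(1))
  structure(list(
    per_residue = tibble::tibble(residue = res,
                                 dS_res = unname(dS_res),
                                 dS_loo = unname(dS_loo)),
    dS_total = dS_total,
    dS_max = GAS_R * sum(log(n_states)),
    n_states = n_states,
    states = states),
    class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  cat("<entropy_report> ", nrow(x$per_residue), " residues: dS_total = ",
      signif(x$dS_total, 4), " of max ", signif(x$dS_max, 4),
      " J mol^-1 K^-1 (sum of marginals ",
      signif(sum(x$per_residue$dS_res), 4), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.entropy_report <- function(x, ...) x$per_residue

#' @export
glance.entropy_report <- function(x, ...) {
  tibble::tibble(dS_total = x$dS_total,
                 dS_sum = sum(x$per_residue$dS_res),
                 dS_max = x$dS_max)
}

#' @export
autoplot.entropy_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_residue, -"residue",
                           names_to = "quantity", values_to = "dS")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$residue, y = .data$dS,
                                  fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = expression(Delta * S ~ (J ~ mol^-1 ~ K^-1))) +
    ggplot2::theme_minimal()
}

#' Entropy-based pair correlation coefficient
#'
#' `cc = 2 (dS_p + dS_q - dS_pq) / (dS_p + dS_q)`: 0 when the rotamer
#' states of the two residues are independent (entropies add), 1 when
#' fully dependent (`dS_p = dS_q = dS_pq`).
#'
#' @param p,q Residue column names.
#' @param states State table as in [entropy_report()].
#' @return The coefficient (scalar).
#' @export
pair_entropy_cc <- function(p, q, states) {
  states <- as.data.frame(states)
  stopifnot(p %in% names(states), q %in% names(states))
  Sp <- plugin_entropy(states[[p]])
  Sq <- plugin_entropy(states[[q]])
  if (Sp + Sq == 0) {
    warning("both marginal entropies are zero; coefficient undefined")
    return(NA_real_)
  }
  Spq <- plugin_entropy(paste(states[[p]], states[[q]], sep = "|"))
  2 * (Sp + Sq - Spq) / (Sp + Sq)
}

#' All-pairs entropy correlation matrix
#'
#' @param states State table as in [entropy_report()].
#' @return Symmetric matrix of [pair_entropy_cc()] values (diagonal 1).
#' @export
entropy_cc_matrix <- function(states) {
  states <- as.data.frame(states)
  res <- names(states)
  m <- diag(1, length(res))
  dimnames(m) <- list(res, res)
  if (length(res) > 1) {
    for (i in seq_along(res)[-length(res)]) {
      for (j in (i + 1):length(res)) {
        m[i, j] <- m[j, i] <- pair_entropy_cc(res[i], res[j], states)
      }
    }
  }
  m
}

# Kabsch rotation aligning mobile (n x 3) onto target (n x 3), both
# already centred.
kabsch <- function(mobile, target) {
  H <- crossprod(mobile, target)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

#' Principal component analysis of backbone coordinates
#'
#' Iterative least-squares superposition of every frame onto the
#' evolving mean structure (5 passes of Kabsch alignment), followed by
#' eigen-decomposition of the coordinate covariance. The low-index
#' components capture slow collective (breathing) deformations.
#'
#' @param coords Frames x coordinates matrix (3N columns, x1 y1 z1 x2
#'   ...) or a frames x atoms x 3 array.
#' @param n Number of components to report (default 10); needs at
#'   least `10 n` frames.
#' @param align Superpose frames before the decomposition (default
#'   `TRUE`).
#' @return A `pca_result`: `mean` (3N), `components` (3N x n,
#'   orthonormal), `eigenvalues` (all 3N, non-increasing),
#'   `projections` (frames x n), `aligned` coordinates.
#' @export
pca_modes <- function(coords, n = 10, align = TRUE) {
  if (length(dim(coords)) == 3) {
    # frames x atoms x 3 -> frames x (x1 y1 z1 x2 ...)
    coords <- t(apply(coords, 1, function(M) as.numeric(t(M))))
  }
  coords <- as.matrix(coords)
  nf <- nrow(coords)
  nat <- ncol(coords) / 3
  if (nat != round(nat)) stop("coordinate columns must be a multiple of 3")
  if (nf < 10 * n) stop("need at least 10 n frames")
  if (max(apply(coords, 2, stats::sd)) == 0) {
    stop("degenerate coordinates: no variance")
  }
  frames <- coords
  if (align) {
    # centre each frame
    for (it in 1:5) {
      mu <- matrix(colMeans(frames), nat, 3, byrow = TRUE)
      mu <- mu - matrix(colMeans(mu), nat, 3, byrow = TRUE)
      for (f in seq_len(nf)) {
        X <- matrix(frames[f, ], nat, 3, byrow = TRUE)
        X <- sweep(X, 2, colMeans(X))
        R <- kabsch(X, mu)
        frames[f, ] <- as.numeric(t(X %*% R))
      }
    }
  }
  mu <- colMeans(frames)
  Xc <- sweep(frames, 2, mu)
  C <- crossprod(Xc) / (nf - 1)
  ed <- eigen(C, symmetric = TRUE)
  comps <- ed$vectors[, seq_len(n), drop = FALSE]
  structure(list(mean = mu, components = comps,
                 eigenvalues = ed$values,
                 all_components = ed$vectors,
                 projections = Xc %*% comps,
                 aligned = frames, n = n),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", x$n, " components of ", length(x$mean),
      " coordinates; top eigenvalues: ",
      paste(signif(utils::head(x$eigenvalues, 3), 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.pca_result <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 variance_fraction = x$eigenvalues / sum(x$eigenvalues))
}

#' Normalised autocorrelation of a principal-component projection
#'
#' Mean-subtracted, variance-normalised autocorrelation, so C(0) = 1
#' and C decays to 0 for a stationary mixing process.
#'
#' @param projection Numeric projection time series.
#' @param dt Timestep in seconds.
#' @param max_lag Largest lag in frames (default n/5).
#' @return A `corr_fn`.
#' @export
pc_autocorr <- function(projection, dt, max_lag = NULL) {
  n <- length(projection)
  if (n < 10) stop("series too short")
  if (stats::sd(projection) == 0) stop("zero-variance projection")
  max_lag <- max_lag %||% (n %/% 5)
  ac <- stats::acf(projection, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)
  new_corr_fn((0:max_lag) * dt, as.numeric(ac$acf), dt = dt)
}

#' Correlation of collective-mode projection with hop rates
#'
#' Averages the projection within each hop-rate bin and reports the
#' per-residue Pearson correlation between the binned projection and
#' the binned hop rates: positive values mean hopping accelerates when
#' the mode opens in the positive direction.
#'
#' @param projection Projection series (frames).
#' @param dt Frame timestep, seconds.
#' @param rates A `hop_rate_series`, or a named list of them (one per
#'   residue).
#' @return A tibble with columns `residue` and `r`.
#' @export
pc_rate_correlation <- function(projection, dt, rates) {
  if (inherits(rates, "hop_rate_series")) rates <- list(site = rates)
  purrr::imap_dfr(rates, function(rs, nm) {
    bin_dur <- attr(rs, "bin_duration")
    per_bin <- as.integer(round(bin_dur / dt))
    n_bins <- nrow(rs)
    need <- n_bins * per_bin
    if (length(projection) < need) {
      stop("projection shorter than the binned rate series")
    }
    pb <- tapply(projection[seq_len(need)],
                 rep(seq_len(n_bins), each = per_bin), mean)
    if (stats::sd(pb) == 0 || stats::sd(rs$rate) == 0) {
      stop("constant series: correlation undefined")
    }
    tibble::tibble(residue = nm, r = stats::cor(as.numeric(pb), rs$rate))
  })
}
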