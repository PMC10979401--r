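# Independent oracles used across the suite.

wrap_deg_test <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

circ_sd_test <- function(theta_deg) {
  th <- theta_deg * pi / 180
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  sqrt(-2 * log(rbar)) * 180 / pi
}

# Correlation function of an n-state exchange process from the
# eigen-decomposition of its generator: C(t) = sum_ij p_i [e^{Gt}]_ij
# P2(u_i . u_j), with p the stationary distribution.
exchange_corrfn_oracle <- function(G, u, t) {
  ed <- eigen(t(G))
  pi_ <- Re(ed$vectors[, which.min(abs(ed$values))])
  pi_ <- pi_ / sum(pi_)
  P2 <- (3 * tcrossprod(u)^2 - 1) / 2
  edG <- eigen(G)
  Q <- edG$vectors
  Qi <- solve(Q)
  vapply(t, function(tt) {
    Et <- Re(Q %*% (exp(edG$values * tt) * Qi))
    sum((pi_ * Et) * P2)
  }, numeric(1))
}

# Symmetric 3-site generator with pairwise rate k
sym3_generator <- function(k) {
  G <- matrix(k, 3, 3)
  diag(G) <- -2 * k
  G
}

# Unit vectors on a cone: tilt (deg) from z, azimuths (deg)
cone_u <- function(azimuth_deg, tilt_deg) {
  a <- tilt_deg * pi / 180
  phi <- azimuth_deg * pi / 180
  cbind(sin(a) * cos(phi), sin(a) * sin(phi), rep(cos(a), length(phi)))
}

# Gauss-Hermite evaluation of the librational order parameter:
# E[P2(u(phi1) . u(phi2))], phi_i ~ N(0, sigma^2), via pracma nodes.
libration_op_gh_oracle <- function(sigma, beta_deg = 110.5, n = 60) {
  gh <- pracma::gaussHermite(n)
  b <- cos(beta_deg * pi / 180)^2
  a <- 1 - b
  # delta = phi1 - phi2 ~ N(0, 2 sigma^2); x = sqrt(2) * sigma * t ...
  # with t the GH variable for exp(-t^2)
  delta <- 2 * sigma * gh$x   # sqrt(2 * (2 sigma^2)) * t / sqrt(2)
  x <- a * cos(delta) + b
  sum(gh$w * (3 * x^2 - 1) / 2) / sqrt(pi)
}

# Per-lag standard error of C(t) from block means
corrfn_block_se <- function(vectors, dt, lags, n_blocks = 10) {
  n <- nrow(vectors)
  bs <- floor(n / n_blocks)
  vals <- vapply(seq_len(n_blocks), function(b) {
    v <- vectors[((b - 1) * bs + 1):(b * bs), , drop = FALSE]
    rank2_correlation(v, lags = lags, dt = dt)$value
  }, numeric(length(lags)))
  apply(vals, 1, stats::sd) / sqrt(n_blocks)
}

# Plateau standard error from block means over the final decade
plateau_block_se <- function(vectors, dt, n_blocks = 20) {
  n <- nrow(vectors)
  bs <- floor(n / n_blocks)
  vals <- vapply(seq_len(n_blocks), function(b) {
    v <- vectors[((b - 1) * bs + 1):(b * bs), , drop = FALSE]
    cf <- rank2_correlation(v, dt = dt)
    attr(cf, "S2")
  }, numeric(1))
  stats::sd(vals) / sqrt(n_blocks)
}

# sigma on a methyl line for given tau (mirror of the package internal)
line_sigma_test <- function(line, tau) {
  sqrt(line$slope / (log10(tau) - line$intercept))
}

deg2rad_test <- function(x) x * pi / 180
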