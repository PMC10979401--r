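test_that("entropy of uniform and degenerate state tables is exact", {
  # 9 equally populated joint states: R ln 9 = 18.27 J/mol/K
  st <- expand.grid(chi1 = 1:3, chi2 = 1:3)
  joint <- data.frame(res = paste(st$chi1, st$chi2))
  er <- entropy_report(joint, n_states = c(res = 9))
  expect_equal(er$dS_total, 8.314 * log(9), tolerance = 1e-12)
  expect_equal(round(er$dS_total, 2), 18.27)
  # single state: zero
  expect_equal(entropy_report(data.frame(a = rep(1, 50)))$dS_total, 0)
  # 3 equal states (valine): R ln 3
  er3 <- entropy_report(data.frame(v = rep(1:3, 100)))
  expect_equal(er3$dS_total, 8.314 * log(3), tolerance = 1e-12)
  expect_error(entropy_report(data.frame()), "empty")
})

test_that("entropy is subadditive and leave-one-out bounded", {
  set.seed(61)
  n <- 3000
  a <- sample.int(3, n, replace = TRUE)
  b <- sample.int(3, n, replace = TRUE)
  c_ <- ifelse(a == 1, 1L, sample.int(3, n, replace = TRUE)) # coupled to a
  er <- entropy_report(data.frame(a = a, b = b, c = c_))
  expect_lte(er$dS_total, sum(er$per_residue$dS_res) + 1e-9)
  expect_true(all(er$per_residue$dS_loo <= er$per_residue$dS_res + 1e-9))
  expect_true(all(er$per_residue$dS_loo >= -1e-9))
  expect_lte(er$dS_total, er$dS_max)
})

test_that("pair correlation is 0 for independence and 1 for dependence", {
  # exact tables: every joint state equally often -> independent
  st <- expand.grid(p = 1:3, q = 1:3)
  cc0 <- pair_entropy_cc("p", "q", st)
  expect_equal(cc0, 0, tolerance = 1e-12)
  # deterministic copy -> 1
  st1 <- data.frame(p = rep(1:3, 50), q = rep(1:3, 50))
  expect_equal(pair_entropy_cc("p", "q", st1), 1, tolerance = 1e-12)
  # simulated independent chains: |cc| < 0.02 at n = 1e5
  set.seed(62)
  sti <- data.frame(p = sample.int(3, 1e5, TRUE),
                    q = sample.int(3, 1e5, TRUE))
  expect_lt(abs(pair_entropy_cc("p", "q", sti)), 0.02)
  # both-frozen pair is flagged undefined
  expect_warning(
    ccna <- pair_entropy_cc("p", "q", data.frame(p = rep(1, 10),
                                                 q = rep(2, 10))),
    "undefined")
  expect_true(is.na(ccna))
})

test_that("hard-core exclusions increase the pair coupling monotonically", {
  # exact enumeration: uniform distribution over allowed joint states
  cc_for_allowed <- function(allowed) {
    reps <- 10L
    st <- allowed[rep(seq_len(nrow(allowed)), reps), ]
    pair_entropy_cc("p", "q", st)
  }
  full <- expand.grid(p = 1:3, q = 1:3)
  ex1 <- full[!(full$p == 1 & full$q == 1), ]
  ex2 <- ex1[!(ex1$p == 2 & ex1$q == 2), ]
  ex3 <- ex2[!(ex2$p == 3 & ex2$q == 3), ]
  ccs <- c(cc_for_allowed(full), cc_for_allowed(ex1),
           cc_for_allowed(ex2), cc_for_allowed(ex3))
  expect_equal(ccs[1], 0, tolerance = 1e-12)
  expect_true(all(diff(ccs) > 0))
  expect_true(all(ccs >= -1e-12 & ccs <= 1))
  m <- entropy_cc_matrix(ex3)
  expect_equal(m["p", "q"], ccs[4], tolerance = 1e-12)
})

test_that("a planted collective mode is recovered as PC1", {
  set.seed(63)
  n_at <- 20
  shape <- rnorm(3 * n_at)
  bb <- simulate_breathing_backbone(n_at, shape, tau_B = 50e-9,
                                    amplitude = 1.5, duration = 5e-6,
                                    dt = 5e-9, seed = 64,
                                    noise_sd = 0.05)
  pc <- pca_modes(bb$coords, n = 5, align = FALSE)
  cossim <- abs(sum(pc$components[, 1] * bb$mode))
  expect_gt(cossim, 0.99)
  expect_true(all(diff(pc$eigenvalues) <= 1e-9))
  # projections of the mean structure are zero by centring
  expect_equal(colMeans(pc$projections), rep(0, 5), tolerance = 1e-9)
  # full back-projection reproduces the centred coordinates
  Xc <- sweep(pc$aligned, 2, pc$mean)
  rec <- (Xc %*% pc$all_components) %*% t(pc$all_components)
  expect_lt(max(abs(rec - Xc)), 1e-6)
})

test_that("alignment does not destroy mode recovery", {
  set.seed(65)
  n_at <- 12
  ref <- rnorm(3 * n_at, sd = 8)
  shape <- rnorm(3 * n_at)
  bb <- simulate_breathing_backbone(n_at, shape, tau_B = 20e-9,
                                    amplitude = 1.0, duration = 1e-6,
                                    dt = 2e-9, seed = 66, ref = ref,
                                    noise_sd = 0.02)
  pc <- pca_modes(bb$coords, n = 3, align = TRUE)
  expect_equal(crossprod(pc$components), diag(3), tolerance = 1e-8)
  expect_gt(pc$eigenvalues[1] / pc$eigenvalues[2], 10)
  expect_error(pca_modes(bb$coords[1:20, ], n = 3), "frames")
  flat <- matrix(1, 200, 3 * n_at)
  expect_error(pca_modes(flat, n = 3), "degenerate")
})

test_that("projection autocorrelation recovers the OU timescale", {
  set.seed(67)
  tauB <- 100e-9
  dt <- 2e-9
  x <- ou_series(2e5, dt, tauB, 1)
  cf <- pc_autocorr(x, dt)
  expect_equal(cf$value[1], 1)
  # integral estimator: for an OU process, integral_0^T C dt equals
  # tau (1 - C(T)) for every T
  sel <- cf$lag <= 3 * tauB
  tau_est <- pracma::trapz(cf$lag[sel], cf$value[sel]) /
    (1 - cf$value[max(which(sel))])
  expect_lt(abs(tau_est - tauB) / tauB, 0.1)
  # white noise decorrelates immediately
  w <- rnorm(1e4)
  cfw <- pc_autocorr(w, dt)
  expect_lt(max(abs(cfw$value[-1])), 3 / sqrt(1e4) * 1.5)
  expect_error(pc_autocorr(rep(1, 100), dt), "zero-variance")
})

test_that("hop rates log-modulated by the mode correlate positively", {
  dt <- 1e-9
  n <- 2e5
  spec_c <- sidechain_spec("Ala", tau_met = 1 / (3 * 2e6),
                           sigma_libr = 0, tau_libr = 1e-9,
                           breathing_amp = 1.2, tau_breathing = 2e-6)
  sim <- simulate_sidechain(spec_c, n * dt, dt, seed = 68)
  hr <- binned_hop_rates(sim$states$methyl, 2e-6)
  out <- pc_rate_correlation(sim$breathing, dt, hr)
  expect_gt(out$r, 0.3)
  # larger modulation amplitude strengthens the correlation
  spec_w <- sidechain_spec("Ala", tau_met = 1 / (3 * 2e6),
                           sigma_libr = 0, tau_libr = 1e-9,
                           breathing_amp = 0.2, tau_breathing = 2e-6)
  simw <- simulate_sidechain(spec_w, n * dt, dt, seed = 68)
  hrw <- binned_hop_rates(simw$states$methyl, 2e-6)
  outw <- pc_rate_correlation(simw$breathing, dt, hrw)
  expect_gt(out$r, outw$r)
  # independent mode: no correlation beyond noise
  spec_0 <- sidechain_spec("Ala", tau_met = 1 / (3 * 2e6),
                           sigma_libr = 0, tau_libr = 1e-9)
  sim0 <- simulate_sidechain(spec_0, n * dt, dt, seed = 69)
  hr0 <- binned_hop_rates(sim0$states$methyl, 2e-6)
  set.seed(70)
  indep <- ou_series(n, dt, 2e-6, 1)
  out0 <- pc_rate_correlation(indep, dt, hr0)
  expect_lt(abs(out0$r), 3 / sqrt(nrow(hr0)))
})
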