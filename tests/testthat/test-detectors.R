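make_md_set <- function() md_sensitivities(10^seq(-10.5, -6.5, by = 0.1))

test_that("NMR rate sensitivities behave in the physical limits", {
  sens <- suppressWarnings(nmr_sensitivities(hets_experiments()))
  expect_true(all(is.finite(sens$R)) && all(sens$R >= 0 | sens$info$type ==
                                              "NOE"))
  # R1 in the extreme narrowing limit (tau = 10 fs) is negligible
  r1 <- sens$R[1, ]
  expect_lt(r1[which.min(abs(sens$z + 14))], 1e-4 * max(r1))
  # R1 at 600 MHz peaks near omega_C tau ~ 1
  r1_600 <- sens$R[sens$info$type == "R1" & sens$info$field_MHz == 600, ]
  wC <- 2 * pi * 600e6 * 67.2828 / 267.5221874
  expect_lt(abs(sens$z[which.max(r1_600)] - (-log10(wC))), 0.3)
  expect_error(nmr_sensitivities(data.frame(type = "T2", field_MHz = 600)),
               "unknown experiment type")
  expect_warning(
    nmr_sensitivities(data.frame(type = "R1p", field_MHz = 600,
                                 MAS_kHz = 12, spinlock_kHz = 12)),
    "rotary-resonance")
})

test_that("MD lag sensitivities follow exp(-t / tau)", {
  s <- md_sensitivities(10^seq(-10.5, -6.5, by = 0.1),
                        z = seq(-11, -6, by = 0.025))
  i9 <- which.min(abs(s$z + 9))
  k1ns <- which.min(abs(s$info$lag_s - 1e-9))
  expect_equal(s$R[k1ns, i9], exp(-1), tolerance = 1e-6)
  expect_true(all(diff(s$R[k1ns, ]) > 0))         # monotone in z
  expect_error(md_sensitivities(c(1e-9, -1)), "lags")
})

test_that("sensitivity sets round-trip through text exactly", {
  s <- suppressWarnings(nmr_sensitivities(hets_experiments()))
  path <- withr::local_tempfile(fileext = ".txt")
  write_sensitivities(s, path)
  s2 <- read_sensitivities(path)
  expect_identical(s2$R, s$R)
  expect_identical(s2$z, s$z)
  expect_identical(s2$scale, s$scale)
  expect_equal(s2$info$field_MHz, s$info$field_MHz)
})

test_that("a single detector is the renormalised leading singular vector", {
  s <- make_md_set()
  d1 <- optimize_detectors(s, 1)
  v1 <- svd(s$R / s$scale)$v[, 1]
  cosim <- abs(sum(d1$rho[1, ] * v1)) /
    sqrt(sum(d1$rho[1, ]^2) * sum(v1^2))
  expect_gt(cosim, 1 - 1e-6)
})

test_that("optimised detectors are non-negative, normalised and tile", {
  s <- make_md_set()
  det <- optimize_detectors(s, 5)
  expect_gt(min(det$rho), -0.05)
  expect_equal(unname(apply(det$rho, 1, max)), rep(1, 5),
               tolerance = 1e-6)
  expect_true(all(diff(det$z0) > 0))
  ssum <- colSums(det$rho_raw)
  expect_lt(max(abs(ssum[det$covered] - 1)), 0.05)
  # integral mode: unit trapezoid integral per window
  di <- optimize_detectors(s, 4, mode = "integral")
  ints <- apply(di$rho, 1, function(r) pracma::trapz(di$z, r))
  expect_equal(unname(ints), rep(1, 4), tolerance = 1e-6)
  expect_error(optimize_detectors(s, 100), "exceeds")
})

test_that("a delta distribution at a window centre excites that window", {
  s <- make_md_set()
  det <- optimize_detectors(s, 4)
  for (i in c(2, 3)) {
    dist <- delta_distribution(10^det$z0[i], det$z, amplitude = 1)
    resp <- responses_from_distribution(dist, det)
    iz <- which.min(abs(det$z - det$z0[i]))
    expect_equal(resp$response[i], det$rho[i, iz], tolerance = 0.05)
    others <- setdiff(seq_len(4), i)
    expect_equal(resp$response[others],
                 det$rho[cbind(others, iz)], tolerance = 0.05)
  }
})

test_that("responses are linear in the distribution and vanish at S2 = 1", {
  s <- make_md_set()
  det <- optimize_detectors(s, 4)
  z <- det$z
  th1 <- exp(-(z + 9)^2 / 0.2)
  th2 <- exp(-(z + 7.5)^2 / 0.4)
  d1 <- timescale_distribution(z, th1, 0.6)
  d2 <- timescale_distribution(z, th2, 0.6)
  mixed <- timescale_distribution(z, 0.3 * d1$theta + 0.7 * d2$theta, 0.6)
  r1 <- responses_from_distribution(d1, det)$response
  r2 <- responses_from_distribution(d2, det)$response
  rm_ <- responses_from_distribution(mixed, det)$response
  expect_equal(rm_, 0.3 * r1 + 0.7 * r2, tolerance = 1e-9)
  d0 <- timescale_distribution(z, th1, 0)  # S2 = 1
  expect_equal(responses_from_distribution(d0, det)$response,
               rep(0, 4), tolerance = 1e-12)
})

test_that("integral-normalised response estimates the local amplitude", {
  s <- make_md_set()
  det <- optimize_detectors(s, 4, mode = "integral")
  z <- det$z
  # uniform theta over the support of window 2
  th <- as.numeric(det$rho[2, ] > 0.2 * max(det$rho[2, ]))
  dist <- timescale_distribution(z, th, amplitude = 0.5)
  resp <- responses_from_distribution(dist, det)
  iz <- which.min(abs(z - det$z0[2]))
  expect_equal(resp$response[2], 0.5 * dist$theta[iz], tolerance = 0.2)
})

test_that("response fitting inverts back-calculation and scales errors", {
  s <- make_md_set()
  det <- optimize_detectors(s, 5)
  dist <- delta_distribution(1e-8, det$z, amplitude = 0.6)
  x <- responses_from_distribution(dist, det)
  m <- backcalc_measurements(x, s, det, S2 = 0.4)
  fit <- fit_responses(m, rep(0.01, length(m)), s, det)
  expect_equal(fit$response, x$response, tolerance = 1e-6)
  expect_equal(attr(fit, "extra")$S2, 0.4, tolerance = 1e-6)
  fit2 <- fit_responses(m, rep(0.02, length(m)), s, det)
  expect_equal(fit2$sd, 2 * fit$sd, tolerance = 1e-9)
})

test_that("single-exponential data fits match the delta response", {
  s <- make_md_set()
  det <- optimize_detectors(s, 5)
  tau0 <- 1e-8
  lags <- s$info$lag_s
  cdat <- 0.4 + 0.6 * exp(-lags / tau0)
  fit <- fit_responses(cdat, rep(1e-4, length(lags)), s, det)
  ref <- responses_from_distribution(
    delta_distribution(tau0, det$z, 0.6), det)
  big <- ref$response > 0.05
  expect_equal(fit$response[big], ref$response[big], tolerance = 0.02)
})

test_that("NMR detector fits recover rate-space responses", {
  sens <- suppressWarnings(nmr_sensitivities(hets_experiments()))
  det <- optimize_detectors(sens, 5)
  dist <- delta_distribution(10^det$z0[3], det$z, amplitude = 0.4)
  x <- responses_from_distribution(dist, det)
  m <- backcalc_measurements(x, sens, det)
  fit <- fit_responses(m, rep(1e-3, length(m)) * pmax(abs(m), 1e-3),
                       sens, det, nonneg = FALSE)
  expect_equal(fit$response, x$response, tolerance = 1e-6)
})

test_that("detector sets round-trip through text", {
  s <- make_md_set()
  det <- optimize_detectors(s, 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_detectors(det, path)
  det2 <- read_detectors(path)
  expect_equal(det2$rho, det$rho, tolerance = 1e-12)
  expect_equal(det2$z0, det$z0, tolerance = 1e-12)
  expect_equal(det2$mode, det$mode)
  # a reloaded set fits identically
  dist <- delta_distribution(1e-8, det$z, 0.5)
  expect_equal(responses_from_distribution(dist, det2)$response,
               responses_from_distribution(dist, det)$response,
               tolerance = 1e-10)
})
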