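md_det_fast <- function() {
  # windows spanning the methyl regime (10 fs - few ns)
  s <- md_sensitivities(10^seq(-13.5, -8, by = 0.25))
  list(sens = s, det = optimize_detectors(s, 5))
}

test_that("librational order parameter has the right limits and shape", {
  expect_equal(libration_order_parameter(0), 1)
  # free-rotation limit: P2(cos 110.5 deg)^2
  lim <- ((3 * cos(110.5 * pi / 180)^2 - 1) / 2)^2
  expect_equal(libration_order_parameter(10), lim, tolerance = 1e-6)
  sig <- seq(0, 2, by = 0.05)
  expect_true(all(diff(libration_order_parameter(sig)) <= 1e-12))
  expect_error(libration_order_parameter(-0.1), "sigma")
})

test_that("closed-form order parameter matches Gauss-Hermite quadrature", {
  for (sig in c(0.05, 0.2, 0.5, 1.0)) {
    expect_equal(libration_order_parameter(sig),
                 libration_op_gh_oracle(sig), tolerance = 1e-6)
  }
})

test_that("the methyl line is recovered exactly and outliers rejected", {
  sigma <- seq(0.09, 0.30, length.out = 16)
  a <- -12.5
  b <- 0.04
  tau <- 10^(a + b / sigma^2)
  line <- fit_methyl_line(data.frame(tau = tau, sigma = sigma))
  expect_equal(line$intercept, a, tolerance = 1e-10)
  expect_equal(line$slope, b, tolerance = 1e-10)
  expect_length(line$excluded, 0)
  # two gross outliers are excluded and the line recovered
  tau2 <- c(tau, 10^(a + b / 0.12^2 + 6), 10^(a + b / 0.28^2 - 6))
  sigma2 <- c(sigma, 0.12, 0.28)
  line2 <- fit_methyl_line(data.frame(tau = tau2, sigma = sigma2))
  expect_setequal(line2$excluded, c(17, 18))
  expect_equal(line2$intercept, a, tolerance = 1e-8)
  expect_equal(line2$slope, b, tolerance = 1e-8)
  expect_error(fit_methyl_line(data.frame(tau = tau[1:3],
                                          sigma = sigma[1:3])),
               "at least 4")
})

test_that("an Arrhenius ensemble yields a positive slope", {
  set.seed(6)
  E <- runif(30, 8, 20)              # kJ/mol barrier heights
  RT <- 8.314e-3 * 300
  tau <- 1e-13 * exp(E / RT) * 10^rnorm(30, sd = 0.05)
  sigma <- sqrt(0.35 / E)
  line <- fit_methyl_line(data.frame(tau = tau, sigma = sigma))
  expect_gt(line$slope, 0)
})

# a calibration line whose domain covers 10 fs - 1 ns: realistic
# sigma (0.08 - 0.3 rad) over that tau span
test_line <- function() {
  sigma <- c(0.09, 0.12, 0.16, 0.20, 0.25, 0.30)
  fit_methyl_line(data.frame(sigma = sigma,
                             tau = 10^(-14.5 + 0.045 / sigma^2)))
}

test_that("methyl parameters are identifiable from model responses", {
  dd <- md_det_fast()
  line <- test_line()
  # single round trip at 30 ps
  resp <- methyl_model_responses(30e-12, dd$det, line = line)
  fit <- extract_methyl_params(resp, dd$det, line)
  expect_lt(abs(fit$tau_met - 30e-12) / 30e-12, 0.05)
  expect_lt(abs(fit$sigma_libr - line_sigma_test(line, fit$tau_met)),
            1e-6)
  # grid of taus on the line, 10 fs - 1 ns: relative error < 10 %
  for (tau in 10^seq(-13.8, -9.1, by = 0.55)) {
    r <- methyl_model_responses(tau, dd$det, line = line)
    f <- suppressWarnings(extract_methyl_params(r, dd$det, line))
    expect_lt(abs(f$tau_met - tau) / tau, 0.1)
  }
  expect_error(extract_methyl_params(rep(0, 5), dd$det, line),
               "zero-amplitude")
})

test_that("rho0 > rho1 corresponds to fast methyl hopping", {
  # windows like the experimental set: fastest centre near 100 ps, so
  # tau = 30 ps falls in the leftover fast window
  s <- md_sensitivities(10^seq(-10, -7, by = 0.25))
  det <- optimize_detectors(s, 4)
  line <- test_line()
  resp <- methyl_model_responses(30e-12, det, line = line)
  expect_gt(resp[1], resp[2])        # rho0 > rho1 at tau = 30 ps
  fit <- suppressWarnings(
    extract_methyl_params(resp, det, line))
  expect_lt(fit$tau_met, 1e-10)
})

test_that("factoring out the methyl model leaves the planted slow motion", {
  s <- md_sensitivities(10^seq(-13.5, -5, by = 0.25))
  det <- optimize_detectors(s, 6)
  sigma <- 0.22
  s2l <- libration_order_parameter(sigma)
  tau_met <- 30e-12
  tau_chi <- 1e-6
  S2chi <- order_param_3site(c(0.7, 0.3, 0))
  # distribution of the full product process
  th <- function(tau, amp) delta_distribution(tau, det$z, amp)$theta * amp
  theta_tot <- th(10^min(det$z), 1 - s2l) +
    th(tau_met, s2l * 8 / 9) +
    th(tau_chi, s2l * (1 / 9) * (1 - S2chi))
  amp_tot <- (1 - s2l) + s2l * 8 / 9 + s2l / 9 * (1 - S2chi)
  dist <- timescale_distribution(det$z, theta_tot / amp_tot, amp_tot)
  resp <- responses_from_distribution(dist, det)

  params <- structure(list(tau_met = tau_met, sigma_libr = sigma,
                           sigma_libr_deg = sigma * 180 / pi,
                           source = "supplied"),
                      class = "methyl_params")
  out <- factor_out_methyl(resp, det, params, split_rho0 = FALSE)
  # residual concentrated at the window nearest 1 us
  slow <- which.min(abs(det$z0 - log10(tau_chi)))
  expect_equal(which.max(out$residual), slow)
  # that window's residual matches the planted (methyl-scaled) value
  planted_resp <- (1 - S2chi) *
    stats::approx(det$z, det$rho[slow, ], xout = log10(tau_chi))$y
  expect_lt(abs(out$rescaled[slow] - planted_resp) / planted_resp, 0.1)
  # display rescaling is x9 over the raw residual (up to S_lib^2)
  expect_equal(out$rescaled, out$residual * 9 / s2l, tolerance = 1e-12)
  # amplitude bookkeeping: methyl model + residual = total responses
  model <- methyl_model_responses(tau_met, det, sigma = sigma)
  expect_equal(sum(model) + sum(out$residual), sum(resp$response),
               tolerance = 0.05 * sum(resp$response))
})

test_that("methyl-only input leaves no residual and rho0 splits in half", {
  dd <- md_det_fast()
  sigma <- 0.2
  resp <- methyl_model_responses(40e-12, dd$det, sigma = sigma)
  params <- structure(list(tau_met = 40e-12, sigma_libr = sigma,
                           sigma_libr_deg = sigma * 180 / pi,
                           source = "supplied"),
                      class = "methyl_params")
  out <- factor_out_methyl(resp, dd$det, params, split_rho0 = FALSE)
  expect_lt(max(abs(out$residual)), 1e-9)
  outs <- factor_out_methyl(resp + 0.01, dd$det, params)
  r0 <- outs[outs$detector == 0, ]
  expect_equal(nrow(r0), 2)
  expect_setequal(r0$side, c("fast", "slow"))
  expect_equal(r0$residual[1], r0$residual[2])
  # inconsistent parameters are flagged
  expect_error(factor_out_methyl(resp - 0.1, dd$det, params),
               "inconsistent")
})
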