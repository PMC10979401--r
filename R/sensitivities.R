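# Physical constants (SI)
GAMMA_H <- 267.5221874e6   # 1H gyromagnetic ratio, rad s^-1 T^-1
GAMMA_C <- 67.2828e6       # 13C
GAMMA_D <- 41.065e6        # 2H
HBAR <- 1.054571817e-34
R_HC <- 1.09e-10           # effective methyl H-C distance, m
R_DC <- 1.09e-10

# Lorentzian spectral density, J(omega, tau) = (2/5) tau / (1 + (omega tau)^2)
jw <- function(omega, tau) (2 / 5) * tau / (1 + (omega * tau)^2)

# Effective dipolar coupling delta = (mu0/4pi) gamma1 gamma2 hbar / r^3 (rad/s)
dip_delta <- function(g1, g2, r) 1e-7 * g1 * g2 * HBAR / r^3

#' Default log-timescale grid
#'
#' @param kind `"nmr"` gives z in `[-14, -3]` (10 fs to 1 ms); `"md"`
#'   spans `log10(2 dt)` to `log10(T / 5)` for a trajectory of length `T`
#'   seconds sampled every `dt`.
#' @param n Number of grid points (default 200).
#' @param dt,T Trajectory timestep and duration (seconds), `"md"` only.
#' @return Numeric grid of `log10(tau / s)` values.
#' @export
default_zgrid <- function(kind = c("nmr", "md"), n = 200, dt = NULL,
                          T = NULL) {
  kind <- match.arg(kind)
  if (kind == "nmr") return(seq(-14, -3, length.out = n))
  stopifnot(!is.null(dt), !is.null(T))
  seq(log10(2 * dt), log10(T / 5), length.out = n)
}

new_sensitivity_set <- function(z, R, info, kind, scale = NULL) {
  structure(list(z = z, R = R, info = info, kind = kind,
                 scale = scale %||% apply(R, 1, max)),
            class = "sensitivity_set")
}

#' Relaxation-rate sensitivities for methyl 13C experiments
#'
#' Builds the sensitivity R_m(z) of each measurement to motion at
#' correlation time tau = 10^z, from Lorentzian spectral densities
#' J(w, tau) = (2/5) tau / (1 + (w tau)^2) and the standard dipolar
#' (1H-13C) expressions:
#'
#'   R1    = (d^2/4) \[J(wH - wC) + 3 J(wC) + 6 J(wH + wC)\]
#'   sigma = (d^2/4) \[6 J(wH + wC) - J(wH - wC)\]   (NOE cross-relaxation)
#'   R1rho = (1/2) R1(lab terms) +
#'           (d^2/4) (1/3) \[J(w1 - 2wr) + J(w1 + 2wr)
#'                           + 2 J(w1 - wr) + 2 J(w1 + wr)\]
#'
#' where d is the effective H-C dipolar coupling, w1 the spin-lock
#' nutation frequency and wr the MAS frequency; the near-rotary-resonance
#' terms J(w1 +/- wr), J(w1 +/- 2wr) dominate for slow motion. Optional
#' add-ons: 13C CSA (default 25 ppm) and the 2H-13C dipolar contribution
#' of a CHD2 methyl; both scale the same spectral-density combinations
#' and can be toggled off.
#'
#' @param experiments Data frame with columns `type` (one of `"R1"`,
#'   `"NOE"`, `"R1p"`), `field_MHz` (1H frequency), and for `"R1p"` also
#'   `MAS_kHz` and `spinlock_kHz`.
#' @param z Log-timescale grid (default [default_zgrid()] `"nmr"`).
#' @param csa_ppm 13C CSA magnitude in ppm (0 disables).
#' @param include_csa,include_dc Toggles for the CSA and 2H-13C add-ons.
#'
#' @return A `sensitivity_set`: grid `z`, matrix `R` (measurement x grid,
#'   units s^-1), and descriptor tibble `info`.
#' @export
#' @examples
#' ex <- hets_experiments()
#' s <- nmr_sensitivities(ex)
#' dim(s$R)
nmr_sensitivities <- function(experiments, z = default_zgrid("nmr"),
                              csa_ppm = 25, include_csa = TRUE,
                              include_dc = TRUE) {
  experiments <- tibble::as_tibble(experiments)
  stopifnot(all(c("type", "field_MHz") %in% names(experiments)))
  bad <- setdiff(experiments$type, c("R1", "NOE", "R1p"))
  if (length(bad)) stop("unknown experiment type: ", paste(bad, collapse = ", "))
  if (any(experiments$field_MHz <= 0)) stop("fields must be > 0")
  tau <- 10^z
  d_hc <- dip_delta(GAMMA_H, GAMMA_C, R_HC)
  d_dc <- dip_delta(GAMMA_D, GAMMA_C, R_DC)

  row_for <- function(type, field, mas_khz, sl_khz) {
    wH <- 2 * pi * field * 1e6
    wC <- wH * GAMMA_C / GAMMA_H
    wD <- wH * GAMMA_D / GAMMA_H
    c2 <- (csa_ppm * 1e-6 * wC)^2 / 3  # CSA interaction strength
    r1_lab <- (d_hc^2 / 4) *
      (jw(wH - wC, tau) + 3 * jw(wC, tau) + 6 * jw(wH + wC, tau))
    # spin-1 (x 8/3) and two deuterons (x 2) for CHD2 labelling
    r1_dc <- (d_dc^2 / 4) * (8 / 3) * 2 *
      (jw(wD - wC, tau) + 3 * jw(wC, tau) + 6 * jw(wD + wC, tau))
    r1_csa <- c2 * jw(wC, tau)
    r1 <- r1_lab +
      (if (include_dc) r1_dc else 0) +
      (if (include_csa) r1_csa else 0)
    if (type == "R1") return(r1)
    if (type == "NOE") {
      return((d_hc^2 / 4) * (6 * jw(wH + wC, tau) - jw(wH - wC, tau)))
    }
    # R1p
    w1 <- 2 * pi * sl_khz * 1e3
    wr <- 2 * pi * mas_khz * 1e3
    if (min(abs(w1 - wr), abs(w1 - 2 * wr)) < 2 * pi * 1e3) {
      warning("spin lock within 1 kHz of a rotary-resonance condition")
    }
    rr <- (1 / 3) * (jw(w1 - 2 * wr, tau) + jw(w1 + 2 * wr, tau) +
                       2 * jw(w1 - wr, tau) + 2 * jw(w1 + wr, tau))
    r1p <- 0.5 * r1_lab + (d_hc^2 / 4) * rr
    if (include_csa) r1p <- r1p + 0.5 * r1_csa + c2 * rr / 2
    if (include_dc) r1p <- r1p + 0.5 * r1_dc
    r1p
  }

  R <- t(mapply(function(ty, f, m, s) row_for(ty, f, m, s),
                experiments$type, experiments$field_MHz,
                experiments$MAS_kHz %||% rep(NA, nrow(experiments)),
                experiments$spinlock_kHz %||% rep(NA, nrow(experiments))))
  dimnames(R) <- NULL
  new_sensitivity_set(z, R, experiments, kind = "nmr")
}

#' The study's experiment set
#'
#' 13C R1 and 1H-13C NOE cross-relaxation at 400, 600 and 700 MHz 1H
#' frequency, and 13C R1rho at 600 MHz with 5 kHz MAS and spin locks of
#' 12, 14 and 19 kHz.
#'
#' @return A tibble of experiment descriptors for [nmr_sensitivities()].
#' @export
hets_experiments <- function() {
  tibble::tibble(
    type = c(rep("R1", 3), rep("NOE", 3), rep("R1p", 3)),
    field_MHz = c(400, 600, 700, 400, 600, 700, 600, 600, 600),
    MAS_kHz = c(rep(NA, 6), 5, 5, 5),
    spinlock_kHz = c(rep(NA, 6), 12, 14, 19))
}

#' Sensitivities of simulation correlation-function lags
#'
#' Each sampled lag t_k of a correlation function senses motion at
#' correlation time tau as `exp(-t_k / tau)`.
#'
#' @param lags Lag times in seconds, all > 0.
#' @param z Log-timescale grid (default spans the lag range).
#' @return A `sensitivity_set` of kind `"md"` (dimensionless rows).
#' @export
#' @examples
#' s <- md_sensitivities(c(1e-9, 1e-8))
#' s$R[1, which.min(abs(s$z + 9))]  # about exp(-1)
md_sensitivities <- function(lags, z = NULL) {
  lags <- as.numeric(lags)
  if (any(lags <= 0)) stop("lags must be > 0")
  if (is.null(z)) {
    z <- seq(log10(min(lags) / 5), log10(max(lags) * 5), length.out = 200)
  }
  R <- t(vapply(lags, function(t) exp(-t / 10^z), numeric(length(z))))
  info <- tibble::tibble(type = "lag", lag_s = lags)
  new_sensitivity_set(z, R, info, kind = "md", scale = rep(1, length(lags)))
}

#' @export
print.sensitivity_set <- function(x, ...) {
  cat("<sensitivity_set> ", nrow(x$R), " measurements (", x$kind,
      "), grid z in [", round(min(x$z), 2), ", ", round(max(x$z), 2),
      "] with ", length(x$z), " points\n", sep = "")
  invisible(x)
}

#' @export
tidy.sensitivity_set <- function(x, ...) {
  m <- nrow(x$R)
  tibble::tibble(
    measurement = rep(seq_len(m), each = length(x$z)),
    z = rep(x$z, m),
    sensitivity = as.numeric(t(x$R)))
}

#' Write / read a sensitivity set as delimited text
#'
#' Matrix block with `#`-prefixed metadata (kind, scales, descriptors);
#' numbers written with 17 significant digits so a round trip reproduces
#' the doubles exactly.
#'
#' @param x A `sensitivity_set`.
#' @param path File path.
#' @export
write_sensitivities <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kind ", x$kind), con)
  writeLines(paste0("# scale ", paste(format(x$scale, digits = 17),
                                      collapse = " ")), con)
  writeLines(paste0("# info ", paste(names(x$info), collapse = ",")), con)
  for (i in seq_len(nrow(x$info))) {
    writeLines(paste0("# inforow ",
                      paste(unlist(x$info[i, ]), collapse = ",")), con)
  }
  writeLines(paste0("# z ", paste(format(x$z, digits = 17),
                                  collapse = " ")), con)
  utils::write.table(format(x$R, digits = 17), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensitivities
#' @export
read_sensitivities <- function(path) {
  ln <- readLines(path)
  meta <- ln[startsWith(ln, "#")]
  body <- ln[!startsWith(ln, "#")]
  get1 <- function(key) sub(paste0("^# ", key, " "), "",
                            meta[grepl(paste0("^# ", key, " "), meta)][1])
  kind <- get1("kind")
  scale <- as.numeric(strsplit(get1("scale"), " +")[[1]])
  z <- as.numeric(strsplit(get1("z"), " +")[[1]])
  cols <- strsplit(get1("info"), ",")[[1]]
  rows <- sub("^# inforow ", "", meta[grepl("^# inforow ", meta)])
  info <- do.call(rbind, lapply(strsplit(rows, ","), function(v) {
    as.data.frame(as.list(stats::setNames(v, cols)))
  }))
  info <- tibble::as_tibble(info)
  for (nm in intersect(c("field_MHz", "MAS_kHz", "spinlock_kHz", "lag_s"),
                       names(info))) {
    info[[nm]] <- suppressWarnings(as.numeric(info[[nm]]))
  }
  R <- as.matrix(utils::read.table(text = body))
  dimnames(R) <- NULL
  new_sensitivity_set(z, R, info, kind = kind, scale = scale)
}
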