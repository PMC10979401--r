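#' Frame hierarchy for a methyl-bearing residue type
#'
#' The motional components resolved for each residue type: methyl
#' rotation (always), chi1 rotation (Val, Leu, Ile), chi2 rotation
#' (Leu, Ile) and reorientation of the Ca-Cb bond, with each rotation
#' split into 3-site hopping and libration — 7 components for Ile/Leu,
#' 5 for Val, 3 for Ala.
#'
#' @param restype One of `"Ala"`, `"Val"`, `"Leu"`, `"Ile"`.
#' @return A tibble with columns `component` and `axis`.
#' @export
#' @examples
#' nrow(frame_hierarchy("Ile"))  # 7
frame_hierarchy <- function(restype = c("Ala", "Val", "Leu", "Ile")) {
  restype <- match.arg(restype)
  comp <- c("methyl-hop", "methyl-libr")
  axis <- c("methyl", "methyl")
  if (restype %in% c("Leu", "Ile")) {
    comp <- c(comp, "chi2-hop", "chi2-libr")
    axis <- c(axis, "chi2", "chi2")
  }
  if (restype %in% c("Val", "Leu", "Ile")) {
    comp <- c(comp, "chi1-hop", "chi1-libr")
    axis <- c(axis, "chi1", "chi1")
  }
  comp <- c(comp, "CaCb")
  axis <- c(axis, "CaCb")
  tibble::tibble(component = comp, axis = axis)
}

#' Split a dihedral series into hops and libration
#'
#' Assigns each angle to the nearest staggered rotamer well (centres
#' -60, 60, 180 degrees by default), replaces it by the circular mean
#' of its state ("hop" series), and keeps the wrapped deviation from
#' that mean ("libration" series). Hop + libration reconstructs the
#' input exactly (modulo 360).
#'
#' @param dihedral Numeric vector of angles in degrees, in (-180, 180].
#' @param centers Ideal state centres in degrees.
#' @return A list with elements `hop`, `libration` (degrees), `state`
#'   (integer index into `centers`) and `state_means`.
#' @export
#' @examples
#' s <- split_hop_libration(c(-58, -61, 62, 179))
#' s$state
split_hop_libration <- function(dihedral, centers = c(-60, 60, 180)) {
  dihedral <- wrap_deg(dihedral)
  dmat <- abs(wrap_deg(outer(dihedral, centers, "-")))
  state <- max.col(-dmat)
  means <- vapply(seq_along(centers), function(i) {
    if (!any(state == i)) return(centers[i])
    circ_mean_deg(dihedral[state == i])
  }, numeric(1))
  hop <- means[state]
  libr <- wrap_deg(dihedral - hop)
  list(hop = hop, libration = libr, state = state, state_means = means)
}

#' Compose the methyl H-C unit vector from a dihedral chain
#'
#' Builds the H-C bond orientation in the outer (Ca-Cb) frame from the
#' dihedral series using ideal tetrahedral geometry: successive
#' rotation axes at 109.47 degrees, H-C at 110.5 degrees to the methyl
#' axis. Innermost rotation first: methyl, then chi2 (if given), then
#' chi1 (if given).
#'
#' @param methyl Methyl rotation angle series, degrees.
#' @param chi1,chi2 Optional chi1/chi2 series, degrees.
#' @return An n x 3 matrix of unit vectors.
#' @export
compose_hc_vectors <- function(methyl, chi1 = NULL, chi2 = NULL) {
  beta <- deg2rad(HC_AXIS_DEG)
  alpha <- deg2rad(TETRA_DEG)
  phi <- deg2rad(methyl)
  u <- cbind(sin(beta) * cos(phi), sin(beta) * sin(phi),
             rep(cos(beta), length(phi)))
  if (!is.null(chi2)) {
    u <- rot_y_fixed(u, alpha)
    u <- rot_z_rows(u, deg2rad(chi2))
  }
  if (!is.null(chi1)) {
    u <- rot_y_fixed(u, alpha)
    u <- rot_z_rows(u, deg2rad(chi1))
  }
  u
}

# Unit vector at tilt `tilt_deg` from z with azimuth series (degrees):
# the geometry of a single rotation seen in its own frame.
cone_vectors <- function(azimuth_deg, tilt_deg) {
  a <- deg2rad(tilt_deg)
  phi <- deg2rad(azimuth_deg)
  cbind(sin(a) * cos(phi), sin(a) * sin(phi), rep(cos(a), length(phi)))
}

#' Frame-wise decomposition of methyl H-C motion
#'
#' Computes one rank-2 correlation function per motion: methyl hopping
#' and libration (H-C at 110.5 degrees to the methyl axis), chi1/chi2
#' hopping and libration (the inner rotation axis at 109.47 degrees to
#' the rotation axis), and Ca-Cb reorientation — each in the frame of
#' the next-outer rotation, assuming the motions are uncorrelated and
#' timescale-separated so the total factorises as the product of the
#' components. The total H-C correlation function is also computed
#' directly from the composed vector chain and compared to the product
#' ([product_residual()]).
#'
#' @param dihedrals Data frame with a `methyl` column and, as required
#'   by `restype`, `chi1` and `chi2` columns (degrees).
#' @param restype Residue type: `"Ala"`, `"Val"`, `"Leu"` or `"Ile"`.
#' @param dt Timestep in seconds.
#' @param cacb_vectors Optional n x 3 unit-vector series for the Ca-Cb
#'   bond in the molecular frame; if omitted the bond is held fixed and
#'   its component is identically 1.
#' @param lags Integer lag indices (default log-spaced to n/2).
#'
#' @return A `decomposed_corr` object: named list of `corr_fn`
#'   components, the directly computed `total`, and the product
#'   `residual` (RMS of product minus total).
#' @export
decompose_sidechain <- function(dihedrals, restype, dt,
                                cacb_vectors = NULL, lags = NULL) {
  hier <- frame_hierarchy(restype)
  need <- setdiff(unique(hier$axis), "CaCb")
  axis_col <- c(methyl = "methyl", chi1 = "chi1", chi2 = "chi2")
  for (ax in need) {
    if (!axis_col[[ax]] %in% names(dihedrals)) {
      stop("residue type ", restype, " requires a '", axis_col[[ax]],
           "' dihedral column")
    }
  }
  n <- nrow(dihedrals)
  if (is.null(lags)) lags <- log_lags(n %/% 2)

  splits <- lapply(stats::setNames(need, need), function(ax) {
    split_hop_libration(dihedrals[[axis_col[[ax]]]])
  })

  comp_fn <- function(component) {
    ax <- hier$axis[hier$component == component]
    if (ax == "CaCb") {
      if (is.null(cacb_vectors)) {
        return(new_corr_fn(lags * dt, rep(1, length(lags)), dt = dt))
      }
      return(rank2_correlation(cacb_vectors, lags = lags, dt = dt))
    }
    tilt <- if (ax == "methyl") HC_AXIS_DEG else TETRA_DEG
    series <- if (grepl("hop", component)) splits[[ax]]$hop
              else splits[[ax]]$libration
    rank2_correlation(cone_vectors(series, tilt), lags = lags, dt = dt)
  }
  comps <- lapply(stats::setNames(hier$component, hier$component), comp_fn)

  vtot <- compose_hc_vectors(
    dihedrals$methyl,
    chi1 = if ("chi1" %in% names(dihedrals) &&
               restype != "Ala") dihedrals$chi1 else NULL,
    chi2 = if ("chi2" %in% names(dihedrals) &&
               restype %in% c("Leu", "Ile")) dihedrals$chi2 else NULL)
  total <- rank2_correlation(vtot, lags = lags, dt = dt)

  out <- structure(list(components = comps, total = total,
                        restype = restype),
                   class = "decomposed_corr")
  out$residual <- product_residual(out, total)
  out
}

#' Product-reconstruction residual
#'
#' Root-mean-square difference between the product of the component
#' correlation functions and the directly computed total: a measure of
#' how well the independence / timescale-separation assumption holds.
#'
#' @param components A `decomposed_corr` (or list of `corr_fn` with
#'   matching lags).
#' @param total A `corr_fn` on the same lags.
#' @return RMS of `prod_n C_n(t) - C_total(t)` over lags.
#' @export
product_residual <- function(components, total) {
  comps <- if (inherits(components, "decomposed_corr")) {
    components$components
  } else {
    components
  }
  for (cf in comps) {
    if (nrow(cf) != nrow(total) || max(abs(cf$lag - total$lag)) > 1e-15) {
      stop("component lags do not match the total")
    }
  }
  prod_vals <- Reduce(`*`, lapply(comps, function(cf) cf$value))
  sqrt(mean((prod_vals - total$value)^2))
}

#' @export
print.decomposed_corr <- function(x, ...) {
  cat("<decomposed_corr> ", x$restype, ": ",
      length(x$components), " components, product residual ",
      signif(x$residual, 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.decomposed_corr <- function(x, ...) {
  purrr::imap_dfr(c(x$components, list(total = x$total)),
                  function(cf, nm) {
                    tibble::tibble(component = nm, lag = cf$lag,
                                   value = cf$value)
                  })
}

#' @export
autoplot.decomposed_corr <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$lag > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag, y = .data$value,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lag time (s)", y = "C(t)") +
    ggplot2::theme_minimal()
}
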