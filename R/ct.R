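#' Default CT density calibration nodes
#'
#' A generic external-beam-planning style HU-to-mass-density curve. Against
#' the packaged printing resins the clinical-style curve slightly
#' overpredicts mass density (e.g. ~1.212 g/cc at 292.48 HU versus the
#' manufacturer 1.21 g/cc), mirroring the behaviour seen when bulk resin
#' ROIs are placed on a characterized planning scanner.
#'
#' @return A tibble with columns `hu` and `density_g_cc`.
#' @export
default_density_calibration <- function() {
  tibble::tibble(
    hu = c(-1000, 0, 1000, 2000),
    density_g_cc = c(0.00121, 1.000, 1.726, 2.32)
  )
}

piecewise_linear <- function(x, nodes_x, nodes_y) {
  if (length(nodes_x) < 2L) abort("At least 2 calibration nodes are required.")
  if (any(diff(nodes_x) <= 0)) {
    abort("Calibration nodes must be strictly increasing in HU.")
  }
  # linear interpolation, extrapolated with the end-segment slopes
  n <- length(nodes_x)
  y <- approx(nodes_x, nodes_y, xout = pmin(pmax(x, nodes_x[1]), nodes_x[n]),
              rule = 2)$y
  lo <- x < nodes_x[1]
  if (any(lo)) {
    s <- (nodes_y[2] - nodes_y[1]) / (nodes_x[2] - nodes_x[1])
    y[lo] <- nodes_y[1] + s * (x[lo] - nodes_x[1])
  }
  hi <- x > nodes_x[n]
  if (any(hi)) {
    s <- (nodes_y[n] - nodes_y[n - 1]) / (nodes_x[n] - nodes_x[n - 1])
    y[hi] <- nodes_y[n] + s * (x[hi] - nodes_x[n])
  }
  y
}

#' Convert an HU image to mass density
#'
#' Linear interpolation between calibration nodes; outside the node range
#' the end-segment slopes are continued.
#'
#' @param hu a `voxel_image` in HU.
#' @param calibration a data frame with columns `hu` and `density_g_cc`,
#'   strictly increasing in HU (default [default_density_calibration()]).
#' @return A `voxel_image` in g/cc.
#' @export
hu_to_density <- function(hu, calibration = default_density_calibration()) {
  stop_if_units(hu, "HU", "hu")
  out <- piecewise_linear(as.vector(hu$data), calibration$hu,
                          calibration$density_g_cc)
  with_data(hu, array(out, dim(hu$data)), units = "g/cc")
}

#' Bilinear HU-to-attenuation coefficients at 364 keV
#'
#' The soft segment runs from air (-1000 HU, zero attenuation) to water;
#' the hard segment's slope is a least-squares fit through the water point
#' to the measured (HU, mu) pairs of the two printing resins. Residuals of
#' the fit against the measured resin coefficients are below 0.1%.
#'
#' @return A list with `energy_keV`, `hu_water`, `mu_water`, `slope_soft`,
#'   `slope_hard` (cm^-1 per HU).
#' @export
default_mu_calibration <- function() {
  hu_w <- -4.05; mu_w <- 0.0896
  pts_hu <- c(292.48, 876.36) - hu_w
  pts_mu <- c(0.1063, 0.1390) - mu_w
  slope_hard <- sum(pts_hu * pts_mu) / sum(pts_hu^2)
  list(energy_keV = 364, hu_water = hu_w, mu_water = mu_w,
       slope_soft = mu_w / (hu_w + 1000), slope_hard = slope_hard)
}

#' Convert an HU image to linear attenuation coefficients
#'
#' @param hu a `voxel_image` in HU.
#' @param energy_keV photon energy; coefficients must be configured for it
#'   (the default calibration covers 364 keV only).
#' @param bilinear a bilinear coefficient list as returned by
#'   [default_mu_calibration()].
#' @return A `voxel_image` of attenuation coefficients in cm^-1 (tagged
#'   `dimensionless`-free as `g/cc` is not applicable; the per-cm scale is
#'   recorded in the `mu_units` attribute).
#' @export
hu_to_mu <- function(hu, energy_keV = 364, bilinear = default_mu_calibration()) {
  stop_if_units(hu, "HU", "hu")
  if (!isTRUE(all.equal(energy_keV, bilinear$energy_keV))) {
    abort(sprintf("No attenuation coefficients configured for %g keV.",
                  energy_keV))
  }
  h <- as.vector(hu$data) - bilinear$hu_water
  mu <- ifelse(h <= 0, bilinear$mu_water + bilinear$slope_soft * h,
               bilinear$mu_water + bilinear$slope_hard * h)
  mu <- pmax(mu, 0)
  out <- with_data(hu, array(mu, dim(hu$data)), units = "dimensionless")
  attr(out, "mu_units") <- "cm^-1"
  out
}
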