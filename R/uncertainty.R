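erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Fractional volume-delineation uncertainty
#'
#' For a contoured structure of equivalent sphere diameter `D` on a grid of
#' voxel size `a`, the fractional volume uncertainty is
#' `u(v)/v = 3 a / (sqrt(6) D)`: linear in voxel size and inversely
#' proportional to object diameter.
#'
#' @param D equivalent sphere diameter in mm (> 0).
#' @param a voxel size in mm (> 0).
#' @return Dimensionless fractional uncertainty.
#' @examples
#' volume_uncertainty(31.3, 4.42)  # 0.173
#' volume_uncertainty(9.9, 4.42)   # 0.547
#' @export
volume_uncertainty <- function(D, a) {
  if (any(D <= 0) || any(a <= 0)) abort("`D` and `a` must be > 0 mm.")
  3 * a / (sqrt(6) * D)
}

#' Fractional calibration-factor uncertainty
#'
#' Quadrature combination of the radionuclide-calibrator assay uncertainty
#' (typically 5%) and the repeat-scan count-rate uncertainty.
#'
#' @param u_Acal_frac fractional calibrator uncertainty (>= 0).
#' @param u_Cref_frac fractional count-rate uncertainty (>= 0).
#' @return Dimensionless fractional uncertainty of Q.
#' @examples
#' calibration_uncertainty(0.05, 0.0555)  # 0.0747
#' @export
calibration_uncertainty <- function(u_Acal_frac, u_Cref_frac) {
  if (any(u_Acal_frac < 0) || any(u_Cref_frac < 0)) {
    abort("Fractional uncertainties must be >= 0.")
  }
  sqrt(u_Acal_frac^2 + u_Cref_frac^2)
}

#' Fractional recovery-coefficient uncertainty
#'
#' First-order propagation `u^2(RC) = g^T V_c g` where `g` is the gradient
#' of the fitted RC curve with respect to `(R_plateau, beta, gamma, v)` and
#' `V_c` is the 4x4 covariance: the fit-parameter covariance bordered by the
#' volume variance `u2_v`. With `u2_v = 0` this reduces to pure
#' fit-parameter propagation.
#'
#' @param fit an `rc_fit`.
#' @param v VOI volume in ml.
#' @param u2_v volume variance in ml^2 (default: the fit's stored `V_c[4,4]`).
#' @return Fractional uncertainty `u(RC)/RC`.
#' @export
rc_uncertainty <- function(fit, v, u2_v = NULL) {
  if (v <= 0) abort("`v` must be > 0 ml.")
  V_c <- fit$V_c
  if (!is.null(u2_v)) V_c[4, 4] <- u2_v
  if (any(abs(V_c - t(V_c)) > 1e-10)) abort("V_c must be symmetric.")
  ev <- eigen(V_c, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1e-300)) {
    abort("V_c must be positive semidefinite.")
  }
  g <- as.numeric(rc_curve_grad(v, fit$R_plateau, fit$beta, fit$gamma))
  rc <- rc_curve(v, fit$R_plateau, fit$beta, fit$gamma)
  sqrt(max(drop(g %*% V_c %*% g), 0)) / rc
}

#' Gaussian count fraction of a blurred sphere
#'
#' `phi = erf(r / (sqrt(2) sigma)) -
#'  (sqrt(2) sigma) / (r sqrt(pi)) * (1 - exp(-r^2 / (2 sigma^2)))`,
#' a fraction in (0, 1) that rises monotonically with `r / sigma`: it
#' vanishes for structures much smaller than the point-spread function and
#' approaches 1 for structures much larger.
#'
#' @param r equivalent sphere radius in mm (> 0).
#' @param sigma Gaussian PSF standard deviation in mm (> 0, typically 3 mm).
#' @return Dimensionless fraction.
#' @examples
#' phi_fraction(15.65, 3)  # 0.847
#' phi_fraction(4.95, 3)   # 0.541
#' @export
phi_fraction <- function(r, sigma = 3) {
  if (any(r <= 0) || any(sigma <= 0)) abort("`r` and `sigma` must be > 0 mm.")
  erf(r / (sqrt(2) * sigma)) -
    (sqrt(2) * sigma) / (r * sqrt(pi)) * (1 - exp(-r^2 / (2 * sigma^2)))
}

#' Fractional mean-counts uncertainty from VOI delineation
#'
#' `u(C)/C = (phi / (2 RC)) * (u(v)/v)`: delineation error translates into
#' count error through the count fraction phi, amplified where recovery is
#' poor.
#'
#' @param phi Gaussian count fraction from [phi_fraction()].
#' @param RC recovery coefficient (> 0).
#' @param u_v_frac fractional volume uncertainty.
#' @return Dimensionless fractional uncertainty.
#' @examples
#' counts_uncertainty(phi_fraction(15.65, 3), 0.514,
#'                    volume_uncertainty(31.3, 4.42))  # 0.143
#' @export
counts_uncertainty <- function(phi, RC, u_v_frac) {
  if (any(RC <= 0)) abort("`RC` must be > 0.")
  phi / (2 * RC) * u_v_frac
}

#' Combined fractional cumulated-activity uncertainty
#'
#' Quadrature sum of the calibration, recovery-coefficient and mean-counts
#' fractional uncertainties, minus the covariance of counts and RC on the
#' shared volume error:
#' `cov = 2 * (phi / (2 RC)) * (v dRC/dv / RC) * (u(v)/v)^2`.
#' The result can never exceed the plain quadrature sum; if the covariance
#' term over-subtracts (negative variance) an error reports all terms.
#'
#' @param u_q_frac,u_RC_frac,u_C_frac fractional components.
#' @param fit an `rc_fit` supplying the curve slope (optional if
#'   `covariance = 0` is acceptable).
#' @param v VOI volume in ml.
#' @param u_v_frac fractional volume uncertainty (drives the covariance).
#' @param phi Gaussian count fraction.
#' @return Fractional uncertainty `u(A_cum)/A_cum`.
#' @export
combined_activity_uncertainty <- function(u_q_frac, u_RC_frac, u_C_frac,
                                          fit = NULL, v = NULL,
                                          u_v_frac = 0, phi = 0) {
  quad <- u_q_frac^2 + u_RC_frac^2 + u_C_frac^2
  covar <- 0
  if (!is.null(fit) && !is.null(v)) {
    ev <- rc_eval_and_derivative(fit, v)
    covar <- 2 * (phi / (2 * ev$RC)) * (v * ev$dRC_dv / ev$RC) * u_v_frac^2
  }
  var_c <- quad - covar
  if (var_c < 0) {
    abort(sprintf(
      "Covariance term over-subtracts: u_q=%.4g u_RC=%.4g u_C=%.4g quad=%.4g cov=%.4g.",
      u_q_frac, u_RC_frac, u_C_frac, quad, covar))
  }
  sqrt(var_c)
}

#' Per-VOI uncertainty budget table
#'
#' Assembles the full fractional budget for a set of VOIs: volume (`u_v`),
#' calibration (`u_q`), recovery coefficient (`u_RC`), mean counts (`u_C`),
#' the count fraction `phi`, and the combined cumulated-activity
#' uncertainty (`u_A`), all as dimensionless fractions.
#'
#' @param vois data frame with columns `name` and `volume_ml`; an optional
#'   `D_mm` column supplies physical insert diameters, otherwise the
#'   equivalent sphere diameter of the volume is used.
#' @param fit an `rc_fit` for RC values, slopes and covariance.
#' @param u_Acal_frac,u_Cref_frac calibration components (defaults: the 5%
#'   calibrator assumption and zero repeat-scan term).
#' @param sigma_mm PSF standard deviation for phi (default 3 mm).
#' @param a_mm voxel size for the volume term (default 4.42 mm).
#' @return A tibble, one row per VOI, with the components above.
#' @export
budget_table <- function(vois, fit, u_Acal_frac = 0.05, u_Cref_frac = 0,
                         sigma_mm = 3, a_mm = 4.42) {
  stopifnot(is.data.frame(vois), all(c("name", "volume_ml") %in% names(vois)))
  u_q <- calibration_uncertainty(u_Acal_frac, u_Cref_frac)
  purrr::map_dfr(seq_len(nrow(vois)), function(i) {
    v <- vois$volume_ml[i]
    geom <- voi_geometry(v, a_mm)
    if ("D_mm" %in% names(vois) && is.finite(vois$D_mm[i])) {
      geom$D_mm <- vois$D_mm[i]
      geom$r_mm <- vois$D_mm[i] / 2
    }
    u_v <- volume_uncertainty(geom$D_mm, a_mm)
    phi <- phi_fraction(geom$r_mm, sigma_mm)
    ev <- rc_eval_and_derivative(fit, v)
    u_rc <- rc_uncertainty(fit, v, u2_v = (u_v * v)^2)
    u_c <- counts_uncertainty(phi, ev$RC, u_v)
    u_a <- combined_activity_uncertainty(u_q, u_rc, u_c, fit = fit, v = v,
                                         u_v_frac = u_v, phi = phi)
    tibble::tibble(
      name = vois$name[i], volume_ml = v, D_mm = geom$D_mm,
      RC = ev$RC, phi = phi, u_v_frac = u_v, u_q_frac = u_q,
      u_RC_frac = u_rc, u_C_frac = u_c, u_A_frac = u_a,
      extrapolated = ev$extrapolated
    )
  })
}

#' Plot an uncertainty budget
#'
#' Fractional uncertainty components versus VOI volume on a log-x axis.
#'
#' @param budget a tibble from [budget_table()].
#' @return A ggplot object.
#' @export
plot_uncertainty_budget <- function(budget) {
  df <- budget |>
    dplyr::select("volume_ml", "u_v_frac", "u_q_frac", "u_RC_frac",
                  "u_C_frac", "u_A_frac") |>
    tidyr::pivot_longer(-"volume_ml", names_to = "component",
                        values_to = "fraction") |>
    dplyr::mutate(component = factor(.data$component,
                                     levels = c("u_v_frac", "u_q_frac",
                                                "u_RC_frac", "u_C_frac",
                                                "u_A_frac"),
                                     labels = c("volume", "calibration",
                                                "recovery coefficient",
                                                "mean counts",
                                                "cumulated activity")))
  ggplot2::ggplot(df, ggplot2::aes(.data$volume_ml, 100 * .data$fraction,
                                   colour = .data$component)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "VOI volume (ml)", y = "fractional uncertainty (%)",
                  colour = NULL)
}
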