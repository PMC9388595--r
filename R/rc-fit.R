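#' Plateau recovery-coefficient curve
#'
#' `rc_curve(v) = R_plateau - R_plateau / (1 + (v / beta)^gamma)`, a
#' three-parameter sigmoid in volume rising from 0 to `R_plateau`. At
#' `v = beta` the curve passes through `R_plateau / 2`.
#'
#' @param v volume in ml.
#' @param R_plateau,beta,gamma curve parameters (`beta` in ml).
#' @return Recovery coefficient values.
#' @export
rc_curve <- function(v, R_plateau, beta, gamma) {
  R_plateau - R_plateau / (1 + (v / beta)^gamma)
}

rc_curve_grad <- function(v, R_plateau, beta, gamma) {
  t <- (v / beta)^gamma
  denom <- (1 + t)^2
  cbind(
    R_plateau = t / (1 + t),
    beta = -R_plateau * gamma * t / (beta * denom),
    gamma = R_plateau * t * log(v / beta) / denom,
    v = R_plateau * gamma * t / (v * denom)
  )
}

#' Fit the recovery-coefficient curve
#'
#' Least-squares fit of [rc_curve()] to measured (volume, RC) points,
#' optionally weighted. Initialization: `R_plateau = max(RC)`,
#' `beta = median(volume)`, `gamma = 1`, with box bounds
#' `R_plateau in (0, 1.5]`, `beta in (0, 1000]` ml, `gamma in (0, 10]`.
#' The 3x3 parameter covariance from the fit is bordered by the volume
#' variance `u2_v` into the 4x4 covariance `V_c` used by the uncertainty
#' propagation (parameter block plus an independent volume block).
#'
#' @param points data frame with columns `volume_ml` and `RC` (>= 4 distinct
#'   volumes), e.g. from [simulate_rc_points()].
#' @param u2_v volume variance in ml^2 attached to `V_c` (scalar; may also be
#'   supplied later per-VOI to [rc_uncertainty()]).
#' @param weights optional per-point weights for the least squares (default
#'   unweighted).
#' @return An `rc_fit` object with elements `R_plateau`, `beta`, `gamma`,
#'   `cov` (3x3), `V_c` (4x4), `points`, `fit` (the underlying `nls` object),
#'   and `fit_range_ml`.
#' @examples
#' pts <- tibble::tibble(volume_ml = c(0.5, 1, 2, 4, 8, 16),
#'                       RC = rc_curve(c(0.5, 1, 2, 4, 8, 16), 0.8, 2, 1.5))
#' fit <- fit_rc_curve(pts)
#' tidy(fit)
#' @export
fit_rc_curve <- function(points, u2_v = 0, weights = NULL) {
  stopifnot(is.data.frame(points),
            all(c("volume_ml", "RC") %in% names(points)))
  if (length(unique(points$volume_ml)) < 4L) {
    abort("At least 4 points with distinct volumes are required.")
  }
  df <- data.frame(v = points$volume_ml, rc = points$RC)
  start <- list(R_plateau = max(df$rc), beta = median(df$v), gamma = 1)
  do_fit <- function() {
    if (is.null(weights)) {
      minpack.lm::nlsLM(
        rc ~ rc_curve(v, R_plateau, beta, gamma), data = df, start = start,
        lower = c(R_plateau = 1e-6, beta = 1e-6, gamma = 1e-6),
        upper = c(R_plateau = 1.5, beta = 1000, gamma = 10),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(
        rc ~ rc_curve(v, R_plateau, beta, gamma), data = df, start = start,
        lower = c(R_plateau = 1e-6, beta = 1e-6, gamma = 1e-6),
        upper = c(R_plateau = 1.5, beta = 1000, gamma = 10),
        weights = weights,
        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }
  fit <- tryCatch(
    do_fit(),
    error = function(e) {
      abort(sprintf(
        "RC curve fit did not converge (start R_plateau=%.3g, beta=%.3g, gamma=%.3g): %s",
        start$R_plateau, start$beta, start$gamma, conditionMessage(e)))
    }
  )
  est <- coef(fit)
  cov3 <- tryCatch(vcov(fit), error = function(e) matrix(0, 3, 3))
  if (any(!is.finite(cov3))) cov3 <- matrix(0, 3, 3)
  V_c <- matrix(0, 4, 4,
                dimnames = list(c("R_plateau", "beta", "gamma", "v"),
                                c("R_plateau", "beta", "gamma", "v")))
  V_c[1:3, 1:3] <- cov3
  V_c[4, 4] <- u2_v
  structure(
    list(R_plateau = unname(est["R_plateau"]), beta = unname(est["beta"]),
         gamma = unname(est["gamma"]), cov = cov3, V_c = V_c,
         points = tibble::as_tibble(points), fit = fit,
         fit_range_ml = range(points$volume_ml)),
    class = "rc_fit"
  )
}

#' @export
print.rc_fit <- function(x, ...) {
  cat(sprintf(
    "<rc_fit> RC(v) = %.4g - %.4g / (1 + (v/%.4g)^%.4g), fitted on %d points (%.3g-%.3g ml)\n",
    x$R_plateau, x$R_plateau, x$beta, x$gamma, nrow(x$points),
    x$fit_range_ml[1], x$fit_range_ml[2]))
  invisible(x)
}

#' Evaluate a fitted RC curve and its volume derivative
#'
#' The analytic derivative is
#' `dRC/dv = R_plateau * gamma * (v/beta)^gamma / (v * (1 + (v/beta)^gamma)^2)`,
#' which is non-negative and vanishes at the plateau. Volumes outside the
#' fitted range are flagged as extrapolated.
#'
#' @param fit an `rc_fit` (or a list with `R_plateau`, `beta`, `gamma`).
#' @param v volume(s) in ml, > 0.
#' @return A tibble with `volume_ml`, `RC`, `dRC_dv`, `extrapolated`.
#' @examples
#' f <- list(R_plateau = 0.8, beta = 2, gamma = 1.5)
#' rc_eval_and_derivative(f, 2)  # RC 0.4, slope 0.15 / ml
#' @export
rc_eval_and_derivative <- function(fit, v) {
  if (any(v <= 0)) abort("`v` must be > 0 ml.")
  t <- (v / fit$beta)^fit$gamma
  rng <- fit$fit_range_ml %||% c(-Inf, Inf)
  tibble::tibble(
    volume_ml = v,
    RC = rc_curve(v, fit$R_plateau, fit$beta, fit$gamma),
    dRC_dv = fit$R_plateau * fit$gamma * t / (v * (1 + t)^2),
    extrapolated = v < rng[1] | v > rng[2]
  )
}

#' @export
tidy.rc_fit <- function(x, conf.level = 0.95, ...) {
  est <- c(R_plateau = x$R_plateau, beta = x$beta, gamma = x$gamma)
  se <- sqrt(pmax(diag(x$cov), 0))
  dfree <- max(nrow(x$points) - 3L, 1L)
  tq <- qt(1 - (1 - conf.level) / 2, dfree)
  tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    conf.low = unname(est - tq * se), conf.high = unname(est + tq * se)
  )
}

#' @export
glance.rc_fit <- function(x, ...) {
  res <- x$points$RC - rc_curve(x$points$volume_ml, x$R_plateau, x$beta,
                                x$gamma)
  tibble::tibble(
    nobs = nrow(x$points),
    sigma = sqrt(sum(res^2) / max(nrow(x$points) - 3L, 1L)),
    rss = sum(res^2),
    df.residual = max(nrow(x$points) - 3L, 1L),
    converged = x$fit$convInfo$isConv %||% TRUE
  )
}

#' Plot a fitted RC curve with confidence bounds
#'
#' Measured points, the fitted curve and a pointwise 95% confidence band
#' from first-order propagation of the fit-parameter covariance.
#'
#' @param object an `rc_fit`.
#' @param v_max upper volume for the curve (default 1.5x the largest point).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rc_fit <- function(object, v_max = NULL, ...) {
  v_max <- v_max %||% (1.5 * max(object$points$volume_ml))
  vv <- seq(min(object$points$volume_ml) / 2, v_max, length.out = 200)
  g <- rc_curve_grad(vv, object$R_plateau, object$beta, object$gamma)[, 1:3]
  se <- sqrt(pmax(rowSums((g %*% object$cov) * g), 0))
  rc_line <- rc_curve(vv, object$R_plateau, object$beta, object$gamma)
  df <- tibble::tibble(volume_ml = vv, RC = rc_line,
                       lo = rc_line - 1.96 * se, hi = rc_line + 1.96 * se)
  ggplot2::ggplot(df, ggplot2::aes(.data$volume_ml, .data$RC)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$points,
                        ggplot2::aes(.data$volume_ml, .data$RC)) +
    ggplot2::labs(x = "VOI volume (ml)", y = "recovery coefficient")
}
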