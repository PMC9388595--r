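test_that("volume uncertainty reproduces both sphere-set endpoints", {
  expect_equal(round(volume_uncertainty(31.3, 4.42), 3), 0.173)
  expect_equal(round(volume_uncertainty(9.9, 4.42), 3), 0.547)
  # dimensionless: scaling D and a together changes nothing
  expect_equal(volume_uncertainty(2 * 31.3, 2 * 4.42),
               volume_uncertainty(31.3, 4.42))
  expect_error(volume_uncertainty(0, 4.42), "> 0")
})

test_that("calibration uncertainty is a quadrature sum", {
  expect_equal(calibration_uncertainty(0.05, 0), 0.05)
  expect_equal(calibration_uncertainty(0, 0), 0)
  expect_equal(calibration_uncertainty(0.05, 0.0555), 0.0747,
               tolerance = 1e-3)
  expect_equal(calibration_uncertainty(0.03, 0.04), 0.05)
})

test_that("phi count fraction has the right limits and monotone shape", {
  expect_equal(phi_fraction(15.65, 3), 0.847, tolerance = 1e-3)
  expect_equal(phi_fraction(4.95, 3), 0.541, tolerance = 1e-3)
  expect_equal(phi_fraction(1e6, 3), 1, tolerance = 1e-5)
  expect_lt(phi_fraction(0.01, 3), 0.01)
  r <- seq(0.5, 60, length.out = 100)
  ph <- phi_fraction(r, 3)
  expect_true(all(ph > 0 & ph < 1))
  expect_true(all(diff(ph) > 0))
  expect_error(phi_fraction(-1, 3), "> 0")
})

test_that("counts uncertainty couples delineation error through phi and RC", {
  expect_equal(counts_uncertainty(0, 0.5, 0.2), 0)
  u <- counts_uncertainty(phi_fraction(15.65, 3), 0.514,
                          volume_uncertainty(31.3, 4.42))
  expect_equal(round(u, 3), 0.143)
  expect_equal(counts_uncertainty(1, 1, 0.2), 0.1)  # ideal-recovery limit
  expect_error(counts_uncertainty(0.8, 0, 0.2), "RC")
})

test_that("RC uncertainty propagates the bordered covariance", {
  pts <- tibble::tibble(volume_ml = c(0.5, 1, 2, 4, 8, 16),
                        RC = rc_curve(c(0.5, 1, 2, 4, 8, 16), 0.8, 2, 1.5))
  fit <- fit_rc_curve(pts)
  fit$V_c[] <- 0
  expect_equal(rc_uncertainty(fit, 4), 0)

  # plateau limit: only var(R_plateau) = s^2 and v -> inf gives s / R_plateau
  fit$V_c[1, 1] <- 0.01^2
  expect_equal(rc_uncertainty(fit, 1e6), 0.01 / fit$R_plateau,
               tolerance = 1e-4)

  bad <- fit
  bad$V_c[1, 2] <- 1; bad$V_c[2, 1] <- 1
  expect_error(rc_uncertainty(bad, 4), "semidefinite")
})

test_that("propagated RC uncertainty tracks the replicate spread", {
  set.seed(202)
  vols <- c(0.5, 1, 2, 4, 8, 16)
  truth <- rc_curve(vols, 0.8, 2, 1.5)
  n_rep <- 200
  rc4 <- numeric(n_rep)
  u4 <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    pts <- tibble::tibble(volume_ml = vols,
                          RC = truth * (1 + rnorm(6, 0, 0.02)))
    fit <- fit_rc_curve(pts)
    rc4[r] <- rc_eval_and_derivative(fit, 4)$RC
    u4[r] <- rc_uncertainty(fit, 4, u2_v = 0) * rc4[r]
  }
  expect_lt(abs(median(u4) / sd(rc4) - 1), 0.25)
})

test_that("combined uncertainty respects its quadrature bounds", {
  expect_equal(combined_activity_uncertainty(0.03, 0.04, 0), 0.05)
  expect_equal(combined_activity_uncertainty(0, 0, 0), 0)

  fit <- list(R_plateau = 0.8, beta = 2, gamma = 1.5,
              fit_range_ml = c(0.5, 16))
  u_q <- 0.0747; u_rc <- 0.192; u_c <- 0.143
  u_v <- volume_uncertainty(31.3, 4.42)
  phi <- phi_fraction(15.65, 3)
  comb <- combined_activity_uncertainty(u_q, u_rc, u_c, fit = fit, v = 16,
                                        u_v_frac = u_v, phi = phi)
  quad <- sqrt(u_q^2 + u_rc^2 + u_c^2)
  expect_lte(comb, quad)
  expect_gte(comb, u_q)

  # a pathological slope that over-subtracts must error, not go imaginary
  steep <- list(R_plateau = 0.8, beta = 16, gamma = 8,
                fit_range_ml = c(0.5, 16))
  expect_error(
    combined_activity_uncertainty(0.001, 0.001, 0.001, fit = steep, v = 16,
                                  u_v_frac = 0.5, phi = 0.9),
    "over-subtracts")
})

test_that("budget table reproduces the sphere-set structure", {
  pts <- tibble::tibble(volume_ml = c(0.5, 1, 2, 4, 8, 16),
                        RC = rc_curve(c(0.5, 1, 2, 4, 8, 16), 0.8, 5, 1.2))
  fit <- fit_rc_curve(pts)
  vois <- tibble::tibble(
    name = c("s0.5", "s1", "s2", "s4", "s8", "s16"),
    volume_ml = c(0.5, 1, 2, 4, 8, 16),
    D_mm = c(9.9, 12.4, 15.4, 19.8, 24.8, 31.3))
  b <- budget_table(vois, fit)
  expect_equal(round(range(b$u_v_frac), 3), c(0.173, 0.547))
  expect_true(all(diff(b$u_v_frac) < 0))
  expect_true(all(diff(b$u_C_frac) < 0))
  expect_true(all(b$u_A_frac <= sqrt(b$u_q_frac^2 + b$u_RC_frac^2 +
                                       b$u_C_frac^2) + 1e-12))
  expect_true(all(b$u_A_frac >= b$u_q_frac))

  # appended tumor volume and the huge-VOI limit
  b2 <- budget_table(tibble::tibble(name = c("tumor", "huge"),
                                    volume_ml = c(22.8, 1e6)), fit)
  expect_equal(round(b2$u_v_frac[1], 3), 0.154)
  expect_true(b2$extrapolated[1])
  expect_equal(b2$u_A_frac[2], b2$u_q_frac[2], tolerance = 0.01)
})
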