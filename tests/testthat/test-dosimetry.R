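nd <- nuclide_data("I-131")

test_that("decay model and cumulated activity integrate a single timepoint", {
  dm <- i131_decay()
  expect_equal(dm$lambda * dm$half_life, log(2), tolerance = 1e-12)

  g <- grid_spec(8, 4.42)
  act <- uniform_image(259, g)
  ct <- cumulated_activity(act, dm)
  # 259 kBq/ml over full decay: 2.591e11 decays/ml
  expect_equal(ct$data[1] * 1e6, 2.591e11, tolerance = 1e-3)
  expect_equal(ct$units, "MBq*s/ml")
  expect_true(all(cumulated_activity(uniform_image(0, g), dm)$data == 0))
  # A numerically equal to lambda integrates to unit activity-time
  act1 <- uniform_image(dm$lambda, g)
  expect_equal(cumulated_activity(act1, dm)$data[1], 1e-3, tolerance = 1e-12)
})

test_that("local deposition dose matches the closed form and scales physically", {
  g <- grid_spec(8, 4.42)
  ct <- uniform_image(2.591e5, g, units = "MBq*s/ml")
  rho <- uniform_image(1, g, units = "g/cc")
  d <- dose_local(ct, nd, rho, mode = "beta_only")
  expect_equal(d$data[1], 7.95, tolerance = 1e-3)
  expect_equal(d$units, "Gy")

  # doubling density halves dose; dose is linear in activity
  rho2 <- uniform_image(2, g, units = "g/cc")
  expect_equal(dose_local(ct, nd, rho2, "beta_only")$data[1], d$data[1] / 2)
  ct3 <- uniform_image(3 * 2.591e5, g, units = "MBq*s/ml")
  expect_equal(dose_local(ct3, nd, rho, "beta_only")$data[1], 3 * d$data[1])

  expect_true(all(dose_local(uniform_image(0, g, units = "MBq*s/ml"),
                             nd, rho)$data == 0))
  rho0 <- uniform_image(0, g, units = "g/cc")
  expect_warning(d0 <- dose_local(ct, nd, rho0), "Zero-density")
  expect_true(all(d0$data == 0))
})

test_that("all-energy local mode conserves total energy exactly", {
  g <- grid_spec(16, 4.42)
  set.seed(3)
  ct <- voxel_image(array(runif(prod(g$dim)), g$dim), g$voxel_size,
                    g$origin, "MBq*s/ml")
  rho <- voxel_image(array(runif(prod(g$dim), 0.9, 1.6), g$dim),
                     g$voxel_size, g$origin, "g/cc")
  d <- dose_local(ct, nd, rho, mode = "all_energy")
  v_ml <- voxel_volume_ml(ct)
  e_dep <- sum(d$data * rho$data * v_ml / 1000)        # Gy * kg = J
  e_rel <- sum(ct$data) * v_ml * 1e6 *
    (nd$mean_beta_energy_MeV + nd$photon_energy_MeV) * 1.602e-13
  expect_equal(e_dep, e_rel, tolerance = 1e-12)
})

test_that("photon kernel reduces to local dose in an optically thick medium", {
  g <- grid_spec(32, 4.42)
  ct <- uniform_image(1, g, units = "MBq*s/ml")
  rho <- uniform_image(1, g, units = "g/cc")
  dk <- suppressWarnings(dose_kernel(ct, nd, rho, mu_cm = 3))
  dl <- dose_local(ct, nd, rho, mode = "all_energy")
  expect_equal(dk$data[16, 16, 16], dl$data[16, 16, 16], tolerance = 1e-3)
  # at 364 keV in water the 30-cm truncated kernel drops > 5% and must say so
  expect_warning(dose_kernel(ct, nd, rho, mu_cm = 0.0896), "renormalizing")
})

test_that("photon kernel conserves energy for interior sources", {
  g <- grid_spec(32, 4.42)
  ct <- uniform_image(0, g, units = "MBq*s/ml")
  ct$data[16, 16, 16] <- 5
  rho <- uniform_image(1, g, units = "g/cc")
  dk <- dose_kernel(ct, nd, rho, mu_cm = 1)
  v_ml <- voxel_volume_ml(ct)
  e_dep <- sum(dk$data * rho$data * v_ml / 1000)
  e_rel <- sum(ct$data) * v_ml * 1e6 *
    (nd$mean_beta_energy_MeV + nd$photon_energy_MeV) * 1.602e-13
  expect_lt(abs(e_dep / e_rel - 1), 0.01)
  # dose decreases monotonically away from a point source
  prof <- dk$data[16:28, 16, 16]
  expect_true(all(diff(prof) < 0))
})

test_that("self-absorbed photon fraction grows with sphere size", {
  g <- grid_spec(48, 4.42)
  rho <- uniform_image(1, g, units = "g/cc")
  frac <- sapply(c(4, 22.8, 120), function(v) {
    occ <- rasterize_compartment(
      compartment_spec("s", "sphere", nominal_volume = v), g)
    ct <- voxel_image(occ$data, g$voxel_size, g$origin, "MBq*s/ml")
    dk <- suppressWarnings(dose_kernel(ct, nd, rho, mu_cm = 0.0896))
    mask <- occ$data >= 0.5
    v_ml <- voxel_volume_ml(ct)
    e_in <- sum((dk$data - dose_local(ct, nd, rho, "beta_only")$data)[mask] *
                  rho$data[mask] * v_ml / 1000)
    e_photon <- sum(ct$data) * v_ml * 1e6 * nd$photon_energy_MeV * 1.602e-13
    e_in / e_photon
  })
  expect_true(all(frac < 1))
  expect_true(all(diff(frac) > 0))
})

test_that("mean dose is a plain mask mean", {
  g <- grid_spec(8, 4.42)
  d <- uniform_image(2, g, units = "Gy")
  d$data[1:256] <- 0
  mask <- array(TRUE, g$dim)
  expect_equal(mean_dose(d, mask), 1)
  expect_error(mean_dose(d, array(FALSE, g$dim)), "Empty")
})

test_that("scenario comparator arithmetic matches the reporting convention", {
  # 59.10 Gy against a 62.15 Gy ground truth is a -4.9% difference
  expect_equal(100 * (59.10 - 62.15) / 62.15, -4.9, tolerance = 0.01)
})

test_that("validation scenarios rank PVC above no correction", {
  g <- grid_spec(64, 4.42)
  ant <- phantom_anthro()
  m <- imaging_model("on", noise = "none")
  pts <- simulate_rc_points(ant, m, g, stream = "rc")
  rc_t <- pts$RC[pts$name == "tumor"]
  res <- run_validation_scenarios(
    ant, m, rc_sources = list(anthro = rc_t), grid = g,
    scenarios = c("ground_truth", "no_pvc", "anthro_pvc"))
  expect_equal(res$percent_diff_vs_gt[res$scenario == "ground_truth"], 0)
  expect_lt(res$percent_diff_vs_gt[res$scenario == "no_pvc"], -30)
  expect_lt(abs(res$percent_diff_vs_gt[res$scenario == "anthro_pvc"]), 1e-6)
  # any RC < 1 strictly increases the tumor dose
  no_pvc <- res$mean_tumor_dose_Gy[res$scenario == "no_pvc"]
  pvc <- res$mean_tumor_dose_Gy[res$scenario == "anthro_pvc"]
  expect_gt(pvc, no_pvc)
  expect_error(
    run_validation_scenarios(ant, m, rc_sources = list(), grid = g,
                             scenarios = "jaszczak_pvc"),
    "Missing 'jaszczak'")
})
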