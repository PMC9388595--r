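test_that("counts convert to activity and back consistently", {
  g <- grid_spec(16, 4.42)
  Q <- 104.2
  img <- uniform_image(Q, g, units = "cps/voxel")  # R_voxel = Q => 1 MBq
  act <- counts_to_activity(img, Q)
  expect_equal(act$data[1] * voxel_volume_ml(act) * 1e-3, 1)  # MBq per voxel
  expect_equal(act$units, "kBq/ml")

  zero <- counts_to_activity(uniform_image(0, g, units = "cps/voxel"), Q)
  expect_true(all(zero$data == 0))

  # simulator round trip on a uniform region, noise off (core voxels are
  # far enough from the zero-padded edge for the blur kernel to be whole)
  g2 <- grid_spec(40, 4.42)
  act_in <- uniform_image(105, g2)
  m <- imaging_model("on", noise = "none")
  back <- counts_to_activity(simulate_spect_image(act_in, m),
                             m$calibration_Q)
  core <- back$data[16:25, 16:25, 16:25]
  expect_equal(core, array(105, dim(core)), tolerance = 1e-9)

  expect_error(counts_to_activity(act_in, Q), "cps/voxel")
  expect_error(counts_to_activity(img, 0), "Q")
})

test_that("partial-volume correction divides by the recovery coefficient", {
  expect_equal(apply_pvc(133.2, 0.5195), 256.4, tolerance = 1e-3)
  expect_equal(apply_pvc(50, 1), 50)
  expect_equal(apply_pvc(50, 0.5), 100)
  expect_error(apply_pvc(50, 0), "RC")
  g <- grid_spec(8, 4.42)
  img <- uniform_image(10, g)
  expect_equal(apply_pvc(img, 0.5)$data, img$data * 2)
})

test_that("equivalent sphere diameter follows the cube-root law", {
  expect_equal(equivalent_sphere_diameter(pi / 6), 10)
  expect_equal(equivalent_sphere_diameter(16), 31.26, tolerance = 1e-3)
  expect_equal(equivalent_sphere_diameter(22.77), 35.17, tolerance = 1e-3)
  v <- c(0.5, 1, 2, 4, 8, 16)
  d <- equivalent_sphere_diameter(v)
  expect_true(all(diff(d) > 0))
  expect_equal(equivalent_sphere_diameter(8 * v),
               2 * d, tolerance = 1e-12)
  expect_error(equivalent_sphere_diameter(0), "> 0")
})

test_that("perfect-PVC closure: the emergent RC restores true concentration", {
  g <- grid_spec(64, 4.42)
  jas <- mini_jaszczak()
  built <- build_digital_phantom(jas, g)
  m0 <- imaging_model("on", noise = "none")
  clean <- simulate_rc_points(jas, m0, g)
  rc16 <- clean$RC[clean$volume_ml == 16]

  reps <- sapply(1:8, function(s) {
    m <- imaging_model("on", noise = "poisson", seed = s)
    act <- counts_to_activity(
      simulate_spect_image(built$activity, m, stream = "closure"),
      m$calibration_Q)
    voi_statistics(act, built$masks$s16)$mean
  })
  corrected <- apply_pvc(mean(reps), rc16)
  mc_sd <- sd(apply_pvc(reps, rc16)) / sqrt(length(reps))
  expect_lt(abs(corrected - 256.41), 3 * mc_sd + 1e-9)
})

test_that("grid resampling preserves structure means and labels", {
  g <- grid_spec(32, 4.42)
  img <- uniform_image(7, g)
  expect_identical(resample_to_grid(img, g), img)
  fine <- grid_spec(c(64, 64, 32), c(2.21, 2.21, 4.42))
  for (meth in c("lanczos", "linear", "nearest")) {
    out <- resample_to_grid(img, fine, meth)
    expect_equal(out$data, array(7, fine$dim), tolerance = 1e-9,
                 info = meth)
  }

  # labels survive nearest-neighbour resampling exactly
  lab <- uniform_image(0, g, units = "dimensionless")
  lab$data[10:20, 10:20, 10:20] <- 3
  same <- resample_to_grid(lab, g, "nearest")
  expect_identical(same$data, lab$data)

  expect_error(
    resample_to_grid(img, grid_spec(8, 4.42, origin = c(1e5, 1e5, 1e5))),
    "overlap")
})

test_that("SPECT-to-CT upsampling preserves the 16-ml sphere VOI mean", {
  # oracle: the same blurred sphere computed directly on the CT grid; the
  # upsampled SPECT-grid image must agree with it over the CT-drawn contour
  g <- grid_spec(48, 4.42)
  ball <- compartment_spec("s16", "sphere", nominal_volume = 16,
                           activity_concentration = 256.41)
  occ <- rasterize_compartment(ball, g)
  ct_grid <- grid_spec(c(128, 128, 64), c(0.977, 0.977, 2.0))
  occ_fine <- rasterize_compartment(ball, ct_grid)
  mask_fine <- occ_fine$data >= 0.5
  fwhm <- 22
  coarse <- gaussian_blur(voxel_image(occ$data * 256.41, g$voxel_size,
                                      g$origin, "kBq/ml"), fwhm)
  ref <- gaussian_blur(voxel_image(occ_fine$data * 256.41,
                                   ct_grid$voxel_size, ct_grid$origin,
                                   "kBq/ml"), fwhm)
  ref_mean <- voi_statistics(ref, mask_fine)$mean
  up <- resample_to_grid(coarse, ct_grid, "lanczos")
  expect_lt(abs(voi_statistics(up, mask_fine)$mean / ref_mean - 1), 0.01)
  # the windowed-sinc filter outperforms plain trilinear interpolation here
  up_lin <- resample_to_grid(coarse, ct_grid, "linear")
  expect_gt(abs(voi_statistics(up_lin, mask_fine)$mean / ref_mean - 1),
            abs(voi_statistics(up, mask_fine)$mean / ref_mean - 1))
  # and total activity over the grid is conserved by the upsampling
  expect_lt(abs(sum(up$data) * voxel_volume_ml(up) /
                  (sum(coarse$data) * voxel_volume_ml(coarse)) - 1), 0.005)
})
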