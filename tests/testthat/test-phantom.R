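test_that("rasterized volumes match analytic shape volumes", {
  g <- small_grid()
  occ16 <- rasterize_compartment(
    compartment_spec("s16", "sphere", nominal_volume = 16), g,
    supersampling = 3)
  v16 <- sum(occ16$data) * voxel_volume_ml(occ16)
  expect_lt(abs(v16 / 16 - 1), 0.02)
  expect_true(all(occ16$data >= 0 & occ16$data <= 1))

  cyl_grid <- grid_spec(128, 4.42)
  occ_cyl <- rasterize_compartment(phantom_cylinder()$background, cyl_grid)
  expect_lt(abs(sum(occ_cyl$data) * voxel_volume_ml(occ_cyl) / 5640 - 1), 0.01)
})

test_that("degenerate and out-of-grid shapes are handled", {
  g <- small_grid()
  occ0 <- rasterize_compartment(
    compartment_spec("s0", "sphere", dimensions = list(diameter = 0),
                     nominal_volume = 0), g)
  expect_true(all(occ0$data == 0))
  expect_error(
    rasterize_compartment(
      compartment_spec("big", "sphere", dimensions = list(diameter = 500)),
      g),
    "big")
})

test_that("rasterization error shrinks as supersampling grows", {
  g <- small_grid()
  err <- sapply(c(1L, 2L, 4L, 8L), function(s) {
    tot <- sapply(c(0.5, 2, 16), function(v) {
      occ <- rasterize_compartment(
        compartment_spec("s", "sphere", nominal_volume = v,
                         center = c(2.1, -1.3, 0.7)), g, supersampling = s)
      abs(sum(occ$data) * voxel_volume_ml(occ) / v - 1)
    })
    mean(tot)
  })
  expect_lt(err[4], err[1])
  expect_lt(err[4], 0.01)
})

test_that("ground-truth phantom carries nominal concentrations exactly", {
  g <- grid_spec(64, 4.42)
  ant <- phantom_anthro()
  built <- build_digital_phantom(ant, g)
  expect_equal(voi_statistics(built$activity, built$masks$tumor)$mean, 259)
  bg_only <- built$masks$head &
    !Reduce(`|`, built$masks[setdiff(names(built$masks), "head")])
  expect_equal(mean(built$activity$data[bg_only]), 26.2)
  # solid bone carries no activity
  bone <- built$masks$skull & !built$masks$brain &
    !built$masks$lacrimal_l & !built$masks$lacrimal_r &
    !built$masks$parotid_l & !built$masks$parotid_r
  expect_true(all(built$activity$data[bone] == 0))
  expect_true(all(built$hu$data[bone] == 876.36))
  expect_true(all(built$density$data[bone] == 1.61))
})

test_that("Jaszczak spheres carry 9.9x the 25.9 kBq/ml background", {
  g <- grid_spec(64, 4.42)
  built <- build_digital_phantom(phantom_jaszczak(), g)
  for (nm in grep("^sphere", names(built$masks), value = TRUE)) {
    expect_equal(voi_statistics(built$activity, built$masks[[nm]])$mean,
                 256.41, info = nm)
  }
})

test_that("zero-activity phantom yields an identically zero activity map", {
  g <- small_grid()
  ph <- phantom_spec(
    background = compartment_spec("bg", "cylinder",
                                  dimensions = list(diameter = 100,
                                                    height = 100),
                                  activity_concentration = 0),
    compartments = list(compartment_spec("s", "sphere", nominal_volume = 8,
                                         activity_concentration = 0))
  )
  built <- build_digital_phantom(ph, g)
  expect_true(all(built$activity$data == 0))
})

test_that("phantom validation catches bad ratios, materials and overlaps", {
  expect_error(
    phantom_spec(
      background = compartment_spec("bg", "sphere", nominal_volume = 500,
                                    activity_concentration = 10),
      compartments = list(
        compartment_spec("hot", "sphere", nominal_volume = 8,
                         activity_concentration = 95)),
      insert_to_background_ratio = 9.9),
    "ratio")
  expect_error(compartment_spec("x", "sphere", nominal_volume = 1,
                                material = "unobtainium"),
               "Unknown material")
  expect_error(compartment_spec("x", "sphere", nominal_volume = 1,
                                activity_concentration = 5,
                                material = "bone-resin"),
               "solid")
  g <- small_grid()
  ph <- phantom_spec(
    background = compartment_spec("bg", "cylinder",
                                  dimensions = list(diameter = 150,
                                                    height = 150),
                                  activity_concentration = 1),
    compartments = list(
      compartment_spec("a", "sphere", nominal_volume = 8, center = c(0, 0, 0),
                       activity_concentration = 9.9, priority = 1),
      compartment_spec("b", "sphere", nominal_volume = 8, center = c(5, 0, 0),
                       activity_concentration = 9.9, priority = 1)),
    insert_to_background_ratio = 9.9)
  expect_error(build_digital_phantom(ph, g), "identical priority")
})

test_that("mask-file compartments rasterize from disk", {
  g <- grid_spec(16, 4.42)
  m <- array(0, g$dim); m[6:10, 6:10, 6:10] <- 1
  f <- tempfile(fileext = ".nii.gz")
  write_image(voxel_image(m, g$voxel_size, g$origin, "dimensionless"), f)
  occ <- rasterize_compartment(
    compartment_spec("lesion", "mask-file", dimensions = list(path = f),
                     nominal_volume = 125 * voxel_volume_ml(g)), g)
  expect_equal(sum(occ$data), 125)
})
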