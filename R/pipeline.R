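#' Create a run configuration
#'
#' A run is fully reproducible from its configuration and seed: the
#' configuration names the phantoms, the imaging models, the grids, the
#' decay/nuclide data and the output directory.
#'
#' @param output_dir directory for the report bundle.
#' @param seed study-level integer seed.
#' @param cdr_modes imaging models to run (`"on"`, `"off"` or both).
#' @param noise `"none"` or `"poisson"`.
#' @param spect_grid,ct_grid [grid_spec()]s (defaults: 128^3 at 4.42 mm
#'   isotropic; 256 x 256 x 128 at 0.977 x 0.977 x 2.0 mm).
#' @param nuclide a [nuclide_data()].
#' @param u_Acal_frac,u_Cref_frac calibration uncertainty components.
#' @param sigma_mm PSF standard deviation for the uncertainty budget.
#' @param write_images write activity/dose NIfTI images into the bundle.
#' @return A `run_config` list.
#' @export
run_config <- function(output_dir, seed = 1L, cdr_modes = c("on", "off"),
                       noise = "none",
                       spect_grid = grid_spec(128, 4.42),
                       ct_grid = grid_spec(c(256, 256, 128),
                                           c(0.977, 0.977, 2.0)),
                       nuclide = nuclide_data("I-131"),
                       u_Acal_frac = 0.05, u_Cref_frac = 0,
                       sigma_mm = 3, write_images = FALSE) {
  structure(
    list(output_dir = output_dir, seed = as.integer(seed),
         cdr_modes = cdr_modes, noise = noise, spect_grid = spect_grid,
         ct_grid = ct_grid, nuclide = nuclide, u_Acal_frac = u_Acal_frac,
         u_Cref_frac = u_Cref_frac, sigma_mm = sigma_mm,
         write_images = write_images),
    class = "run_config"
  )
}

#' Run the full quantification / dosimetry / uncertainty pipeline
#'
#' Orchestrates the three phantom studies end to end for each imaging
#' model: (1) calibration-factor recovery on the uniform cylinder; (2)
#' recovery-coefficient measurement and curve fit on the Jaszczak spheres;
#' (3) the four dosimetry validation scenarios on the anthropomorphic
#' phantom; (4) the per-sphere uncertainty budget with the tumor volume
#' appended; (5) the fillable-volume comparison between measured volumes
#' and CT-grid contours. Tables are written as CSV and JSON into
#' `config$output_dir` together with a run log recording the seed and
#' package versions.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `calibration`, `rc_points`, `rc_fits`,
#'   `scenarios`, `budget`, `volume_comparison` tibbles and `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  stage <- "setup"
  result <- tryCatch({
    cyl <- phantom_cylinder()
    jas <- phantom_jaszczak()
    ant <- phantom_anthro()
    decay <- decay_model(config$nuclide$half_life_s)

    calib <- list(); rc_points <- list(); rc_fits <- list(); scen <- list()
    for (mode in config$cdr_modes) {
      model <- imaging_model(mode, noise = config$noise, seed = config$seed)

      stage <- sprintf("calibration (cdr %s)", mode)
      built <- build_digital_phantom(cyl, config$spect_grid)
      img <- simulate_spect_image(built$activity, model,
                                  stream = paste0("calib-", mode))
      core <- compartment_spec("core", "cylinder", center = cyl$background$center,
                               dimensions = list(diameter = 100, height = 90))
      core_mask <- rasterize_compartment(core, config$spect_grid)$data >= 0.5
      st <- voi_statistics(img, core_mask)
      cal <- calibration_factor(
        st$mean, voxel_volume_ml(img),
        C_ref = cyl$background$activity_concentration * 1e-3,
        delta_t = 0, lambda = decay$lambda)
      cal$cdr_mode <- mode
      cal$configured_Q <- model$calibration_Q
      calib[[mode]] <- cal

      stage <- sprintf("rc measurement (cdr %s)", mode)
      pts <- simulate_rc_points(jas, model, config$spect_grid,
                                stream = paste0("rc-", mode))
      pts$cdr_mode <- mode
      rc_points[[mode]] <- pts
      fit <- fit_rc_curve(pts)
      rc_fits[[mode]] <- fit

      stage <- sprintf("anthro rc (cdr %s)", mode)
      model_clean <- imaging_model(mode, noise = "none", seed = config$seed)
      anthro_pts <- simulate_rc_points(ant, model_clean, config$spect_grid,
                                       stream = paste0("anthro-rc-", mode))
      anthro_rc <- anthro_pts$RC[anthro_pts$name == "tumor"]

      stage <- sprintf("scenarios (cdr %s)", mode)
      scen[[mode]] <- run_validation_scenarios(
        ant, model, rc_sources = list(jaszczak = fit, anthro = anthro_rc),
        decay = decay, nuclide = config$nuclide, grid = config$spect_grid,
        stream = paste0("scen-", mode))
    }

    stage <- "uncertainty budget"
    vois <- dplyr::bind_rows(
      dplyr::select(rc_points[[config$cdr_modes[1]]], "name", "volume_ml"),
      tibble::tibble(name = "tumor", volume_ml = 22.8)
    )
    budget <- budget_table(vois, rc_fits[[config$cdr_modes[1]]],
                           u_Acal_frac = config$u_Acal_frac,
                           u_Cref_frac = config$u_Cref_frac,
                           sigma_mm = config$sigma_mm,
                           a_mm = config$spect_grid$voxel_size[1])

    stage <- "volume comparison"
    fillable <- purrr::keep(ant$compartments, function(cp) {
      lookup_material(cp$material)$fillable && cp$name != "brain"
    })
    volcmp <- purrr::map_dfr(fillable, function(cp) {
      occ <- rasterize_compartment(cp, config$ct_grid)
      contour <- sum(occ$data >= 0.5) * voxel_volume_ml(occ)
      compare_volumes(cp$nominal_volume, contour, name = cp$name)
    })

    stage <- "report"
    calib <- dplyr::bind_rows(calib)
    rc_points <- dplyr::bind_rows(rc_points)
    scen <- dplyr::bind_rows(scen)
    utils::write.csv(calib, out("calibration.csv"), row.names = FALSE)
    jsonlite::write_json(calib, out("calibration.json"), auto_unbox = TRUE,
                         digits = NA)
    utils::write.csv(rc_points, out("rc_points.csv"), row.names = FALSE)
    fits_json <- purrr::imap(rc_fits, function(f, mode) {
      list(cdr_mode = mode, R_plateau = f$R_plateau, beta = f$beta,
           gamma = f$gamma, covariance = f$cov,
           ci95 = tidy(f)[, c("term", "conf.low", "conf.high")])
    })
    jsonlite::write_json(fits_json, out("rc_fit.json"), auto_unbox = TRUE,
                         digits = NA)
    utils::write.csv(scen, out("scenarios.csv"), row.names = FALSE)
    jsonlite::write_json(scen, out("scenarios.json"), auto_unbox = TRUE,
                         digits = NA)
    utils::write.csv(budget, out("uncertainty_budget.csv"), row.names = FALSE)
    jsonlite::write_json(budget, out("uncertainty_budget.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(volcmp, out("volume_comparison.csv"), row.names = FALSE)
    jsonlite::write_json(volcmp, out("volume_comparison.json"),
                         auto_unbox = TRUE, digits = NA)

    if (isTRUE(config$write_images)) {
      stage <- "images"
      built <- build_digital_phantom(ant, config$spect_grid)
      write_image(built$activity, out("anthro_activity_gt.nii.gz"))
      model <- imaging_model(config$cdr_modes[1], noise = config$noise,
                             seed = config$seed)
      spect <- simulate_spect_image(built$activity, model, stream = "images")
      write_image(spect, out("anthro_spect.nii.gz"))
      dose <- dose_local(cumulated_activity(counts_to_activity(
        spect, model$calibration_Q), decay_model(config$nuclide$half_life_s)),
        config$nuclide, built$density, mode = "all_energy")
      write_image(dose, out("anthro_dose.nii.gz"))
    }

    writeLines(c(
      sprintf("spectdose %s", as.character(utils::packageVersion("spectdose"))),
      sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("seed %d", config$seed),
      sprintf("noise %s", config$noise),
      sprintf("cdr_modes %s", paste(config$cdr_modes, collapse = ",")),
      sprintf("spect_grid %s @ %s mm",
              paste(config$spect_grid$dim, collapse = "x"),
              paste(config$spect_grid$voxel_size, collapse = "x")),
      sprintf("ct_grid %s @ %s mm",
              paste(config$ct_grid$dim, collapse = "x"),
              paste(config$ct_grid$voxel_size, collapse = "x"))
    ), out("run_log.txt"))

    list(calibration = calib, rc_points = rc_points, rc_fits = rc_fits,
         scenarios = scen, budget = budget, volume_comparison = volcmp,
         files = list.files(config$output_dir, full.names = TRUE))
  }, error = function(e) {
    abort(sprintf("Pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
  invisible(result)
}
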