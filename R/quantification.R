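#' VOI statistics of a voxel image
#'
#' @param image a `voxel_image`.
#' @param mask logical/0-1 array on the same grid, or a `voxel_image`.
#' @return A one-row tibble with `mean`, `sd`, `total`, `n_voxels`,
#'   `volume_ml`.
#' @examples
#' g <- grid_spec(8, 4.42)
#' img <- voxel_image(array(2, g$dim), g$voxel_size, g$origin, "kBq/ml")
#' voi_statistics(img, array(TRUE, g$dim))
#' @export
voi_statistics <- function(image, mask) {
  stopifnot(inherits(image, "voxel_image"))
  if (inherits(mask, "voxel_image")) {
    stop_if_grid_mismatch(image, mask, "image and mask")
    mask <- mask$data > 0
  }
  if (!all(dim(mask) == dim(image$data))) {
    abort("The image and mask do not share a grid (dimensions differ).")
  }
  vals <- image$data[mask > 0]
  if (length(vals) == 0L) abort("Empty VOI mask.")
  tibble::tibble(
    mean = mean(vals),
    sd = if (length(vals) > 1L) sd(vals) else 0,
    total = sum(vals),
    n_voxels = length(vals),
    volume_ml = length(vals) * voxel_volume_ml(image)
  )
}

#' System calibration factor Q
#'
#' Converts the mean count rate of a voxel in a calibration VOI into a
#' sensitivity in cps/MBq. The syringe-assayed concentration `C_ref` is
#' decay-corrected to scan time, i.e. the denominator concentration is
#' `C_ref * exp(-lambda * delta_t)`: physical decay between source
#' preparation and scan lowers the concentration actually imaged.
#'
#' @param R_mean mean count rate of a voxel in the VOI (cps/voxel).
#' @param V_voxel voxel volume in ml.
#' @param C_ref activity concentration at syringe-measurement time (MBq/ml).
#' @param delta_t seconds between syringe measurement and scan (>= 0).
#' @param lambda decay constant in 1/s.
#' @return A one-row tibble with `Q_cps_per_MBq`, `R_mean`, `V_voxel_ml`,
#'   `C_scan_MBq_ml` (the decay-corrected concentration), `delta_t_s`.
#' @examples
#' calibration_factor(2, 0.1, 0.2, delta_t = 0, lambda = 1e-6)
#' @export
calibration_factor <- function(R_mean, V_voxel, C_ref, delta_t = 0,
                               lambda = i131_decay()$lambda) {
  if (C_ref <= 0) abort("`C_ref` must be > 0 MBq/ml.")
  if (R_mean <= 0 || V_voxel <= 0 || lambda <= 0) {
    abort("`R_mean`, `V_voxel` and `lambda` must be > 0.")
  }
  if (delta_t < 0) abort("`delta_t` must be >= 0 s.")
  c_scan <- C_ref * exp(-lambda * delta_t)
  tibble::tibble(
    Q_cps_per_MBq = R_mean / (V_voxel * c_scan),
    R_mean = R_mean, V_voxel_ml = V_voxel,
    C_scan_MBq_ml = c_scan, delta_t_s = delta_t
  )
}

#' Recovery coefficient of a VOI
#'
#' Ratio of the measured mean activity concentration in an object VOI to the
#' true concentration; quantifies partial-volume signal loss.
#'
#' @param measured_conc_mean measured mean concentration (kBq/ml).
#' @param true_conc true concentration (kBq/ml, > 0).
#' @return The dimensionless recovery coefficient.
#' @examples
#' recovery_coefficient(133.2, 256.41)
#' @export
recovery_coefficient <- function(measured_conc_mean, true_conc) {
  if (any(true_conc <= 0)) abort("`true_conc` must be > 0.")
  measured_conc_mean / true_conc
}

#' Measure recovery coefficients from a simulated phantom
#'
#' Builds the phantom, simulates a SPECT image, converts it back to
#' concentration with the model's own Q, and tabulates per-insert recovery
#' coefficients against the known true concentrations. This is the
#' simulation counterpart of a hot-sphere phantom study.
#'
#' @param phantom a [phantom_spec()] whose inserts carry nonzero activity.
#' @param model an [imaging_model()].
#' @param grid a [grid_spec()] (default: 128^3 at 4.42 mm).
#' @param stream substream label for the noise draw.
#' @return A tibble with one row per active insert: `name`, `volume_ml`,
#'   `equivalent_diameter_mm`, `true_kBq_ml`, `measured_kBq_ml`, `RC`.
#' @export
simulate_rc_points <- function(phantom, model, grid = grid_spec(128, 4.42),
                               stream = "rc") {
  built <- build_digital_phantom(phantom, grid)
  img <- simulate_spect_image(built$activity, model, stream = stream)
  act <- counts_to_activity(img, model$calibration_Q)
  active <- purrr::keep(phantom$compartments,
                        ~ .x$activity_concentration > 0)
  purrr::map_dfr(active, function(cp) {
    st <- voi_statistics(act, built$masks[[cp$name]])
    tibble::tibble(
      name = cp$name,
      volume_ml = cp$nominal_volume,
      equivalent_diameter_mm = equivalent_sphere_diameter(cp$nominal_volume),
      true_kBq_ml = cp$activity_concentration,
      measured_kBq_ml = st$mean,
      RC = recovery_coefficient(st$mean, cp$activity_concentration)
    )
  })
}
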