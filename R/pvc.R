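#' Convert a count-rate image to activity concentration
#'
#' Per voxel, activity is `R_voxel / Q` in MBq; dividing by the voxel volume
#' and rescaling gives concentration in kBq/ml. Total activity in the image
#' equals total counts divided by Q.
#'
#' @param image a `voxel_image` in cps/voxel.
#' @param Q calibration factor in cps/MBq (> 0).
#' @return A `voxel_image` in kBq/ml.
#' @export
counts_to_activity <- function(image, Q) {
  stop_if_units(image, "cps/voxel", "image")
  if (Q <= 0) abort("`Q` must be > 0 cps/MBq.")
  conc <- image$data / Q / voxel_volume_ml(image) * 1e3  # MBq/ml -> kBq/ml
  with_data(image, conc, units = "kBq/ml")
}

#' Apply a volume-based partial-volume correction
#'
#' Divides a measured VOI-mean concentration (or a whole image) by the
#' recovery coefficient of the VOI's volume. This is a single VOI-level
#' scale factor, not a voxelwise deconvolution.
#'
#' @param activity_mean measured concentration(s) in kBq/ml, or a
#'   `voxel_image`.
#' @param RC recovery coefficient (> 0).
#' @return The corrected value(s), same type as the input.
#' @examples
#' apply_pvc(133.2, 0.5195)
#' @export
apply_pvc <- function(activity_mean, RC) {
  if (any(RC <= 0)) abort("`RC` must be > 0.")
  if (inherits(activity_mean, "voxel_image")) {
    return(with_data(activity_mean, activity_mean$data / RC))
  }
  activity_mean / RC
}

#' Equivalent sphere diameter of a volume
#'
#' `D = 10 * (6 V / pi)^(1/3)` mm for `V` in ml.
#'
#' @param volume volume(s) in ml (> 0).
#' @return Diameter(s) in mm.
#' @examples
#' equivalent_sphere_diameter(16)    # 31.26 mm
#' equivalent_sphere_diameter(pi / 6)  # 10 mm
#' @export
equivalent_sphere_diameter <- function(volume) {
  if (any(volume <= 0)) abort("`volume` must be > 0 ml.")
  10 * (6 * volume / pi)^(1 / 3)
}

#' Equivalent-sphere geometry of a VOI
#'
#' @param volume VOI volume in ml.
#' @param voxel_size voxel edge length `a` in mm (isotropic).
#' @return A one-row tibble with `volume_ml`, `D_mm`, `r_mm`, `a_mm`.
#' @export
voi_geometry <- function(volume, voxel_size) {
  D <- equivalent_sphere_diameter(volume)
  tibble::tibble(volume_ml = volume, D_mm = D, r_mm = D / 2,
                 a_mm = voxel_size)
}

lanczos_kernel <- function(x, a = 3) {
  out <- numeric(length(x))
  nz <- abs(x) < a & abs(x) > 1e-12
  out[abs(x) <= 1e-12] <- 1
  xz <- x[nz]
  out[nz] <- a * sin(pi * xz) * sin(pi * xz / a) / (pi^2 * xz^2)
  out
}

# interpolation weight matrix mapping source samples (centers src_c) to
# target positions tgt_c along one axis
interp_matrix <- function(src_c, tgt_c, method) {
  n <- length(src_c); m <- length(tgt_c)
  dx <- src_c[2] - src_c[1]
  pos <- (tgt_c - src_c[1]) / dx + 1  # fractional source index
  W <- matrix(0, m, n)
  if (method == "nearest") {
    idx <- pmin(pmax(round(pos), 1), n)
    W[cbind(seq_len(m), idx)] <- 1
  } else if (method == "linear") {
    i0 <- pmin(pmax(floor(pos), 1), n - 1)
    f <- pmin(pmax(pos - i0, 0), 1)
    W[cbind(seq_len(m), i0)] <- 1 - f
    W[cbind(seq_len(m), i0 + 1)] <- W[cbind(seq_len(m), i0 + 1)] + f
  } else {  # lanczos, order 3
    a <- 3L
    for (t in seq_len(m)) {
      i0 <- floor(pos[t])
      idx <- (i0 - a + 1L):(i0 + a)
      w <- lanczos_kernel(pos[t] - idx, a)
      idx_cl <- pmin(pmax(idx, 1L), n)  # clamp at edges
      w <- w / sum(w)
      for (q in seq_along(idx)) W[t, idx_cl[q]] <- W[t, idx_cl[q]] + w[q]
    }
  }
  W
}

apply_axis_matrix <- function(arr, W, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- W %*% matrix(a, nrow = da[1])
  out <- array(m, c(nrow(W), da[2], da[3]))
  aperm(out, order(perm))
}

#' Resample a voxel image onto a different grid
#'
#' Separable interpolation at the target voxel centers. `"lanczos"` (order
#' 3) matches the upsampling used to bring reconstructed SPECT onto a CT
#' grid; `"linear"` is a conservative fallback; `"nearest"` preserves label
#' images exactly.
#'
#' @param image a `voxel_image`.
#' @param target_grid a [grid_spec()].
#' @param method `"lanczos"`, `"linear"` or `"nearest"`.
#' @return A `voxel_image` on `target_grid`.
#' @export
resample_to_grid <- function(image, target_grid,
                             method = c("lanczos", "linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(image, "voxel_image"), inherits(target_grid, "grid_spec"))
  src <- grid_of(image)
  if (all(src$dim == target_grid$dim) &&
      all(abs(src$voxel_size - target_grid$voxel_size) < 1e-9) &&
      all(abs(src$origin - target_grid$origin) < 1e-9)) {
    return(image)
  }
  src_lo <- src$origin; src_hi <- src$origin + src$dim * src$voxel_size
  tgt_lo <- target_grid$origin
  tgt_hi <- target_grid$origin + target_grid$dim * target_grid$voxel_size
  if (any(pmin(src_hi, tgt_hi) <= pmax(src_lo, tgt_lo))) {
    abort("The source and target grids do not overlap.")
  }
  out <- image$data
  for (axis in 1:3) {
    W <- interp_matrix(axis_centers(src, axis), axis_centers(target_grid, axis),
                       method)
    out <- apply_axis_matrix(out, W, axis)
  }
  if (image$units %in% c("kBq/ml", "cps/voxel") && method != "nearest") {
    out[out < 0] <- 0  # clip interpolation undershoot on physical images
  }
  voxel_image(out, target_grid$voxel_size, target_grid$origin, image$units)
}
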