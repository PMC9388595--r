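#' @importFrom rlang abort warn `%||%`
#' @importFrom stats coef vcov qt median sd setNames rnorm rpois qnorm pnorm
#' @importFrom stats approx fft
#' @importFrom utils head tail
NULL

VALID_UNITS <- c("kBq/ml", "cps/voxel", "HU", "g/cc", "Gy", "dimensionless",
                 "MBq*s/ml")

#' Create a 3-D voxel image
#'
#' A `voxel_image` is a 3-D scalar field with grid metadata and a mandatory
#' physical units tag. All downstream operations (VOI statistics,
#' quantification, dosimetry) check the units tag before consuming an image.
#' The coordinate convention places the image origin at the corner of voxel
#' `(1,1,1)`; voxel centers sit at `origin + (i - 1/2) * voxel_size`.
#'
#' @param data numeric 3-D array of voxel values.
#' @param voxel_size numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, position of the grid corner in mm.
#' @param units one of `"kBq/ml"`, `"cps/voxel"`, `"HU"`, `"g/cc"`, `"Gy"`,
#'   `"dimensionless"`, `"MBq*s/ml"`.
#' @return A `voxel_image` object.
#' @examples
#' img <- voxel_image(array(1, c(4, 4, 4)), voxel_size = c(4.42, 4.42, 4.42),
#'                    units = "kBq/ml")
#' voxel_volume_ml(img)
#' @export
voxel_image <- function(data, voxel_size, origin = c(0, 0, 0),
                        units = "dimensionless") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array.")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    abort("`voxel_size` must be three strictly positive lengths in mm.")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L) abort("`origin` must be a length-3 mm triplet.")
  units <- match.arg(units, VALID_UNITS)
  if (units %in% c("kBq/ml", "cps/voxel") && any(data < 0, na.rm = TRUE)) {
    abort(sprintf("A '%s' image must be non-negative.", units))
  }
  structure(
    list(data = data, voxel_size = voxel_size, origin = origin, units = units),
    class = "voxel_image"
  )
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_image> %d x %d x %d voxels, %.4g x %.4g x %.4g mm [%s]\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], x$units))
  cat(sprintf("  range [%.4g, %.4g], origin (%.4g, %.4g, %.4g) mm\n",
              min(x$data), max(x$data), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Grid description for rasterization and simulation
#'
#' @param dim integer length-3 number of voxels per axis.
#' @param voxel_size voxel edge lengths in mm.
#' @param origin grid corner position in mm. The default `"centered"` places
#'   the grid symmetric about the coordinate origin, which is where packaged
#'   phantom compartments are centered.
#' @return A `grid_spec` list with elements `dim`, `voxel_size`, `origin`.
#' @examples
#' grid_spec(c(128, 128, 128), 4.42)
#' @export
grid_spec <- function(dim, voxel_size, origin = "centered") {
  dim <- as.integer(dim)
  if (length(dim) == 1L) dim <- rep(dim, 3L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(dim < 1L) || any(voxel_size <= 0)) {
    abort("grid dimensions must be >= 1 and voxel_size > 0.")
  }
  if (identical(origin, "centered")) origin <- -dim * voxel_size / 2
  structure(list(dim = dim, voxel_size = voxel_size,
                 origin = as.numeric(origin)), class = "grid_spec")
}

grid_of <- function(img) {
  grid_spec(dim(img$data), img$voxel_size, img$origin)
}

#' Voxel volume in ml
#'
#' @param x a `voxel_image` or `grid_spec`.
#' @return Volume of one voxel in ml (1 ml = 1000 mm^3).
#' @export
voxel_volume_ml <- function(x) {
  vs <- if (inherits(x, "voxel_image")) x$voxel_size else x$voxel_size
  prod(vs) / 1000
}

#' Voxel center coordinates along one axis
#' @noRd
axis_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dim[axis]) - 0.5) * grid$voxel_size[axis]
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$data) == dim(b$data)) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "images") {
  if (!same_grid(a, b)) {
    abort(sprintf("The %s do not share a grid (dim/voxel_size/origin differ).",
                  what))
  }
  invisible(TRUE)
}

stop_if_units <- function(img, expected, arg = "image") {
  if (!identical(img$units, expected)) {
    abort(sprintf("`%s` must carry units '%s', got '%s'.",
                  arg, expected, img$units))
  }
  invisible(TRUE)
}

#' Replace the voxel data of an image, keeping grid metadata
#' @noRd
with_data <- function(img, data, units = img$units) {
  voxel_image(data, img$voxel_size, img$origin, units)
}

#' Convert a voxel image to a long tibble
#'
#' One row per voxel with physical center coordinates; intended for plotting
#' and ad-hoc summaries of small images, not for whole-volume processing.
#'
#' @param x a `voxel_image`.
#' @param ... unused.
#' @return A tibble with columns `i, j, k, x_mm, y_mm, z_mm, value`.
#' @export
as_tibble.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  g <- grid_of(x)
  tibble::tibble(
    i = rep(seq_len(d[1]), times = d[2] * d[3]),
    j = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    k = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(x$data)
  ) |>
    dplyr::mutate(
      x_mm = axis_centers(g, 1)[.data$i],
      y_mm = axis_centers(g, 2)[.data$j],
      z_mm = axis_centers(g, 3)[.data$k]
    ) |>
    dplyr::select("i", "j", "k", "x_mm", "y_mm", "z_mm", "value")
}

#' Plot an axial slice of a voxel image
#'
#' @param img a `voxel_image`.
#' @param k slice index along the third axis (default: middle slice).
#' @return A ggplot object.
#' @export
plot_slice <- function(img, k = NULL) {
  d <- dim(img$data)
  k <- k %||% ceiling(d[3] / 2)
  g <- grid_of(img)
  df <- expand.grid(x_mm = axis_centers(g, 1), y_mm = axis_centers(g, 2))
  df$value <- as.vector(img$data[, , k])
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = img$units) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("axial slice k = %d", k))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom dplyr .data
NULL
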