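#' Material registry for digital phantoms
#'
#' Radiological properties of the bulk materials used in the packaged
#' phantoms: water, a soft printing resin (Accura60-like) and a dense
#' bone-mimicking resin (PerFORM-like). HU are measured values on a
#' high-resolution CT; densities are manufacturer values. Solid resins are
#' impermeable, so compartments made of them never carry activity.
#'
#' @return A tibble with columns `material`, `hu`, `density_g_cc`,
#'   `mu_364keV_cm`, `fillable`.
#' @export
material_registry <- function() {
  tibble::tibble(
    material = c("water", "soft-resin", "bone-resin"),
    hu = c(-4.05, 292.48, 876.36),
    density_g_cc = c(1.00, 1.21, 1.61),
    mu_364keV_cm = c(0.0896, 0.1063, 0.1390),
    fillable = c(TRUE, FALSE, FALSE)
  )
}

lookup_material <- function(material) {
  reg <- material_registry()
  row <- reg[reg$material == material, ]
  if (nrow(row) != 1L) {
    abort(sprintf("Unknown material '%s'; registry knows: %s.", material,
                  paste(reg$material, collapse = ", ")))
  }
  row
}

#' Describe one phantom compartment
#'
#' A compartment is an analytic shape (or an explicit mask) carrying an
#' activity concentration and a bulk material. Dimensions are full sizes in
#' mm: `diameter` for spheres, `diameter` + `height` for z-axis cylinders,
#' `axes` (three full axis lengths) for ellipsoids. If a sphere's diameter is
#' omitted it is derived from `nominal_volume`.
#'
#' @param name compartment name (used for masks and error messages).
#' @param shape one of `"cylinder"`, `"sphere"`, `"ellipsoid"`, `"mask-file"`.
#' @param center mm triplet, shape center.
#' @param dimensions named list of mm sizes (see Details), or a path for
#'   `"mask-file"` shapes (`list(path = ...)`).
#' @param nominal_volume physically measured fillable volume in ml (> 0).
#' @param activity_concentration kBq/ml at the reference time (>= 0).
#' @param material one of the [material_registry()] materials.
#' @param priority optional explicit override priority; by default the
#'   position in the phantom's compartment list is used, later entries
#'   overriding earlier ones.
#' @return A `compartment_spec` object.
#' @export
compartment_spec <- function(name, shape, center = c(0, 0, 0),
                             dimensions = list(), nominal_volume = NULL,
                             activity_concentration = 0,
                             material = "water", priority = NULL) {
  shape <- match.arg(shape, c("cylinder", "sphere", "ellipsoid", "mask-file"))
  if (is.null(nominal_volume)) {
    nominal_volume <- switch(shape,
      sphere = if (!is.null(dimensions$diameter))
        pi / 6 * (dimensions$diameter / 10)^3 else NULL,
      cylinder = if (!is.null(dimensions$diameter) &&
                     !is.null(dimensions$height))
        pi * (dimensions$diameter / 10)^2 / 4 * dimensions$height / 10
      else NULL,
      ellipsoid = if (!is.null(dimensions$axes))
        pi / 6 * prod(dimensions$axes / 10) else NULL,
      NULL
    )
  }
  if (is.null(nominal_volume) || nominal_volume < 0) {
    abort(sprintf("Compartment '%s': nominal_volume must be supplied (or derivable) and >= 0.",
                  name))
  }
  if (shape == "sphere" && is.null(dimensions$diameter)) {
    dimensions$diameter <- equivalent_sphere_diameter(nominal_volume)
  }
  if (activity_concentration < 0) {
    abort(sprintf("Compartment '%s': activity_concentration must be >= 0.",
                  name))
  }
  mat <- lookup_material(material)
  if (!mat$fillable && activity_concentration > 0) {
    abort(sprintf(
      "Compartment '%s' is solid %s and cannot carry activity.",
      name, material))
  }
  structure(
    list(name = name, shape = shape, center = as.numeric(center),
         dimensions = dimensions, nominal_volume = nominal_volume,
         activity_concentration = activity_concentration,
         material = material, priority = priority),
    class = "compartment_spec"
  )
}

#' Describe a digital phantom
#'
#' A background compartment plus an ordered list of inserts; later entries
#' override earlier ones where they overlap. If `insert_to_background_ratio`
#' is set, every fillable insert with nonzero activity must have exactly that
#' concentration ratio against the background (checked to 1e-9 relative).
#'
#' @param background a [compartment_spec()] defining the main chamber.
#' @param compartments list of [compartment_spec()] inserts.
#' @param insert_to_background_ratio optional dimensionless ratio.
#' @param reference_time reference time in s for the stated concentrations.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(background, compartments = list(),
                         insert_to_background_ratio = NULL,
                         reference_time = 0) {
  stopifnot(inherits(background, "compartment_spec"))
  for (cp in compartments) stopifnot(inherits(cp, "compartment_spec"))
  if (!is.null(insert_to_background_ratio)) {
    bg_c <- background$activity_concentration
    for (cp in compartments) {
      if (cp$activity_concentration > 0 && lookup_material(cp$material)$fillable) {
        ratio <- cp$activity_concentration / bg_c
        if (abs(ratio / insert_to_background_ratio - 1) > 1e-9) {
          abort(sprintf(
            "Insert '%s' has ratio %.9g against background, expected %.9g.",
            cp$name, ratio, insert_to_background_ratio))
        }
      }
    }
  }
  structure(
    list(background = background, compartments = compartments,
         insert_to_background_ratio = insert_to_background_ratio,
         reference_time = reference_time),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> background '%s' (%.4g kBq/ml) + %d compartments\n",
              x$background$name, x$background$activity_concentration,
              length(x$compartments)))
  for (cp in x$compartments) {
    cat(sprintf("  %-14s %-10s %7.3f ml  %8.4g kBq/ml  %s\n", cp$name,
                cp$shape, cp$nominal_volume, cp$activity_concentration,
                cp$material))
  }
  invisible(x)
}

shape_bbox <- function(spec) {
  half <- switch(spec$shape,
    sphere = rep(spec$dimensions$diameter / 2, 3),
    cylinder = c(spec$dimensions$diameter / 2, spec$dimensions$diameter / 2,
                 spec$dimensions$height / 2),
    ellipsoid = spec$dimensions$axes / 2,
    abort(sprintf("Compartment '%s': no analytic bbox for shape '%s'.",
                  spec$name, spec$shape))
  )
  list(lo = spec$center - half, hi = spec$center + half)
}

# signed distance to the shape boundary in mm, positive inside
inside_distance <- function(spec, x, y, z) {
  cx <- spec$center
  switch(spec$shape,
    sphere = {
      r <- spec$dimensions$diameter / 2
      if (r <= 0) rep(-Inf, length(x))
      else r - sqrt((x - cx[1])^2 + (y - cx[2])^2 + (z - cx[3])^2)
    },
    cylinder = {
      r <- spec$dimensions$diameter / 2
      h <- spec$dimensions$height / 2
      pmin(r - sqrt((x - cx[1])^2 + (y - cx[2])^2), h - abs(z - cx[3]))
    },
    ellipsoid = {
      ax <- spec$dimensions$axes / 2
      u <- (x - cx[1]) / ax[1]; v <- (y - cx[2]) / ax[2]
      w <- (z - cx[3]) / ax[3]
      m <- sqrt(u^2 + v^2 + w^2)
      gradn <- sqrt((u / ax[1])^2 + (v / ax[2])^2 + (w / ax[3])^2)
      # first-order distance to the unit level set of the scaled radius
      ifelse(m < 1e-12, min(ax), (1 - m) * m / pmax(gradn, 1e-12))
    }
  )
}

#' Rasterize a compartment to a fractional occupancy image
#'
#' Computes, for every voxel, the fraction of `supersampling^3` regularly
#' placed subvoxel centers that fall inside the compartment's analytic shape.
#' Occupancy-integrated volume converges to the analytic volume as the
#' supersampling factor grows.
#'
#' @param spec a [compartment_spec()].
#' @param grid a [grid_spec()].
#' @param supersampling integer >= 1, subvoxels per axis (default 3).
#' @return A dimensionless `voxel_image` with values in `[0, 1]`.
#' @examples
#' g <- grid_spec(32, 4.42)
#' occ <- rasterize_compartment(
#'   compartment_spec("sphere16", "sphere", nominal_volume = 16), g)
#' sum(occ$data) * voxel_volume_ml(occ)  # close to 16 ml
#' @export
rasterize_compartment <- function(spec, grid, supersampling = 3L) {
  stopifnot(inherits(spec, "compartment_spec"), inherits(grid, "grid_spec"))
  supersampling <- as.integer(supersampling)
  if (supersampling < 1L) abort("`supersampling` must be >= 1.")
  occ <- array(0, grid$dim)

  if (spec$shape == "mask-file") {
    mask <- read_image(spec$dimensions$path)
    if (!all(dim(mask$data) == grid$dim)) {
      abort(sprintf("Compartment '%s': mask-file grid does not match.",
                    spec$name))
    }
    occ[] <- as.numeric(mask$data > 0)
    return(voxel_image(occ, grid$voxel_size, grid$origin, "dimensionless"))
  }

  bbox <- shape_bbox(spec)
  if (all(bbox$hi <= bbox$lo)) {  # degenerate (zero-size) shape
    return(voxel_image(occ, grid$voxel_size, grid$origin, "dimensionless"))
  }
  glo <- grid$origin
  ghi <- grid$origin + grid$dim * grid$voxel_size
  if (any(bbox$lo < glo - 1e-9) || any(bbox$hi > ghi + 1e-9)) {
    abort(sprintf(
      "Compartment '%s' extends outside the grid (bbox [%s] vs grid [%s]).",
      spec$name,
      paste(sprintf("%.1f..%.1f", bbox$lo, bbox$hi), collapse = ", "),
      paste(sprintf("%.1f..%.1f", glo, ghi), collapse = ", ")))
  }

  idx_lo <- pmax(1L, floor((bbox$lo - glo) / grid$voxel_size) + 1L)
  idx_hi <- pmin(grid$dim, ceiling((bbox$hi - glo) / grid$voxel_size))
  ii <- idx_lo[1]:idx_hi[1]; jj <- idx_lo[2]:idx_hi[2]; kk <- idx_lo[3]:idx_hi[3]

  # subvoxel center offsets within a voxel, per axis, in mm
  off <- lapply(1:3, function(a) {
    ((seq_len(supersampling) - 0.5) / supersampling - 0.5) * grid$voxel_size[a]
  })
  sub <- expand.grid(ox = off[[1]], oy = off[[2]], oz = off[[3]])

  cx <- axis_centers(grid, 1)[ii]
  cy <- axis_centers(grid, 2)[jj]
  cz <- axis_centers(grid, 3)[kk]
  vox <- expand.grid(x = cx, y = cy, z = cz)
  # each subvoxel contributes an antialiased fraction: the boundary is
  # treated as locally planar across the subvoxel, so the fraction ramps
  # linearly with signed distance over one subvoxel width
  h_sub <- mean(grid$voxel_size) / supersampling
  acc <- numeric(nrow(vox))
  for (s in seq_len(nrow(sub))) {
    d <- inside_distance(spec, vox$x + sub$ox[s], vox$y + sub$oy[s],
                         vox$z + sub$oz[s])
    acc <- acc + pmin(pmax(0.5 + d / h_sub, 0), 1)
  }
  occ[ii, jj, kk] <- array(acc / nrow(sub), c(length(ii), length(jj),
                                              length(kk)))
  voxel_image(occ, grid$voxel_size, grid$origin, "dimensionless")
}

#' Build a voxelized digital phantom
#'
#' Rasterizes the background and every compartment onto a common grid and
#' assembles the ground-truth activity, HU and density maps plus binary VOI
#' masks. Voxels inside a compartment's binary mask (fractional occupancy
#' >= 0.5) carry exactly that compartment's concentration and material, so
#' mask means of the ground truth reproduce nominal concentrations exactly.
#' Later compartments override earlier ones; compartments with an explicit
#' equal `priority` may not overlap.
#'
#' @param phantom a [phantom_spec()].
#' @param grid a [grid_spec()].
#' @param supersampling passed to [rasterize_compartment()].
#' @return A list with elements `activity` (kBq/ml), `hu` (HU), `density`
#'   (g/cc), `masks` (named list of binary arrays), and `occupancy` (named
#'   list of fractional-occupancy `voxel_image`s, background included).
#' @export
build_digital_phantom <- function(phantom, grid, supersampling = 3L) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(grid, "grid_spec"))
  comps <- phantom$compartments
  bg <- phantom$background
  occ_bg <- rasterize_compartment(bg, grid, supersampling)
  mask_bg <- occ_bg$data >= 0.5
  air_hu <- -1000; air_rho <- 0.00121

  activity <- array(0, grid$dim)
  hu <- array(air_hu, grid$dim)
  density <- array(air_rho, grid$dim)
  bg_mat <- lookup_material(bg$material)
  activity[mask_bg] <- bg$activity_concentration
  hu[mask_bg] <- bg_mat$hu
  density[mask_bg] <- bg_mat$density_g_cc

  masks <- list(); occs <- list(background = occ_bg)
  claimed <- list()  # explicit-priority overlap accounting
  for (cp in comps) {
    occ <- rasterize_compartment(cp, grid, supersampling)
    m <- occ$data >= 0.5
    if (!is.null(cp$priority)) {
      key <- as.character(cp$priority)
      prev <- claimed[[key]]
      if (!is.null(prev) && any(m & prev$mask)) {
        abort(sprintf(
          "Compartments '%s' and '%s' overlap with identical priority %s.",
          prev$name, cp$name, key))
      }
      claimed[[key]] <- list(name = cp$name, mask = m | (prev$mask %||% FALSE))
    }
    mat <- lookup_material(cp$material)
    activity[m] <- if (mat$fillable) cp$activity_concentration else 0
    hu[m] <- mat$hu
    density[m] <- mat$density_g_cc
    masks[[cp$name]] <- m
    occs[[cp$name]] <- occ
  }
  masks[[bg$name]] <- mask_bg
  list(
    activity = voxel_image(activity, grid$voxel_size, grid$origin, "kBq/ml"),
    hu = voxel_image(hu, grid$voxel_size, grid$origin, "HU"),
    density = voxel_image(density, grid$voxel_size, grid$origin, "g/cc"),
    masks = masks,
    occupancy = occs
  )
}
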