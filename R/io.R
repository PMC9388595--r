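#' Read a voxel image from NIfTI or MetaImage
#'
#' NIfTI (`.nii` / `.nii.gz`) is read with RNifti; voxel size comes from
#' `pixdim` and the origin from the stored transform offset. MetaImage
#' (`.mha`) files written by [write_image()] carry the units tag in the
#' header; for NIfTI the units tag is stored in the `descrip` field when
#' possible, and can be overridden with the `units` argument.
#'
#' @param path file path ending in `.nii`, `.nii.gz` or `.mha`.
#' @param units optional units override.
#' @return A `voxel_image`.
#' @export
read_image <- function(path, units = NULL) {
  if (grepl("\\.mha$", path, ignore.case = TRUE)) {
    return(read_mha(path, units))
  }
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    abort("Only NIfTI (.nii/.nii.gz) and MetaImage (.mha) are supported.")
  }
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  vs <- abs(hdr$pixdim[2:4])
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  u <- units %||% trimws(hdr$descrip)
  if (is.null(u) || !nzchar(u) || !u %in% VALID_UNITS) u <- "dimensionless"
  voxel_image(array(as.numeric(img), dim(img)[1:3]), vs, origin, u)
}

#' Write a voxel image to NIfTI or MetaImage
#'
#' @param image a `voxel_image` (must carry a units tag).
#' @param path output path ending in `.nii`, `.nii.gz` or `.mha`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "voxel_image"))
  if (is.null(image$units) || !nzchar(image$units)) {
    abort("Refusing to write an image without a units tag.")
  }
  if (grepl("\\.mha$", path, ignore.case = TRUE)) {
    return(write_mha(image, path))
  }
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    abort("Only NIfTI (.nii/.nii.gz) and MetaImage (.mha) are supported.")
  }
  xf <- diag(4)
  diag(xf)[1:3] <- image$voxel_size
  xf[1:3, 4] <- image$origin
  nim <- RNifti::asNifti(image$data,
                         reference = list(pixdim = c(1, image$voxel_size, 0,
                                                     0, 0, 0),
                                          descrip = image$units))
  RNifti::sform(nim) <- structure(xf, code = 2L)
  RNifti::qform(nim) <- structure(xf, code = 2L)
  RNifti::writeNifti(nim, path)
  invisible(path)
}

read_mha <- function(path, units = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  d <- as.integer(strsplit(hdr$DimSize, " ")[[1]])
  vs <- as.numeric(strsplit(hdr$ElementSpacing, " ")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset, " ")[[1]])
  type <- hdr$ElementType
  what <- if (type == "MET_DOUBLE") "double" else if (type == "MET_UCHAR")
    "integer" else abort(sprintf("Unsupported MetaImage type %s.", type))
  size <- if (type == "MET_DOUBLE") 8L else 1L
  vals <- readBin(con, what = if (size == 1L) "raw" else "double",
                  n = prod(d), size = if (size == 1L) 1L else 8L,
                  endian = "little")
  if (size == 1L) vals <- as.integer(vals)
  u <- units %||% hdr$Units %||% "dimensionless"
  voxel_image(array(as.numeric(vals), d), vs, origin, u)
}

write_mha <- function(image, path) {
  d <- dim(image$data)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ObjectType = Image", "NDims = 3", "BinaryData = True",
    "BinaryDataByteOrderMSB = False", "CompressedData = False",
    sprintf("TransformMatrix = 1 0 0 0 1 0 0 0 1"),
    sprintf("Offset = %.9g %.9g %.9g", image$origin[1], image$origin[2],
            image$origin[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g", image$voxel_size[1],
            image$voxel_size[2], image$voxel_size[3]),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("Units = %s", image$units),
    "ElementType = MET_DOUBLE",
    "ElementDataFile = LOCAL"
  )
  writeLines(hdr, con)
  writeBin(as.vector(image$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a phantom specification from YAML
#'
#' The document has a `background` block and a `compartments` list, each
#' with `name`, `shape`, `center`, `dimensions`, `nominal_volume`,
#' `activity_concentration` and `material` entries, plus optional top-level
#' `insert_to_background_ratio` and `reference_time`.
#'
#' @param path a YAML file path.
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  as_comp <- function(x) {
    compartment_spec(
      name = x$name, shape = x$shape,
      center = as.numeric(x$center %||% c(0, 0, 0)),
      dimensions = lapply(x$dimensions %||% list(), function(d)
        if (is.list(d)) unlist(d) else as.numeric(d)),
      nominal_volume = x$nominal_volume,
      activity_concentration = x$activity_concentration %||% 0,
      material = x$material %||% "water",
      priority = x$priority
    )
  }
  phantom_spec(
    background = as_comp(doc$background),
    compartments = lapply(doc$compartments %||% list(), as_comp),
    insert_to_background_ratio = doc$insert_to_background_ratio,
    reference_time = doc$reference_time %||% 0
  )
}

extdata_path <- function(file) {
  system.file("extdata", file, package = "spectdose", mustWork = TRUE)
}

#' Packaged phantom specifications
#'
#' Three digital phantoms mirror the physical phantoms of an I-131
#' quantification study: a 5.64-L uniform calibration cylinder at
#' 105 kBq/ml; a hot-sphere Jaszczak phantom with 0.5/1/2/4/8/16-ml spheres
#' at 9.9:1 against a 25.9 kBq/ml background; and an anthropomorphic
#' head-and-neck phantom with a bone-resin skull, fillable glands and a
#' 22.8-ml tumor at 259 kBq/ml over a 26.2 kBq/ml background.
#'
#' @return A [phantom_spec()].
#' @export
phantom_cylinder <- function() read_phantom_spec(extdata_path("cylinder.yaml"))

#' @rdname phantom_cylinder
#' @export
phantom_jaszczak <- function() read_phantom_spec(extdata_path("jaszczak.yaml"))

#' @rdname phantom_cylinder
#' @export
phantom_anthro <- function() read_phantom_spec(extdata_path("anthro.yaml"))

#' Compare a measured fillable volume with its contoured volume
#'
#' Sign convention: `absolute_difference = contour - measured`;
#' `percent_difference = 100 * absolute_difference / measured`.
#'
#' @param measured physically measured volume in ml (> 0).
#' @param contour contoured volume in ml.
#' @param name optional VOI name.
#' @return A one-row tibble with `name`, `measured_volume_ml`,
#'   `contour_volume_ml`, `absolute_difference_ml`, `percent_difference`.
#' @examples
#' compare_volumes(22.77, 22.50)  # -0.27 ml, -1.19%
#' @export
compare_volumes <- function(measured, contour, name = NA_character_) {
  if (any(measured <= 0)) abort("`measured` must be > 0 ml.")
  abs_diff <- contour - measured
  tibble::tibble(
    name = name,
    measured_volume_ml = measured,
    contour_volume_ml = contour,
    absolute_difference_ml = abs_diff,
    percent_difference = 100 * abs_diff / measured
  )
}
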