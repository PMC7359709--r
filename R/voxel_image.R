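#' Construct a 3D voxel intensity volume
#'
#' A `voxel_image` holds a 3D scalar intensity grid together with its voxel
#' spacing. Axis 1 is the graft's long axis (the slice axis of the scanner),
#' axes 2 and 3 are the in-plane row and column directions. Intensities are
#' kept on their native numeric scale (8/16-bit counts or floats): masking
#' ranges are calibrated by the operator in image units, so no automatic
#' normalization is applied.
#'
#' @param data numeric 3D array, ordered slice x row x column.
#' @param spacing numeric length-3 vector `c(dz, dy, dx)` in mm/voxel.
#' @return An object of class `voxel_image` with elements `data` and `spacing`.
#' @examples
#' img <- voxel_image(array(0, c(4, 8, 8)), spacing = rep(0.1171875, 3))
#' dim(img$data)
#' @export
voxel_image <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array (slice x row x col)", call. = FALSE)
  }
  if (dim(data)[1] < 1L) stop("`data` must have at least one slice", call. = FALSE)
  if (!all(is.finite(data))) stop("intensities must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive values (dz, dy, dx) in mm", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing), class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_image> %d slices x %d x %d, spacing %s mm, intensity [%g, %g]\n",
    d[1], d[2], d[3], paste(signif(x$spacing, 6), collapse = " x "),
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' Construct a per-voxel material label volume
#'
#' A `label_volume` assigns every voxel of a scan to exactly one material.
#' Label 0 is always background; the remaining labels name the graft
#' materials (lumen, thrombus, wall, shrink tubing).
#'
#' @param labels integer 3D array on the same grid as the source image.
#' @param spacing voxel spacing `c(dz, dy, dx)` in mm.
#' @param materials named integer vector mapping material name to label value;
#'   must include `background = 0` and cover every value present in `labels`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing,
                         materials = c(background = 0L, lumen = 1L,
                                       thrombus = 2L, wall = 3L, shrink = 4L)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  if (any(labels != round(labels))) stop("labels must be integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  materials <- vapply(materials, as.integer, integer(1))
  if (is.null(names(materials)) || any(!nzchar(names(materials)))) {
    stop("`materials` must be a named vector", call. = FALSE)
  }
  if (!any(materials == 0L)) stop("`materials` must include background = 0", call. = FALSE)
  present <- sort(unique(as.vector(labels)))
  missing <- setdiff(present, materials)
  if (length(missing)) {
    stop("label value(s) absent from `materials`: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three positive values", call. = FALSE)
  }
  structure(list(labels = labels, spacing = spacing, materials = materials),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  counts <- vapply(x$materials, function(m) sum(x$labels == m), numeric(1))
  cat(sprintf("<label_volume> %d slices x %d x %d, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 6), collapse = " x ")))
  cat("  voxels:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}

.material_code <- function(labels, material) {
  if (!material %in% names(labels$materials)) {
    stop(sprintf("unknown material '%s' (have: %s)", material,
                 paste(names(labels$materials), collapse = ", ")), call. = FALSE)
  }
  labels$materials[[material]]
}

#' Voxel size from field of view and reconstruction matrix
#'
#' The scanner's isotropic voxel size is the field of view divided by the
#' reconstruction matrix: a 60 mm field of view at a 512 x 512 matrix gives
#' 0.1171875 mm, i.e. 117 um voxels at the printed (truncated) precision.
#'
#' @param fov_mm field of view in mm, > 0.
#' @param matrix_size reconstruction matrix dimension (voxel count), integer >= 1.
#' @return voxel size in mm/voxel, exactly `fov_mm / matrix_size`.
#' @examples
#' compute_voxel_size(60, 512) # 0.1171875 mm = 117.1875 um
#' @export
compute_voxel_size <- function(fov_mm, matrix_size) {
  if (!is.numeric(fov_mm) || length(fov_mm) != 1L || !is.finite(fov_mm) || fov_mm <= 0) {
    stop("`fov_mm` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(matrix_size) || length(matrix_size) != 1L ||
      !is.finite(matrix_size) || matrix_size < 1 || matrix_size != round(matrix_size)) {
    stop("`matrix_size` must be a positive integer", call. = FALSE)
  }
  fov_mm / matrix_size
}

#' Reconstructed projection count after frame averaging
#'
#' MicroCT acquisitions average groups of consecutive projections before
#' reconstruction (3672 acquired frames under four-projection averaging yield
#' 918 reconstructed projections). The acquired count must divide evenly:
#' a partial averaging group is undefined.
#'
#' @param acquired number of acquired projections, > 0.
#' @param averaging projections averaged per reconstructed frame, >= 1.
#' @return integer count `acquired / averaging`.
#' @examples
#' reconstructed_projection_count(3672, 4) # 918
#' @export
reconstructed_projection_count <- function(acquired, averaging) {
  if (!is.numeric(acquired) || length(acquired) != 1L || acquired <= 0 ||
      acquired != round(acquired)) {
    stop("`acquired` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(averaging) || length(averaging) != 1L || averaging < 1 ||
      averaging != round(averaging)) {
    stop("`averaging` must be a positive integer", call. = FALSE)
  }
  if (acquired %% averaging != 0) {
    stop(sprintf("%d projections are not divisible into groups of %d",
                 acquired, averaging), call. = FALSE)
  }
  as.integer(acquired / averaging)
}
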