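#' Read and write voxel volumes
#'
#' Volumes are stored either as NIfTI-1 (`.nii` / `.nii.gz`, spacing carried in
#' the header `pixdim`) or as multi-page grayscale TIFF stacks. TIFF has no
#' standardized z-spacing tag, so TIFF volumes carry a JSON sidecar
#' `<path>.json` with `{"spacing_mm": [dz, dy, dx]}`; alternatively an explicit
#' `spacing` override may be given on read. Write-then-read round trips are
#' bit-exact for integer grids.
#'
#' On disk, NIfTI data are ordered x (column), y (row), z (slice) as is
#' conventional; in memory the package uses slice x row x col. The reader and
#' writer permute accordingly.
#'
#' @param path file path; extension selects the format.
#' @param spacing optional `c(dz, dy, dx)` mm override; required for TIFF
#'   stacks without a sidecar.
#' @return `read_volume` returns a [voxel_image()]; `write_volume` returns
#'   `path` invisibly.
#' @seealso [read_label_volume()] for integer material label volumes.
#' @export
read_volume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- .volume_format(path)
  if (ext == "nifti") {
    nii <- RNifti::readNifti(path)
    arr <- as.array(nii)
    if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume", call. = FALSE)
    sp <- if (is.null(spacing)) rev(RNifti::pixdim(nii)) else as.numeric(spacing)
    voxel_image(aperm(arr, c(3, 2, 1)), sp)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    bits <- attr(pages[[1]], "bits.per.sample")
    if (identical(bits, 32L) || identical(bits, 32)) {
      pages <- tiff::readTIFF(path, all = TRUE) # float samples
      if (!is.list(pages)) pages <- list(pages)
    }
    dims <- vapply(pages, function(p) dim(p)[1:2], numeric(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stop("ragged TIFF stack: slices have mismatched shapes", call. = FALSE)
    }
    if (is.null(spacing)) {
      sidecar <- paste0(path, ".json")
      if (!file.exists(sidecar)) {
        stop("TIFF volume has no spacing: provide `spacing` or a '", sidecar,
             "' sidecar with spacing_mm", call. = FALSE)
      }
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (is.null(meta$spacing_mm)) stop("sidecar lacks 'spacing_mm'", call. = FALSE)
      spacing <- as.numeric(meta$spacing_mm)
    }
    arr <- array(0, c(length(pages), dims[1, 1], dims[2, 1]))
    for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
    voxel_image(arr, spacing)
  }
}

#' @rdname read_volume
#' @param image a [voxel_image()].
#' @export
write_volume <- function(image, path) {
  stopifnot(inherits(image, "voxel_image"))
  ext <- .volume_format(path)
  if (ext == "nifti") {
    nii <- RNifti::asNifti(aperm(image$data, c(3, 2, 1)))
    RNifti::pixdim(nii) <- rev(image$spacing)
    RNifti::writeNifti(nii, path)
  } else {
    .write_tiff_stack(image$data, path)
    jsonlite::write_json(list(spacing_mm = image$spacing), paste0(path, ".json"),
                         auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' Read and write material label volumes
#'
#' Label volumes are integer-typed TIFF or NIfTI grids; the material-name map
#' (and, for TIFF, the spacing) is persisted in a JSON sidecar `<path>.json`.
#' The round trip is lossless. Reading fails when the pixel type is not
#' integer or when a label value present in the grid is absent from the
#' persisted material map.
#'
#' @param path file path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @param spacing optional spacing override, `c(dz, dy, dx)` mm.
#' @return `read_label_volume` returns a [label_volume()].
#' @export
read_label_volume <- function(path, spacing = NULL) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("label volume requires a '", sidecar, "' sidecar with the material map",
         call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$materials)) stop("sidecar lacks 'materials'", call. = FALSE)
  materials <- vapply(meta$materials, as.integer, integer(1))
  if (is.null(spacing) && !is.null(meta$spacing_mm)) spacing <- as.numeric(meta$spacing_mm)
  img <- read_volume(path, spacing = spacing)
  if (any(img$data != round(img$data))) {
    stop("label volume has non-integer pixel values", call. = FALSE)
  }
  label_volume(img$data, img$spacing, materials)
}

#' @rdname read_label_volume
#' @param labels a [label_volume()].
#' @export
write_label_volume <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  ext <- .volume_format(path)
  if (ext == "nifti") {
    nii <- RNifti::asNifti(aperm(labels$labels, c(3, 2, 1)))
    RNifti::pixdim(nii) <- rev(labels$spacing)
    RNifti::writeNifti(nii, path, datatype = "int16")
  } else {
    .write_tiff_stack(labels$labels, path)
  }
  jsonlite::write_json(
    list(spacing_mm = labels$spacing, materials = as.list(labels$materials)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

.volume_format <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") return("nifti")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop("unsupported volume format '", ext, "' (use .nii, .nii.gz, .tif, .tiff)",
       call. = FALSE)
}

# tiff stores float samples only on [0,1]; integer-valued grids go through the
# 8/16-bit path (bit-exact), anything else must use NIfTI.
.write_tiff_stack <- function(data, path) {
  rng <- range(data)
  if (all(data == round(data)) && rng[1] >= 0 && rng[2] <= 65535) {
    bits <- if (rng[2] <= 255) 8L else 16L
    scale <- 2^bits - 1
    pages <- lapply(seq_len(dim(data)[1]), function(k) data[k, , ] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  } else if (rng[1] >= 0 && rng[2] <= 1) {
    pages <- lapply(seq_len(dim(data)[1]), function(k) data[k, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    stop("TIFF supports integer volumes in [0, 65535] or floats in [0, 1]; ",
         "write this volume as NIfTI instead", call. = FALSE)
  }
  invisible(path)
}
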