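#' Per-slice cross-sectional area profile
#'
#' Ordered per-slice cross-sectional areas (mm^2) of one material — the
#' AreaPerSlice table of the workflow.
#'
#' @param material material name.
#' @param areas numeric vector of per-slice areas (mm^2), one per slice.
#' @param slice_spacing slice spacing dz in mm.
#' @return object of class `slice_profile`.
#' @export
slice_profile <- function(material, areas, slice_spacing) {
  areas <- as.numeric(areas)
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stop("areas must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(slice_spacing) || slice_spacing <= 0) {
    stop("slice_spacing must be > 0", call. = FALSE)
  }
  structure(list(material = material, areas = areas,
                 slice_spacing = as.numeric(slice_spacing)),
            class = "slice_profile")
}

#' @export
print.slice_profile <- function(x, ...) {
  occ <- .occupied_span(x$areas)
  cat(sprintf("<slice_profile> %s: %d slices at dz = %g mm", x$material,
              length(x$areas), x$slice_spacing))
  if (is.null(occ)) cat(" (empty)\n") else {
    cat(sprintf(", occupied %d..%d, area %.4g mm^2 (max)\n",
                occ[1], occ[2], max(x$areas)))
  }
  invisible(x)
}

#' @export
as.data.frame.slice_profile <- function(x, ...) {
  data.frame(slice_index = seq_along(x$areas),
             z_mm = (seq_along(x$areas) - 0.5) * x$slice_spacing,
             area_mm2 = x$areas)
}

#' Export a slice profile as CSV
#'
#' Writes columns `slice_index`, `z_mm`, `area_mm2`.
#' @param profile a [slice_profile()].
#' @param path output CSV path.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

.occupied_span <- function(areas) {
  occ <- which(areas > 0)
  if (!length(occ)) return(NULL)
  c(min(occ), max(occ))
}

#' Cross-sectional area of a material in every slice
#'
#' `areas[z]` is the voxel count of the material in slice `z` times the
#' in-plane pixel area dy * dx.
#'
#' @param labels a [label_volume()].
#' @param material material name present in the label map.
#' @return a [slice_profile()].
#' @export
area_per_slice <- function(labels, material) {
  stopifnot(inherits(labels, "label_volume"))
  code <- .material_code(labels, material)
  counts <- rowSums(labels$labels == code, dims = 1)
  slice_profile(material, counts * labels$spacing[2] * labels$spacing[3],
                labels$spacing[1])
}

#' Volume of a material
#'
#' Voxel count times voxel volume dz * dy * dx; by construction identical to
#' the slice-area sum times dz.
#'
#' @inheritParams area_per_slice
#' @return volume in mm^3.
#' @export
volume_of <- function(labels, material) {
  # summed per slice so the identity volume == sum(areas) * dz holds exactly,
  # ulp for ulp, rather than only to rounding
  sum(area_per_slice(labels, material)$areas) * labels$spacing[1]
}

#' Length of a material along the slice axis
#'
#' Span convention from the slice-numbering system: (last occupied slice -
#' first occupied slice + 1) * dz. Interior empty slices — a fully occluded
#' cross-section — lie inside the span and are counted: an occluded segment is
#' still graft length.
#'
#' @inheritParams area_per_slice
#' @return length in mm.
#' @export
length_of <- function(labels, material) {
  stopifnot(inherits(labels, "label_volume"))
  code <- .material_code(labels, material)
  occ <- which(apply(labels$labels == code, 1, any))
  if (!length(occ)) stop(sprintf("material '%s' occupies no slice", material),
                         call. = FALSE)
  (max(occ) - min(occ) + 1) * labels$spacing[1]
}

#' Average cross-sectional area through length normalization
#'
#' The headline physical metric: luminal (or thrombus) volume divided by the
#' measured length, i.e. average volume per length = average cross-sectional
#' area.
#'
#' @param volume volume in mm^3.
#' @param length length in mm, > 0.
#' @return average area in mm^2.
#' @export
average_area <- function(volume, length) {
  if (!is.numeric(length) || length <= 0) {
    stop("length must be > 0 for length normalization", call. = FALSE)
  }
  volume / length
}

#' Caliper measurements of one graft sample
#'
#' @param length graft length in mm.
#' @param outer_diameter,inner_diameter outer/inner diameter in mm.
#' @param wall_thickness wall thickness in mm.
#' @return object of class `caliper_record`.
#' @export
caliper_record <- function(length, outer_diameter, inner_diameter,
                           wall_thickness = (outer_diameter - inner_diameter) / 2) {
  if (inner_diameter >= outer_diameter) {
    stop("inner diameter must be smaller than outer diameter", call. = FALSE)
  }
  vals <- c(length, outer_diameter, inner_diameter, wall_thickness)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("caliper measurements must be positive", call. = FALSE)
  }
  structure(list(length = length, outer_diameter = outer_diameter,
                 inner_diameter = inner_diameter, wall_thickness = wall_thickness),
            class = "caliper_record")
}

#' Luminal volume by cylindrical subtraction
#'
#' For samples where only the thrombus is radiopaque, luminal volume is the
#' caliper-based cylindrical approximation pi * (d/2)^2 * L minus the measured
#' thrombus volume. A thrombus volume exceeding the cylinder capacity signals
#' inconsistent measurements and is an error.
#'
#' @param caliper a [caliper_record()] (supplies the inner diameter).
#' @param measured_length measured graft length in mm.
#' @param thrombus_volume measured thrombus volume in mm^3, >= 0.
#' @return luminal volume in mm^3.
#' @examples
#' cal <- caliper_record(30, 5, 4)
#' lumen_from_subtraction(cal, 30, 90) # 286.99 mm^3
#' @export
lumen_from_subtraction <- function(caliper, measured_length, thrombus_volume) {
  stopifnot(inherits(caliper, "caliper_record"))
  if (thrombus_volume < 0) stop("thrombus volume must be >= 0", call. = FALSE)
  cylinder <- pi * (caliper$inner_diameter / 2)^2 * measured_length
  if (thrombus_volume > cylinder) {
    stop(sprintf("thrombus volume (%.3g mm^3) exceeds the caliper cylinder (%.3g mm^3)",
                 thrombus_volume, cylinder), call. = FALSE)
  }
  cylinder - thrombus_volume
}

#' Mean and standard deviation of per-slice areas over the occupied span
#'
#' The per-slice variability statistic (mean +/- SD of area over all analyzed
#' slices of a deposit). Computed over the occupied span — first to last
#' non-zero slice inclusive, interior zero-area (occluded) slices included —
#' with the sample (n-1) standard deviation.
#'
#' @param profile a [slice_profile()].
#' @return named vector `c(mean = , sd = )` in mm^2.
#' @export
profile_stats <- function(profile) {
  stopifnot(inherits(profile, "slice_profile"))
  if (!length(profile$areas)) stop("empty profile", call. = FALSE)
  occ <- .occupied_span(profile$areas)
  if (is.null(occ)) stop("profile has no occupied slices", call. = FALSE)
  a <- profile$areas[occ[1]:occ[2]]
  c(mean = mean(a), sd = if (length(a) > 1L) stats::sd(a) else 0)
}

#' Per-slice conservation residuals against the caliper cylinder
#'
#' Validation logic for doubly-measured samples: in each cross-sectional slice
#' the lumen and thrombus areas are added and compared with the material's
#' internal cross-section pi * (d/2)^2 computed from the caliper-measured
#' inner diameter (the "expected area" line). Positive residuals indicate
#' over-segmentation relative to the caliper cylinder.
#'
#' @param lumen,thrombus aligned [slice_profile()]s (same slice count and
#'   spacing).
#' @param caliper a [caliper_record()].
#' @param slices optional slice indices to evaluate (default: slices occupied
#'   by either material, spanning the union).
#' @return list of class `conservation_residuals`: `residuals` (mm^2, one per
#'   evaluated slice), `slices`, `expected_area`, `max_abs`, `mean`.
#' @export
conservation_residuals <- function(lumen, thrombus, caliper, slices = NULL) {
  stopifnot(inherits(lumen, "slice_profile"), inherits(thrombus, "slice_profile"),
            inherits(caliper, "caliper_record"))
  if (length(lumen$areas) != length(thrombus$areas)) {
    stop("profiles are not aligned: slice counts differ", call. = FALSE)
  }
  expected <- pi * (caliper$inner_diameter / 2)^2
  if (is.null(slices)) {
    both <- .occupied_span(lumen$areas + thrombus$areas)
    if (is.null(both)) stop("no occupied slices to validate", call. = FALSE)
    slices <- both[1]:both[2]
  }
  res <- lumen$areas[slices] + thrombus$areas[slices] - expected
  structure(list(residuals = res, slices = slices, expected_area = expected,
                 max_abs = max(abs(res)), mean = mean(res)),
            class = "conservation_residuals")
}

#' @export
print.conservation_residuals <- function(x, ...) {
  cat(sprintf(
    "<conservation_residuals> %d slices vs expected %.4g mm^2: max |r| = %.4g, mean = %.4g mm^2\n",
    length(x$residuals), x$expected_area, x$max_abs, x$mean))
  invisible(x)
}

#' Morphometric summary of one material
#'
#' Volume, span length, average cross-sectional area (volume/length) and the
#' per-slice area mean +/- SD for one material of one sample.
#'
#' @inheritParams area_per_slice
#' @return list of class `graft_metrics`: `material`, `volume` (mm^3),
#'   `length` (mm), `average_area` (mm^2), `area_mean`, `area_sd` (mm^2),
#'   `first_slice`, `last_slice`.
#' @export
graft_metrics <- function(labels, material) {
  prof <- area_per_slice(labels, material)
  occ <- .occupied_span(prof$areas)
  if (is.null(occ)) stop(sprintf("material '%s' occupies no slice", material),
                         call. = FALSE)
  vol <- volume_of(labels, material)
  len <- length_of(labels, material)
  st <- profile_stats(prof)
  structure(list(material = material, volume = vol, length = len,
                 average_area = average_area(vol, len),
                 area_mean = unname(st["mean"]), area_sd = unname(st["sd"]),
                 first_slice = occ[1], last_slice = occ[2]),
            class = "graft_metrics")
}

#' @export
print.graft_metrics <- function(x, ...) {
  cat(sprintf(
    "<graft_metrics> %s: V = %.4g mm^3, L = %.4g mm, V/L = %.4g mm^2 (per-slice %.4g +/- %.4g mm^2, slices %d..%d)\n",
    x$material, x$volume, x$length, x$average_area, x$area_mean, x$area_sd,
    x$first_slice, x$last_slice))
  invisible(x)
}

#' @export
as.data.frame.graft_metrics <- function(x, ...) {
  data.frame(material = x$material, volume_mm3 = x$volume, length_mm = x$length,
             average_area_mm2 = x$average_area, area_mean_mm2 = x$area_mean,
             area_sd_mm2 = x$area_sd, first_slice = x$first_slice,
             last_slice = x$last_slice)
}
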