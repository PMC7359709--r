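#' Inclusive intensity range
#'
#' The masking wand grows a region over pixels whose intensity lies within a
#' user-specified range. Bounds are inclusive; `-Inf`/`Inf` leave a side open.
#'
#' @param lo,hi lower and upper bounds in image intensity units, `lo <= hi`.
#' @return object of class `intensity_range`.
#' @export
intensity_range <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (length(lo) != 1L || length(hi) != 1L || is.na(lo) || is.na(hi) || lo > hi) {
    stop("need scalar bounds with lo <= hi", call. = FALSE)
  }
  structure(list(lo = lo, hi = hi), class = "intensity_range")
}

.in_range <- function(x, range) x >= range$lo & x <= range$hi

#' Segmentation calibration for one material
#'
#' Bundles the core intensity range of the target material, the "medium gray"
#' border band of partial-volume pixels at its edge, and the number of border
#' layers to annex (one, per the standard calibration: the selection includes
#' the interior of the target plus one layer of medium gray border pixels).
#'
#' @param core_range [intensity_range()] of the target material proper.
#' @param border_range [intensity_range()] of the partial-volume border band;
#'   `NULL` disables border growth.
#' @param border_layers number of one-pixel border layers to annex (>= 0).
#' @return object of class `segmentation_calibration`.
#' @export
segmentation_calibration <- function(core_range, border_range = NULL,
                                     border_layers = 1L) {
  stopifnot(inherits(core_range, "intensity_range"))
  if (!is.null(border_range)) stopifnot(inherits(border_range, "intensity_range"))
  border_layers <- as.integer(border_layers)
  if (is.na(border_layers) || border_layers < 0L) {
    stop("`border_layers` must be >= 0", call. = FALSE)
  }
  structure(list(core_range = core_range, border_range = border_range,
                 border_layers = border_layers),
            class = "segmentation_calibration")
}

# 4-neighbour binary dilation of a logical matrix
.dilate4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  if (nr > 1L) {
    out[-nr, ] <- m[-1, ]
    out[-1, ] <- out[-1, ] | m[-nr, ]
  }
  if (nc > 1L) {
    out[, -nc] <- out[, -nc] | m[, -1]
    out[, -1] <- out[, -1] | m[, -nc]
  }
  out
}

# 4-connected component of `inrange` containing seed (frontier expansion)
.flood4 <- function(inrange, seed) {
  visited <- matrix(FALSE, nrow(inrange), ncol(inrange))
  if (!inrange[seed[1], seed[2]]) return(visited)
  frontier <- visited
  frontier[seed[1], seed[2]] <- TRUE
  visited <- frontier
  repeat {
    frontier <- .dilate4(frontier) & inrange & !visited
    if (!any(frontier)) break
    visited <- visited | frontier
  }
  visited
}

# all 4-connected components of a logical matrix; returns integer matrix
.components4 <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  k <- 0L
  remaining <- m
  while (any(remaining)) {
    idx <- which(remaining)[1]
    seed <- c((idx - 1L) %% nrow(m) + 1L, (idx - 1L) %/% nrow(m) + 1L)
    comp <- .flood4(remaining, seed)
    k <- k + 1L
    lab[comp] <- k
    remaining <- remaining & !comp
  }
  lab
}

#' Masking wand: seeded intensity-range region growing on one slice
#'
#' Returns exactly the 4-connected set of pixels, contiguous to the seed
#' (the operator's mouse click), whose intensity lies within `range`. When the
#' seed pixel itself is outside the range the mask is empty.
#'
#' @param image a [voxel_image()].
#' @param slice_index slice to operate on (1-based).
#' @param seed in-plane pixel `c(row, col)`.
#' @param range an [intensity_range()].
#' @return logical matrix mask of the slice.
#' @export
masking_wand <- function(image, slice_index, seed, range) {
  stopifnot(inherits(image, "voxel_image"), inherits(range, "intensity_range"))
  d <- dim(image$data)
  if (slice_index < 1L || slice_index > d[1]) {
    stop("slice_index out of bounds", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (length(seed) != 2L || any(is.na(seed)) ||
      seed[1] < 1L || seed[1] > d[2] || seed[2] < 1L || seed[2] > d[3]) {
    stop("seed pixel out of slice bounds", call. = FALSE)
  }
  sl <- image$data[slice_index, , ]
  .flood4(.in_range(sl, range), seed)
}

#' Annex partial-volume border layers to a mask
#'
#' Repeats `layers` times: add every pixel 4-adjacent to the current mask
#' whose intensity lies in `border_range` (the medium-gray partial-volume
#' band). `layers = 0` is the identity; the result is always a superset of the
#' input, and the operation is idempotent once no adjacent border-band pixels
#' remain.
#'
#' @param mask logical matrix from the same slice.
#' @param slice numeric matrix of slice intensities.
#' @param border_range an [intensity_range()].
#' @param layers number of one-pixel layers to add.
#' @return logical matrix mask.
#' @export
include_border_layer <- function(mask, slice, border_range, layers = 1L) {
  stopifnot(is.logical(mask), all(dim(mask) == dim(slice)))
  if (is.null(border_range) || layers < 1L) return(mask)
  band <- .in_range(slice, border_range)
  for (i in seq_len(layers)) {
    add <- .dilate4(mask) & band & !mask
    if (!any(add)) break
    mask <- mask | add
  }
  mask
}

#' Propagate a seed point from the previous slice's mask
#'
#' Automates the operator's slice-to-slice clicking: the next seed is the
#' in-mask pixel nearest the mask centroid. For convex masks this is the
#' centroid pixel itself; for crescents (whose centroid can fall outside the
#' region) the nearest in-mask pixel is returned, guaranteeing a valid seed.
#' Ties break toward the first pixel in column-major order.
#'
#' @param prev_mask non-empty logical matrix.
#' @return integer `c(row, col)`.
#' @export
propagate_seed <- function(prev_mask) {
  idx <- which(prev_mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot propagate a seed from an empty mask", call. = FALSE)
  centroid <- colMeans(idx)
  d2 <- (idx[, 1] - centroid[1])^2 + (idx[, 2] - centroid[2])^2
  as.integer(idx[which.min(d2), ])
}

#' Segment one material through a slice stack
#'
#' Reproduces the per-cross-section workflow: the first analyzed slice is
#' segmented with the wand from `seed`; each subsequent slice is seeded by
#' [propagate_seed()] from the most recent non-empty mask. If the propagated
#' seed lands outside the core range (the region moved or changed shape), the
#' largest in-range 4-connected component on that slice is taken instead.
#' Slices where nothing is in range yield an empty mask and traversal
#' continues: a fully occluded cross-section is a real outcome, not an error.
#' After wand growth each slice mask annexes the calibrated border layers.
#'
#' `method = "threshold"` replaces the per-slice wand with a global intensity
#' threshold (every in-range pixel on the slice, regardless of connectivity),
#' an alternative reading of the bright-thrombus selection; the default is the
#' per-slice wand.
#'
#' @param image a [voxel_image()].
#' @param calibration a [segmentation_calibration()].
#' @param seed in-plane `c(row, col)` on the first analyzed slice.
#' @param slices increasing vector of slice indices to analyze; default all.
#' @param method `"wand"` (seeded region growing) or `"threshold"`.
#' @return A list of class `segmentation`: `mask` (logical array, slice x row
#'   x col, `FALSE` on unanalyzed slices), `slices`, and `qc`, a per-slice data
#'   frame of seed used, component size and fallback/empty flags.
#' @export
segment_target <- function(image, calibration, seed, slices = NULL,
                           method = c("wand", "threshold")) {
  stopifnot(inherits(image, "voxel_image"),
            inherits(calibration, "segmentation_calibration"))
  method <- match.arg(method)
  d <- dim(image$data)
  if (is.null(slices)) slices <- seq_len(d[1])
  slices <- as.integer(slices)
  if (any(slices < 1L | slices > d[1])) stop("slice range out of bounds", call. = FALSE)

  mask <- array(FALSE, d)
  qc <- data.frame(slice = slices, seed_row = NA_integer_, seed_col = NA_integer_,
                   pixels = 0L, fallback = FALSE, empty = FALSE)
  prev <- NULL
  seed <- as.integer(seed)

  for (i in seq_along(slices)) {
    z <- slices[i]
    sl <- image$data[z, , ]
    inr <- .in_range(sl, calibration$core_range)
    if (method == "threshold") {
      m <- inr
      use_seed <- c(NA_integer_, NA_integer_)
      fb <- FALSE
    } else {
      use_seed <- if (is.null(prev)) seed else propagate_seed(prev)
      fb <- FALSE
      if (inr[use_seed[1], use_seed[2]]) {
        m <- .flood4(inr, use_seed)
      } else {
        m <- .fallback_component(inr, prev)
        if (is.null(m)) m <- matrix(FALSE, d[2], d[3]) else fb <- TRUE
      }
    }
    if (any(m)) {
      m <- include_border_layer(m, sl, calibration$border_range,
                                calibration$border_layers)
      prev <- m
    }
    if (i == 1L && !any(m)) {
      stop("first analyzed slice yields an empty mask: calibration unusable",
           call. = FALSE)
    }
    mask[z, , ] <- m
    qc$seed_row[i] <- use_seed[1]; qc$seed_col[i] <- use_seed[2]
    qc$pixels[i] <- sum(m); qc$fallback[i] <- fb; qc$empty[i] <- !any(m)
  }
  structure(list(mask = mask, slices = slices, qc = qc), class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d slices analyzed, %d empty, %d fallback seeds, %d voxels\n",
              length(x$slices), sum(x$qc$empty), sum(x$qc$fallback), sum(x$mask)))
  invisible(x)
}

# fallback region when the propagated seed lands out of range: the largest
# in-range component overlapping the previous slice's mask; failing that, the
# largest component not touching the slice border (the graft's materials are
# interior regions — a border-touching component is background)
.fallback_component <- function(inr, prev = NULL) {
  comp <- .components4(inr)
  k <- max(comp)
  if (k == 0L) return(NULL)
  sizes <- tabulate(comp, nbins = k)
  if (!is.null(prev)) {
    overlap <- tabulate(comp[prev & comp > 0L], nbins = k)
    if (any(overlap > 0L)) {
      cand <- which(overlap > 0L)
      return(comp == cand[which.max(sizes[cand])])
    }
  }
  border <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1], comp[, ncol(comp)]))
  interior <- setdiff(seq_len(k), border)
  if (!length(interior)) return(NULL)
  comp == interior[which.max(sizes[interior])]
}

# fill enclosed holes of a logical mask: complement pixels unreachable from the
# slice border (4-connectivity) are holes
.fill_holes <- function(mask) {
  outside <- !mask
  frontier <- matrix(FALSE, nrow(mask), ncol(mask))
  frontier[1, ] <- outside[1, ]; frontier[nrow(mask), ] <- outside[nrow(mask), ]
  frontier[, 1] <- outside[, 1]; frontier[, ncol(mask)] <- outside[, ncol(mask)]
  reach <- frontier
  repeat {
    frontier <- .dilate4(frontier) & outside & !reach
    if (!any(frontier)) break
    reach <- reach | frontier
  }
  mask | (outside & !reach)
}

#' Analysis mode: ordered material targets for one sample type
#'
#' Encodes the per-material workflow of the three sample types:
#' \describe{
#'   \item{PVA}{radiopaque cast renders the lumen bright; the lumen is the
#'     single target.}
#'   \item{ePTFE}{iodine-stained thrombus is bright; the thrombus is the
#'     single target and luminal volume comes from caliper subtraction.}
#'   \item{collagen_ePTFE}{four nested materials are labeled sequentially —
#'     lumen (dark), outermost shrink tubing, graft wall — and the remaining
#'     material inside the wall is the thrombus.}
#' }
#'
#' @param material_type one of `"PVA"`, `"ePTFE"`, `"collagen_ePTFE"`.
#' @param targets ordered list; each element a list with `material` (name),
#'   `calibration` ([segmentation_calibration()]) and `seed`
#'   (`c(slice, row, col)`).
#' @param slices slice range analyzed (default: full volume).
#' @param method segmentation primitive, see [segment_target()].
#' @return object of class `analysis_mode`.
#' @export
analysis_mode <- function(material_type = c("PVA", "ePTFE", "collagen_ePTFE"),
                          targets, slices = NULL, method = "wand") {
  material_type <- match.arg(material_type)
  if (!length(targets)) stop("`targets` must be non-empty", call. = FALSE)
  for (t in targets) {
    stopifnot(is.character(t$material), inherits(t$calibration, "segmentation_calibration"),
              length(t$seed) == 3L)
  }
  expected <- switch(material_type, PVA = "lumen", ePTFE = "thrombus",
                     collagen_ePTFE = c("lumen", "shrink", "wall"))
  got <- vapply(targets, `[[`, "", "material")
  if (!setequal(got, expected)) {
    stop(sprintf("%s mode requires targets {%s}, got {%s}", material_type,
                 paste(expected, collapse = ", "), paste(got, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(material_type = material_type, targets = targets,
                 slices = slices, method = method), class = "analysis_mode")
}

#' Sequential four-material labeling with a thrombus remainder rule
#'
#' Labels the collagen-coated ePTFE situation slice by slice in the stated
#' order: first the (dark) lumen, next the outermost heat-shrink tubing, then
#' the graft wall — each with its own wand calibration, claiming only
#' still-unclaimed pixels — and finally the remaining material inside the
#' wall, which is the thrombus. The thrombus is computed per slice as the
#' hole-filled wall interior minus all explicitly claimed pixels, so lumen
#' plus thrombus tile the wall interior exactly. Slices where the wall does
#' not close around the lumen are flagged in the result rather than failing.
#'
#' @param image a [voxel_image()].
#' @param mode an [analysis_mode()] of material type `collagen_ePTFE`.
#' @return list of class `four_material_segmentation`: `labels` (a
#'   [label_volume()]), `qc` (per slice and material), `flagged_slices`.
#' @export
segment_four_material <- function(image, mode) {
  stopifnot(inherits(image, "voxel_image"), inherits(mode, "analysis_mode"))
  if (mode$material_type != "collagen_ePTFE") {
    stop("four-material labeling applies to collagen_ePTFE mode", call. = FALSE)
  }
  d <- dim(image$data)
  slices <- if (is.null(mode$slices)) seq_len(d[1]) else as.integer(mode$slices)
  materials <- c(background = 0L, lumen = 1L, thrombus = 2L, wall = 3L, shrink = 4L)
  ord <- c("lumen", "shrink", "wall")
  targets <- setNames(mode$targets, vapply(mode$targets, `[[`, "", "material"))[ord]

  labels <- array(0L, d)
  prev <- setNames(vector("list", 3L), ord)
  qc <- list()
  flagged <- integer(0)

  for (z in slices) {
    sl <- image$data[z, , ]
    claimed <- matrix(0L, d[2], d[3])
    masks <- list()
    for (nm in ord) {
      tg <- targets[[nm]]
      cal <- tg$calibration
      inr <- .in_range(sl, cal$core_range) & claimed == 0L
      use_seed <- if (is.null(prev[[nm]])) tg$seed[2:3] else propagate_seed(prev[[nm]])
      fb <- FALSE
      if (inr[use_seed[1], use_seed[2]]) {
        m <- .flood4(inr, use_seed)
      } else if (is.null(prev[[nm]]) && z < tg$seed[1]) {
        # before this material's first (operator-clicked) slice: the material
        # may genuinely be absent (e.g. occluded lumen); no fallback yet
        m <- matrix(FALSE, d[2], d[3])
      } else {
        m <- .fallback_component(inr, prev[[nm]])
        if (is.null(m)) m <- matrix(FALSE, d[2], d[3]) else fb <- TRUE
      }
      if (any(m)) {
        grown <- include_border_layer(m, sl, cal$border_range, cal$border_layers)
        m <- grown & claimed == 0L
        prev[[nm]] <- m
      }
      claimed[m] <- materials[[nm]]
      masks[[nm]] <- m
      qc[[length(qc) + 1L]] <- data.frame(slice = z, material = nm,
                                          seed_row = use_seed[1], seed_col = use_seed[2],
                                          pixels = sum(m), fallback = fb)
    }
    interior <- .fill_holes(masks$wall) & !masks$wall
    if (any(masks$lumen & !interior) || (!any(interior) && any(masks$lumen))) {
      flagged <- c(flagged, z)
    }
    thrombus <- interior & claimed == 0L
    claimed[thrombus] <- materials[["thrombus"]]
    qc[[length(qc) + 1L]] <- data.frame(slice = z, material = "thrombus",
                                        seed_row = NA_integer_, seed_col = NA_integer_,
                                        pixels = sum(thrombus), fallback = FALSE)
    labels[z, , ] <- claimed
  }

  structure(list(labels = label_volume(labels, image$spacing, materials),
                 qc = do.call(rbind, qc), flagged_slices = flagged),
            class = "four_material_segmentation")
}

#' @export
print.four_material_segmentation <- function(x, ...) {
  cat("<four_material_segmentation>\n")
  print(x$labels)
  if (length(x$flagged_slices)) {
    cat("  flagged (wall not closed):", paste(x$flagged_slices, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a single-material segmentation to a label volume
#'
#' @param seg a `segmentation` from [segment_target()].
#' @param image the segmented [voxel_image()] (for spacing).
#' @param material material name for the mask.
#' @return a [label_volume()] with background plus the one material.
#' @export
as_label_volume <- function(seg, image, material) {
  stopifnot(inherits(seg, "segmentation"))
  codes <- c(background = 0L, lumen = 1L, thrombus = 2L, wall = 3L, shrink = 4L)
  if (!material %in% names(codes)) stop("unknown material name", call. = FALSE)
  lab <- array(0L, dim(seg$mask))
  lab[seg$mask] <- codes[[material]]
  label_volume(lab, image$spacing, codes[c("background", material)])
}
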