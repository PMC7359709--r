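#' Parametric synthetic graft phantom specification
#'
#' Describes a synthetic microCT scan of a tubular graft with exactly known
#' geometry, standing in for an ex vivo scan. The phantom is a straight
#' circular tube along the slice axis carrying a mural (wall-attached)
#' thrombus deposit whose per-slice cross-sectional area follows a
#' parameterized axial profile. Three contrast situations are rendered:
#' \describe{
#'   \item{lumen_opaque}{a radiopaque cast fills the open lumen (bright lumen
#'     in a gray wall) — the hydrogel/PVA situation.}
#'   \item{thrombus_opaque}{iodine-stained thrombus is bright in a dark,
#'     unstained wall with an open (dark) lumen — the ePTFE situation.}
#'   \item{four_material}{dark open lumen, bright stained thrombus, gray wall
#'     and an outermost shrink-tubing ring — the collagen-coated ePTFE
#'     situation with four nested materials.}
#' }
#'
#' Partial-volume "medium gray" border pixels arise from supersampled
#' occupancy averaging, not blurring: every voxel is subdivided
#' `supersample`^2 times in plane, each subsample assigned a material, and the
#' voxel intensity is the occupancy-weighted mean of the material levels.
#'
#' @param inner_diameter,outer_diameter graft inner/outer diameter, mm.
#' @param length graft length, mm.
#' @param spacing isotropic voxel size, mm (default 60 mm FOV / 512).
#' @param contrast_mode one of `"lumen_opaque"`, `"thrombus_opaque"`,
#'   `"four_material"`.
#' @param thrombus list describing the per-slice thrombus area profile
#'   A_T(z) = baseline + amplitude * sin(2 pi z / period + phase), clipped to
#'   `[0, pi (inner_diameter/2)^2]`, with fields `baseline`, `amplitude`
#'   (mm^2), `period` (mm) and `eccentricity` in `[0, 1)` (0 = concentric
#'   annular deposit, larger = more mural/crescent-shaped). The phase and the
#'   attachment direction are drawn from `rng_seed`.
#' @param intensities named per-material mean intensity levels; `NULL` uses
#'   the mode defaults (see [default_intensities()]).
#' @param noise_sigma additive Gaussian noise SD, intensity units.
#' @param supersample integer in-plane antialiasing factor (>= 1).
#' @param shrink_thickness shrink-tubing ring thickness, mm (four_material).
#' @param margin background margin around/beyond the graft, mm.
#' @param rng_seed integer seed; identical specs generate bit-identical
#'   phantoms, and the geometry is seed-stable under `noise_sigma` changes.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(inner_diameter = 4, outer_diameter = 5, length = 30,
                         spacing = 0.1171875,
                         contrast_mode = c("lumen_opaque", "thrombus_opaque",
                                           "four_material"),
                         thrombus = list(baseline = 0, amplitude = 0,
                                         period = 12, eccentricity = 0.5),
                         intensities = NULL, noise_sigma = 0, supersample = 8L,
                         shrink_thickness = 0.35, margin = 1, rng_seed = 1L) {
  contrast_mode <- match.arg(contrast_mode)
  if (!(inner_diameter > 0 && inner_diameter < outer_diameter)) {
    stop("need 0 < inner_diameter < outer_diameter", call. = FALSE)
  }
  if (length <= 0 || spacing <= 0 || margin < 0 || shrink_thickness <= 0) {
    stop("invalid geometry parameter", call. = FALSE)
  }
  supersample <- as.integer(supersample)
  if (is.na(supersample) || supersample < 1L) stop("supersample must be >= 1", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  def <- list(baseline = 0, amplitude = 0, period = 12, eccentricity = 0.5)
  thrombus <- utils::modifyList(def, thrombus[names(thrombus) %in% names(def)])
  cap <- pi * (inner_diameter / 2)^2
  if (thrombus$baseline < 0 || thrombus$amplitude < 0 || thrombus$period <= 0) {
    stop("thrombus baseline/amplitude must be >= 0, period > 0", call. = FALSE)
  }
  if (thrombus$baseline > cap) {
    stop(sprintf("thrombus baseline %.3g mm^2 exceeds lumen capacity %.3g mm^2",
                 thrombus$baseline, cap), call. = FALSE)
  }
  if (thrombus$eccentricity < 0 || thrombus$eccentricity >= 1) {
    stop("eccentricity must be in [0, 1)", call. = FALSE)
  }
  if (is.null(intensities)) intensities <- default_intensities(contrast_mode)
  needed <- c("background", "lumen", "thrombus", "wall",
              if (contrast_mode == "four_material") "shrink")
  if (!all(needed %in% names(intensities))) {
    stop("intensities must name: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  structure(list(inner_diameter = inner_diameter, outer_diameter = outer_diameter,
                 length = length, spacing = spacing, contrast_mode = contrast_mode,
                 thrombus = thrombus, intensities = intensities,
                 noise_sigma = noise_sigma, supersample = supersample,
                 shrink_thickness = shrink_thickness, margin = margin,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Default per-material intensity levels for each contrast mode
#'
#' Levels are on an arbitrary 8-bit-like scale, ordered to mimic the real
#' contrast situations: a bright cast (lumen_opaque), bright stained thrombus
#' in a radiolucent wall (thrombus_opaque), and four distinguishable nested
#' levels (four_material, lumen black).
#'
#' @param contrast_mode phantom contrast mode.
#' @return named numeric vector of intensity levels.
#' @export
default_intensities <- function(contrast_mode) {
  switch(contrast_mode,
    lumen_opaque = c(background = 10, lumen = 220, thrombus = 100, wall = 120),
    thrombus_opaque = c(background = 10, lumen = 15, thrombus = 220, wall = 60),
    four_material = c(background = 0, lumen = 20, thrombus = 220, wall = 160,
                      shrink = 90),
    stop("unknown contrast mode", call. = FALSE)
  )
}

# evaluate code with a temporary RNG state seeded from `seed`
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

# grid layout shared by profile and renderer
.phantom_grid <- function(spec) {
  h <- spec$spacing
  half <- spec$outer_diameter / 2 +
    (if (spec$contrast_mode == "four_material") spec$shrink_thickness else 0) +
    spec$margin
  n <- 2L * as.integer(ceiling(half / h)) + 1L # odd: axis on the central voxel
  mz <- as.integer(ceiling(spec$margin / h))
  nz_graft <- as.integer(round(spec$length / h))
  list(h = h, n = n, c0 = (n + 1L) / 2, mz = mz, nz_graft = nz_graft,
       nz = nz_graft + 2L * mz,
       z_centers = ((seq_len(nz_graft + 2L * mz)) - mz - 0.5) * h)
}

#' Axial thrombus area profile of a phantom
#'
#' Deterministic given the spec's seed: a clipped sinusoid emulating the
#' axial variability of a single thrombus. Slices outside the graft span have
#' zero area.
#'
#' @param spec a [phantom_spec()].
#' @return a [slice_profile()] of target thrombus areas (mm^2) per grid slice.
#' @export
thrombus_area_profile <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- .phantom_grid(spec)
  phase <- .with_seed(spec$rng_seed, stats::runif(2, 0, 2 * pi))[1]
  cap <- pi * (spec$inner_diameter / 2)^2
  a <- spec$thrombus$baseline +
    spec$thrombus$amplitude * sin(2 * pi * g$z_centers / spec$thrombus$period + phase)
  a <- pmin(pmax(a, 0), cap)
  inside <- g$z_centers > 0 & g$z_centers < spec$length
  a[!inside] <- 0
  slice_profile("thrombus", a, g$h)
}

# mean over ss x ss blocks of a fine logical/numeric matrix with coarse-major
# ordering (fine index = (coarse - 1) * ss + sub)
.block_mean <- function(m, ss, n) {
  if (ss == 1L) return(m + 0)
  a <- colMeans(array(m, c(ss, n, ss, n)))
  colMeans(aperm(a, c(2, 1, 3)))
}

#' Generate a synthetic graft phantom with exact ground truth
#'
#' Renders the spec's geometry on the voxel grid by in-plane supersampling
#' (each voxel subdivided `supersample`^2 times; the intensity is the
#' occupancy-weighted mean of material levels, which manufactures the single
#' layer of medium-gray partial-volume border pixels that the calibration rule
#' targets), adds Gaussian noise of SD `noise_sigma` after the geometry, and
#' derives ground-truth labels from majority subvoxel occupancy (ties go to
#' the enclosed material: lumen, then thrombus, then wall, then shrink). The
#' thrombus is realized per slice as an eccentric annular/crescent deposit on
#' the inner wall: the open lumen is a disk of radius rho(z) =
#' sqrt(r_in^2 - A_T(z)/pi) whose center is offset by
#' eccentricity * (r_in - rho) along a seed-drawn direction, so the deposit's
#' area matches the target profile analytically.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom`: `image` (a [voxel_image()]) and `truth`,
#'   a list with `labels` (exact [label_volume()]), `true_lumen_volume`,
#'   `true_thrombus_volume` (mm^3, from the truth labels), `true_length` (mm),
#'   `area_profiles` (per-material [slice_profile()]s), `target_profile`,
#'   `seed_hints` (per-material `c(slice, row, col)` operator-click points),
#'   `span` (first and last graft slice), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- .phantom_grid(spec)
  ss <- spec$supersample
  h <- g$h
  n <- g$n
  four <- spec$contrast_mode == "four_material"
  lv <- spec$intensities

  draws <- .with_seed(spec$rng_seed, stats::runif(2, 0, 2 * pi))
  theta <- draws[2]
  r_in <- spec$inner_diameter / 2
  r_out <- spec$outer_diameter / 2
  r_shk <- r_out + spec$shrink_thickness
  cap <- pi * r_in^2

  target <- thrombus_area_profile(spec)
  if (max(target$areas) > cap + 1e-9) {
    stop("thrombus profile exceeds lumen capacity", call. = FALSE)
  }

  # fine in-plane coordinates (mm, axis at 0), coarse-major ordering
  sub <- ((seq_len(ss)) - 0.5) / ss - 0.5
  fine <- as.vector(t(outer(seq_len(n) - g$c0, sub, "+"))) * h
  d2c <- outer(fine^2, fine^2, "+")
  inner_f <- d2c <= r_in^2
  wall_f <- d2c <= r_out^2 & !inner_f
  occ_wall <- .block_mean(wall_f, ss, n)
  occ_shk <- if (four) .block_mean(d2c <= r_shk^2 & !inner_f & !wall_f, ss, n)
             else matrix(0, n, n)
  occ_inner_full <- .block_mean(inner_f, ss, n)

  img <- array(lv[["background"]], c(g$nz, n, n))
  labels <- array(0L, c(g$nz, n, n))
  mats <- c(background = 0L, lumen = 1L, thrombus = 2L, wall = 3L, shrink = 4L)

  render <- function(rho) {
    if (rho >= r_in) {
      occ_l <- occ_inner_full
      occ_t <- matrix(0, n, n)
    } else if (rho <= 0) {
      occ_l <- matrix(0, n, n)
      occ_t <- occ_inner_full
    } else {
      e <- spec$thrombus$eccentricity * (r_in - rho)
      ey <- e * sin(theta); ex <- e * cos(theta)
      d2o <- outer((fine - ey)^2, (fine - ex)^2, "+")
      occ_l <- .block_mean(d2o <= rho^2 & inner_f, ss, n)
      occ_t <- occ_inner_full - occ_l
    }
    intensity <- occ_l * lv[["lumen"]] + occ_t * lv[["thrombus"]] +
      occ_wall * lv[["wall"]] + occ_shk * (if (four) lv[["shrink"]] else 0) +
      (1 - occ_l - occ_t - occ_wall - occ_shk) * lv[["background"]]
    occ_bg <- 1 - occ_l - occ_t - occ_wall - occ_shk
    # ties go to the enclosed material: priority lumen, thrombus, wall, shrink
    lab_idx <- max.col(cbind(as.vector(occ_l), as.vector(occ_t),
                             as.vector(occ_wall), as.vector(occ_shk),
                             as.vector(occ_bg)), ties.method = "first")
    lab <- matrix(c(1L, 2L, 3L, 4L, 0L)[lab_idx], n, n)
    list(intensity = intensity, labels = lab)
  }

  cache <- new.env(parent = emptyenv())
  inside <- g$z_centers > 0 & g$z_centers < spec$length
  for (k in seq_len(g$nz)) {
    if (!inside[k]) next
    rho <- sqrt(max(r_in^2 - target$areas[k] / pi, 0))
    key <- sprintf("%.12e", rho)
    sl <- if (!is.null(cache[[key]])) cache[[key]] else (cache[[key]] <- render(rho))
    img[k, , ] <- sl$intensity
    labels[k, , ] <- sl$labels
  }

  if (spec$noise_sigma > 0) {
    noise <- .with_seed(spec$rng_seed, {
      stats::runif(2)                       # geometry draws, kept in sequence
      stats::rnorm(length(img), 0, spec$noise_sigma)
    })
    img <- img + noise
  }

  keep <- mats[c("background", "lumen", "thrombus", "wall", if (four) "shrink")]
  truth_labels <- label_volume(labels, rep(h, 3), keep)
  span <- range(which(inside))
  profiles <- lapply(setdiff(names(keep), "background"),
                     function(m) area_per_slice(truth_labels, m))
  names(profiles) <- setdiff(names(keep), "background")

  truth <- list(
    labels = truth_labels,
    true_lumen_volume = volume_of(truth_labels, "lumen"),
    true_thrombus_volume = volume_of(truth_labels, "thrombus"),
    true_length = (span[2] - span[1] + 1) * h,
    area_profiles = profiles,
    target_profile = target,
    seed_hints = .seed_hints(labels, g, spec, theta, target),
    span = span,
    spec = spec
  )
  structure(list(image = voxel_image(img, rep(h, 3)), truth = truth),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s, ID %g mm x %g mm, lumen %.4g mm^3, thrombus %.4g mm^3\n",
              x$truth$spec$contrast_mode, x$truth$spec$inner_diameter,
              x$truth$spec$length, x$truth$true_lumen_volume,
              x$truth$true_thrombus_volume))
  invisible(x)
}

# operator-click points: for each material, a pixel of that truth label near a
# geometric anchor on a suitable slice
.seed_hints <- function(labels, g, spec, theta, target) {
  h <- g$h
  c0 <- g$c0
  r_in <- spec$inner_diameter / 2
  r_out <- spec$outer_diameter / 2
  inside <- which(g$z_centers > 0 & g$z_centers < spec$length)
  z1 <- min(inside)
  pick <- function(z, anchor_mm, code) {
    idx <- which(labels[z, , ] == code, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    ay <- anchor_mm[1] / h + c0; ax <- anchor_mm[2] / h + c0
    j <- which.min((idx[, 1] - ay)^2 + (idx[, 2] - ax)^2)
    c(slice = z, row = idx[j, 1], col = idx[j, 2])
  }
  u <- c(sin(theta), cos(theta))
  lum_slices <- inside[vapply(inside, function(z) any(labels[z, , ] == 1L), TRUE)]
  zl <- if (length(lum_slices)) min(lum_slices) else z1
  rho1 <- sqrt(max(r_in^2 - target$areas[zl] / pi, 0))
  e1 <- spec$thrombus$eccentricity * (r_in - rho1)
  vox_area <- h^2
  with_thr <- inside[target$areas[inside] > vox_area]
  zt <- if (length(with_thr)) min(with_thr) else inside[which.max(target$areas[inside])]
  rhot <- sqrt(max(r_in^2 - target$areas[zt] / pi, 0))
  et <- spec$thrombus$eccentricity * (r_in - rhot)
  tt <- (max(rhot - et, 0) + r_in) / 2
  hints <- list(
    lumen = pick(zl, u * e1, 1L),
    thrombus = pick(zt, -u * tt, 2L),
    wall = pick(z1, -u * (r_in + r_out) / 2, 3L),
    shrink = if (spec$contrast_mode == "four_material") {
      pick(z1, -u * (r_out + (r_out + spec$shrink_thickness)) / 2, 4L)
    }
  )
  hints[!vapply(hints, is.null, TRUE)]
}

#' Recompute morphometry from phantom truth labels
#'
#' Definitional check on the ground truth: per-material [graft_metrics()]
#' recomputed from the truth label volume. Volumes equal the stored true
#' volumes exactly (both are voxel counts times voxel volume).
#'
#' @param truth the `truth` element of a [generate_phantom()] result.
#' @return named list of [graft_metrics()] for each non-empty material.
#' @export
truth_summary <- function(truth) {
  mats <- setdiff(names(truth$labels$materials), "background")
  out <- list()
  for (m in mats) {
    if (any(truth$labels$labels == truth$labels$materials[[m]])) {
      out[[m]] <- graft_metrics(truth$labels, m)
    }
  }
  out
}

#' Wand calibrations emulating the trained operator for a phantom
#'
#' Builds the [analysis_mode()] a trained operator would calibrate on this
#' phantom's intensity scale. Core ranges cover mixes that are at least 75%
#' target; border bands extend to the inter-material intensity midpoints, so a
#' mask plus one border layer claims exactly the pixels that are majority
#' target. Equal-mix (50/50) border pixels belong to the enclosed material —
#' the same convention as the border-layer rule, which assigns the medium-gray
#' edge to the selected target — so enclosing materials' bands start just
#' inside their midpoints. Seeds come from the phantom's truth hints.
#'
#' @param phantom a [generate_phantom()] result.
#' @return an [analysis_mode()] ready for [segment_target()] /
#'   [segment_four_material()].
#' @export
phantom_analysis_mode <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  spec <- phantom$truth$spec
  lv <- spec$intensities
  hints <- phantom$truth$seed_hints
  span <- phantom$truth$span
  eps <- 1e-6 * max(abs(lv))
  mid <- function(a, b) (lv[[a]] + lv[[b]]) / 2

  if (spec$contrast_mode == "lumen_opaque") {
    lo <- max(mid("lumen", "wall"), mid("lumen", "thrombus"))
    cal <- segmentation_calibration(
      intensity_range(lv[["lumen"]] - 0.25 * (lv[["lumen"]] - max(lv[["wall"]], lv[["thrombus"]])), Inf),
      intensity_range(lo, Inf)
    )
    analysis_mode("PVA",
                  list(list(material = "lumen", calibration = cal, seed = hints$lumen)),
                  slices = span[1]:span[2])
  } else if (spec$contrast_mode == "thrombus_opaque") {
    lo <- max(mid("thrombus", "wall"), mid("thrombus", "lumen"))
    cal <- segmentation_calibration(
      intensity_range(lv[["thrombus"]] - 0.25 * (lv[["thrombus"]] - max(lv[["wall"]], lv[["lumen"]])), Inf),
      intensity_range(lo, Inf)
    )
    thr <- which(phantom$truth$target_profile$areas > 0)
    z_range <- if (length(thr)) range(thr) else span
    analysis_mode("ePTFE",
                  list(list(material = "thrombus", calibration = cal, seed = hints$thrombus)),
                  slices = max(z_range[1], hints$thrombus[["slice"]]):z_range[2])
  } else {
    gap_l <- min(lv[["wall"]], lv[["thrombus"]]) - lv[["lumen"]]
    cal_lumen <- segmentation_calibration(
      intensity_range(-Inf, lv[["lumen"]] + 0.25 * gap_l),
      intensity_range(-Inf, min(mid("lumen", "wall"), mid("lumen", "thrombus")))
    )
    gap_s <- min(abs(lv[["shrink"]] - lv[["background"]]), abs(lv[["wall"]] - lv[["shrink"]]))
    cal_shrink <- segmentation_calibration(
      intensity_range(lv[["shrink"]] - 0.25 * gap_s, lv[["shrink"]] + 0.25 * gap_s),
      intensity_range(mid("background", "shrink"), mid("shrink", "wall"))
    )
    gap_w <- min(lv[["thrombus"]] - lv[["wall"]], lv[["wall"]] - lv[["shrink"]],
                 lv[["wall"]] - lv[["lumen"]])
    cal_wall <- segmentation_calibration(
      intensity_range(lv[["wall"]] - 0.25 * gap_w, lv[["wall"]] + 0.25 * gap_w),
      intensity_range(min(mid("lumen", "wall"), mid("shrink", "wall")) + eps,
                      mid("wall", "thrombus") - eps)
    )
    analysis_mode("collagen_ePTFE",
                  list(list(material = "lumen", calibration = cal_lumen, seed = hints$lumen),
                       list(material = "shrink", calibration = cal_shrink, seed = hints$shrink),
                       list(material = "wall", calibration = cal_wall, seed = hints$wall)),
                  slices = span[1]:span[2])
  }
}

#' Serialize / deserialize a phantom spec
#'
#' Phantom specs round-trip through YAML (or JSON via the same schema).
#' @param spec a [phantom_spec()].
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_phantom_spec` returns a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  lst <- unclass(spec)
  lst$intensities <- as.list(lst$intensities)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  lst$intensities <- unlist(lst$intensities)
  do.call(phantom_spec, lst)
}
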