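test_that("thrombus area profile obeys its parameters and determinism", {
  spec <- phantom_spec(thrombus = list(baseline = 3, amplitude = 0), length = 6)
  prof <- thrombus_area_profile(spec)
  inside <- prof$areas[prof$areas > 0]
  expect_true(all(abs(inside - 3) < 1e-12)) # amplitude 0 -> constant
  clean <- thrombus_area_profile(phantom_spec(length = 6))
  expect_true(all(clean$areas == 0)) # baseline 0, amplitude 0 -> clean graft
  s1 <- phantom_spec(thrombus = list(baseline = 4, amplitude = 2), rng_seed = 9, length = 6)
  expect_identical(thrombus_area_profile(s1)$areas, thrombus_area_profile(s1)$areas)
  # clipping: amplitude overshooting capacity clips to [0, pi r^2]
  cap <- pi * 2^2
  big <- thrombus_area_profile(phantom_spec(
    thrombus = list(baseline = cap * 0.9, amplitude = cap), length = 6))
  expect_true(all(big$areas >= 0 & big$areas <= cap + 1e-12))
})

test_that("phantom spec validates geometry and thrombus capacity", {
  expect_error(phantom_spec(inner_diameter = 5, outer_diameter = 4), "inner_diameter")
  expect_error(phantom_spec(thrombus = list(baseline = 100)), "capacity")
  expect_error(phantom_spec(thrombus = list(eccentricity = 1)), "eccentricity")
  expect_error(phantom_spec(supersample = 0), "supersample")
})

test_that("clean lumen-opaque phantom has exact-cylinder truth", {
  ph <- small_phantom("lumen_opaque", length = 6)
  expect_identical(sum(ph$truth$labels$labels == 2L), 0L) # no thrombus voxels
  analytic <- pi * 2^2 * 6
  expect_lt(abs(ph$truth$true_lumen_volume - analytic) / analytic, 0.02)
  expect_lt(abs(ph$truth$true_length - 6), ph$truth$spec$spacing + 1e-12)
})

test_that("noise-free supersample-1 phantom takes only the material levels", {
  ph <- small_phantom("lumen_opaque", length = 2, supersample = 1)
  lv <- default_intensities("lumen_opaque")
  expect_true(all(ph$image$data %in% lv))
})

test_that("phantom generation is deterministic and geometry is noise-stable", {
  a <- small_phantom("four_material", length = 2, baseline = 4, amplitude = 1, seed = 7)
  b <- small_phantom("four_material", length = 2, baseline = 4, amplitude = 1, seed = 7)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$labels$labels, b$truth$labels$labels)
  # adding noise must not move the geometry (truth labels unchanged)
  c <- small_phantom("four_material", length = 2, baseline = 4, amplitude = 1,
                     seed = 7, noise_sigma = 5)
  expect_identical(c$truth$labels$labels, a$truth$labels$labels)
  expect_false(identical(c$image$data, a$image$data))
})

test_that("raising the thrombus baseline strictly shrinks the true lumen", {
  vols <- vapply(c(0, 2, 5, 9), function(b) {
    small_phantom("four_material", length = 2, baseline = b)$truth$true_lumen_volume
  }, numeric(1))
  expect_true(all(diff(vols) < 0))
})

test_that("per-slice truth conservation holds at the acceptance bound", {
  # lumen + thrombus areas tile the wall interior; against the analytic
  # cylinder cross-section the binary voxelization residual stays within
  # 2 voxel-areas for the default 4 mm ID construction
  ph <- small_phantom("four_material", length = 4, baseline = 6.49, amplitude = 1.19)
  cal <- caliper_record(4, 5, 4)
  cr <- conservation_residuals(ph$truth$area_profiles$lumen,
                               ph$truth$area_profiles$thrombus, cal)
  vox_area <- ph$truth$spec$spacing^2
  expect_lte(cr$max_abs, 2 * vox_area)
  # fully occupied: with a full-capacity thrombus the lumen area is zero
  full <- small_phantom("four_material", length = 2, baseline = pi * 4 - 1e-9)
  expect_identical(sum(full$truth$labels$labels == 1L), 0L)
})

test_that("supersampling refines the partial-volume rendering", {
  # what supersampling refines is the occupancy estimate: the slice intensity
  # integral converges to the analytic area-weighted mixture of levels
  # (averaged over several diameters; the binary label count instead converges
  # to the exact coverage-threshold count, which retains lattice quantization)
  integral_err <- function(ss) {
    errs <- vapply(c(4, 4.4, 4.8), function(id) {
      spec <- phantom_spec(inner_diameter = id, outer_diameter = id + 1,
                           length = 2, supersample = ss)
      ph <- generate_phantom(spec)
      lv <- spec$intensities
      r_in <- id / 2; r_out <- id / 2 + 0.5
      analytic <- (pi * r_in^2 * (lv[["lumen"]] - lv[["background"]]) +
                   pi * (r_out^2 - r_in^2) * (lv[["wall"]] - lv[["background"]])) /
        spec$spacing^2
      sl <- ph$image$data[ph$truth$span[1] + 3, , ]
      abs(sum(sl - lv[["background"]]) - analytic)
    }, numeric(1))
    mean(errs)
  }
  errs <- vapply(c(1L, 4L, 8L), integral_err, numeric(1))
  expect_lte(errs[2], errs[1])
  expect_lte(errs[3], errs[2])
  # and the ss = 8 label count stays within 2% of the analytic cylinder
  ph <- small_phantom("lumen_opaque", length = 2)
  analytic_vol <- pi * 4 * 2
  expect_lt(abs(ph$truth$true_lumen_volume - analytic_vol) / analytic_vol, 0.02)
})

test_that("truth_summary recomputes the stored truth exactly", {
  ph <- small_phantom("four_material", length = 3, baseline = 5, amplitude = 0)
  ts <- truth_summary(ph$truth)
  expect_identical(ts$lumen$volume, ph$truth$true_lumen_volume)
  expect_identical(ts$thrombus$volume, ph$truth$true_thrombus_volume)
  vox_area <- ph$truth$spec$spacing^2
  # constant-profile deposit: per-slice truth area SD within one voxel-area
  expect_lte(ts$thrombus$area_sd, vox_area)
  expect_lt(abs(ts$lumen$length - 3), ph$truth$spec$spacing + 1e-12)
})

test_that("phantom specs round trip through YAML and JSON", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec(contrast_mode = "four_material", length = 7,
                       thrombus = list(baseline = 2, amplitude = 1, period = 5,
                                       eccentricity = 0.3),
                       noise_sigma = 4, rng_seed = 42)
  for (f in c("s.yaml", "s.json")) {
    p <- file.path(dir, f)
    write_phantom_spec(spec, p)
    back <- read_phantom_spec(p)
    expect_equal(back[setdiff(names(back), "intensities")],
                 spec[setdiff(names(spec), "intensities")])
    expect_equal(unname(back$intensities), unname(spec$intensities))
  }
})
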