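make_labels <- function(dim = c(6, 8, 8), spacing = rep(0.1171875, 3)) {
  label_volume(array(0L, dim), spacing)
}

test_that("area per slice is voxel count times pixel area", {
  lv <- make_labels()
  lv$labels[3, 4, 4] <- 1L
  prof <- area_per_slice(lv, "lumen")
  expect_equal(prof$areas[3], 0.1171875^2, tolerance = 1e-15)
  expect_equal(prof$areas[3], 0.013732910156, tolerance = 1e-9) # printed precision
  expect_true(all(prof$areas[-3] == 0))
  expect_true(all(area_per_slice(lv, "thrombus")$areas == 0))
  expect_error(area_per_slice(lv, "fibrin"), "unknown material")
})

test_that("interior slices of a 4 mm phantom lumen are near the analytic disk", {
  ph <- small_phantom("lumen_opaque", length = 3)
  prof <- ph$truth$area_profiles$lumen
  span <- ph$truth$span
  inner <- prof$areas[(span[1] + 1):(span[2] - 1)]
  expect_true(all(abs(inner - pi * 4) / (pi * 4) < 0.03))
})

test_that("volume equals the slice-area sum times dz exactly", {
  set.seed(5)
  for (i in 1:20) {
    lv <- make_labels(c(4, 6, 6), spacing = runif(3, 0.05, 0.4))
    lv$labels[] <- sample(0:2, length(lv$labels), replace = TRUE)
    for (m in c("lumen", "thrombus")) {
      prof <- area_per_slice(lv, m)
      expect_identical(volume_of(lv, m), sum(prof$areas) * lv$spacing[1])
    }
  }
  lv <- make_labels(c(10, 10, 10))
  lv$labels[1:10, 1:10, 1:10] <- 1L # 1000 voxels at 117.1875 um isotropic
  expect_equal(volume_of(lv, "lumen"), 1000 * 0.1171875^3)
  expect_equal(volume_of(lv, "lumen"), 1.6093254089, tolerance = 1e-9)
})

test_that("length uses the slice-numbering span and counts interior gaps", {
  lv <- make_labels(c(300, 4, 4))
  lv$labels[11:266, 2, 2] <- 1L
  expect_equal(length_of(lv, "lumen"), 256 * 0.1171875) # 30 mm
  lv2 <- make_labels(c(40, 4, 4), spacing = c(0.5, 1, 1))
  lv2$labels[7, 2, 2] <- 1L
  expect_equal(length_of(lv2, "lumen"), 0.5) # single slice -> dz
  lv2$labels[c(1:10, 21:30), 3, 3] <- 2L # gap inside the span
  expect_equal(length_of(lv2, "thrombus"), 30 * 0.5)
  expect_error(length_of(lv2, "wall"), "occupies no slice")
})

test_that("average area is volume over length", {
  expect_equal(average_area(376.99, 30), 12.566, tolerance = 1e-4)
  expect_equal(average_area(0, 30), 0) # fully occluded graft
  expect_error(average_area(10, 0), "length")
})

test_that("cylindrical subtraction lumen honours the caliper capacity", {
  cal <- caliper_record(30, 5, 4)
  expect_equal(lumen_from_subtraction(cal, 30, 0), pi * 4 * 30)
  expect_equal(lumen_from_subtraction(cal, 30, 90), pi * 4 * 30 - 90)
  expect_equal(lumen_from_subtraction(cal, 30, 90), 286.9911, tolerance = 1e-6)
  expect_error(lumen_from_subtraction(cal, 30, 400), "exceeds")
  expect_error(lumen_from_subtraction(cal, 30, -1), ">= 0")
  expect_error(caliper_record(30, 4, 5), "inner diameter")
})

test_that("profile statistics use the sample SD over the occupied span", {
  p <- slice_profile("thrombus", c(0, 0, 2, 2, 2, 0), 0.1)
  st <- profile_stats(p)
  expect_equal(unname(st), c(2, 0))
  p2 <- slice_profile("thrombus", c(1, 3), 0.1)
  expect_equal(unname(profile_stats(p2)), c(2, sqrt(2)))
  expect_error(profile_stats(slice_profile("x", numeric(0), 0.1)), "empty")
  expect_error(profile_stats(slice_profile("x", c(0, 0), 0.1)), "occupied")
})

test_that("sinusoidal deposit SD approaches amplitude over sqrt(2)", {
  amp <- 1.5
  spec <- phantom_spec(length = 36, thrombus = list(baseline = 5, amplitude = amp,
                                                    period = 9))
  prof <- thrombus_area_profile(spec)
  st <- profile_stats(prof)
  expect_lt(abs(st["sd"] - amp / sqrt(2)) / (amp / sqrt(2)), 0.10)
})

test_that("conservation residuals compare against the caliper cylinder", {
  cal <- caliper_record(10, 5, 4)
  expected <- pi * 4
  lum <- slice_profile("lumen", c(0, 8, 9, 0), 0.1)
  thr <- slice_profile("thrombus", c(0, expected - 8, expected - 9 + 0.2, 0), 0.1)
  cr <- conservation_residuals(lum, thr, cal)
  expect_equal(cr$slices, 2:3)
  expect_equal(cr$residuals, c(0, 0.2), tolerance = 1e-12)
  expect_equal(cr$max_abs, 0.2, tolerance = 1e-12)
  bad <- slice_profile("thrombus", c(0, 1), 0.1)
  expect_error(conservation_residuals(lum, bad, cal), "aligned")
  # zero-thrombus truth: residual is only the partial-volume quantization
  ph <- small_phantom("four_material", length = 2)
  cr0 <- conservation_residuals(ph$truth$area_profiles$lumen,
                                ph$truth$area_profiles$thrombus,
                                caliper_record(2, 5, 4))
  expect_lt(cr0$max_abs, 2 * ph$truth$spec$spacing^2)
})

test_that("graft_metrics ties the pieces together consistently", {
  ph <- small_phantom("four_material", length = 3, baseline = 5)
  gm <- graft_metrics(ph$truth$labels, "thrombus")
  expect_equal(gm$average_area, gm$volume / gm$length, tolerance = 1e-12)
  expect_identical(gm$volume, ph$truth$true_thrombus_volume)
})
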