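test_that("masking wand equals the brute-force flood-fill oracle", {
  set.seed(101)
  for (i in 1:50) {
    img <- random_test_image(32)
    seed <- sample(32, 2, replace = TRUE)
    lo <- sample(0:3, 1); hi <- sample(lo:4, 1)
    got <- masking_wand(img, 1, seed, intensity_range(lo, hi))
    want <- naive_flood_fill(img$data[1, , ], seed, lo, hi)
    expect_identical(got, want)
  }
})

test_that("wand handles uniform, disjoint and out-of-range cases", {
  img <- voxel_image(array(5, c(1, 8, 8)), rep(1, 3))
  expect_true(all(masking_wand(img, 1, c(3, 3), intensity_range(0, 10))))
  # two disjoint in-range blobs: only the seeded one is selected
  sl <- matrix(0, 9, 9)
  sl[2:3, 2:3] <- 7; sl[7:8, 7:8] <- 7
  img2 <- voxel_image(array(sl, c(1, 9, 9)), rep(1, 3))
  m <- masking_wand(img2, 1, c(2, 2), intensity_range(6, 8))
  expect_identical(sum(m), 4L)
  expect_true(all(which(m, arr.ind = TRUE)[, 1] <= 3))
  # seed outside the range -> empty mask
  expect_false(any(masking_wand(img2, 1, c(5, 5), intensity_range(6, 8))))
  expect_error(masking_wand(img2, 1, c(0, 5), intensity_range(6, 8)), "bounds")
  expect_error(masking_wand(img2, 2, c(5, 5), intensity_range(6, 8)), "bounds")
})

test_that("widening the wand range never shrinks the mask", {
  set.seed(33)
  for (i in 1:20) {
    img <- random_test_image(24)
    seed <- sample(24, 2, replace = TRUE)
    narrow <- masking_wand(img, 1, seed, intensity_range(2, 3))
    wide <- masking_wand(img, 1, seed, intensity_range(1, 4))
    expect_true(all(wide[narrow]))
  }
})

test_that("border layer annexes exactly the in-band adjacent ring", {
  # disk of bright pixels surrounded by a one-pixel medium-gray ring
  n <- 15
  d2 <- outer((1:n - 8)^2, (1:n - 8)^2, "+")
  sl <- matrix(10, n, n)
  sl[d2 <= 9] <- 200
  ring <- d2 > 9 & d2 <= 16
  sl[ring] <- 120
  img <- voxel_image(array(sl, c(1, n, n)), rep(1, 3))
  core <- masking_wand(img, 1, c(8, 8), intensity_range(150, 255))
  grown <- include_border_layer(core, sl, intensity_range(100, 140), 1)
  # grows by exactly the ring pixels adjacent to the core
  added <- grown & !core
  expect_true(all(sl[added] == 120))
  adjacent_ring <- ring & graftCT:::.dilate4(core)
  expect_identical(added, adjacent_ring)
  # identity and stability
  expect_identical(include_border_layer(core, sl, intensity_range(100, 140), 0), core)
  expect_identical(include_border_layer(core, sl, intensity_range(300, 400), 3), core)
  # monotone: result is a superset; idempotent once the band is exhausted
  g2 <- include_border_layer(grown, sl, intensity_range(100, 140), 5)
  expect_true(all(g2[grown]))
  expect_identical(include_border_layer(g2, sl, intensity_range(100, 140), 1), g2)
})

test_that("seed propagation lands inside the region", {
  one <- matrix(FALSE, 5, 5); one[2, 4] <- TRUE
  expect_identical(propagate_seed(one), c(2L, 4L))
  disk <- outer((1:11 - 6)^2, (1:11 - 6)^2, "+") <= 9
  expect_identical(propagate_seed(disk), c(6L, 6L))
  # crescent whose centroid falls outside the region
  d2a <- outer((1:21 - 11)^2, (1:21 - 11)^2, "+")
  d2b <- outer((1:21 - 11)^2, (1:21 - 8)^2, "+")
  crescent <- d2a <= 64 & d2b > 36
  ctr <- colMeans(which(crescent, arr.ind = TRUE))
  expect_false(crescent[round(ctr[1]), round(ctr[2])])
  got <- propagate_seed(crescent)
  expect_identical(got, naive_centroid_seed(crescent))
  expect_true(crescent[got[1], got[2]])
  expect_error(propagate_seed(matrix(FALSE, 3, 3)), "empty")
})

test_that("single-target segmentation recovers the phantom lumen", {
  ph <- small_phantom("lumen_opaque", length = 4, baseline = 3, amplitude = 1)
  mode <- phantom_analysis_mode(ph)
  tg <- mode$targets[[1]]
  seg <- segment_target(ph$image, tg$calibration, tg$seed[2:3], slices = mode$slices)
  truth_n <- sum(ph$truth$labels$labels == 1L)
  expect_lt(abs(sum(seg$mask) - truth_n) / truth_n, 0.05)
  expect_false(any(seg$qc$empty))
})

test_that("an occluded middle slice yields an empty mask without stopping traversal", {
  # baseline at capacity, large amplitude: the profile clips to full occlusion
  # around the sinusoid peak
  cap <- pi * 4
  ph <- small_phantom("four_material", length = 6, baseline = cap * 0.8,
                      amplitude = cap * 0.4, seed = 7) # interior occlusion block
  lumen_areas <- ph$truth$area_profiles$lumen$areas
  span <- ph$truth$span
  occluded <- which(lumen_areas == 0)
  occluded <- occluded[occluded > span[1] & occluded < span[2]]
  expect_gt(length(occluded), 0)
  mode <- phantom_analysis_mode(ph)
  tg <- mode$targets[[1]] # lumen; start where the operator first sees it open
  seg <- segment_target(ph$image, tg$calibration, tg$seed[2:3],
                        slices = tg$seed[1]:span[2])
  per_slice <- rowSums(seg$mask, dims = 1)
  expect_true(all(per_slice[occluded] == 0))
  expect_gt(per_slice[min(occluded) - 1], 0)
  expect_gt(per_slice[max(occluded) + 1], 0)
})

test_that("full-span calibration on a wall-less in-range tube fills each slice", {
  img <- voxel_image(array(50, c(5, 7, 7)), rep(1, 3))
  cal <- segmentation_calibration(intensity_range(0, 255), border_layers = 0L)
  seg <- segment_target(img, cal, c(4, 4))
  expect_true(all(seg$mask))
  # unusable calibration on the first slice is an error
  bad <- segmentation_calibration(intensity_range(300, 400))
  expect_error(segment_target(img, bad, c(4, 4)), "empty mask")
})

test_that("global-threshold method selects every in-range pixel", {
  sl <- matrix(0, 8, 8); sl[2, 2] <- 9; sl[7, 7] <- 9
  img <- voxel_image(array(sl, c(1, 8, 8)), rep(1, 3))
  cal <- segmentation_calibration(intensity_range(8, 10), border_layers = 0L)
  wand <- segment_target(img, cal, c(2, 2), method = "wand")
  thr <- segment_target(img, cal, c(2, 2), method = "threshold")
  expect_identical(sum(wand$mask), 1L)
  expect_identical(sum(thr$mask), 2L)
})

test_that("four-material labeling is a partition matching truth conservation", {
  ph <- small_phantom("four_material", length = 4, baseline = 6.49, amplitude = 1.19)
  seg <- segment_four_material(ph$image, phantom_analysis_mode(ph))
  # partition: every voxel has exactly one label, all labels mapped
  expect_true(all(seg$labels$labels %in% seg$labels$materials))
  # per-slice lumen + thrombus equals the truth interior within 2 voxel-areas
  lum <- area_per_slice(seg$labels, "lumen")$areas
  thr <- area_per_slice(seg$labels, "thrombus")$areas
  tlum <- ph$truth$area_profiles$lumen$areas
  tthr <- ph$truth$area_profiles$thrombus$areas
  span <- ph$truth$span[1]:ph$truth$span[2]
  vox_area <- ph$truth$spec$spacing^2
  expect_lt(max(abs((lum + thr) - (tlum + tthr))[span]), 2 * vox_area)
  expect_length(seg$flagged_slices, 0)
})

test_that("zero-thrombus four-material remainder is at most a partial-volume shell", {
  ph <- small_phantom("four_material", length = 3)
  seg <- segment_four_material(ph$image, phantom_analysis_mode(ph))
  thr <- area_per_slice(seg$labels, "thrombus")$areas
  # one-voxel ring upper bound per slice: circumference / spacing pixels
  h <- ph$truth$spec$spacing
  ring_area <- ceiling(2 * pi * 2 / h) * h^2
  expect_true(all(thr <= ring_area))
})
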