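test_that("threshold segmentation equals the per-pixel oracle on phantoms", {
  for (seed in 1:3) {
    ph <- generate_l3_phantom(runif(1, 50, 250), runif(1, 50, 500),
                              pixel_spacing_mm = 1.5, dim_px = c(256, 256),
                              seed = seed)
    seg <- segment_muscle(ph$slice)
    expect_identical(seg$mask, window_oracle(ph$slice, -29, 150))
    # mask covers exactly the ground-truth muscle compartment
    expect_identical(seg$mask, ph$truth$labels == "muscle")
    segf <- segment_fat(ph$slice)
    expect_identical(segf$mask, ph$truth$labels == "fat")
  }
})

test_that("SMA is pixel count times pixel area", {
  ph <- generate_l3_phantom(150, 0, pixel_spacing_mm = 1, seed = 1)
  seg <- segment_muscle(ph$slice)
  expect_equal(sum(seg$mask), 15000)
  expect_equal(seg$area_cm2, 150)
  # single fat pixel at 0.5 mm spacing -> 0.0025 cm^2
  hu <- matrix(-1000, 8, 8); hu[4, 4] <- -100
  expect_equal(segment_fat(ct_slice(hu, 0.5))$area_cm2, 0.0025)
})

test_that("an all-air slice yields zero area with a warning", {
  air <- ct_slice(matrix(-1000, 32, 32), 1)
  expect_warning(seg <- segment_muscle(air), "empty")
  expect_equal(seg$area_cm2, 0)
})

test_that("the HU window is closed: boundary values are included", {
  hu <- matrix(-1000, 4, 4)
  hu[1, 1] <- -29; hu[2, 2] <- 150      # exactly on the muscle bounds
  hu[3, 3] <- -30; hu[4, 4] <- 151      # just outside
  seg <- segment_muscle(ct_slice(hu, 1))
  expect_equal(sum(seg$mask), 2)
  expect_true(seg$mask[1, 1] && seg$mask[2, 2])
})

test_that("widening the window never decreases the area", {
  ph <- generate_l3_phantom(120, 250, seed = 5, dim_px = c(256, 256),
                            pixel_spacing_mm = 1.5)
  base <- segment_muscle(ph$slice, window = c(-29, 150))$area_cm2
  for (pad in c(10, 50, 200)) {
    wider <- segment_muscle(ph$slice, window = c(-29 - pad, 150 + pad))$area_cm2
    expect_gte(wider, base)
  }
})

test_that("area scales with the square of pixel spacing", {
  hu <- matrix(-1000, 16, 16); hu[5:10, 5:10] <- 50
  a1 <- segment_muscle(ct_slice(hu, 1))$area_cm2
  a2 <- segment_muscle(ct_slice(hu, 2))$area_cm2
  expect_equal(a2, 4 * a1)
})

test_that("the ROI mask confines segmentation", {
  hu <- matrix(50, 10, 10)  # all pixels in the muscle window
  roi <- matrix(FALSE, 10, 10); roi[1:5, ] <- TRUE
  seg <- segment_muscle(ct_slice(hu, 1, roi = roi))
  expect_true(all(seg$mask[roi] ))
  expect_false(any(seg$mask[!roi]))
  expect_equal(sum(seg$mask), 50)
})

test_that("small-component cleanup removes specks but keeps the main body", {
  hu <- matrix(-1000, 30, 30)
  hu[5:14, 5:14] <- 40   # 100-px block
  hu[25, 25] <- 40       # isolated speck
  hu[20, 3] <- 40; hu[21, 4] <- 40  # 2-px diagonal component (8-connected)
  seg0 <- segment_muscle(ct_slice(hu, 1), min_component_px = 0)
  expect_equal(sum(seg0$mask), 103)
  seg3 <- segment_muscle(ct_slice(hu, 1), min_component_px = 3)
  expect_equal(sum(seg3$mask), 100)
  seg2 <- segment_muscle(ct_slice(hu, 1), min_component_px = 2)
  expect_equal(sum(seg2$mask), 102)  # diagonal pair survives 8-connectivity
})

test_that("ct_slice validates its inputs", {
  expect_error(ct_slice(matrix(numeric(0), 0, 0), 1), "empty")
  expect_error(ct_slice(matrix(-2000, 2, 2), 1), "uncalibrated")
  expect_error(ct_slice(matrix(0, 2, 2), -1), "spacing")
  expect_error(ct_slice(matrix(0, 2, 2), 1, roi = matrix(TRUE, 3, 3)), "roi")
})
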