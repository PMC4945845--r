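test_that("lung fields are recovered from the phantom with high overlap", {
  ph <- small_phantom()
  lung <- segment_lung_fields(ph$volume)
  expect_gte(dice(lung, ph$truth$lung_mask), 0.95)
  # idempotence: same volume, same mask
  lung2 <- segment_lung_fields(ph$volume)
  expect_identical(lung$mask, lung2$mask)
})

test_that("degenerate volumes raise the documented errors", {
  # all soft tissue: nothing below threshold
  v <- ct_volume(array(30, c(12, 12, 12)), 1)
  expect_error(segment_lung_fields(v), "no lung fields")
  # only border-connected air: everything removed as ambient background
  arr <- array(30, c(16, 16, 16))
  arr[1:4, , ] <- -1000
  v <- ct_volume(arr, 1)
  expect_error(segment_lung_fields(v, min_component_voxels = 10),
               "border-connected")
})

test_that("analysis exclusions implement the -1000..0 HU and airway rules", {
  arr <- array(30, c(12, 12, 12))
  arr[3:10, 3:10, 3:10] <- -800
  v <- ct_volume(arr, 1)
  lung <- region_mask(array(arr < -300, dim(arr)), "lung", v$spacing)

  # no exclusions fire: analysis mask equals lung mask
  an <- apply_analysis_exclusions(v, lung)
  expect_identical(an$mask, lung$mask)

  # boundary values are included, strictly-outside values excluded
  v2 <- v
  v2$values[3, 3, 3] <- 0        # inclusive boundary
  v2$values[3, 3, 4] <- -1000    # inclusive boundary
  v2$values[3, 3, 5] <- 10       # excluded
  v2$values[3, 3, 6] <- -1000.5  # excluded
  an2 <- apply_analysis_exclusions(v2, lung)
  expect_true(an2$mask[3, 3, 3])
  expect_true(an2$mask[3, 3, 4])
  expect_false(an2$mask[3, 3, 5])
  expect_false(an2$mask[3, 3, 6])
  expect_equal(unname(attr(an2, "exclusions")["out_of_range"]), 2)

  # airway lumen voxels are excluded exactly
  lum <- region_mask(array(FALSE, dim(arr)), "airway_lumen", v$spacing)
  lum$mask[4:6, 4:6, 4:6] <- TRUE
  an3 <- apply_analysis_exclusions(v, lung, lum)
  expect_equal(sum(an3$mask & lum$mask), 0)
  expect_true(all(an3$mask | !lung$mask | lum$mask))

  # empty result errors
  v3 <- v
  v3$values[lung$mask] <- 20
  expect_error(apply_analysis_exclusions(v3, lung), "empty analysis mask")
})

test_that("analysis mask invariants hold on the phantom", {
  ph <- small_phantom()
  lung <- segment_lung_fields(ph$volume)
  lum <- segment_airway_tree(ph$volume, ph$truth$seed_point)
  an <- apply_analysis_exclusions(ph$volume, lung, lum)
  expect_true(all(lung$mask[an$mask]))                    # analysis within lung
  expect_equal(sum(an$mask & lum$mask), 0)                # no airway voxels
  hu <- ph$volume$values[an$mask]
  expect_true(all(hu >= -1000 & hu <= 0))
  # the lumen voxels inside the lung mask are exactly the truth lumen there
  expect_equal(sum(lung$mask & lum$mask & !ph$truth$airway_lumen_mask$mask), 0)
})
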