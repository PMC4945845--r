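test_that("digital cylinder lumen area and wall thickness are recovered", {
  cp <- build_cylinder_phantom(4, 1.5, spacing = 0.5)
  m <- measure_segment(cp$volume, cp$centerline)
  expect_equal(m$quality_flag, "ok")
  expect_lt(abs(m$mean_lumen_area - pi * 16) / (pi * 16), 0.05)
  expect_lt(abs(m$mean_wall_thickness - 1.5), 0.25)   # half a voxel
})

test_that("measurement is rotation-invariant for an oblique cylinder", {
  ax <- build_cylinder_phantom(4, 1.5, spacing = 0.5, axis = c(0, 0, 1))
  ob <- build_cylinder_phantom(4, 1.5, spacing = 0.5, axis = c(1, 0, 1))
  ma <- measure_segment(ax$volume, ax$centerline)
  mo <- measure_segment(ob$volume, ob$centerline)
  expect_lt(abs(mo$mean_lumen_area - pi * 16) / (pi * 16), 0.05)
  expect_lt(abs(mo$mean_wall_thickness - 1.5), 0.25)
  expect_lt(abs(mo$mean_lumen_area - ma$mean_lumen_area) / (pi * 16), 0.06)
})

test_that("a wall at the voxel resolution limit is flagged unreliable", {
  cp <- build_cylinder_phantom(4, 0.3, spacing = 0.5)
  m <- measure_segment(cp$volume, cp$centerline)
  expect_equal(m$quality_flag, "unreliable")
})

test_that("a straight tube yields one generation-1 segment", {
  cp <- build_cylinder_phantom(5, 1.5, spacing = 0.8, length_mm = 50)
  lum <- region_mask(cp$volume$values < -900, "airway_lumen", cp$volume$spacing)
  tree <- extract_centerline_tree(lum)
  expect_equal(nrow(tree$segments), 1L)
  expect_equal(tree$segments$generation, 1L)
})

test_that("a trifurcation assigns all three children generation 2", {
  # parent tube along z splitting into three children (+x, -x, +y)
  sp <- 1
  shape <- c(60, 60, 60)
  lum <- array(FALSE, shape)
  mk <- function(lum, p0, u, len, r) {
    seg <- data.frame(x0 = p0[1], y0 = p0[2], z0 = p0[3],
                      ux = u[1], uy = u[2], uz = u[3], length_mm = len)
    lungqct:::render_segment(lum, seg, r, rep(sp, 3))
  }
  j <- c(30, 30, 32)
  lum <- mk(lum, c(30, 30, 4), c(0, 0, 1), 28, 4)
  lum <- mk(lum, j, c(1, 0, 0.4) / sqrt(1.16), 20, 3)
  lum <- mk(lum, j, c(-1, 0, 0.4) / sqrt(1.16), 20, 3)
  lum <- mk(lum, j, c(0, 1, 0.4) / sqrt(1.16), 20, 3)
  tree <- extract_centerline_tree(region_mask(lum, "airway_lumen", sp))
  s <- tree$segments
  expect_equal(sum(s$generation == 1), 1L)
  expect_equal(sum(s$generation == 2), 3L)
  expect_equal(max(s$generation), 2L)
})

test_that("generation labels are a BFS depth labelling on the study phantom", {
  ph <- study_phantom()
  tree <- extract_centerline_tree(ph$truth$airway_lumen_mask)
  s <- tree$segments
  expect_equal(nrow(s), 2^6 - 1)
  expect_equal(max(s$generation), 6L)
  root <- s$id[is.na(s$parent_id)]
  expect_length(root, 1L)
  for (i in seq_len(nrow(s))) {
    if (!is.na(s$parent_id[i]))
      expect_equal(s$generation[i],
                   s$generation[s$id == s$parent_id[i]] + 1L)
  }
})

test_that("disconnected lumen masks are rejected", {
  m <- array(FALSE, c(20, 20, 20))
  m[5:8, 5:8, 5:8] <- TRUE
  m[14:17, 14:17, 14:17] <- TRUE
  expect_error(extract_centerline_tree(region_mask(m, "airway_lumen", 1)),
               "disconnected")
})

test_that("region growing requires an air seed and reports leaks", {
  ph <- small_phantom()
  # soft-tissue seed (body wall, +30 HU)
  expect_error(segment_airway_tree(ph$volume, c(5, 28, 40)), "not in air")
  # ambient-air seed floods immediately
  expect_error(segment_airway_tree(ph$volume, c(2, 2, 2)), "unsegmentable")
  # intact phantom: no leak, high overlap
  lum <- segment_airway_tree(ph$volume, ph$truth$seed_point)
  expect_gte(dice(lum, ph$truth$airway_lumen_mask), 0.9)
  expect_false(attr(lum, "grow_info")$leaked)
})

test_that("per-generation summary drops deep generations and flags gaps", {
  ph <- study_phantom()
  tree <- extract_centerline_tree(ph$truth$airway_lumen_mask)
  tree$segments$mean_lumen_area <- pi * 4^2
  tree$segments$mean_wall_thickness <- 1.5
  tree$segments$quality_flag <- "ok"
  s1 <- per_generation_summary(tree, max_generation = 1)
  expect_equal(nrow(s1), 1L)
  s4 <- per_generation_summary(tree, max_generation = 4)
  expect_equal(s4$generation, 1:4)
  expect_false(any(s4$absent))
  expect_equal(s4$n_segments, c(1L, 2L, 4L, 8L))
  # a tree with no generation-2 segments flags the row absent
  t2 <- tree
  keep <- t2$segments$generation == 1
  t2$segments <- t2$segments[keep, ]
  t2$centerlines <- t2$centerlines[keep]
  s <- per_generation_summary(t2, max_generation = 2)
  expect_true(s$absent[2])
})

test_that("subject normalizations follow the stated arithmetic", {
  su <- data.frame(generation = 1, mean_area = 245, mean_wall = 2.5,
                   n_segments = 1, n_flagged = 0, absent = FALSE)
  n <- normalize_to_subject(su, 7)
  expect_equal(n$area_over_tlc, 35)
  expect_equal(n$wall_over_area, 2.5 / 245)
  expect_equal(n$wall_over_radius, 2.5 / sqrt(245 / pi))
  expect_error(normalize_to_subject(su, 0), "positive")
  # doubling wall and area halves wall_over_area, leaves area_over_tlc doubled
  # scaling law: doubling the radius (area x4) while the wall doubles
  # halves wall_over_area; area_over_tlc scales with area at fixed TLC
  su2 <- su; su2$mean_area <- 4 * 245; su2$mean_wall <- 5
  n2 <- normalize_to_subject(su2, 7)
  expect_equal(n2$wall_over_area, n$wall_over_area / 2)
  expect_equal(n2$area_over_tlc, 4 * n$area_over_tlc)
})
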