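test_that("noise-free edema-free parenchyma equals the analytic mixing value", {
  sp <- small_spec(lung_air_fraction = 0.9, noise_sd = 0, evlw_weight = 0,
                   vessel_weight = 0)
  ph <- build_phantom(sp)
  vals <- ph$volume$values[ph$truth$lung_mask$mask]
  expect_true(all(vals == -1000 * 0.9 + 30 * 0.1))   # -897, machine exact
})

test_that("same seed gives a bit-identical phantom, different seed does not", {
  a <- build_phantom(small_spec(seed = 7))
  b <- build_phantom(small_spec(seed = 7))
  c <- build_phantom(small_spec(seed = 8))
  expect_identical(a$volume$values, b$volume$values)
  expect_false(identical(a$volume$values, c$volume$values))
})

test_that("single-generation spec yields a single trachea segment", {
  ph <- build_phantom(small_spec())
  expect_equal(nrow(ph$truth$tree$segments), 1L)
  expect_equal(ph$truth$tree$segments$generation, 1L)
})

test_that("ground-truth masks partition the grid", {
  ph <- small_phantom()
  shape <- dim(ph$volume$values)
  lumen <- ph$truth$airway_lumen_mask$mask
  wall <- ph$truth$airway_wall_mask$mask
  paren <- ph$truth$lung_mask$mask
  body <- ph$volume$values > -1000 & !lumen & !wall & !paren
  # pairwise disjoint
  expect_equal(sum(lumen & wall), 0)
  expect_equal(sum(lumen & paren), 0)
  expect_equal(sum(wall & paren), 0)
  # evlw voxels are parenchyma
  expect_true(all(paren[ph$truth$evlw_voxel_mask$mask]))
})

test_that("skewness decreases and congestion rises with the edema weight", {
  # sample skewness of the parenchymal mixture strictly decreases as
  # evlw_weight rises from 0 to 0.15 (more edema -> lighter-tailed relative
  # to its width); checked per seed over 10 seeds
  for (seed in 1:10) {
    sp0 <- phantom_spec(evlw_weight = 0, seed = seed)
    sp1 <- phantom_spec(evlw_weight = 0.15, seed = seed)
    h0 <- sample_parenchyma_hu(sp0, 40000, seed = seed)$pre
    h1 <- sample_parenchyma_hu(sp1, 40000, seed = seed)$pre
    expect_lt(distribution_moments(h1)$skewness, distribution_moments(h0)$skewness)
    expect_gt(congestion_index(h1), congestion_index(h0))
  }
})

test_that("geometry that cannot fit or resolve raises informative errors", {
  expect_error(build_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                          voxel_spacing = 1)),
               "exceeds the grid")
  expect_error(build_phantom(small_spec(voxel_spacing = 8, root_radius = 7)),
               "unresolvable")
  expect_error(phantom_spec(evlw_weight = 1.5), "\\[0, 1\\]")
  expect_error(phantom_spec(radius_ratio = 0), "\\(0, 1\\]")
})

test_that("bronchodilator with zero effect is the identity", {
  ph <- small_phantom()
  out <- apply_bronchodilator(ph$volume, ph$truth, 0, 0)
  expect_identical(out$volume$values, ph$volume$values)
})

test_that("full clearance matches an edema-free phantom within sampling error", {
  sp <- small_spec(evlw_weight = 0.02, seed = 3)
  ph <- build_phantom(sp)
  post <- apply_bronchodilator(ph$volume, ph$truth, clearance = 1, seed = 4)
  hu_post <- post$volume$values[post$truth$lung_mask$mask]
  sp0 <- small_spec(evlw_weight = 0, seed = 5)
  ph0 <- build_phantom(sp0)
  hu0 <- ph0$volume$values[ph0$truth$lung_mask$mask]
  expect_equal(sum(post$truth$evlw_voxel_mask$mask), 0)
  expect_equal(congestion_index(hu_post), congestion_index(hu0), tolerance = 0.15)
  expect_equal(mean(hu_post), mean(hu0), tolerance = 0.005)
})

test_that("clearance shifts the histogram left and sharpens it (sign suite)", {
  # sign pattern after strong clearance: skew up, kurtosis up, FWHM down,
  # %>-500 down, mean HU more negative; checked per seed over 10 seeds
  for (seed in 1:10) {
    sp <- phantom_spec(evlw_weight = 0.018, seed = seed)
    hu <- sample_parenchyma_hu(sp, 50000, clearance = 0.9, seed = seed)
    pre <- density_metrics_from_values(hu$pre)
    post <- density_metrics_from_values(hu$post)
    expect_gt(post$skewness, pre$skewness)
    expect_gt(post$kurtosis, pre$kurtosis)
    expect_lt(post$fwhm, pre$fwhm)
    expect_lt(post$pct_gt_m500, pre$pct_gt_m500)
    expect_lt(post$mean_hu, pre$mean_hu)
  }
})

test_that("wall thinning reduces wall voxels but leaves the lumen untouched", {
  ph <- study_phantom()
  post <- apply_bronchodilator(ph$volume, ph$truth, clearance = 0,
                               wall_thinning = 0.25, seed = 2)
  expect_lt(sum(post$truth$airway_wall_mask$mask),
            sum(ph$truth$airway_wall_mask$mask))
  # lumen voxels are bit-identical
  lum <- ph$truth$airway_lumen_mask$mask
  expect_identical(post$volume$values[lum], ph$volume$values[lum])
  expect_equal(attr(post$truth$tree, "geometry")$wall_mm,
               attr(ph$truth$tree, "geometry")$wall_mm * 0.75)
})
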