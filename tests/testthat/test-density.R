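test_that("moments match symmetry, frozen brute-force values and analytic limits", {
  # symmetric sample
  expect_equal(distribution_moments(c(-1, 0, 1))$skewness, 0)

  # frozen values computed independently by direct evaluation of the
  # central-moment formulas for {-900, -850, -800, -200}
  m <- distribution_moments(c(-900, -850, -800, -200))
  expect_equal(m$mean_hu, -687.5)
  expect_equal(m$skewness, 1.10120380499, tolerance = 1e-10)
  expect_equal(m$kurtosis, -0.70752757093, tolerance = 1e-9)
  expect_equal(distribution_moments(c(-900, -850, -800, -200), excess = FALSE)$kurtosis,
               -0.70752757093 + 3, tolerance = 1e-9)

  # exponential analytic limits: skew -> 2, excess kurtosis -> 6
  set.seed(11)
  x <- rexp(1e6)
  m <- distribution_moments(x)
  se_s <- block_se(x, function(b) distribution_moments(b)$skewness)
  se_k <- block_se(x, function(b) distribution_moments(b)$kurtosis)
  expect_lt(abs(m$skewness - 2), 3 * se_s)
  expect_lt(abs(m$kurtosis - 6), 3 * se_k)

  expect_error(distribution_moments(c(1, 1, 1)), "zero variance")
  expect_error(distribution_moments(c(1, 2)), "at least 3")
})

test_that("moments agree with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(3)
  x <- rnorm(5000, -800, 60) + rexp(5000, 1 / 40)
  m <- distribution_moments(x)
  expect_equal(m$skewness, e1071::skewness(x, type = 1), tolerance = 1e-12)
  expect_equal(m$kurtosis, e1071::kurtosis(x, type = 1), tolerance = 1e-12)
})

test_that("FWHM recovers the Gaussian closed form and degenerate conventions", {
  set.seed(21)
  x <- rnorm(1e6, -827, 50)
  expect_equal(fwhm(density_histogram(x, 1)), 2 * sqrt(2 * log(2)) * 50,
               tolerance = 0.02)

  # single occupied bin -> one bin width
  h1 <- density_histogram(rep(-500.5, 100), 1)
  expect_equal(fwhm(h1), 1)

  # flat-top histogram over width W -> W
  hu <- rep(seq(-700.5, -601.5, by = 1), each = 50)
  expect_equal(fwhm(density_histogram(hu, 1)), 100, tolerance = 0.01)
})

test_that("congestion index uses a strict threshold", {
  expect_equal(congestion_index(c(-600, -400)), 50)
  expect_equal(congestion_index(rep(-800, 10)), 0)
  expect_equal(congestion_index(c(-500, -499)), 50)  # -500 itself excluded
  # monotone non-increasing in the threshold
  set.seed(5)
  x <- rnorm(2000, -700, 150)
  thr <- seq(-900, -300, by = 50)
  ci <- vapply(thr, function(t) congestion_index(x, t), numeric(1))
  expect_true(all(diff(ci) <= 0))
})

test_that("air/tissue partition is exact and conserves volume", {
  expect_equal(voxel_air_fraction(-1000), 1)
  expect_equal(voxel_air_fraction(55), 0)
  expect_equal(voxel_air_fraction(-472.5), 0.5)
  # clamping
  expect_equal(voxel_air_fraction(-1100), 1)
  expect_equal(voxel_air_fraction(500), 0)

  hu <- runif(1000, -1100, 100)
  expect_true(all(voxel_air_fraction(hu) + (1 - voxel_air_fraction(hu)) == 1))

  # uniform volumes
  mk <- function(hu, n_side, sp) {
    v <- ct_volume(array(hu, rep(n_side, 3)), sp)
    m <- region_mask(array(TRUE, rep(n_side, 3)), "analysis", v$spacing)
    lung_air_tissue_volumes(v, m)
  }
  # 20^3 voxels at 8.55 mm ~ 5 L of pure air
  sp <- (5e6 / 8000)^(1 / 3)
  r <- mk(-1000, 20, sp)
  expect_equal(r$v_air, 5, tolerance = 1e-9)
  expect_equal(r$v_tis, 0, tolerance = 1e-9)
  r <- mk(-472.5, 20, (4e6 / 8000)^(1 / 3))
  expect_equal(r$v_air, 2, tolerance = 1e-9)
  expect_equal(r$v_tis, 2, tolerance = 1e-9)
  expect_equal(r$v_air + r$v_tis, r$masked_volume, tolerance = 1e-9)
})

test_that("phantom air/tissue volumes match the ground-truth fraction map", {
  ph <- small_phantom()
  lung <- segment_lung_fields(ph$volume)
  lum <- segment_airway_tree(ph$volume, ph$truth$seed_point)
  an <- apply_analysis_exclusions(ph$volume, lung, lum)
  vols <- lung_air_tissue_volumes(ph$volume, an)
  truth_air <- sum(ph$truth$true_air_fraction_map[an$mask]) *
    voxel_volume_ml(ph$volume) / 1000
  expect_equal(vols$v_air, truth_air, tolerance = 0.02)
  expect_equal(vols$v_air + vols$v_tis, vols$masked_volume, tolerance = 1e-9)
})

test_that("density metrics are invariant under voxel permutation", {
  ph <- small_phantom()
  lung <- segment_lung_fields(ph$volume)
  m1 <- compute_density_metrics(ph$volume, lung)
  # permute the voxels inside the mask
  v2 <- ph$volume
  idx <- which(lung$mask)
  set.seed(1)
  v2$values[idx] <- v2$values[sample(idx)]
  m2 <- compute_density_metrics(v2, lung)
  for (f in c("mean_hu", "skewness", "kurtosis", "fwhm", "pct_gt_m500",
              "v_air", "v_tis"))
    expect_equal(m1[[f]], m2[[f]], tolerance = 1e-12)
})

test_that("percent change follows the magnitude convention for mean HU", {
  mk <- function(mean_hu, pct) {
    structure(list(mean_hu = mean_hu, skewness = 2, kurtosis = 10, fwhm = 100,
                   pct_gt_m500 = pct, v_air = 4, v_tis = 1, n_voxels = 10),
              class = "density_metrics")
  }
  pre <- mk(-800, 2); post <- mk(-870, 0.12)
  pc <- percent_change(pre, post)
  expect_equal(unname(pc["mean_hu"]), 8.75)          # leftward shift positive
  expect_equal(unname(pc["pct_gt_m500"]), -94)
  expect_true(all(percent_change(pre, pre) == 0))
  pc_signed <- percent_change(pre, post, mean_convention = "signed")
  expect_equal(unname(pc_signed["mean_hu"]), 100 * (-870 + 800) / 800)
})
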