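test_that("Welch t agrees between raw samples, summaries and stats::t.test", {
  set.seed(4)
  x <- rnorm(23, 10, 2); y <- rnorm(29, 11, 3)
  a <- independent_t(x, y)
  b <- independent_t(mean_x = mean(x), sd_x = sd(x), n_x = length(x),
                     mean_y = mean(y), sd_y = sd(y), n_y = length(y))
  expect_equal(a$t, b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  tt <- t.test(x, y)
  expect_equal(a$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(a$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(a$p, tt$p.value, tolerance = 1e-12)

  # identical samples: t = 0, p = 1
  z <- rnorm(10)
  id <- independent_t(z, z)
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
  expect_error(independent_t(1, c(1, 2)), "at least 2")
})

test_that("published summary statistics reproduce the group significance", {
  # body weight: 77.4 +/- 14.4 (n=29) vs 91.4 +/- 17.7 (n=31)
  w <- independent_t(mean_x = 77.4, sd_x = 14.4, n_x = 29,
                     mean_y = 91.4, sd_y = 17.7, n_y = 31)
  expect_equal(abs(w$t), 3.37, tolerance = 0.005)
  expect_lt(w$p, 0.01)
  # histogram skewness: 2.86 +/- 1.07 vs 2.11 +/- 0.79
  s <- independent_t(mean_x = 2.86, sd_x = 1.07, n_x = 29,
                     mean_y = 2.11, sd_y = 0.79, n_y = 31)
  expect_equal(abs(s$t), 3.07, tolerance = 0.005)
  expect_lt(s$p, 0.01)
})

test_that("paired t handles degenerate differences and matches stats::t.test", {
  set.seed(8)
  pre <- rnorm(15); post <- pre + rnorm(15, 0.3)
  a <- paired_t(pre, post)
  tt <- t.test(post, pre, paired = TRUE)
  expect_equal(a$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(a$p, tt$p.value, tolerance = 1e-12)

  same <- paired_t(pre, pre)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shift <- paired_t(pre, pre + 2)
  expect_equal(shift$t, Inf)
  expect_equal(shift$p, 0)
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("Bonferroni adjustment is min(1, p*m) with monotone flags", {
  a <- bonferroni_adjust(0.01, m = 6)
  expect_equal(a$adjusted, 0.06)
  expect_false(a$significant)
  b <- bonferroni_adjust(0.001, m = 6)
  expect_equal(b$adjusted, 0.006)
  expect_true(b$significant)
  expect_equal(bonferroni_adjust(c(0.2, 0.9), m = 1)$adjusted, c(0.2, 0.9))
  p0 <- runif(20)
  expect_true(all(bonferroni_adjust(p0)$adjusted >= p0))  # adjusted >= raw
  # lowering alpha never adds a significant result
  p <- runif(50)
  s1 <- bonferroni_adjust(p, alpha = 0.05)$significant
  s2 <- bonferroni_adjust(p, alpha = 0.01)$significant
  expect_true(all(!s2 | s1))
})

test_that("correlate recovers exact linear relations and rejects degeneracy", {
  x <- 1:10
  cc <- correlate(x, 2 * x)
  expect_equal(cc$r, 1)
  expect_equal(cc$slope, 2)
  expect_equal(cc$intercept, 0, tolerance = 1e-12)
  expect_error(correlate(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(correlate(1:2, 1:2), "at least 3")
})

test_that("a degenerate copula (rho = 1) gives sample r of exactly 1", {
  tc <- data.frame(group = "hf", variable = "fev1_pct", generation = 2, rho = 1)
  cs <- cohort_spec(n_per_group = c(control = 5, hf = 20),
                    target_correlations = tc, spiro_cor = 0, gen_cor = 0,
                    seed = 2)
  # radius noise is linear in the latent, spirometry too; but area = pi r^2
  # is monotone, so test on the latent-linear radius scale
  co <- sample_cohort(cs)
  h <- co$subjects[co$subjects$group == "hf", ]
  r <- cor(sqrt(h$area_g2), h$fev1_pct)
  expect_equal(r, 1, tolerance = 1e-10)
})

test_that("copula cohorts achieve the target correlation in expectation", {
  tc <- expand.grid(variable = c("fvc_pct", "fev1_pct", "fef2575_pct",
                                 "pef_pct"),
                    generation = 1:6, stringsAsFactors = FALSE)
  tc$group <- "hf"
  tc$rho <- 0.6
  rs <- vapply(1:60, function(k) {
    cs <- cohort_spec(n_per_group = c(control = 2, hf = 31),
                      target_correlations = tc, seed = 1000 + k)
    h <- sample_cohort(cs)$subjects
    h <- h[h$group == "hf", ]
    cor(h$area_g2, h$fev1_pct)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.05)
})

test_that("infeasible correlation targets raise an error", {
  tc <- data.frame(group = rep("hf", 2),
                   variable = c("fev1_pct", "fvc_pct"),
                   generation = c(2, 2), rho = c(0.99, -0.99))
  cs <- cohort_spec(target_correlations = tc, spiro_cor = 0.9, seed = 1)
  expect_error(sample_cohort(cs), "not positive definite")
})

test_that("study tables carry the group and bronchodilator structure", {
  co <- sample_cohort(cohort_spec(n_per_group = c(control = 15, hf = 15),
                                  seed = 31))
  recs <- simulate_cohort_records(co, n_voxels = 20000)
  tb <- build_study_tables(recs)
  expect_named(tb, c("table1", "table2", "table3", "table4"))
  # spirometry lower in HF
  t1 <- tb$table1
  expect_true(all(t1$hf_mean[t1$variable != "tlc"] <
                    t1$control_mean[t1$variable != "tlc"]))
  # baseline: HF lower skew/kurt, higher fwhm and congestion
  t2 <- tb$table2
  get <- function(v, col) t2[t2$variable == v, col]
  expect_lt(get("skewness", "hf_mean"), get("skewness", "control_mean"))
  expect_lt(get("kurtosis", "hf_mean"), get("kurtosis", "control_mean"))
  expect_gt(get("fwhm", "hf_mean"), get("fwhm", "control_mean"))
  expect_gt(get("pct_gt_m500", "hf_mean"), get("pct_gt_m500", "control_mean"))
  # change signs: mean +, skew +, kurtosis +, fwhm -, %>-500 -
  for (g in c("control_change_mean", "hf_change_mean")) {
    expect_gt(get("mean_hu", g), 0)
    expect_gt(get("skewness", g), 0)
    expect_gt(get("kurtosis", g), 0)
    expect_lt(get("fwhm", g), 0)
    expect_lt(get("pct_gt_m500", g), 0)
  }
  # baseline-vs-change correlations: mean +, all others negative
  t4 <- tb$table4
  expect_true(all(t4$r[t4$variable == "mean_hu"] > 0))
  expect_true(all(t4$r[t4$variable != "mean_hu"] < 0))
  # bookkeeping: every subject appears in the flat table twice (pre+post)
  st <- do.call(rbind, lapply(recs, lungqct:::subject_record_row))
  expect_equal(nrow(st), 2 * length(recs))
})

test_that("identical groups produce no systematic significance", {
  g <- lungqct:::default_group_params()
  rej <- vapply(1:200, function(k) {
    cs <- cohort_spec(n_per_group = c(control = 29, hf = 31),
                      groups = list(control = g$control, hf = g$control),
                      seed = 5000 + k)
    s <- sample_cohort(cs)$subjects
    independent_t(s$evlw_weight[s$group == "control"],
                  s$evlw_weight[s$group == "hf"])$p < 0.05
  }, logical(1))
  # 95% binomial band around 5% for 200 replicates
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
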