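#' One subject's analysis record
#'
#' The unit of cohort statistics: group label, TLC, spirometry, pre and
#' (optionally) post-bronchodilator density metrics and per-generation
#' airway tables.
#'
#' @param subject_id identifier.
#' @param group `"control"` or `"hf"`.
#' @param tlc total lung capacity, L.
#' @param spirometry named list with `fvc_pct`, `fev1_pct`, `fef2575_pct`,
#'   `pef_pct` (% predicted).
#' @param pre,post [compute_density_metrics()] results (`post` may be
#'   `NULL` when no post scan exists).
#' @param pre_airways,post_airways normalized [per_generation_summary()]
#'   data frames.
#' @param flags character vector of stage warnings/errors.
#' @export
subject_record <- function(subject_id, group, tlc, spirometry,
                           pre, post = NULL,
                           pre_airways = NULL, post_airways = NULL,
                           flags = character()) {
  group <- match.arg(group, c("control", "hf"))
  structure(list(subject_id = subject_id, group = group, tlc = tlc,
                 spirometry = spirometry, pre = pre, post = post,
                 pre_airways = pre_airways, post_airways = post_airways,
                 flags = flags),
            class = "subject_record")
}

comparison_result <- function(variable, mean_x, sd_x, n_x, mean_y, sd_y, n_y,
                              t, df, p, test) {
  structure(list(variable = variable,
                 mean_x = mean_x, sd_x = sd_x, n_x = n_x,
                 mean_y = mean_y, sd_y = sd_y, n_y = n_y,
                 t = t, df = df, p = p, p_adjusted = NA_real_, test = test),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s t-test>%s %.2f+/-%.2f (n=%d) vs %.2f+/-%.2f (n=%d): t=%.3f, df=%.1f, p=%.3g\n",
              x$test, if (is.null(x$variable)) "" else paste0(" ", x$variable),
              x$mean_x, x$sd_x, x$n_x, x$mean_y, x$sd_y, x$n_y, x$t, x$df, x$p))
  invisible(x)
}

#' Welch two-sample t-test (raw samples or summary statistics)
#'
#' Unequal-variance (Welch) two-sample t-test with the Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value.  The same closed form is
#' used for raw samples and for the summary form `(mean, sd, n)` per group,
#' so printed cohort tables can be re-tested without subject-level data.
#'
#' @param x,y raw numeric samples (each n >= 2), or `NULL` when the
#'   summary form is used.
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y group summary statistics.
#' @param variable optional label.
#' @return a `comparison_result` (`t` is for `x - y`).
#' @examples
#' independent_t(mean_x = 77.4, sd_x = 14.4, n_x = 29,
#'               mean_y = 91.4, sd_y = 17.7, n_y = 31)
#' @export
independent_t <- function(x = NULL, y = NULL,
                          mean_x = NULL, sd_x = NULL, n_x = NULL,
                          mean_y = NULL, sd_y = NULL, n_y = NULL,
                          variable = NULL) {
  if (!is.null(x) || !is.null(y)) {
    if (length(x) < 2 || length(y) < 2)
      stopf("need at least 2 observations per group")
    mean_x <- mean(x); sd_x <- sd(x); n_x <- length(x)
    mean_y <- mean(y); sd_y <- sd(y); n_y <- length(y)
  }
  if (n_x < 2 || n_y < 2) stopf("need at least 2 observations per group")
  if (!is.finite(sd_x) || !is.finite(sd_y) || (sd_x == 0 && sd_y == 0))
    stopf("degenerate samples: zero variance in both groups")
  vx <- sd_x^2 / n_x
  vy <- sd_y^2 / n_y
  se2 <- vx + vy
  t <- (mean_x - mean_y) / sqrt(se2)
  df <- se2^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
  p <- 2 * pt(-abs(t), df)
  comparison_result(variable, mean_x, sd_x, n_x, mean_y, sd_y, n_y,
                    t, df, p, "independent")
}

#' Paired t-test of pre versus post measurements
#'
#' One-sample t-test on the per-subject differences `post - pre`, flagging
#' whether the change differs from zero.  A zero-variance difference
#' vector is handled explicitly: all-zero differences give `t = 0, p = 1`;
#' a constant nonzero shift is reported as a degenerate certain change
#' (`p = 0`).
#'
#' @param pre,post numeric vectors of equal length (n >= 2).
#' @param variable optional label.
#' @return a `comparison_result` with `test = "paired"`; `t` is for the
#'   mean difference `post - pre`.
#' @export
paired_t <- function(pre, post, variable = NULL) {
  if (length(pre) != length(post))
    stopf("pre and post must have equal length (%d vs %d)",
          length(pre), length(post))
  n <- length(pre)
  if (n < 2) stopf("need at least 2 pairs")
  d <- post - pre
  sdd <- sd(d)
  md <- mean(d)
  # a numerically constant difference vector is a degenerate certain change
  if (sdd <= 1e-12 * max(abs(d), .Machine$double.eps)) sdd <- 0
  if (sdd == 0) {
    t <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    t <- md / (sdd / sqrt(n))
    p <- 2 * pt(-abs(t), n - 1)
  }
  res <- comparison_result(variable, mean(pre), sd(pre), n,
                           mean(post), sd(post), n, t, n - 1, p, "paired")
  res$mean_difference <- md
  res$sd_difference <- sdd
  res
}

#' Bonferroni correction across generation-level tests
#'
#' `adjusted = min(1, p * m)` with `m` the number of generation-level
#' tests (the study tests generations 1-6, so `m` defaults to 6).
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param alpha significance level for the flags.
#' @param m number of tests corrected for.
#' @return list `adjusted`, `significant`.
#' @export
bonferroni_adjust <- function(p_values, alpha = 0.05, m = 6) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must be in [0, 1]")
  if (m < 1) stopf("`m` must be >= 1")
  adjusted <- pmin(1, p_values * m)
  list(adjusted = adjusted, significant = !is.na(adjusted) & adjusted < alpha)
}

#' Pearson correlation with least-squares line
#'
#' Pearson correlation coefficient with two-sided p-value plus the
#' ordinary least-squares regression of `y` on `x`.
#'
#' @param x,y numeric vectors, n >= 3, both with positive variance.
#' @return list `r`, `p`, `slope`, `intercept`, `n`.
#' @export
correlate <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stopf("need at least 3 complete pairs, got %d", n)
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm.fit(cbind(1, x), y)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), n = n)
}

metric_fields <- c("mean_hu", "skewness", "kurtosis", "fwhm", "pct_gt_m500",
                   "v_air", "v_tis")

rec_field <- function(records, f) vapply(records, function(r) r[[f]], numeric(1))
rec_metric <- function(records, time, f)
  vapply(records, function(r) {
    m <- r[[time]]
    if (is.null(m)) NA_real_ else m[[f]]
  }, numeric(1))
rec_gen <- function(records, time, g, col)
  vapply(records, function(r) {
    a <- r[[paste0(time, "_airways")]]
    if (is.null(a)) return(NA_real_)
    v <- a[[col]][a$generation == g]
    if (length(v) == 0) NA_real_ else v
  }, numeric(1))

#' Build the study's cohort tables
#'
#' Assembles the four study-style outputs from a list of
#' [subject_record()]s:
#' \describe{
#'   \item{table1}{group characteristics (TLC, spirometry): mean, SD per
#'     group, Welch t and p.}
#'   \item{table2}{baseline density metrics per group with Welch tests,
#'     plus mean and SD of the per-subject percent changes after
#'     bronchodilator with the change-from-zero paired test per group.}
#'   \item{table3}{Pearson r between baseline generation-level airway
#'     luminal area and spirometry, per group, with Bonferroni adjustment
#'     across generations.}
#'   \item{table4}{Pearson r between each density index's baseline value
#'     and its percent change after bronchodilator, per group.}
#' }
#' Subjects without a post state contribute to baseline tables only.
#'
#' @param records list of [subject_record()]s (>= 2 per group).
#' @param alpha significance level.
#' @param bonferroni_m number of generation-level tests corrected across.
#' @param max_generation generations included in table3.
#' @return list of data frames `table1`, `table2`, `table3`, `table4`.
#' @export
build_study_tables <- function(records, alpha = 0.05, bonferroni_m = 6,
                               max_generation = 6) {
  groups <- vapply(records, function(r) r$group, character(1))
  for (g in c("control", "hf"))
    if (sum(groups == g) < 2)
      stopf("need at least 2 subjects in group '%s', got %d", g, sum(groups == g))
  ctl <- records[groups == "control"]
  hf <- records[groups == "hf"]

  # --- table 1: characteristics ---------------------------------------
  char_vals <- function(recs, v) {
    if (v == "tlc") rec_field(recs, "tlc")
    else vapply(recs, function(r) as.numeric(r$spirometry[[v]]), numeric(1))
  }
  t1 <- do.call(rbind, lapply(c("tlc", spiro_vars), function(v) {
    xc <- char_vals(ctl, v); xh <- char_vals(hf, v)
    tt <- independent_t(xc, xh, variable = v)
    data.frame(variable = v,
               control_mean = mean(xc), control_sd = sd(xc), control_n = length(xc),
               hf_mean = mean(xh), hf_sd = sd(xh), hf_n = length(xh),
               t = tt$t, p = tt$p, significant = tt$p < alpha)
  }))

  # --- table 2: density metrics, baseline + percent change ------------
  has_post <- function(recs) recs[vapply(recs, function(r) !is.null(r$post), logical(1))]
  pc_of <- function(recs)
    lapply(has_post(recs), function(r) percent_change(r$pre, r$post))
  pc_ctl <- pc_of(ctl); pc_hf <- pc_of(hf)
  t2 <- do.call(rbind, lapply(metric_fields[1:5], function(f) {
    bc <- rec_metric(ctl, "pre", f); bh <- rec_metric(hf, "pre", f)
    tt <- independent_t(bc, bh, variable = f)
    dc <- vapply(pc_ctl, function(p) p[[f]], numeric(1))
    dh <- vapply(pc_hf, function(p) p[[f]], numeric(1))
    zt <- function(d) if (length(d) >= 2) paired_t(rep(0, length(d)), d)$p else NA_real_
    data.frame(variable = f,
               control_mean = mean(bc), control_sd = sd(bc),
               hf_mean = mean(bh), hf_sd = sd(bh),
               p_group = tt$p, sig_group = tt$p < alpha,
               control_change_mean = mean(dc), control_change_sd = sd(dc),
               hf_change_mean = mean(dh), hf_change_sd = sd(dh),
               p_change_control = zt(dc), p_change_hf = zt(dh),
               sig_change_control = !is.na(zt(dc)) && zt(dc) < alpha,
               sig_change_hf = !is.na(zt(dh)) && zt(dh) < alpha)
  }))

  # --- table 3: airway area vs spirometry ----------------------------
  t3 <- do.call(rbind, lapply(c("control", "hf"), function(g) {
    recs <- if (g == "control") ctl else hf
    do.call(rbind, lapply(spiro_vars, function(v) {
      sp <- vapply(recs, function(r) as.numeric(r$spirometry[[v]]), numeric(1))
      rows <- do.call(rbind, lapply(seq_len(max_generation), function(k) {
        ar <- rec_gen(recs, "pre", k, "mean_area")
        ok <- is.finite(ar) & is.finite(sp)
        if (sum(ok) < 3)
          return(data.frame(group = g, variable = v, generation = k,
                            r = NA_real_, p = NA_real_, n = sum(ok)))
        cc <- correlate(ar[ok], sp[ok])
        data.frame(group = g, variable = v, generation = k,
                   r = cc$r, p = cc$p, n = cc$n)
      }))
      adj <- bonferroni_adjust(rows$p, alpha = alpha, m = bonferroni_m)
      rows$p_adjusted <- adj$adjusted
      rows$significant <- adj$significant
      rows
    }))
  }))

  # --- table 4: baseline value vs percent change ----------------------
  t4 <- do.call(rbind, lapply(c("control", "hf"), function(g) {
    recs <- has_post(if (g == "control") ctl else hf)
    do.call(rbind, lapply(metric_fields[1:5], function(f) {
      base <- rec_metric(recs, "pre", f)
      chg <- vapply(recs, function(r) percent_change(r$pre, r$post)[[f]], numeric(1))
      ok <- is.finite(base) & is.finite(chg)
      if (sum(ok) < 3)
        return(data.frame(group = g, variable = f, r = NA_real_, p = NA_real_,
                          n = sum(ok), significant = NA))
      cc <- correlate(base[ok], chg[ok])
      data.frame(group = g, variable = f, r = cc$r, p = cc$p, n = cc$n,
                 significant = cc$p < alpha)
    }))
  }))

  rownames(t1) <- rownames(t2) <- rownames(t3) <- rownames(t4) <- NULL
  list(table1 = t1, table2 = t2, table3 = t3, table4 = t4)
}
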