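# default structure-function correlation targets: per group, spirometry
# variable x airway generation (Pearson rho of luminal area vs % predicted)
default_target_correlations <- function() {
  gens <- 1:6
  ctl <- rbind(fev1_pct = c(.46, .56, .32, .31, .31, .29),
               fvc_pct  = c(.39, .53, .33, .31, .28, .31),
               fef2575_pct = c(.53, .49, .24, .25, .40, .30),
               pef_pct  = c(.59, .63, .25, .40, .54, .47))
  hf <- rbind(fev1_pct = c(.55, .49, .40, .51, .44, .28),
              fvc_pct  = c(.54, .47, .38, .47, .35, .19),
              fef2575_pct = c(.50, .47, .31, .46, .50, .40),
              pef_pct  = c(.64, .62, .58, .50, .54, .46))
  mk <- function(M, group) data.frame(
    group = group,
    variable = rep(rownames(M), times = length(gens)),
    generation = rep(gens, each = nrow(M)),
    rho = as.vector(M))
  rbind(mk(ctl, "control"), mk(hf, "hf"))
}

default_group_params <- function() {
  list(
    control = list(
      evlw_weight_mean = 0.010, evlw_weight_sd = 0.004,
      tlc_mean = 6.8, tlc_sd = 1.1,
      root_radius_mean = 8.8, root_radius_sd = 0.5,
      root_wall_mean = 2.55, root_wall_sd = 0.25,
      spiro_mean = c(fvc_pct = 101, fev1_pct = 103, fef2575_pct = 118, pef_pct = 110),
      spiro_sd = c(fvc_pct = 15, fev1_pct = 15, fef2575_pct = 36, pef_pct = 22),
      clearance_mean = 0.93, clearance_slope = 0.5,
      wall_thinning_mean = 0.12, wall_thinning_sd = 0.04),
    hf = list(
      evlw_weight_mean = 0.018, evlw_weight_sd = 0.007,
      tlc_mean = 6.2, tlc_sd = 1.2,
      root_radius_mean = 9.2, root_radius_sd = 0.5,
      root_wall_mean = 2.6, root_wall_sd = 0.25,
      spiro_mean = c(fvc_pct = 83, fev1_pct = 82, fef2575_pct = 86, pef_pct = 88),
      spiro_sd = c(fvc_pct = 18, fev1_pct = 19, fef2575_pct = 36, pef_pct = 24),
      clearance_mean = 0.94, clearance_slope = 0.5,
      wall_thinning_mean = 0.12, wall_thinning_sd = 0.04))
}

#' Synthetic cohort specification
#'
#' Parameters of the two-group (control / heart failure) synthetic cohort:
#' group sizes, per-group distributions of edema burden, lung size and
#' airway geometry, spirometry (% predicted) distributions, the targeted
#' Pearson correlations between generation-level airway luminal area and
#' spirometry (achieved through a Gaussian copula), and the bronchodilator
#' response model (fractional edema clearance, increasing with baseline
#' burden through `clearance_slope` on the logit scale, and fractional
#' airway wall thinning).
#'
#' @param n_per_group named counts, e.g. `c(control = 29, hf = 31)`.
#' @param groups per-group parameter lists; see
#'   `lungqct:::default_group_params()` for the fields.
#' @param target_correlations data frame (`group`, `variable`,
#'   `generation`, `rho`) of targeted area-spirometry correlations.
#' @param spiro_cor,gen_cor latent correlation within the spirometry block
#'   and within the generation-area block.
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(control = 29, hf = 31),
                        groups = default_group_params(),
                        target_correlations = default_target_correlations(),
                        spiro_cor = 0.7, gen_cor = 0.7,
                        seed = 1L) {
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% names(groups)))
    stopf("`n_per_group` must be named after entries of `groups`")
  if (any(n_per_group < 2)) stopf("need at least 2 subjects per group")
  if (any(abs(target_correlations$rho) > 1)) stopf("|rho| must be <= 1")
  for (g in names(groups)) {
    p <- groups[[g]]
    check_fraction(p$clearance_mean, paste0(g, "$clearance_mean"))
    check_fraction(p$wall_thinning_mean, paste0(g, "$wall_thinning_mean"))
  }
  structure(list(n_per_group = n_per_group, groups = groups,
                 target_correlations = target_correlations,
                 spiro_cor = spiro_cor, gen_cor = gen_cor,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

spiro_vars <- c("fvc_pct", "fev1_pct", "fef2575_pct", "pef_pct")

# symmetric square root of the latent correlation matrix for one group
# (4 spirometry + 6 generation-area variables); errors when the target set
# is not positive semi-definite
group_latent_correlation <- function(cspec, group) {
  R <- diag(10)
  R[1:4, 1:4] <- cspec$spiro_cor
  R[5:10, 5:10] <- cspec$gen_cor
  diag(R) <- 1
  tc <- cspec$target_correlations
  tc <- tc[tc$group == group, , drop = FALSE]
  for (i in seq_len(nrow(tc))) {
    vi <- match(tc$variable[i], spiro_vars)
    gi <- 4 + tc$generation[i]
    R[vi, gi] <- R[gi, vi] <- tc$rho[i]
  }
  ed <- eigen(R, symmetric = TRUE)
  if (min(ed$values) < -1e-8)
    stopf("infeasible correlation targets for group '%s': matrix not positive definite (min eigenvalue %.3g)",
          group, min(ed$values))
  # symmetric square root (tolerates exactly singular targets, e.g. rho = 1)
  ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
}

#' Sample a synthetic cohort
#'
#' Draws subject-level parameters for each group: spirometry and
#' generation-level airway luminal areas jointly from a Gaussian copula
#' achieving the targeted correlations in expectation, plus edema weight,
#' TLC, airway geometry and the subject's bronchodilator response
#' (clearance increasing with baseline edema burden).  Deterministic given
#' the seed.
#'
#' @param cspec a [cohort_spec()].
#' @return object of class `cohort_sample`: a data frame `subjects` with
#'   one row per subject (spirometry, TLC, `evlw_weight`, airway geometry,
#'   stub per-generation areas `area_g1..area_g6` in mm^2 and walls
#'   `wall_g1..wall_g6` in mm, `clearance`, `wall_thinning`, `seed`), and
#'   the generating `cspec`.
#' @seealso [phantom_spec_for_subject()], [simulate_cohort_records()]
#' @export
sample_cohort <- function(cspec) {
  stopifnot(inherits(cspec, "cohort_spec"))
  rows <- list()
  with_seed(cspec$seed, {
    sid <- 0L
    for (g in names(cspec$n_per_group)) {
      p <- cspec$groups[[g]]
      n <- cspec$n_per_group[[g]]
      L <- group_latent_correlation(cspec, g)
      Z <- matrix(rnorm(n * 10), n, 10) %*% L
      spiro <- sweep(sweep(Z[, 1:4, drop = FALSE], 2, p$spiro_sd[spiro_vars], "*"),
                     2, p$spiro_mean[spiro_vars], "+")
      colnames(spiro) <- spiro_vars
      spiro[spiro < 1] <- 1
      rr <- cspec$groups[[g]]$root_radius_mean
      radii <- vapply(1:6, function(k)
        (rr + p$root_radius_sd * Z[, 4 + k]) * 0.71^(k - 1), numeric(n))
      areas <- pi * pmax(radii, 0.5)^2
      colnames(areas) <- paste0("area_g", 1:6)
      ew <- pmin(0.25, pmax(5e-4, rnorm(n, p$evlw_weight_mean, p$evlw_weight_sd)))
      zw <- (ew - p$evlw_weight_mean) / p$evlw_weight_sd
      clearance <- plogis(qlogis(p$clearance_mean) + p$clearance_slope * zw)
      thinning <- pmin(0.5, pmax(0, rnorm(n, p$wall_thinning_mean, p$wall_thinning_sd)))
      tlc <- pmin(10, pmax(3, rnorm(n, p$tlc_mean, p$tlc_sd)))
      wall_root <- pmax(1, rnorm(n, p$root_wall_mean, p$root_wall_sd))
      walls <- vapply(1:6, function(k) wall_root * 0.9^(k - 1), numeric(n))
      colnames(walls) <- paste0("wall_g", 1:6)
      df <- data.frame(subject_id = sprintf("%s%02d", toupper(substr(g, 1, 1)),
                                            seq_len(n)),
                       group = g, tlc = tlc, spiro, evlw_weight = ew,
                       root_radius = rr + p$root_radius_sd * Z[, 5],
                       root_wall = wall_root,
                       clearance = clearance, wall_thinning = thinning,
                       areas, walls,
                       seed = child_seed(cspec$seed, sid + seq_len(n)),
                       stringsAsFactors = FALSE)
      sid <- sid + n
      rows[[g]] <- df
    }
  })
  subjects <- do.call(rbind, rows)
  rownames(subjects) <- NULL
  structure(list(subjects = subjects, cspec = cspec), class = "cohort_sample")
}

#' @export
print.cohort_sample <- function(x, ...) {
  cat(sprintf("<cohort_sample> %d subjects (%s)\n", nrow(x$subjects),
              paste(sprintf("%s n=%d", names(table(x$subjects$group)),
                            table(x$subjects$group)), collapse = ", ")))
  invisible(x)
}

#' Phantom specification for one cohort subject
#'
#' Maps a sampled subject's parameters (edema weight, airway geometry,
#' per-subject seed) onto a [phantom_spec()], optionally at a reduced grid
#' for fast cohort-scale rendering.
#'
#' @param cohort a `cohort_sample`.
#' @param i subject row index.
#' @param ... overrides passed to [phantom_spec()] (e.g. `grid_shape`,
#'   `voxel_spacing`, `airway_generations`).
#' @return a [phantom_spec()].
#' @export
phantom_spec_for_subject <- function(cohort, i, ...) {
  s <- cohort$subjects[i, ]
  args <- list(evlw_weight = s$evlw_weight,
               root_radius = max(2, s$root_radius),
               root_wall = s$root_wall,
               seed = s$seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

#' Histogram-level simulation of a cohort's subject records
#'
#' Fast path for cohort-scale statistics: for each sampled subject, draws a
#' paired pre/post parenchymal attenuation sample from the subject's
#' mixture model (no 3-D rendering; see [sample_parenchyma_hu()]), computes
#' the density metrics, and attaches per-generation airway tables built
#' from the subject's sampled areas and walls (walls thinned by the
#' subject's `wall_thinning` in the post state).
#'
#' @param cohort a `cohort_sample` from [sample_cohort()].
#' @param n_voxels parenchymal voxels per subject.
#' @param bronchodilator if `FALSE`, no post state is simulated.
#' @return list of `subject_record` objects, one per subject.
#' @export
simulate_cohort_records <- function(cohort, n_voxels = 50000,
                                    bronchodilator = TRUE) {
  stopifnot(inherits(cohort, "cohort_sample"))
  lapply(seq_len(nrow(cohort$subjects)), function(i) {
    s <- cohort$subjects[i, ]
    spec <- phantom_spec_for_subject(cohort, i)
    hu <- sample_parenchyma_hu(spec, n_voxels,
                               clearance = if (bronchodilator) s$clearance,
                               seed = s$seed)
    voxel_ml <- s$tlc * 1000 / n_voxels
    pre <- density_metrics_from_values(hu$pre, voxel_ml)
    post <- if (bronchodilator) density_metrics_from_values(hu$post, voxel_ml)
    gens <- 1:6
    pre_air <- data.frame(generation = gens,
                          mean_area = as.numeric(s[paste0("area_g", gens)]),
                          mean_wall = as.numeric(s[paste0("wall_g", gens)]),
                          n_segments = 2L^(gens - 1L), n_flagged = 0L,
                          absent = FALSE)
    pre_air <- normalize_to_subject(pre_air, s$tlc)
    post_air <- NULL
    if (bronchodilator) {
      post_air <- pre_air
      post_air$mean_wall <- pre_air$mean_wall * (1 - s$wall_thinning)
      post_air <- normalize_to_subject(post_air[
        c("generation", "mean_area", "mean_wall", "n_segments", "n_flagged",
          "absent")], s$tlc)
    }
    subject_record(subject_id = s$subject_id, group = s$group, tlc = s$tlc,
                   spirometry = as.list(s[spiro_vars]),
                   pre = pre, post = post,
                   pre_airways = pre_air, post_airways = post_air)
  })
}
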