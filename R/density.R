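#' Attenuation-distribution moments
#'
#' Mean, sample skewness and excess kurtosis of a vector of HU values,
#' computed from central moments on the raw voxel values:
#' `g1 = m3 / m2^1.5` and `g2 = m4 / m2^2 - 3` with `mk` the k-th central
#' moment (denominator n).  Lower skewness and kurtosis indicate a heavier
#' high-attenuation tail, the signature of pulmonary congestion.
#'
#' @param values numeric vector of HU values, `n >= 3`.
#' @param excess if `FALSE`, report raw kurtosis `m4/m2^2` instead of
#'   excess kurtosis.
#' @return named list `mean_hu`, `skewness`, `kurtosis`.
#' @export
distribution_moments <- function(values, excess = TRUE) {
  n <- length(values)
  if (n < 3) stopf("need at least 3 values, got %d", n)
  mu <- mean(values)
  d <- values - mu
  m2 <- mean(d^2)
  if (m2 <= 0) stopf("degenerate distribution: zero variance")
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  list(mean_hu = mu,
       skewness = m3 / m2^1.5,
       kurtosis = m4 / m2^2 - if (excess) 3 else 0)
}

#' Attenuation histogram
#'
#' Fixed-width binning of HU values.  Bin edges are aligned to multiples of
#' `bin_width` so histograms of different scans are comparable.
#'
#' @param values numeric vector of HU values.
#' @param bin_width bin width in HU (default 1).
#' @return object of class `density_histogram` with `bin_edges`, `mids`,
#'   `counts`, `bin_width`.
#' @export
density_histogram <- function(values, bin_width = 1) {
  if (!is_scalar_num(bin_width) || bin_width <= 0)
    stopf("`bin_width` must be a positive scalar")
  lo <- floor(min(values) / bin_width)
  hi <- floor(max(values) / bin_width)
  idx <- pmin(floor(values / bin_width) - lo + 1, hi - lo + 1)
  counts <- tabulate(idx, nbins = hi - lo + 1)
  edges <- (lo:(hi + 1)) * bin_width
  structure(list(bin_edges = edges,
                 mids = (head(edges, -1) + tail(edges, -1)) / 2,
                 counts = counts, bin_width = bin_width),
            class = "density_histogram")
}

#' Full width at half maximum of an attenuation histogram
#'
#' Width in HU between the two half-maximum crossings of the histogram,
#' searching outward from the modal bin (ties broken toward lower HU) and
#' interpolating linearly between adjacent bin centres.  A flat-top
#' histogram therefore returns its full width, and a single occupied bin
#' returns one bin width.
#'
#' @param hist a `density_histogram` (or numeric vector of HU values, which
#'   is binned at 1 HU first).
#' @return FWHM in HU.
#' @export
fwhm <- function(hist) {
  if (is.numeric(hist)) hist <- density_histogram(hist)
  stopifnot(inherits(hist, "density_histogram"))
  counts <- as.numeric(hist$counts)
  mids <- hist$mids
  nb <- length(counts)
  mode_i <- which.max(counts)   # first maximum = lower-HU tie break
  half <- counts[mode_i] / 2
  # pad with zero bins so boundary-touching histograms still cross
  counts_p <- c(0, counts, 0)
  mids_p <- c(mids[1] - hist$bin_width, mids, mids[nb] + hist$bin_width)
  mi <- mode_i + 1L
  cross <- function(side) {
    i <- mi
    repeat {
      j <- i + side
      if (j < 1 || j > nb + 2)
        stopf("half maximum never crossed on the %s side",
              if (side < 0) "low-HU" else "high-HU")
      if (counts_p[j] < half) {
        frac <- (counts_p[i] - half) / (counts_p[i] - counts_p[j])
        return(mids_p[i] + frac * (mids_p[j] - mids_p[i]))
      }
      i <- j
    }
  }
  cross(+1L) - cross(-1L)
}

#' Pulmonary congestion index
#'
#' Percentage of voxels with attenuation strictly greater than the
#' threshold (default -500 HU), an index of extravascular lung water.
#'
#' @param values numeric vector of HU values.
#' @param threshold threshold in HU; voxels at exactly the threshold do not
#'   count.
#' @return percentage in `[0, 100]`.
#' @export
congestion_index <- function(values, threshold = -500) {
  if (length(values) < 1) stopf("need at least one value")
  100 * sum(values > threshold) / length(values)
}

#' Per-voxel air and tissue fractions
#'
#' Linear partition of attenuation between pure air (-1000 HU) and pure
#' tissue (+55 HU): `f_air = (55 - hu) / 1055`, clamped to `[0, 1]`;
#' `f_tis = 1 - f_air` exactly.
#'
#' @param hu numeric vector of HU values.
#' @return `voxel_air_fraction()` returns `f_air`.
#' @export
voxel_air_fraction <- function(hu) air_fraction_of_hu(hu)

#' Lung air and tissue volumes
#'
#' Mean per-voxel air and tissue fractions over the mask multiplied by the
#' total masked volume, in litres.  `v_air + v_tis` equals the masked
#' volume exactly.
#'
#' @param volume a [ct_volume()].
#' @param mask a [region_mask()] (non-empty).
#' @return named list `v_air`, `v_tis`, `masked_volume` (all L).
#' @export
lung_air_tissue_volumes <- function(volume, mask) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "region_mask"))
  check_aligned(volume, mask)
  n <- sum(mask$mask)
  if (n == 0) stopf("empty mask")
  total_l <- n * voxel_volume_ml(volume) / 1000
  f_air <- mean(air_fraction_of_hu(volume$values[mask$mask]))
  list(v_air = f_air * total_l, v_tis = (1 - f_air) * total_l,
       masked_volume = total_l)
}

#' Density metrics of a masked CT volume
#'
#' Bundles the congestion indices of the attenuation histogram (mean HU,
#' skewness, excess kurtosis, FWHM, percentage of voxels above -500 HU)
#' with the air/tissue volume partition for the voxels of `mask`.
#'
#' @param volume a [ct_volume()].
#' @param mask analysis [region_mask()], e.g. from
#'   [apply_analysis_exclusions()].
#' @param bin_width histogram bin width, HU.
#' @param congestion_threshold threshold for the congestion index, HU.
#' @param excess_kurtosis report excess (default) or raw kurtosis.
#' @return object of class `density_metrics`: `mean_hu`, `skewness`,
#'   `kurtosis`, `fwhm`, `pct_gt_m500`, `v_air`, `v_tis`, `n_voxels`.
#' @export
compute_density_metrics <- function(volume, mask, bin_width = 1,
                                    congestion_threshold = -500,
                                    excess_kurtosis = TRUE) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "region_mask"))
  check_aligned(volume, mask)
  if (!any(mask$mask)) stopf("empty mask")
  values <- volume$values[mask$mask]
  vols <- lung_air_tissue_volumes(volume, mask)
  density_metrics_from_values(values, voxel_volume_ml(volume),
                              bin_width = bin_width,
                              congestion_threshold = congestion_threshold,
                              excess_kurtosis = excess_kurtosis,
                              v_air = vols$v_air, v_tis = vols$v_tis)
}

#' @rdname compute_density_metrics
#' @param values raw HU values (value-level entry point used by the
#'   histogram-level cohort simulation).
#' @param voxel_ml volume of one voxel, mL.
#' @param v_air,v_tis optional precomputed air/tissue volumes, L.
#' @export
density_metrics_from_values <- function(values, voxel_ml = 1,
                                        bin_width = 1,
                                        congestion_threshold = -500,
                                        excess_kurtosis = TRUE,
                                        v_air = NULL, v_tis = NULL) {
  mom <- distribution_moments(values, excess = excess_kurtosis)
  h <- density_histogram(values, bin_width)
  total_l <- length(values) * voxel_ml / 1000
  if (is.null(v_air)) {
    f_air <- mean(air_fraction_of_hu(values))
    v_air <- f_air * total_l
    v_tis <- (1 - f_air) * total_l
  }
  structure(list(mean_hu = mom$mean_hu, skewness = mom$skewness,
                 kurtosis = mom$kurtosis, fwhm = fwhm(h),
                 pct_gt_m500 = congestion_index(values, congestion_threshold),
                 v_air = v_air, v_tis = v_tis,
                 n_voxels = length(values)),
            class = "density_metrics")
}

#' @export
print.density_metrics <- function(x, ...) {
  cat(sprintf(paste0("<density_metrics> mean %.1f HU, skew %.2f, kurtosis %.2f, ",
                     "FWHM %.1f HU, %%>-500 %.2f, Vair %.2f L, Vtis %.2f L (n=%d)\n"),
              x$mean_hu, x$skewness, x$kurtosis, x$fwhm, x$pct_gt_m500,
              x$v_air, x$v_tis, x$n_voxels))
  invisible(x)
}

#' Percent change between paired density metrics
#'
#' Per-index percent change from a baseline to a post-bronchodilator scan.
#' For mean HU the magnitude convention `100*(|post| - |pre|)/|pre|` is
#' used, so a leftward shift of the histogram (toward -1000 HU, i.e. fluid
#' clearing) is a positive change; all other indices use
#' `100*(post - pre)/|pre|`.
#'
#' @param pre,post `density_metrics` objects.
#' @param mean_convention `"magnitude"` (default) or `"signed"`.
#' @return named numeric vector of percent changes (`NA` where the
#'   baseline value is zero).
#' @export
percent_change <- function(pre, post, mean_convention = c("magnitude", "signed")) {
  stopifnot(inherits(pre, "density_metrics"), inherits(post, "density_metrics"))
  mean_convention <- match.arg(mean_convention)
  pc <- function(a, b) if (abs(a) < .Machine$double.eps) NA_real_ else 100 * (b - a) / abs(a)
  mean_pc <- if (mean_convention == "magnitude")
    pc(abs(pre$mean_hu), abs(post$mean_hu)) else pc(pre$mean_hu, post$mean_hu)
  c(mean_hu = mean_pc,
    skewness = pc(pre$skewness, post$skewness),
    kurtosis = pc(pre$kurtosis, post$kurtosis),
    fwhm = pc(pre$fwhm, post$fwhm),
    pct_gt_m500 = pc(pre$pct_gt_m500, post$pct_gt_m500),
    v_air = pc(pre$v_air, post$v_air),
    v_tis = pc(pre$v_tis, post$v_tis))
}
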