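#' Segment the lung fields of a thoracic CT volume
#'
#' Threshold-based lung-field extraction: voxels below `threshold_hu` are
#' candidate air, components connected to the grid border (ambient air) are
#' discarded, the two largest remaining components are kept as the lung
#' fields, and a one-voxel morphological closing fills small interior
#' defects (vessels, noise voxels above threshold).  Component labelling
#' uses 26-connectivity.
#'
#' @param volume a [ct_volume()].
#' @param threshold_hu lung/soft-tissue threshold, HU.  The default -320
#'   sits midway between aerated parenchyma and soft tissue.
#' @param min_component_voxels components smaller than this are ignored.
#' @return a [region_mask()] with label `"lung"`.
#' @examples
#' ph <- build_phantom(phantom_spec(grid_shape = c(48, 48, 48),
#'                                  voxel_spacing = 2.5,
#'                                  airway_generations = 1,
#'                                  root_radius = 6, root_length = 30))
#' lung <- segment_lung_fields(ph$volume)
#' @export
segment_lung_fields <- function(volume, threshold_hu = -320,
                                min_component_voxels = 100) {
  stopifnot(inherits(volume, "ct_volume"))
  shape <- dim(volume$values)
  sub <- volume$values < threshold_hu
  if (!any(sub)) stopf("no lung fields: no voxels below %g HU", threshold_hu)
  labels <- cpp_label_components(as.logical(sub), shape, 26L)
  labarr <- array(labels, shape)
  border <- cpp_border_touching_labels(labels, shape)
  sizes <- tabulate(labels)
  keep <- setdiff(which(sizes >= min_component_voxels), border)
  if (length(keep) == 0)
    stopf("no lung fields: all sub-threshold regions are border-connected or too small")
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  keep <- head(keep, 2L)
  if (length(keep) == 1L)
    warnf("only one interior air component found; proceeding as fused lung fields")
  m <- array(labels %in% keep, shape)
  # one-voxel closing (26-connected structuring element)
  m <- array(cpp_dilate(as.logical(m), shape, 26L), shape)
  m <- array(cpp_erode(as.logical(m), shape, 26L), shape)
  region_mask(m, "lung", volume$spacing)
}

#' Apply the analysis-mask exclusion rules
#'
#' Restricts a lung mask to the voxels entering histogram analysis: airway
#' lumen voxels and voxels outside the -1000 to 0 HU range are excluded
#' (boundary values -1000 and 0 are kept).  The counts removed by each rule
#' are attached as the `"exclusions"` attribute.
#'
#' @param volume a [ct_volume()].
#' @param lung lung-field [region_mask()].
#' @param airway_lumen optional airway-lumen [region_mask()].
#' @param hu_range inclusive analysis range, HU.
#' @return a [region_mask()] with label `"analysis"`.
#' @export
apply_analysis_exclusions <- function(volume, lung, airway_lumen = NULL,
                                      hu_range = c(-1000, 0)) {
  stopifnot(inherits(volume, "ct_volume"), inherits(lung, "region_mask"))
  check_aligned(volume, lung)
  m <- lung$mask
  n_lung <- sum(m)
  n_air <- 0L
  if (!is.null(airway_lumen)) {
    check_aligned(volume, airway_lumen)
    n_air <- sum(m & airway_lumen$mask)
    m <- m & !airway_lumen$mask
  }
  in_range <- volume$values >= hu_range[1] & volume$values <= hu_range[2]
  n_range <- sum(m & !in_range)
  m <- m & in_range
  if (!any(m)) stopf("empty analysis mask after exclusions")
  out <- region_mask(m, "analysis", volume$spacing)
  attr(out, "exclusions") <- c(lung_voxels = n_lung, airway = n_air,
                               out_of_range = n_range, retained = sum(m))
  out
}
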