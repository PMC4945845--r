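#' Airway tree container
#'
#' A rooted centerline tree: a data frame of segments (`id`, `parent_id`,
#' `generation` with the trachea as generation 1, per-segment lumen/wall
#' measurements and a quality flag) plus one ordered matrix of mm
#' centerline points per segment.
#'
#' @param segments segment data frame.
#' @param centerlines list of n x 3 matrices of mm points, one per segment.
#' @param geometry optional generating geometry (phantom ground truth).
#' @export
airway_tree <- function(segments, centerlines, geometry = NULL) {
  stopifnot(is.data.frame(segments), length(centerlines) == nrow(segments))
  if (sum(is.na(segments$parent_id)) != 1L)
    stopf("airway tree must have exactly one root")
  structure(list(segments = segments, centerlines = centerlines),
            class = "airway_tree", geometry = geometry)
}

#' @export
print.airway_tree <- function(x, ...) {
  s <- x$segments
  cat(sprintf("<airway_tree> %d segments, generations 1-%d\n",
              nrow(s), max(s$generation)))
  print(table(generation = s$generation))
  invisible(x)
}

#' Segment the airway lumen by leak-controlled region growing
#'
#' Grows a 6-connected region of sub-threshold voxels from a seed inside
#' the trachea, relaxing the threshold stepwise from `grow_start` to
#' `grow_stop` HU.  After each relaxation the accepted-volume growth ratio
#' is checked: a step that grows the region by more than `leak_ratio` times
#' is rolled back entirely and growing stops, containing segmentation leaks
#' through thin or defective airway walls.
#'
#' @param volume a [ct_volume()].
#' @param seed_point voxel index `c(i, j, k)` inside the trachea (1-based);
#'   defaults to [find_trachea_seed()].
#' @param grow_start,grow_stop,grow_step threshold schedule, HU.
#' @param leak_ratio maximum allowed per-step volume growth factor.
#' @param max_initial_ml initial region larger than this means the seed
#'   region is already leaking (mL).
#' @return a [region_mask()] with label `"airway_lumen"`; the threshold
#'   schedule bookkeeping is attached as attribute `"grow_info"`.
#' @export
segment_airway_tree <- function(volume, seed_point = NULL,
                                grow_start = -950, grow_stop = -500,
                                grow_step = 25, leak_ratio = 2,
                                max_initial_ml = 150) {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.null(seed_point)) seed_point <- find_trachea_seed(volume)
  shape <- dim(volume$values)
  seed_point <- as.integer(seed_point)
  if (length(seed_point) != 3L || any(seed_point < 1L) || any(seed_point > shape))
    stopf("seed_point must be a voxel index inside the volume")
  hu <- volume$values[seed_point[1], seed_point[2], seed_point[3]]
  if (hu >= grow_start)
    stopf("seed voxel is not in air (%.0f HU >= %.0f HU): not a luminal seed",
          hu, grow_start)
  thresholds <- seq(grow_start, grow_stop, by = grow_step)
  seed0 <- (seed_point[1] - 1L) +
    shape[1] * ((seed_point[2] - 1L) + shape[2] * (seed_point[3] - 1L))
  res <- cpp_region_grow(as.numeric(volume$values), shape, seed0,
                         thresholds, leak_ratio)
  init_ml <- res$step_counts[1] * voxel_volume_ml(volume)
  if (is.na(res$step_counts[1]) || init_ml > max_initial_ml)
    stopf("unsegmentable: initial region at %.0f HU is already %.0f mL (leak)",
          grow_start, init_ml)
  out <- region_mask(array(res$mask, shape), "airway_lumen", volume$spacing)
  attr(out, "grow_info") <- list(thresholds = thresholds,
                                 step_counts = res$step_counts,
                                 final_threshold = thresholds[res$last_step],
                                 leaked = res$leaked,
                                 n_voxels = res$n_voxels)
  out
}

#' Locate a trachea seed voxel automatically
#'
#' Scans slices from the cranial end of the volume for the first compact
#' interior air region (the tracheal lumen surrounded by mediastinal
#' tissue) and returns a voxel index a couple of slices caudal to it.
#'
#' @param volume a [ct_volume()].
#' @param air_threshold HU below which a voxel counts as luminal air.
#' @param area_range_mm2 acceptable cross-sectional area range of the
#'   candidate lumen.
#' @return voxel index `c(i, j, k)`.
#' @export
find_trachea_seed <- function(volume, air_threshold = -900,
                              area_range_mm2 = c(20, 1200)) {
  shape <- dim(volume$values)
  pix_mm2 <- prod(volume$spacing[1:2])
  for (z in seq_len(ceiling(0.5 * shape[3]))) {
    sl <- volume$values[, , z] < air_threshold
    if (!any(sl)) next
    labs <- cpp_label_components(as.logical(sl), c(shape[1:2], 1L), 26L)
    labarr0 <- array(labs, shape[1:2])
    border <- setdiff(unique(c(labarr0[1, ], labarr0[shape[1], ],
                               labarr0[, 1], labarr0[, shape[2]])), 0L)
    sizes <- tabulate(labs)
    cand <- setdiff(which(sizes * pix_mm2 >= area_range_mm2[1] &
                          sizes * pix_mm2 <= area_range_mm2[2]), border)
    if (length(cand) == 0) next
    labarr <- array(labs, shape[1:2])
    centre <- shape[1:2] / 2
    best <- NULL; bestd <- Inf
    for (lb in cand) {
      w <- which(labarr == lb, arr.ind = TRUE)
      ctr <- colMeans(w)
      d <- sum((ctr - centre)^2)
      if (d < bestd) { bestd <- d; best <- round(ctr) }
    }
    z2 <- min(shape[3], z + 2L)
    if (volume$values[best[1], best[2], z2] < air_threshold)
      return(as.integer(c(best, z2)))
    return(as.integer(c(best, z)))
  }
  stopf("no tracheal air region found in the cranial half of the volume")
}

#' Extract a centerline tree from an airway lumen mask
#'
#' Wavefront decomposition of the lumen: a 26-connected BFS geodesic
#' distance is propagated from the root voxel, voxels are binned into
#' distance shells, shells are split into connected clusters, and the
#' cluster adjacency graph is read as the airway tree - a wavefront that
#' splits into two clusters marks a bifurcation.  Cluster centroids form
#' the centerlines.  Generations count bifurcations from the root
#' (trachea = 1); terminal spurs shorter than `prune_mm` are removed and
#' the tree re-merged.
#'
#' @param lumen an airway-lumen [region_mask()] (one connected component).
#' @param root voxel index of the tracheal end; defaults to the voxel of
#'   the lowest slice index in the mask (ties toward the mask centroid).
#' @param shell_width shell thickness in BFS steps.
#' @param prune_mm terminal stubs of at most two clusters shorter than
#'   this are pruned (default one voxel); single-cluster stubs are always
#'   pruned.
#' @return an [airway_tree()] with geometry only (no measurements).
#' @export
extract_centerline_tree <- function(lumen, root = NULL, shell_width = 1L,
                                    prune_mm = NULL) {
  stopifnot(inherits(lumen, "region_mask"))
  shape <- dim(lumen$mask)
  spacing <- lumen$spacing
  if (is.null(prune_mm)) prune_mm <- max(spacing)
  if (!any(lumen$mask)) stopf("empty lumen mask")
  if (is.null(root)) {
    zmin <- which(apply(lumen$mask, 3, any))[1]
    w <- which(lumen$mask[, , zmin], arr.ind = TRUE)
    ctr <- colMeans(w)
    i <- which.min((w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2)
    root <- c(w[i, ], zmin)
  }
  root <- as.integer(root)
  root0 <- (root[1] - 1L) + shape[1] * ((root[2] - 1L) + shape[2] * (root[3] - 1L))
  res <- cpp_wavefront_clusters(as.logical(lumen$mask), shape, root0,
                                as.integer(shell_width))
  if (res$n_mask < sum(lumen$mask))
    stopf("lumen mask is disconnected: %d of %d voxels reachable from the root",
          res$n_mask, sum(lumen$mask))
  cl <- data.frame(id = seq_len(res$n_clusters), shell = res$shell,
                   size = res$size, parent = res$parent)
  cl$x <- (res$cx + 0.5) * spacing[1]
  cl$y <- (res$cy + 0.5) * spacing[2]
  cl$z <- (res$cz + 0.5) * spacing[3]

  kids <- split(cl$id, factor(cl$parent, levels = cl$id))
  # walk the cluster tree into segments
  seg_clusters <- list()
  seg_parent <- integer()
  walk <- list(list(start = res$root_cluster, parent = NA_integer_))
  while (length(walk) > 0) {
    job <- walk[[length(walk)]]
    walk[[length(walk)]] <- NULL
    chain <- integer()
    cur <- job$start
    repeat {
      chain <- c(chain, cur)
      ch <- kids[[as.character(cur)]]
      if (length(ch) == 1L) { cur <- ch } else break
    }
    sid <- length(seg_clusters) + 1L
    seg_clusters[[sid]] <- chain
    seg_parent[sid] <- job$parent
    ch <- kids[[as.character(cur)]]
    for (c2 in ch) walk[[length(walk) + 1L]] <- list(start = c2, parent = sid)
  }

  seg_len <- function(chain) {
    p <- as.matrix(cl[match(chain, cl$id), c("x", "y", "z")])
    if (nrow(p) < 2) return(0)
    sum(sqrt(rowSums(diff(p)^2)))
  }

  # prune short terminal spurs, re-merging single-child chains
  repeat {
    n <- length(seg_clusters)
    has_child <- tabulate(seg_parent[!is.na(seg_parent)], nbins = n) > 0
    lens <- vapply(seg_clusters, seg_len, numeric(1))
    # a spur is a leaf that is too short to be a resolved branch: either
    # a one/two-cluster stub or shorter than the prune length
    ncl <- lengths(seg_clusters)
    spur <- which(!has_child & !is.na(seg_parent) &
                    (ncl <= 1L | (lens < prune_mm & ncl <= 2L)))
    spur <- spur[vapply(spur, function(s)
      sum(seg_parent == seg_parent[s], na.rm = TRUE) > 1L, logical(1))]
    if (length(spur) == 0) break
    drop <- spur[1]
    keep <- setdiff(seq_len(n), drop)
    remap <- match(seg_parent, keep)
    seg_clusters <- seg_clusters[keep]
    seg_parent <- remap[keep]
    # merge parents left with exactly one child
    repeat {
      n <- length(seg_clusters)
      cnt <- tabulate(seg_parent[!is.na(seg_parent)], nbins = n)
      mergeable <- which(cnt == 1L)
      if (length(mergeable) == 0) break
      p <- mergeable[1]
      child <- which(!is.na(seg_parent) & seg_parent == p)
      seg_clusters[[p]] <- c(seg_clusters[[p]], seg_clusters[[child]])
      gkids <- which(!is.na(seg_parent) & seg_parent == child)
      seg_parent[gkids] <- p
      keep <- setdiff(seq_len(n), child)
      remap <- match(seg_parent, keep)
      seg_clusters <- seg_clusters[keep]
      seg_parent <- remap[keep]
    }
  }

  # generations by depth from the root segment
  n <- length(seg_clusters)
  gen <- integer(n)
  rootseg <- which(is.na(seg_parent))
  gen[rootseg] <- 1L
  todo <- rootseg
  while (length(todo) > 0) {
    cur <- todo[1]; todo <- todo[-1]
    ch <- which(!is.na(seg_parent) & seg_parent == cur)
    gen[ch] <- gen[cur] + 1L
    todo <- c(todo, ch)
  }

  centerlines <- lapply(seg_clusters, function(chain)
    as.matrix(cl[match(chain, cl$id), c("x", "y", "z")]))
  segments <- data.frame(
    id = seq_len(n), parent_id = seg_parent, generation = gen,
    length_mm = vapply(seg_clusters, seg_len, numeric(1)),
    mean_lumen_area = NA_real_, mean_wall_thickness = NA_real_,
    n_cross_sections = NA_integer_, quality_flag = NA_character_,
    stringsAsFactors = FALSE)
  airway_tree(segments, centerlines)
}

# orthonormal basis perpendicular to unit tangent t
perp_basis <- function(t) {
  a <- c(1, 0, 0)
  if (abs(sum(a * t)) > 0.9) a <- c(0, 1, 0)
  e1 <- a - sum(a * t) * t
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(t[2] * e1[3] - t[3] * e1[2],
          t[3] * e1[1] - t[1] * e1[3],
          t[1] * e1[2] - t[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# moving-average smoothing of an n x 3 centerline
smooth_centerline <- function(p, k = 3L) {
  n <- nrow(p)
  if (n < 3 || k < 2) return(p)
  out <- p
  h <- k %/% 2L
  for (i in seq_len(n)) {
    j <- max(1, i - h):min(n, i + h)
    out[i, ] <- colMeans(p[j, , drop = FALSE])
  }
  out
}

#' Measure luminal area and wall thickness along a centerline
#'
#' At cross-sections perpendicular to the smoothed centerline, rays are
#' cast outward and the luminal edge located as the half-maximum crossing
#' between the lumen and wall attenuation plateaus, the outer wall edge as
#' the half-maximum crossing back toward the surrounding parenchyma
#' (full-width-half-maximum edge principle).  The cross-sectional area is
#' the polygon of luminal edge radii; wall thickness is the mean
#' outer-minus-inner edge distance over rays with a detectable outer edge.
#' Cross-sections within half a luminal diameter of either end of the
#' centerline (bifurcation zones) are discarded, and the medians across the
#' retained cross-sections are returned.
#'
#' @param volume a [ct_volume()].
#' @param centerline n x 3 matrix of mm points (n >= 3).
#' @param n_rays number of rays per cross-section.
#' @param step radial sampling step, mm (default quarter voxel).
#' @param max_radius_mm how far rays are cast.
#' @param min_contrast_inner,min_contrast_outer minimum HU contrast for
#'   the lumen/wall and wall/parenchyma edges.
#' @param min_valid_frac minimum fraction of rays with a detectable lumen
#'   edge for a cross-section to count.
#' @return list `mean_lumen_area` (mm^2), `mean_wall_thickness` (mm),
#'   `n_cross_sections`, `quality_flag` (`"ok"`/`"unreliable"`).
#' @export
measure_segment <- function(volume, centerline, n_rays = 48L, step = NULL,
                            max_radius_mm = 25,
                            min_contrast_inner = 200,
                            min_contrast_outer = 50,
                            min_valid_frac = 0.6) {
  stopifnot(inherits(volume, "ct_volume"))
  centerline <- rbind(centerline)
  if (nrow(centerline) < 3)
    return(list(mean_lumen_area = NA_real_, mean_wall_thickness = NA_real_,
                n_cross_sections = 0L, quality_flag = "unreliable"))
  spacing <- volume$spacing
  if (is.null(step)) step <- 0.25 * min(spacing)
  p <- smooth_centerline(centerline)
  n <- nrow(p)
  tang <- rbind(p[2, ] - p[1, ],
                (p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE]) / 2,
                p[n, ] - p[n - 1, ])
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-9)
  theta <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
  tt <- seq(step, max_radius_mm, by = step)
  nst <- length(tt)
  shape <- dim(volume$values)
  arc <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))

  areas <- rep(NA_real_, n)
  walls <- rep(NA_real_, n)
  radii <- rep(NA_real_, n)
  wall_valid_frac <- rep(0, n)
  sin_d <- sin(2 * pi / n_rays)
  for (i in seq_len(n)) {
    b <- perp_basis(tang[i, ])
    dirs <- outer(cos(theta), b$e1) + outer(sin(theta), b$e2)   # n_rays x 3
    pts <- matrix(rep(p[i, ], each = n_rays * nst), ncol = 3) +
      dirs[rep(seq_len(n_rays), each = nst), ] * rep(tt, times = n_rays)
    vox <- sweep(pts, 2, spacing, "/") - 0.5
    prof <- cpp_interp_trilinear(as.numeric(volume$values), shape, vox)
    S <- matrix(prof, nrow = nst, ncol = n_rays)
    edges <- cpp_ray_edges(S, step, 3L,
                           as.integer(ceiling(3.5 / step)),
                           as.integer(ceiling(6 / step)),
                           min_contrast_inner, min_contrast_outer)
    r_in <- edges[, 1]
    ok <- is.finite(r_in)
    if (sum(ok) < min_valid_frac * n_rays) next
    r_fill <- r_in
    r_fill[!ok] <- median(r_in[ok])
    areas[i] <- 0.5 * sin_d * sum(r_fill * c(r_fill[-1], r_fill[1]))
    radii[i] <- median(r_in[ok])
    thick <- edges[, 2] - edges[, 1]
    okw <- is.finite(thick)
    wall_valid_frac[i] <- mean(okw)
    if (any(okw)) walls[i] <- mean(thick[okw])
  }

  ok_cs <- which(is.finite(areas))
  if (length(ok_cs) == 0)
    return(list(mean_lumen_area = NA_real_, mean_wall_thickness = NA_real_,
                n_cross_sections = 0L, quality_flag = "unreliable"))
  # drop cross-sections within half a diameter (one radius) of either end
  r_med <- median(radii[ok_cs])
  keep <- ok_cs[arc[ok_cs] > r_med & (arc[n] - arc[ok_cs]) > r_med]
  if (length(keep) < 3) keep <- ok_cs
  area <- median(areas[keep])
  wall_ok <- keep[is.finite(walls[keep])]
  wall <- if (length(wall_ok) > 0) median(walls[wall_ok]) else NA_real_
  flag <- "ok"
  if (length(keep) < 3 || !is.finite(area)) {
    flag <- "unreliable"
  } else if (!is.finite(wall) || wall < 1.2 * min(spacing) ||
             mean(wall_valid_frac[keep]) < 0.2) {
    # wall at or below the voxel resolution limit, or hardly any rays with
    # outer-edge contrast: thickness not trustworthy
    flag <- "unreliable"
  }
  list(mean_lumen_area = area, mean_wall_thickness = wall,
       n_cross_sections = length(keep), quality_flag = flag)
}

#' Measure every segment of an airway tree
#'
#' Runs [measure_segment()] along each centerline of `tree` and fills the
#' measurement columns of the segment table.
#'
#' @param volume a [ct_volume()].
#' @param tree an [airway_tree()].
#' @param ... passed to [measure_segment()].
#' @return the tree with `mean_lumen_area`, `mean_wall_thickness`,
#'   `n_cross_sections` and `quality_flag` populated.
#' @export
measure_airway_tree <- function(volume, tree, ...) {
  stopifnot(inherits(tree, "airway_tree"))
  for (i in seq_len(nrow(tree$segments))) {
    m <- measure_segment(volume, tree$centerlines[[i]], ...)
    tree$segments$mean_lumen_area[i] <- m$mean_lumen_area
    tree$segments$mean_wall_thickness[i] <- m$mean_wall_thickness
    tree$segments$n_cross_sections[i] <- m$n_cross_sections
    tree$segments$quality_flag[i] <- m$quality_flag
  }
  tree
}

#' Per-generation airway summary
#'
#' Averages segment measurements within each generation up to
#' `max_generation` (deeper generations are dropped from analysis).
#' Segments flagged unreliable are excluded from the means but counted in
#' `n_flagged`.
#'
#' @param tree a measured [airway_tree()].
#' @param max_generation deepest generation retained (default 6).
#' @return data frame with one row per generation: `generation`,
#'   `mean_area` (mm^2), `mean_wall` (mm), `n_segments`, `n_flagged`,
#'   `absent`.
#' @export
per_generation_summary <- function(tree, max_generation = 6L) {
  stopifnot(inherits(tree, "airway_tree"))
  s <- tree$segments
  if (nrow(s) == 0) stopf("empty airway tree")
  out <- do.call(rbind, lapply(seq_len(max_generation), function(g) {
    sg <- s[s$generation == g, , drop = FALSE]
    ok <- sg[!is.na(sg$quality_flag) & sg$quality_flag %in% c("ok", "truth"), ,
             drop = FALSE]
    data.frame(generation = g,
               mean_area = if (nrow(ok)) mean(ok$mean_lumen_area) else NA_real_,
               mean_wall = if (nrow(ok)) mean(ok$mean_wall_thickness) else NA_real_,
               n_segments = nrow(ok),
               n_flagged = nrow(sg) - nrow(ok),
               absent = nrow(sg) == 0)
  }))
  rownames(out) <- NULL
  out
}

#' Normalize a generation summary to subject size
#'
#' Adds the two size normalizations: luminal area over the subject's total
#' lung capacity (`area_over_tlc`, mm^2/L) and wall thickness over the
#' luminal area at the same generation (`wall_over_area`, mm/mm^2).  The
#' wall-over-radius ratio (dimensionless) is also emitted.
#'
#' @param summary data frame from [per_generation_summary()].
#' @param tlc total lung capacity, L (> 0).
#' @return the summary with `area_over_tlc`, `wall_over_area`,
#'   `wall_over_radius` columns added.
#' @export
normalize_to_subject <- function(summary, tlc) {
  if (!is_scalar_num(tlc) || tlc <= 0) stopf("`tlc` must be positive, got %s", tlc)
  summary$area_over_tlc <- summary$mean_area / tlc
  summary$wall_over_area <- summary$mean_wall / summary$mean_area
  summary$wall_over_radius <- summary$mean_wall / sqrt(summary$mean_area / pi)
  summary
}
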