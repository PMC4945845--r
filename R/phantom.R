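#' Digital thorax phantom specification
#'
#' Parameters of the synthetic thorax generator: a soft-tissue body
#' ellipsoid containing two lung ellipsoids of noisy air/tissue parenchyma
#' and a rendered dichotomous airway tree of known geometry.  The phantom is
#' the ground-truthed stand-in for patient CT volumes: every mask and every
#' airway dimension is known exactly by construction.
#'
#' The parenchymal attenuation model has three per-voxel components:
#' \itemize{
#'   \item with probability `evlw_weight`, an extravascular lung water
#'     (edema) voxel drawn from `Normal(evlw_mean, evlw_sd)`;
#'   \item with probability `(1-evlw_weight)*vessel_weight`, a
#'     vascular/interstitial voxel on the fixed right tail of the histogram:
#'     `base + Exponential(mean = vessel_tail_hu)`;
#'   \item otherwise an aerated voxel `base + Normal(0, sd_eff)`, where
#'     `base = -1000*f + body_hu*(1-f)` is the air/tissue mixing value at
#'     air fraction `f = lung_air_fraction` and
#'     `sd_eff = sqrt(noise_sd^2 + (evlw_noise_coupling*evlw_weight)^2)`
#'     couples parenchymal heterogeneity to the edema burden, so the
#'     histogram widens with congestion and narrows again when fluid clears.
#' }
#' With the defaults this reproduces the qualitative congested-lung
#' histogram: a dominant aerated peak near -815 HU with a heavy right tail,
#' whose skewness and kurtosis fall, and whose mean, width and percentage of
#' voxels above -500 HU rise, as `evlw_weight` increases.
#'
#' The airway tree is a symmetric dichotomous tree: the trachea (generation
#' 1) runs along the slice axis and each segment splits into two children
#' rotated by `branch_angle` degrees, the branching plane alternating
#' between the x-z and y-z planes per generation.  Radius, wall thickness
#' and length decay geometrically (`radius_ratio`, `wall_ratio`,
#' `length_ratio`).  Lumen voxels are -1000 HU, wall voxels `wall_hu`;
#' voxels are assigned by centre-point membership so the truth masks are
#' exact (a known bias of up to one voxel in rendered radii).
#'
#' @param grid_shape voxels per axis (x, y, z with z the slice axis).
#' @param voxel_spacing mm per axis.
#' @param body_hu HU of soft tissue.
#' @param lung_air_fraction target mean per-voxel air fraction in `[0,1]`.
#' @param noise_sd baseline parenchymal noise SD, HU.
#' @param evlw_weight probability a parenchymal voxel is an edema voxel.
#' @param evlw_mean,evlw_sd HU distribution of the edema component.
#' @param evlw_noise_coupling HU per unit `evlw_weight` added (in
#'   quadrature) to the aerated-voxel noise SD.
#' @param vessel_weight fixed weight of the vascular right-tail component.
#' @param vessel_tail_hu mean of the exponential right tail, HU.
#' @param airway_generations number of generations to render (trachea = 1).
#' @param root_radius,root_wall trachea luminal radius and wall, mm.
#' @param radius_ratio,wall_ratio,length_ratio per-generation geometric
#'   decay factors in `(0, 1]`.
#' @param root_length trachea length, mm.
#' @param branch_angle child rotation from the parent direction, degrees.
#' @param wall_hu HU of the airway wall (defaults to `body_hu`).
#' @param seed RNG seed making the phantom fully reproducible.
#' @return an object of class `phantom_spec`.
#' @seealso [build_phantom()], [apply_bronchodilator()], [cohort_spec()]
#' @export
phantom_spec <- function(grid_shape = c(188, 132, 180),
                         voxel_spacing = c(0.75, 0.75, 0.75),
                         body_hu = 30,
                         lung_air_fraction = 0.83,
                         noise_sd = 16,
                         evlw_weight = 0.015,
                         evlw_mean = -300,
                         evlw_sd = 100,
                         evlw_noise_coupling = 4400,
                         vessel_weight = 0.08,
                         vessel_tail_hu = 120,
                         airway_generations = 6,
                         root_radius = 8.8,
                         root_wall = 2.6,
                         radius_ratio = 0.71,
                         wall_ratio = 0.9,
                         root_length = 45,
                         length_ratio = 0.71,
                         branch_angle = 35,
                         wall_hu = body_hu,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(rep3(grid_shape, "grid_shape")),
               voxel_spacing = rep3(voxel_spacing, "voxel_spacing"),
               body_hu = body_hu,
               lung_air_fraction = lung_air_fraction,
               noise_sd = noise_sd,
               evlw_weight = evlw_weight,
               evlw_mean = evlw_mean, evlw_sd = evlw_sd,
               evlw_noise_coupling = evlw_noise_coupling,
               vessel_weight = vessel_weight,
               vessel_tail_hu = vessel_tail_hu,
               airway_generations = as.integer(airway_generations),
               root_radius = root_radius, root_wall = root_wall,
               radius_ratio = radius_ratio, wall_ratio = wall_ratio,
               root_length = root_length, length_ratio = length_ratio,
               branch_angle = branch_angle,
               wall_hu = wall_hu,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  check_fraction(s$lung_air_fraction, "lung_air_fraction")
  check_fraction(s$evlw_weight, "evlw_weight")
  check_fraction(s$vessel_weight, "vessel_weight")
  for (nm in c("radius_ratio", "wall_ratio", "length_ratio")) {
    v <- s[[nm]]
    if (!is_scalar_num(v) || v <= 0 || v > 1)
      stopf("`%s` must be in (0, 1], got %g", nm, v)
  }
  for (nm in c("root_radius", "root_wall", "root_length", "vessel_tail_hu"))
    if (!is_scalar_num(s[[nm]]) || s[[nm]] <= 0)
      stopf("`%s` must be a positive length, got %g", nm, s[[nm]])
  for (nm in c("noise_sd", "evlw_sd", "evlw_noise_coupling"))
    if (!is_scalar_num(s[[nm]]) || s[[nm]] < 0)
      stopf("`%s` must be non-negative", nm)
  if (s$airway_generations < 1L)
    stopf("`airway_generations` must be >= 1")
  if (any(s$voxel_spacing <= 0)) stopf("voxel spacing must be positive")
  if (any(s$grid_shape < 8L)) stopf("grid_shape must be at least 8 voxels per axis")
  invisible(s)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> grid %s @ %s mm, %d airway generations, evlw_weight %.3f, seed %d\n",
    paste(x$grid_shape, collapse = "x"),
    paste(format(x$voxel_spacing, digits = 3), collapse = "x"),
    x$airway_generations, x$evlw_weight, x$seed))
  invisible(x)
}

# effective aerated-parenchyma noise SD at edema weight w
parenchyma_noise_sd <- function(spec, w = spec$evlw_weight) {
  sqrt(spec$noise_sd^2 + (spec$evlw_noise_coupling * w)^2)
}

# air/tissue mixing value of aerated parenchyma, HU
parenchyma_base_hu <- function(spec) {
  -1000 * spec$lung_air_fraction + spec$body_hu * (1 - spec$lung_air_fraction)
}

# rotate unit vector u by `angle` (rad) towards the component of world axis
# `e` orthogonal to u
rotate_towards <- function(u, e, angle, max_polar = 60 * pi / 180) {
  ehat <- e - sum(e * u) * u
  n <- sqrt(sum(ehat^2))
  if (n < 1e-8) stopf("degenerate branching plane")
  ehat <- ehat / n
  v <- cos(angle) * u + sin(angle) * ehat
  v <- v / sqrt(sum(v^2))
  # airways keep heading caudally: clamp the polar angle from the slice
  # axis, preserving azimuth, so deep generations do not curl outward
  polar <- acos(max(-1, min(1, v[3])))
  if (polar > max_polar) {
    nxy <- sqrt(sum(v[1:2]^2))
    if (nxy > 1e-9) v <- c(v[1:2] / nxy * sin(max_polar), cos(max_polar))
  }
  v
}

# Symmetric dichotomous airway tree geometry in mm.  Returns a data frame
# of segments with start/end points, direction, radius, wall and length.
airway_tree_geometry <- function(spec) {
  ext <- spec$grid_shape * spec$voxel_spacing
  start <- c(ext[1] / 2, ext[2] / 2, 0.05 * ext[3])
  ang <- spec$branch_angle * pi / 180
  rows <- list()
  nid <- 0L
  recurse <- function(p0, u, gen, parent) {
    nid <<- nid + 1L
    id <- nid
    len <- spec$root_length * spec$length_ratio^(gen - 1)
    r <- spec$root_radius * spec$radius_ratio^(gen - 1)
    w <- spec$root_wall * spec$wall_ratio^(gen - 1)
    p1 <- p0 + u * len
    rows[[id]] <<- data.frame(
      id = id, parent_id = parent, generation = gen,
      x0 = p0[1], y0 = p0[2], z0 = p0[3],
      x1 = p1[1], y1 = p1[2], z1 = p1[3],
      ux = u[1], uy = u[2], uz = u[3],
      radius_mm = r, wall_mm = w, length_mm = len)
    if (gen < spec$airway_generations) {
      e <- if (gen %% 2L == 1L) c(1, 0, 0) else c(0, 1, 0)
      for (sgn in c(-1, 1))
        recurse(p1, rotate_towards(u, sgn * e, ang), gen + 1L, id)
    }
  }
  recurse(start, c(0, 0, 1), 1L, NA_integer_)
  do.call(rbind, rows)
}

# logical bounding-box render of one cylinder segment into accumulator
# arrays; radius_mm may include the wall.  cap_mm extends the cylinder past
# its distal end (wall end-caps).
render_segment <- function(acc, seg, radius_mm, spacing, cap_mm = 0) {
  shape <- dim(acc)
  p0 <- c(seg$x0, seg$y0, seg$z0)
  u <- c(seg$ux, seg$uy, seg$uz)
  len <- seg$length_mm
  marg <- radius_mm + cap_mm + max(spacing)
  lo <- pmax(1L, floor((pmin(p0, p0 + u * len) - marg) / spacing + 0.5))
  hi <- pmin(shape, ceiling((pmax(p0, p0 + u * len) + marg) / spacing + 0.5))
  if (any(lo > hi)) return(acc)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  xs <- (ix - 0.5) * spacing[1] - p0[1]
  ys <- (iy - 0.5) * spacing[2] - p0[2]
  zs <- (iz - 0.5) * spacing[3] - p0[3]
  tpar <- outer(outer(xs * u[1], ys * u[2], "+"), zs * u[3], "+")
  r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+") - tpar^2
  hit <- tpar >= 0 & tpar <= len + cap_mm & r2 < radius_mm^2
  acc[ix, iy, iz] <- acc[ix, iy, iz] | hit
  acc
}

# render lumen and wall masks for a tree geometry data frame; wall voxels
# never overlap lumen voxels
render_tree_masks <- function(tree, shape, spacing, wall_mm = tree$wall_mm) {
  lumen <- array(FALSE, shape)
  wall <- array(FALSE, shape)
  for (i in seq_len(nrow(tree))) {
    seg <- tree[i, ]
    w <- wall_mm[i]
    wall <- render_segment(wall, seg, seg$radius_mm + w, spacing, cap_mm = w)
    lumen <- render_segment(lumen, seg, seg$radius_mm, spacing, cap_mm = 0)
  }
  wall <- wall & !lumen
  list(lumen = lumen, wall = wall)
}

ellipsoid_mask <- function(shape, spacing, centre, semi) {
  xs <- ((seq_len(shape[1]) - 0.5) * spacing[1] - centre[1]) / semi[1]
  ys <- ((seq_len(shape[2]) - 0.5) * spacing[2] - centre[2]) / semi[2]
  zs <- ((seq_len(shape[3]) - 0.5) * spacing[3] - centre[3]) / semi[3]
  outer(outer(xs^2, ys^2, "+"), zs^2, "+") <= 1
}

# clamp of the linear air-fraction map, shared with the density module
air_fraction_of_hu <- function(hu) pmin(1, pmax(0, (55 - hu) / 1055))

#' Build a digital thorax phantom
#'
#' Renders the thorax described by a [phantom_spec()] and returns the CT
#' volume together with its exact ground truth: lung/lumen/wall masks, the
#' true airway tree, the per-voxel air-fraction map and the edema voxel
#' mask.  The same seed always yields a bit-identical volume.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `volume` (a [ct_volume()]) and `truth`
#'   (class `phantom_truth`: `lung_mask`, `airway_lumen_mask`,
#'   `airway_wall_mask`, `evlw_voxel_mask` as [region_mask()] objects, the
#'   ground-truth `tree` as an [airway_tree], `true_air_fraction_map`,
#'   `seed_point` voxel index of a trachea seed, and the generating `spec`).
#' @examples
#' ph <- build_phantom(phantom_spec(grid_shape = c(48, 48, 48),
#'                                  voxel_spacing = 2.5,
#'                                  airway_generations = 1,
#'                                  root_radius = 6, root_length = 30))
#' ph$volume
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  shape <- spec$grid_shape
  spacing <- spec$voxel_spacing
  if (min(spacing) > spec$root_radius)
    stopf("voxel spacing (%g mm) exceeds the root radius (%g mm): airway unresolvable",
          min(spacing), spec$root_radius)
  ext <- shape * spacing

  tree <- airway_tree_geometry(spec)
  # capsule bounding box per segment: radial extent (r+w)*sqrt(1-u_a^2)
  # around the axis, plus the distal wall cap along the direction
  for (ax in 1:3) {
    u <- tree[[c("ux", "uy", "uz")[ax]]]
    rw <- tree$radius_mm + tree$wall_mm
    perp <- rw * sqrt(pmax(0, 1 - u^2))
    a0 <- tree[[c("x0", "y0", "z0")[ax]]]
    a1 <- tree[[c("x1", "y1", "z1")[ax]]] + u * tree$wall_mm
    lo <- pmin(a0, a1) - perp
    hi <- pmax(a0, a1) + perp
    bad <- lo < 0 | hi > ext[ax]
    if (any(bad))
      stopf("airway tree generation %d exceeds the grid on axis %d; enlarge grid_shape or shrink the tree",
            min(tree$generation[bad]), ax)
  }

  body <- ellipsoid_mask(shape, spacing, ext / 2, c(0.47, 0.47, 0.49) * ext)
  lung_region <-
    ellipsoid_mask(shape, spacing, c(0.295, 0.50, 0.55) * ext, c(0.185, 0.35, 0.33) * ext) |
    ellipsoid_mask(shape, spacing, c(0.705, 0.50, 0.55) * ext, c(0.185, 0.35, 0.33) * ext)

  tm <- render_tree_masks(tree, shape, spacing)
  lumen <- tm$lumen
  wall <- tm$wall
  parenchyma <- lung_region & !lumen & !wall

  values <- array(-1000, shape)
  values[body] <- spec$body_hu
  values[wall] <- spec$wall_hu
  values[lumen] <- -1000

  base <- parenchyma_base_hu(spec)
  sde <- parenchyma_noise_sd(spec)
  idx <- which(parenchyma)
  n <- length(idx)
  hu <- numeric(n)
  comp <- integer(n)
  z <- numeric(n)
  evlw <- array(FALSE, shape)
  if (n > 0) {
    with_seed(spec$seed, {
      u <- runif(n)
      z <- rnorm(n)
      ex <- rexp(n) * spec$vessel_tail_hu
      comp <- ifelse(u < spec$evlw_weight, 2L,
                     ifelse(u < spec$evlw_weight +
                              (1 - spec$evlw_weight) * spec$vessel_weight, 1L, 0L))
      hu <- base + sde * z
      hu[comp == 1L] <- base + ex[comp == 1L]
      hu[comp == 2L] <- spec$evlw_mean + spec$evlw_sd * z[comp == 2L]
    })
    values[idx] <- hu
    evlw[idx[comp == 2L]] <- TRUE
  }

  afr <- array(0, shape)
  afr[!body] <- 1
  afr[lumen] <- 1
  if (n > 0) {
    af <- rep(spec$lung_air_fraction, n)
    af[comp != 0L] <- air_fraction_of_hu(hu[comp != 0L])
    afr[idx] <- af
  }

  seed_mm <- c(tree$x0[1], tree$y0[1], tree$z0[1]) +
    c(tree$ux[1], tree$uy[1], tree$uz[1]) * max(3 * max(spacing), 0.1 * tree$length_mm[1])
  seed_point <- pmin(shape, pmax(1L, round(seed_mm / spacing + 0.5)))

  truth <- structure(list(
    lung_mask = region_mask(parenchyma, "lung", spacing),
    lung_region = lung_region,
    airway_lumen_mask = region_mask(lumen, "airway_lumen", spacing),
    airway_wall_mask = region_mask(wall, "airway_wall", spacing),
    evlw_voxel_mask = region_mask(evlw, "other", spacing),
    true_air_fraction_map = afr,
    tree = truth_airway_tree(tree, spacing),
    paren = list(idx = idx, comp = comp, z = z),
    seed_point = as.integer(seed_point),
    spec = spec), class = "phantom_truth")

  list(volume = ct_volume(values, spacing), truth = truth)
}

# ground-truth geometry as an airway_tree object with straight centerlines
truth_airway_tree <- function(tree, spacing) {
  step <- 1.5 * max(spacing)
  centerlines <- lapply(seq_len(nrow(tree)), function(i) {
    seg <- tree[i, ]
    np <- max(3L, ceiling(seg$length_mm / step) + 1L)
    tt <- seq(0, seg$length_mm, length.out = np)
    cbind(seg$x0 + tt * seg$ux, seg$y0 + tt * seg$uy, seg$z0 + tt * seg$uz)
  })
  segments <- data.frame(
    id = tree$id, parent_id = tree$parent_id, generation = tree$generation,
    radius_mm = tree$radius_mm, wall_mm = tree$wall_mm,
    length_mm = tree$length_mm,
    mean_lumen_area = pi * tree$radius_mm^2,
    mean_wall_thickness = tree$wall_mm,
    n_cross_sections = NA_integer_,
    quality_flag = "truth",
    stringsAsFactors = FALSE)
  airway_tree(segments, centerlines, geometry = tree)
}

#' Simulate bronchodilator response on a phantom
#'
#' Emulates the albuterol response seen in congested lungs: a fraction
#' `clearance` of the edema voxels is resampled from the non-edema
#' parenchymal model, the parenchymal heterogeneity coupled to the edema
#' burden shrinks accordingly (the attenuation histogram shifts left and
#' narrows), and airway walls thin by the fraction `wall_thinning` while
#' the lumen is left untouched.
#'
#' @param volume,truth a phantom volume and its `phantom_truth`, from
#'   [build_phantom()].
#' @param clearance fraction of edema voxels cleared, in `[0,1]`.
#' @param wall_thinning fractional reduction of airway wall thickness.
#' @param seed RNG seed for the resampling.
#' @return a list `(volume, truth)` for the post-bronchodilator state.
#' @export
apply_bronchodilator <- function(volume, truth, clearance, wall_thinning = 0,
                                 seed = NULL) {
  stopifnot(inherits(volume, "ct_volume"), inherits(truth, "phantom_truth"))
  check_fraction(clearance, "clearance")
  check_fraction(wall_thinning, "wall_thinning")
  if (clearance == 0 && wall_thinning == 0)
    return(list(volume = volume, truth = truth))

  spec <- truth$spec
  shape <- dim(volume$values)
  spacing <- volume$spacing
  values <- volume$values
  afr <- truth$true_air_fraction_map
  paren <- truth$paren
  evlw <- truth$evlw_voxel_mask$mask
  base <- parenchyma_base_hu(spec)
  w0 <- spec$evlw_weight
  sde_pre <- parenchyma_noise_sd(spec, w0)
  sde_post <- parenchyma_noise_sd(spec, w0 * (1 - clearance))

  with_seed(seed, {
    # narrow the aerated-parenchyma distribution with the cleared burden
    if (clearance > 0) {
      i0 <- paren$comp == 0L
      values[paren$idx[i0]] <- base + sde_post * paren$z[i0]

      ie <- which(paren$comp == 2L)
      n_clear <- round(clearance * length(ie))
      if (n_clear > 0) {
        cleared <- if (n_clear == length(ie)) ie else sample(ie, n_clear)
        nv <- length(cleared)
        to_vessel <- runif(nv) < spec$vessel_weight
        znew <- rnorm(nv)
        exnew <- rexp(nv) * spec$vessel_tail_hu
        hu_new <- base + sde_post * znew
        hu_new[to_vessel] <- base + exnew[to_vessel]
        values[paren$idx[cleared]] <- hu_new
        evlw[paren$idx[cleared]] <- FALSE
        paren$comp[cleared] <- ifelse(to_vessel, 1L, 0L)
        paren$z[cleared] <- znew
        afr[paren$idx[cleared]] <-
          ifelse(to_vessel, air_fraction_of_hu(hu_new), spec$lung_air_fraction)
      }
    }

    wall_new_mask <- truth$airway_wall_mask$mask
    tree_geom <- attr(truth$tree, "geometry")
    wall_post <- tree_geom$wall_mm
    if (wall_thinning > 0) {
      wall_post <- tree_geom$wall_mm * (1 - wall_thinning)
      tm <- render_tree_masks(tree_geom, shape, spacing, wall_mm = wall_post)
      wall_new_mask <- tm$wall
      converted <- which(truth$airway_wall_mask$mask & !wall_new_mask & !tm$lumen)
      if (length(converted) > 0) {
        in_lung <- truth$lung_region[converted]
        conv_lung <- converted[in_lung]
        if (length(conv_lung) > 0) {
          nv <- length(conv_lung)
          to_vessel <- runif(nv) < spec$vessel_weight
          znew <- rnorm(nv)
          exnew <- rexp(nv) * spec$vessel_tail_hu
          hu_new <- base + sde_post * znew
          hu_new[to_vessel] <- base + exnew[to_vessel]
          values[conv_lung] <- hu_new
          afr[conv_lung] <-
            ifelse(to_vessel, air_fraction_of_hu(hu_new), spec$lung_air_fraction)
          paren$idx <- c(paren$idx, conv_lung)
          paren$comp <- c(paren$comp, ifelse(to_vessel, 1L, 0L))
          paren$z <- c(paren$z, znew)
          truth$lung_mask$mask[conv_lung] <- TRUE
        }
        conv_body <- converted[!in_lung]
        if (length(conv_body) > 0) {
          values[conv_body] <- spec$body_hu
          afr[conv_body] <- 0
        }
      }
    }
  })

  tree_geom2 <- attr(truth$tree, "geometry")
  tree_geom2$wall_mm <- wall_post
  new_truth <- truth
  new_truth$airway_wall_mask <- region_mask(wall_new_mask, "airway_wall", spacing)
  new_truth$evlw_voxel_mask <- region_mask(evlw, "other", spacing)
  new_truth$true_air_fraction_map <- afr
  new_truth$paren <- paren
  new_truth$tree <- truth_airway_tree(tree_geom2, spacing)
  new_truth$applied <- list(clearance = clearance, wall_thinning = wall_thinning)

  list(volume = ct_volume(values, spacing), truth = new_truth)
}

#' Punch a one-voxel channel through an airway wall
#'
#' Test fixture for the leak detector of [segment_airway_tree()]: carves a
#' one-voxel-wide air channel radially through the wall of the first
#' segment of the given generation, connecting the lumen to the surrounding
#' parenchyma as a segmentation-leak defect.  Truth masks are left
#' untouched (the channel is a defect, not anatomy).
#'
#' @param volume,truth phantom volume and truth from [build_phantom()].
#' @param generation generation of the wall to breach.
#' @return list with the breached `volume` and the punched voxel indices.
#' @export
punch_wall_channel <- function(volume, truth, generation = 3) {
  geom <- attr(truth$tree, "geometry")
  seg <- geom[geom$generation == generation, ][1, ]
  if (is.na(seg$id)) stopf("no segment of generation %d in tree", generation)
  spacing <- volume$spacing
  p <- c(seg$x0, seg$y0, seg$z0) + 0.5 * seg$length_mm * c(seg$ux, seg$uy, seg$uz)
  u <- c(seg$ux, seg$uy, seg$uz)
  # radial directions orthogonal to the axis; pick one that ends in lung
  cand <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  dir <- NULL
  for (e in cand) {
    d <- e - sum(e * u) * u
    nd <- sqrt(sum(d^2))
    if (nd < 1e-6) next
    d <- d / nd
    endp <- p + d * (seg$radius_mm + seg$wall_mm + 2)
    iv <- round(endp / spacing + 0.5)
    if (all(iv >= 1) && all(iv <= dim(volume$values)) &&
        truth$lung_mask$mask[iv[1], iv[2], iv[3]]) { dir <- d; break }
  }
  if (is.null(dir)) dir <- cand[[1]] - sum(cand[[1]] * u) * u
  tt <- seq(seg$radius_mm - max(spacing), seg$radius_mm + seg$wall_mm + max(spacing),
            by = 0.25 * min(spacing))
  pts <- t(vapply(tt, function(s) round((p + s * dir) / spacing + 0.5), numeric(3)))
  # make the voxel chain 6-connected by inserting axis-wise steps
  chain <- list(pts[1, ])
  for (i in 2:nrow(pts)) {
    cur <- chain[[length(chain)]]
    nxt <- pts[i, ]
    while (any(cur != nxt)) {
      ax <- which(cur != nxt)[1]
      cur[ax] <- cur[ax] + sign(nxt[ax] - cur[ax])
      chain[[length(chain) + 1]] <- cur
    }
  }
  vox <- unique(do.call(rbind, chain))
  vox <- vox[apply(vox >= 1, 1, all) & apply(sweep(vox, 2, dim(volume$values), "<="), 1, all), , drop = FALSE]
  values <- volume$values
  values[vox] <- -1000
  list(volume = ct_volume(values, spacing), punched = vox)
}

#' Build a single-airway cylinder phantom
#'
#' A straight airway (lumen -1000 HU inside a wall) embedded in a uniform
#' parenchyma-like background - the analytic fixture for airway
#' measurement: the true luminal area is `pi * radius_mm^2` and the true
#' wall thickness `wall_mm`, at any axis orientation.
#'
#' @param radius_mm luminal radius, mm.
#' @param wall_mm wall thickness, mm.
#' @param spacing voxel spacing, mm (scalar or length 3).
#' @param length_mm cylinder length, mm.
#' @param axis direction of the cylinder axis (normalized internally).
#' @param background_hu HU of the surrounding parenchyma.
#' @param wall_hu HU of the wall.
#' @return list with `volume`, the true `centerline` (trimmed of the end
#'   caps), `radius_mm`, `wall_mm`.
#' @export
build_cylinder_phantom <- function(radius_mm, wall_mm, spacing = 0.5,
                                   length_mm = 40, axis = c(0, 0, 1),
                                   background_hu = -825, wall_hu = 30) {
  spacing <- rep3(spacing, "spacing")
  u <- axis / sqrt(sum(axis^2))
  marg <- radius_mm + wall_mm + 5
  ext_needed <- abs(u) * length_mm + 2 * marg
  shape <- as.integer(ceiling(ext_needed / spacing))
  ext <- shape * spacing
  p0 <- ext / 2 - u * length_mm / 2
  seg <- data.frame(x0 = p0[1], y0 = p0[2], z0 = p0[3],
                    ux = u[1], uy = u[2], uz = u[3],
                    length_mm = length_mm)
  lumen <- array(FALSE, shape)
  wall <- array(FALSE, shape)
  wall <- render_segment(wall, seg, radius_mm + wall_mm, spacing, cap_mm = wall_mm)
  lumen <- render_segment(lumen, seg, radius_mm, spacing, cap_mm = 0)
  wall <- wall & !lumen
  values <- array(background_hu, shape)
  values[wall] <- wall_hu
  values[lumen] <- -1000
  trim <- 0.15 * length_mm
  tt <- seq(trim, length_mm - trim, by = 1.5 * max(spacing))
  centerline <- cbind(p0[1] + tt * u[1], p0[2] + tt * u[2], p0[3] + tt * u[3])
  list(volume = ct_volume(values, spacing), centerline = centerline,
       radius_mm = radius_mm, wall_mm = wall_mm)
}

#' Draw a paired pre/post parenchymal attenuation sample
#'
#' Histogram-level fast path of the phantom generator: draws `n` voxels
#' from the parenchymal mixture of `spec` (no 3-D rendering) and, when
#' `clearance` is given, the matched post-bronchodilator values of the same
#' voxels under the clearance model of [apply_bronchodilator()].  Used for
#' cohort-scale simulation where only the attenuation histogram matters.
#'
#' @param spec a [phantom_spec()] (only the mixture fields are used).
#' @param n number of voxels.
#' @param clearance optional fraction of edema voxels cleared.
#' @param seed RNG seed.
#' @return list with numeric vectors `pre` and (if requested) `post`.
#' @export
sample_parenchyma_hu <- function(spec, n, clearance = NULL, seed = NULL) {
  base <- parenchyma_base_hu(spec)
  w <- spec$evlw_weight
  sde <- parenchyma_noise_sd(spec, w)
  out <- with_seed(seed, {
    u <- runif(n)
    z <- rnorm(n)
    ex <- rexp(n) * spec$vessel_tail_hu
    comp <- ifelse(u < w, 2L, ifelse(u < w + (1 - w) * spec$vessel_weight, 1L, 0L))
    pre <- base + sde * z
    pre[comp == 1L] <- base + ex[comp == 1L]
    pre[comp == 2L] <- spec$evlw_mean + spec$evlw_sd * z[comp == 2L]
    res <- list(pre = pre)
    if (!is.null(clearance)) {
      check_fraction(clearance, "clearance")
      sde_post <- parenchyma_noise_sd(spec, w * (1 - clearance))
      post <- pre
      i0 <- comp == 0L
      post[i0] <- base + sde_post * z[i0]
      ie <- which(comp == 2L)
      n_clear <- round(clearance * length(ie))
      if (n_clear > 0) {
        cleared <- if (n_clear == length(ie)) ie else sample(ie, n_clear)
        nv <- length(cleared)
        to_vessel <- runif(nv) < spec$vessel_weight
        hu_new <- base + sde_post * rnorm(nv)
        hu_new[to_vessel] <- base + (rexp(nv) * spec$vessel_tail_hu)[to_vessel]
        post[cleared] <- hu_new
      }
      res$post <- post
    }
    res
  })
  out
}
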