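#' Pipeline configuration
#'
#' All tunable thresholds of the per-subject pipeline in one validated
#' object.  Defaults follow the analysis conventions used throughout the
#' package: lung threshold -320 HU, analysis range -1000..0 HU, congestion
#' threshold -500 HU, six airway generations, Bonferroni across six
#' generation-level tests, alpha 0.05.
#'
#' @param lung_threshold_hu lung/soft-tissue segmentation threshold, HU.
#' @param congestion_threshold_hu congestion index threshold, HU.
#' @param hu_range inclusive analysis attenuation range, HU.
#' @param bin_width histogram bin width, HU.
#' @param grow_start,grow_stop,grow_step,leak_ratio airway region-growing
#'   schedule (see [segment_airway_tree()]).
#' @param max_generation deepest airway generation analysed.
#' @param alpha type-I error level.
#' @param bonferroni_m number of generation-level tests corrected across.
#' @param mean_convention percent-change convention for mean HU.
#' @param seed RNG seed for any stochastic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(lung_threshold_hu = -320,
                            congestion_threshold_hu = -500,
                            hu_range = c(-1000, 0),
                            bin_width = 1,
                            grow_start = -950, grow_stop = -500,
                            grow_step = 25, leak_ratio = 2,
                            max_generation = 6L,
                            alpha = 0.05, bonferroni_m = 6,
                            mean_convention = "magnitude",
                            seed = 1L) {
  cfg <- list(lung_threshold_hu = lung_threshold_hu,
              congestion_threshold_hu = congestion_threshold_hu,
              hu_range = hu_range, bin_width = bin_width,
              grow_start = grow_start, grow_stop = grow_stop,
              grow_step = grow_step, leak_ratio = leak_ratio,
              max_generation = as.integer(max_generation),
              alpha = alpha, bonferroni_m = bonferroni_m,
              mean_convention = mean_convention, seed = as.integer(seed))
  for (nm in c("lung_threshold_hu", "congestion_threshold_hu",
               "grow_start", "grow_stop"))
    if (cfg[[nm]] < -1024 || cfg[[nm]] > 3071)
      stopf("`%s` must be within [-1024, 3071] HU", nm)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stopf("`alpha` must be in (0, 1)")
  structure(cfg, class = "pipeline_config")
}

# one timepoint of the per-subject pipeline
analyse_timepoint <- function(volume, config, tlc) {
  lung <- segment_lung_fields(volume, threshold_hu = config$lung_threshold_hu)
  lumen <- segment_airway_tree(volume,
                               grow_start = config$grow_start,
                               grow_stop = config$grow_stop,
                               grow_step = config$grow_step,
                               leak_ratio = config$leak_ratio)
  analysis <- apply_analysis_exclusions(volume, lung, lumen,
                                        hu_range = config$hu_range)
  metrics <- compute_density_metrics(volume, analysis,
                                     bin_width = config$bin_width,
                                     congestion_threshold = config$congestion_threshold_hu)
  tree <- extract_centerline_tree(lumen)
  tree <- measure_airway_tree(volume, tree)
  airways <- normalize_to_subject(
    per_generation_summary(tree, max_generation = config$max_generation), tlc)
  list(metrics = metrics, airways = airways, tree = tree,
       exclusions = attr(analysis, "exclusions"))
}

#' Run the full pipeline for one subject
#'
#' Executes lung segmentation, airway segmentation and morphometry, and
#' density analysis for the baseline (and optionally post-bronchodilator)
#' volume of one subject.  A failing post-scan stage never invalidates the
#' baseline results: the error is recorded in `flags` and the paired
#' fields stay absent.
#'
#' @param pre baseline [ct_volume()] or NIfTI path.
#' @param post optional post-bronchodilator volume or path.
#' @param tlc total lung capacity, L.
#' @param spirometry named list of % predicted spirometry values.
#' @param config a [pipeline_config()].
#' @param subject_id,group identifiers for the record.
#' @return a [subject_record()].
#' @export
run_subject <- function(pre, post = NULL, tlc, spirometry = NULL,
                        config = pipeline_config(),
                        subject_id = "subject", group = "control") {
  load_vol <- function(v) if (inherits(v, "ct_volume")) v else read_volume(v)
  flags <- character()
  pre_res <- analyse_timepoint(load_vol(pre), config, tlc)
  post_res <- NULL
  if (!is.null(post)) {
    post_res <- tryCatch(analyse_timepoint(load_vol(post), config, tlc),
                         error = function(e) {
                           flags <<- c(flags, paste0("post: ", conditionMessage(e)))
                           NULL
                         })
  }
  subject_record(subject_id = subject_id, group = group, tlc = tlc,
                 spirometry = spirometry,
                 pre = pre_res$metrics, post = post_res$metrics,
                 pre_airways = pre_res$airways,
                 post_airways = post_res$airways,
                 flags = flags)
}

#' Run the pipeline for a cohort manifest
#'
#' Reads a cohort manifest (data frame or CSV path with columns
#' `subject_id`, `group`, `tlc`, the spirometry columns and `pre_path` /
#' `post_path` NIfTI paths), runs [run_subject()] for every row, builds
#' the study tables and optionally writes them as CSV.  Subjects whose
#' baseline volume is missing or fails are excluded with a log entry; the
#' run is deterministic given manifest and config.
#'
#' @param manifest data frame or CSV path.
#' @param config a [pipeline_config()].
#' @param out_dir if given, tables and the per-subject metric table are
#'   written here as CSV.
#' @return list with `records`, `tables`, `subject_table`, `log`.
#' @export
run_cohort <- function(manifest, config = pipeline_config(), out_dir = NULL) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group", "tlc", "pre_path") %in% names(manifest)))
    stopf("manifest needs columns subject_id, group, tlc, pre_path")
  for (g in unique(manifest$group))
    if (sum(manifest$group == g) < 2)
      stopf("need at least 2 subjects per group; group '%s' has %d",
            g, sum(manifest$group == g))
  log <- character()
  records <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    spir <- as.list(row[intersect(spiro_vars, names(row))])
    post <- if ("post_path" %in% names(row) && !is.na(row$post_path) &&
                nzchar(row$post_path) && file.exists(row$post_path)) row$post_path
    if (!file.exists(row$pre_path)) {
      log <- c(log, sprintf("excluded %s: missing baseline volume %s",
                            row$subject_id, row$pre_path))
      next
    }
    rec <- tryCatch(
      run_subject(row$pre_path, post, tlc = row$tlc, spirometry = spir,
                  config = config, subject_id = row$subject_id,
                  group = row$group),
      error = function(e) {
        log <<- c(log, sprintf("excluded %s: %s", row$subject_id,
                               conditionMessage(e)))
        NULL
      })
    if (!is.null(rec)) {
      records[[length(records) + 1L]] <- rec
      log <- c(log, sprintf("analysed %s (%s)%s", rec$subject_id, rec$group,
                            if (length(rec$flags)) paste0(" [", paste(rec$flags, collapse = "; "), "]")
                            else ""))
    }
  }
  if (length(records) == 0) stopf("no subjects could be analysed")
  tables <- build_study_tables(records, alpha = config$alpha,
                               bonferroni_m = config$bonferroni_m,
                               max_generation = config$max_generation)
  subject_table <- do.call(rbind, lapply(records, subject_record_row))
  out <- list(records = records, tables = tables,
              subject_table = subject_table, log = log)
  if (!is.null(out_dir)) write_cohort_results(out, out_dir)
  out
}

# flat one-row-per-subject-timepoint summary
subject_record_row <- function(r) {
  row_of <- function(time) {
    m <- r[[time]]
    if (is.null(m)) return(NULL)
    data.frame(subject_id = r$subject_id, group = r$group, timepoint = time,
               tlc = r$tlc, mean_hu = m$mean_hu, skewness = m$skewness,
               kurtosis = m$kurtosis, fwhm = m$fwhm,
               pct_gt_m500 = m$pct_gt_m500, v_air = m$v_air, v_tis = m$v_tis,
               n_voxels = m$n_voxels)
  }
  rbind(row_of("pre"), row_of("post"))
}

fmt_csv <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  df
}

write_cohort_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$tables))
    write.csv(fmt_csv(result$tables[[nm]]),
              file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
  write.csv(fmt_csv(result$subject_table),
            file.path(out_dir, "subjects.csv"), row.names = FALSE)
  writeLines(result$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Render a sampled cohort to NIfTI volumes and a manifest
#'
#' Builds the pre (and optionally post) phantom volume for every subject
#' of a [sample_cohort()] result, writes them as NIfTI under `dir` and
#' returns the manifest data frame (also written as `manifest.csv`) that
#' [run_cohort()] consumes.
#'
#' @param cohort a `cohort_sample`.
#' @param dir output directory.
#' @param bronchodilator also render the post-clearance volume?
#' @param ... phantom overrides per subject (e.g. a reduced `grid_shape`,
#'   `airway_generations`), passed to [phantom_spec_for_subject()].
#' @return the manifest data frame.
#' @export
write_cohort_phantoms <- function(cohort, dir, bronchodilator = TRUE, ...) {
  stopifnot(inherits(cohort, "cohort_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(nrow(cohort$subjects)), function(i) {
    s <- cohort$subjects[i, ]
    spec <- phantom_spec_for_subject(cohort, i, ...)
    ph <- build_phantom(spec)
    pre_path <- file.path(dir, paste0(s$subject_id, "_pre.nii.gz"))
    write_volume(ph$volume, pre_path)
    post_path <- NA_character_
    if (bronchodilator) {
      po <- apply_bronchodilator(ph$volume, ph$truth,
                                 clearance = s$clearance,
                                 wall_thinning = s$wall_thinning,
                                 seed = child_seed(s$seed, 1L))
      post_path <- file.path(dir, paste0(s$subject_id, "_post.nii.gz"))
      write_volume(po$volume, post_path)
    }
    data.frame(subject_id = s$subject_id, group = s$group, tlc = s$tlc,
               fvc_pct = s$fvc_pct, fev1_pct = s$fev1_pct,
               fef2575_pct = s$fef2575_pct, pef_pct = s$pef_pct,
               pre_path = pre_path, post_path = post_path,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Serialize an airway tree to JSON
#'
#' Writes the segment table (id, parent, generation, endpoints in mm,
#' radius/area and wall measurements) and centerlines to a JSON file.
#'
#' @param tree an [airway_tree()].
#' @param path output path.
#' @export
write_airway_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "airway_tree"))
  segs <- tree$segments
  nodes <- lapply(seq_len(nrow(segs)), function(i) {
    cl <- tree$centerlines[[i]]
    c(as.list(segs[i, ]),
      list(start_mm = unname(cl[1, ]), end_mm = unname(cl[nrow(cl), ])))
  })
  jsonlite::write_json(nodes, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_airway_tree_json
#' @param metrics a `density_metrics` object.
#' @export
write_density_metrics_json <- function(metrics, path) {
  stopifnot(inherits(metrics, "density_metrics"))
  jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
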