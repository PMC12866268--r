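#' Build and validate a pipeline run configuration
#'
#' A run processes a set of phantom cases (each an ICA-like and an MCA-like
#' tube), assembles the per-patient feature table, simulates a cohort and
#' runs the full statistical analysis. Configurations can come from a YAML
#' file (`read_run_config()`) or be built in code.
#'
#' @param cases list of cases; each case is
#'   `list(id =, mca = list(curve =, radius =), ica = list(curve =, radius =))`
#'   where `curve` is `list(kind =, params =)` and `radius` a
#'   [radius_profile()] argument list.
#' @param out_dir output directory.
#' @param cohort_n simulated cohort size.
#' @param spacing voxel spacing, mm.
#' @param threshold segmentation threshold (default: midway between
#'   background and vessel values).
#' @param step_mm,window centerline resampling parameters.
#' @param noise_sd phantom intensity noise.
#' @param seed master seed; every stage derives a named substream from it.
#' @param welch,profile_ci statistical flags.
#' @return A validated `vt_run_config`.
#' @export
run_config <- function(cases, out_dir, cohort_n = 213, spacing = c(0.4, 0.4, 0.4),
                       threshold = NULL, step_mm = 0.25, window = 5L,
                       noise_sd = 0, seed = 1L, welch = FALSE, profile_ci = FALSE) {
  if (!length(cases)) stop("config needs at least one case")
  for (cs in cases) {
    if (is.null(cs$id) || is.null(cs$mca) || is.null(cs$ica))
      stop("each case needs id, mca and ica entries")
  }
  structure(list(cases = cases, out_dir = out_dir, cohort_n = cohort_n,
                 spacing = rep_len(as.numeric(spacing), 3L),
                 threshold = threshold, step_mm = step_mm, window = as.integer(window),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 welch = welch, profile_ci = profile_ci),
            class = "vt_run_config")
}

#' @rdname run_config
#' @param path YAML configuration file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

build_phantom_pair <- function(cs, config) {
  mk <- function(part) {
    cv <- make_curve(part$curve$kind, part$curve$params)
    rp <- do.call(radius_profile, part$radius)
    tube_phantom(cv, rp, spacing = config$spacing, noise_sd = config$noise_sd)
  }
  list(mca = mk(cs$mca), ica = mk(cs$ica))
}

process_case <- function(cs, config, case_dir, seed) {
  dir.create(case_dir, recursive = TRUE, showWarnings = FALSE)
  ph <- build_phantom_pair(cs, config)
  segs <- list()
  for (part in c("ica", "mca")) {
    r <- rasterize(ph[[part]], seed = substream_seed(seed, paste0(part, ":", cs$id)))
    write_volume(r$volume, file.path(case_dir, paste0(part, ".nii.gz")))
    write_volume(r$mask, file.path(case_dir, paste0(part, "_truth_mask.nii.gz")))
    thr <- config$threshold %||%
      (ph[[part]]$background_value + ph[[part]]$vessel_value) / 2
    lm <- landmark_set(cca_bifurcation = r$landmarks_mm$start,
                       ica_bifurcation = r$landmarks_mm$end,
                       pre_occlusion = r$landmarks_mm$end + c(0, 0, 1e-3))
    mask <- segment_vessels(r$volume, thr)
    dmap <- distance_map(mask)
    cl <- extract_centerline(mask, dmap, r$landmarks_mm$start, r$landmarks_mm$end,
                             step_mm = config$step_mm, window = config$window)
    write_centerline(cl, file.path(case_dir, paste0(part, "_centerline.csv")))
    write_landmarks(lm, file.path(case_dir, paste0(part, ".mrk.json")))
    write.csv(r$truth, file.path(case_dir, paste0(part, "_truth_features.csv")),
              row.names = FALSE)
    segs[[part]] <- cl
  }
  build_feature_record(segs$ica, segs$mca, cs$id)
}

#' Execute the full phantom-to-analysis pipeline
#'
#' Stages: rasterize each case's tubes, write NIfTI volumes and ground-truth
#' masks, segment, extract centerlines, compute the per-patient feature
#' records; then simulate a cohort and run the full statistical analysis.
#' Per-case failures are logged and skipped (the run continues); reruns with
#' the same seed produce byte-identical outputs. A manifest listing every
#' output file with its MD5 checksum is written as `manifest.json`.
#'
#' @param config a `vt_run_config`.
#' @return The manifest, invisibly (also written to
#'   `file.path(config$out_dir, "manifest.json")`).
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "vt_run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  records <- list(); skipped <- list(); warnings_log <- character(0)
  for (cs in config$cases) {
    rec <- withCallingHandlers(
      tryCatch(process_case(cs, config, file.path(out, cs$id), seed),
               error = function(e) e),
      warning = function(w) {
        warnings_log <<- c(warnings_log, paste0(cs$id, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (inherits(rec, "error")) {
      skipped[[cs$id]] <- conditionMessage(rec)
    } else {
      records[[cs$id]] <- rec
    }
  }
  if (length(records)) {
    features <- do.call(rbind, c(records, list(make.row.names = FALSE)))
    write_feature_records(features, file.path(out, "features.csv"))
  }
  spec <- cohort_spec(n = config$cohort_n, seed = seed)
  cohort <- simulate_cohort(spec, seed = seed)
  write.csv(cohort, file.path(out, "cohort.csv"), row.names = FALSE)
  analysis <- run_full_analysis(cohort, welch = config$welch,
                                profile_ci = config$profile_ci)
  write_analysis(analysis, file.path(out, "analysis"))
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out, "manifest.json"))
  manifest <- list(
    config = list(n_cases = length(config$cases), cohort_n = config$cohort_n,
                  spacing = config$spacing, threshold = config$threshold,
                  step_mm = config$step_mm, window = config$window,
                  noise_sd = config$noise_sd, seed = seed,
                  welch = config$welch, profile_ci = config$profile_ci),
    version = as.character(utils::packageVersion("vasctort")),
    cases_processed = names(records),
    cases_skipped = skipped,
    warnings = warnings_log,
    files = lapply(setNames(files, substring(files, nchar(out) + 2)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
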