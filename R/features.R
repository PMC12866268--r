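#' Geodesic length of a centerline
#'
#' Length along the centerline trajectory: the sum of successive node
#' distances (equal to the final cumulative length).
#'
#' @param cl a `vt_centerline`.
#' @return Length in mm.
#' @export
geodesic_length <- function(cl) {
  stopifnot(inherits(cl, "vt_centerline"))
  cl$cum_length[length(cl$cum_length)]
}

#' Tortuosity index
#'
#' Ratio of geodesic length to the endpoint chord, minus one:
#' `TI = L / ||B - A|| - 1`, where A and B are the proximal and distal
#' endpoints. Dimensionless, zero for a straight segment, invariant under
#' rigid motion and uniform scaling.
#'
#' @param cl a `vt_centerline`.
#' @return TI (>= 0).
#' @export
#' @examples
#' semi <- centerline(t(sapply(seq(0, pi, length.out = 400),
#'                    function(a) c(10 * sin(a), 10 * (1 - cos(a)), 0))))
#' tortuosity_index(semi) # ~ pi/2 - 1
tortuosity_index <- function(cl) {
  stopifnot(inherits(cl, "vt_centerline"))
  if (cl$chord < 1e-6)
    stop("tortuosity index undefined: chord below tolerance (closed or recurrent path)")
  geodesic_length(cl) / cl$chord - 1
}

#' Bending length
#'
#' Maximal orthogonal distance between any centerline node and the infinite
#' axis through the two extremal points A and B. Zero for a straight segment;
#' scales linearly under uniform scaling.
#'
#' @param cl a `vt_centerline`.
#' @return Bending length in mm.
#' @export
bending_length <- function(cl) {
  stopifnot(inherits(cl, "vt_centerline"))
  if (cl$chord < 1e-6) stop("bending length undefined: chord axis degenerate")
  n <- nrow(cl$nodes)
  max_line_distance(cl$nodes, cl$nodes[1, ], cl$nodes[n, ])
}

#' Mean inscribed-sphere diameter along a centerline
#'
#' Arithmetic mean of twice the per-node maximal inscribed sphere radius.
#' Assumes uniformly resampled nodes (the output of [extract_centerline()]),
#' so node density does not bias the average.
#'
#' @param cl a `vt_centerline` with radii.
#' @return Mean diameter in mm.
#' @export
mean_diameter <- function(cl) {
  stopifnot(inherits(cl, "vt_centerline"))
  if (is.null(cl$radii)) stop("centerline has no radii")
  mean(2 * cl$radii)
}

#' Mean diameter over the distal segment end
#'
#' Mean inscribed-sphere diameter over the nodes whose cumulative geodesic
#' length lies within `window_mm` (default 10 mm) of the distal endpoint B —
#' the pre-occlusion landmark. Segments shorter than the window fall back to
#' the whole-segment mean with a warning.
#'
#' @param cl a `vt_centerline` with radii, distally anchored at the
#'   pre-occlusion point.
#' @param window_mm distal window length, mm.
#' @return Mean distal diameter in mm.
#' @export
diameter_at_occlusion <- function(cl, window_mm = 10) {
  stopifnot(inherits(cl, "vt_centerline"))
  if (is.null(cl$radii)) stop("centerline has no radii")
  total <- geodesic_length(cl)
  if (total < window_mm) {
    warning(sprintf(
      "segment (%.1f mm) shorter than the %g mm distal window; using whole segment",
      total, window_mm))
    return(mean(2 * cl$radii))
  }
  sel <- cl$cum_length >= total - window_mm
  mean(2 * cl$radii[sel])
}

#' Assemble the per-patient feature record
#'
#' Combines the ICA segment (common carotid bifurcation to ICA bifurcation)
#' and the MCA segment (ICA bifurcation to the pre-occlusion point) into the
#' six per-patient descriptors. The ICA contributes its tortuosity index
#' only; MCA length and bending length are reported in cm, diameters in mm.
#'
#' @param ica_centerline,mca_centerline `vt_centerline` objects (the MCA one
#'   must carry radii).
#' @param patient_id identifier string.
#' @return One-row data.frame with columns `patient_id`, `mca_length_cm`,
#'   `mca_bl_cm`, `mca_ti`, `mean_mca_diameter_mm`,
#'   `diameter_at_occlusion_mm`, `ica_ti`.
#' @export
build_feature_record <- function(ica_centerline, mca_centerline, patient_id) {
  stopifnot(inherits(ica_centerline, "vt_centerline"),
            inherits(mca_centerline, "vt_centerline"))
  data.frame(
    patient_id = as.character(patient_id),
    mca_length_cm = geodesic_length(mca_centerline) / 10,
    mca_bl_cm = bending_length(mca_centerline) / 10,
    mca_ti = tortuosity_index(mca_centerline),
    mean_mca_diameter_mm = mean_diameter(mca_centerline),
    diameter_at_occlusion_mm = diameter_at_occlusion(mca_centerline),
    ica_ti = tortuosity_index(ica_centerline),
    stringsAsFactors = FALSE
  )
}

feature_columns <- c("mca_length_cm", "mca_bl_cm", "mca_ti",
                     "mean_mca_diameter_mm", "diameter_at_occlusion_mm", "ica_ti")

#' Write / read per-patient feature records as CSV
#'
#' @param records data.frame of feature records ([build_feature_record()] rows).
#' @param path CSV path.
#' @return `path` invisibly (writer); the data.frame (reader).
#' @export
write_feature_records <- function(records, path) {
  stopifnot(all(c("patient_id", feature_columns) %in% names(records)))
  write.csv(records[, c("patient_id", feature_columns)], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_records
#' @export
read_feature_records <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, colClasses = c(patient_id = "character"))
}

#' Write / read a centerline as CSV
#'
#' Columns: `x_mm,y_mm,z_mm,radius_mm,cum_length_mm` (radius empty when absent).
#'
#' @param cl a `vt_centerline`.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `vt_centerline` (reader).
#' @export
write_centerline <- function(cl, path) {
  stopifnot(inherits(cl, "vt_centerline"))
  df <- data.frame(x_mm = cl$nodes[, 1], y_mm = cl$nodes[, 2], z_mm = cl$nodes[, 3],
                   radius_mm = if (is.null(cl$radii)) NA_real_ else cl$radii,
                   cum_length_mm = cl$cum_length)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centerline
#' @export
read_centerline <- function(path) {
  df <- read.csv(path)
  radii <- if (all(is.na(df$radius_mm))) NULL else df$radius_mm
  centerline(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]), radii)
}
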