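#' 3D scalar volume with physical geometry
#'
#' Minimal container for an angiographic volume or phantom: a 3D array plus
#' voxel spacing and world origin in mm. World coordinates follow
#' `world = origin + (index - 1) * spacing` with 1-based R indices on a
#' right-handed axis-aligned grid.
#'
#' @param values 3D numeric or logical array.
#' @param spacing voxel size per axis, mm (length 3, > 0).
#' @param origin world position of voxel (1,1,1), mm.
#' @return An object of class `vt_volume`.
#' @export
voxel_volume <- function(values, spacing = c(0.4, 0.4, 0.4), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (any(dim(values) < 1L)) stop("grid must be non-empty")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0 on all axes")
  structure(list(values = values, spacing = spacing, origin = rep_len(as.numeric(origin), 3L)),
            class = "vt_volume")
}

#' @export
print.vt_volume <- function(x, ...) {
  cat(sprintf("<vt_volume %s, spacing %s mm, origin %s mm, range [%g, %g]>\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

# world <-> continuous (1-based) index coordinates
world_to_index <- function(vol, xyz) {
  sweep(sweep(matrix(xyz, ncol = 3), 2, vol$origin), 2, vol$spacing, "/") + 1
}

index_to_world <- function(vol, ijk) {
  sweep(sweep(matrix(ijk, ncol = 3) - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

in_bounds <- function(vol, xyz) {
  idx <- world_to_index(vol, xyz)
  all(idx >= 1 - 1e-9) && all(sweep(idx, 2, dim(vol$values)) <= 1e-9)
}

#' Write a volume as NIfTI
#'
#' The affine is `diag(spacing)` with the origin in the translation column
#' (sform code 2).
#'
#' @param vol a `vt_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "vt_volume"))
  vals <- vol$values
  if (is.logical(vals)) storage.mode(vals) <- "integer"
  img <- RNifti::asNifti(vals)
  aff <- diag(4)
  diag(aff)[1:3] <- vol$spacing
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' Only axis-aligned affines (diagonal rotation part) are supported; spacing
#' and origin are taken from the stored xform.
#'
#' @param path NIfTI file path.
#' @return A `vt_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6)
    stop("only axis-aligned volumes are supported")
  voxel_volume(unclass(img)[, , , drop = FALSE], spacing = abs(diag(rot)),
               origin = aff[1:3, 4])
}

#' Landmark triple delimiting the two analysis segments
#'
#' @param cca_bifurcation,ica_bifurcation,pre_occlusion 3D world points, mm:
#'   the common carotid bifurcation, the intracranial ICA bifurcation, and the
#'   arterial end immediately proximal to the occlusion.
#' @return A `vt_landmarks` object.
#' @export
landmark_set <- function(cca_bifurcation, ica_bifurcation, pre_occlusion) {
  pts <- rbind(cca_bifurcation, ica_bifurcation, pre_occlusion)
  if (ncol(pts) != 3L) stop("landmarks must be 3D points")
  d <- stats::dist(pts)
  if (any(d < 1e-9)) stop("landmark points must be pairwise distinct")
  structure(list(cca_bifurcation = as.numeric(cca_bifurcation),
                 ica_bifurcation = as.numeric(ica_bifurcation),
                 pre_occlusion = as.numeric(pre_occlusion)),
            class = "vt_landmarks")
}

#' Read landmarks from Slicer markups JSON or CSV
#'
#' Accepts a 3D Slicer fiducial markups file (`.mrk.json`) whose control-point
#' labels contain `cca`, `ica` and `occl` (case-insensitive), or a CSV with
#' columns `label,x,y,z` in mm.
#'
#' @param path file path.
#' @return A `vt_landmarks` object.
#' @export
read_landmarks <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    cps <- doc$markups[[1]]$controlPoints
    labels <- vapply(cps, function(p) tolower(p$label), "")
    pos <- lapply(cps, function(p) as.numeric(unlist(p$position)))
  } else {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    labels <- tolower(tab$label)
    pos <- lapply(seq_len(nrow(tab)), function(i) as.numeric(tab[i, c("x", "y", "z")]))
  }
  pick <- function(pat) {
    hit <- grep(pat, labels)
    if (length(hit) != 1L) stop("expected exactly one landmark matching '", pat, "'")
    pos[[hit]]
  }
  landmark_set(cca_bifurcation = pick("cca"),
               ica_bifurcation = pick("ica"),
               pre_occlusion = pick("occl"))
}

#' Write landmarks as a Slicer fiducial markups JSON
#'
#' @param lm a `vt_landmarks` object.
#' @param path output path (conventionally `.mrk.json`).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "vt_landmarks"))
  cp <- function(label, p) list(label = label, position = as.numeric(p))
  doc <- list(markups = list(list(
    type = "Fiducial",
    coordinateSystem = "LPS",
    controlPoints = list(cp("cca_bifurcation", lm$cca_bifurcation),
                         cp("ica_bifurcation", lm$ica_bifurcation),
                         cp("pre_occlusion", lm$pre_occlusion))
  )))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
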