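#' Tube phantom specification
#'
#' A synthetic vessel: a parametric center curve swept by a radius profile,
#' rasterized onto an isotropic-or-anisotropic voxel grid. Stands in for a
#' contrast-filled artery on CT angiography; intensity is a constant vessel
#' value over a constant background, optionally with additive Gaussian noise.
#'
#' @param curve a `vt_curve`.
#' @param radius a `vt_radius_profile`.
#' @param spacing voxel size per axis, mm (default 0.4 isotropic, the working
#'   resolution of clinical CTA reconstructions).
#' @param margin padding around the tube, mm.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param vessel_value,background_value intensities of lumen and background.
#' @return A `vt_phantom` object.
#' @export
tube_phantom <- function(curve, radius, spacing = c(0.4, 0.4, 0.4), margin = 4,
                         noise_sd = 0, vessel_value = 200, background_value = 0) {
  stopifnot(inherits(curve, "vt_curve"), inherits(radius, "vt_radius_profile"))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0 on all axes")
  if (margin < 0) stop("margin must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(curve = curve, radius = radius, spacing = spacing,
                 margin = margin, noise_sd = noise_sd,
                 vessel_value = vessel_value, background_value = background_value),
            class = "vt_phantom")
}

#' Rasterize a tube phantom into a voxel volume
#'
#' A voxel is foreground iff its center lies within the local radius of the
#' center curve (point-in-tube test against a dense curve sampling, step
#' `min(spacing)/4`). No anti-aliasing is applied, so the companion mask is an
#' exact, reproducible oracle for segmentation. Noise (if any) is drawn from
#' the `"rasterize"` substream of `seed`.
#'
#' @param phantom a `vt_phantom`.
#' @param seed master seed used when `noise_sd > 0`.
#' @return A list with `volume` (intensities, `vt_volume`), `mask`
#'   (ground-truth logical `vt_volume`), `truth` (analytic features,
#'   see [analytic_features()]), and `landmarks_mm` (curve endpoints).
#' @export
#' @examples
#' ph <- tube_phantom(make_curve("straight", list(length = 30)),
#'                    radius_profile("constant", value = 1.5))
#' r <- rasterize(ph)
#' sum(r$mask$values) * prod(r$mask$spacing) # ~ pi * 1.5^2 * 30
rasterize <- function(phantom, seed = 1L) {
  stopifnot(inherits(phantom, "vt_phantom"))
  cv <- phantom$curve
  L <- curve_arc_length(cv)
  step <- min(phantom$spacing) / 4
  n_dense <- max(51L, ceiling(L / step) + 1L)
  # resample uniformly in arc length so radius lookup by normalized s is exact
  tg <- seq(0, cv$t_max, length.out = 4L * n_dense)
  pts0 <- cv$fun(tg)
  seg <- sqrt(rowSums((pts0[-1, , drop = FALSE] - pts0[-nrow(pts0), , drop = FALSE])^2))
  al <- c(0, cumsum(seg))
  s_tgt <- seq(0, al[length(al)], length.out = n_dense)
  pts <- cbind(approx(al, pts0[, 1], xout = s_tgt)$y,
               approx(al, pts0[, 2], xout = s_tgt)$y,
               approx(al, pts0[, 3], xout = s_tgt)$y)
  radii <- phantom$radius$r(s_tgt / max(s_tgt))
  if (any(radii <= 0)) stop("radius profile must be positive everywhere")
  if (max(2 * radii) < max(phantom$spacing)) {
    warning("tube thinner than one voxel everywhere; refusing to rasterize")
    stop("unresolvable phantom: tube diameter below voxel size")
  }
  pad <- max(radii) + phantom$margin
  # shift the grid by an irrational sub-voxel fraction: axis-aligned phantoms
  # would otherwise sit in measure-zero alignment with voxel centers, making
  # partial-volume errors alignment artifacts rather than generic O(spacing)
  lo <- apply(pts, 2, min) - pad - 0.381966011 * phantom$spacing
  hi <- apply(pts, 2, max) + pad
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / phantom$spacing)) + 1L)
  maskv <- .rasterize_tube(pts, radii, dims, phantom$spacing, lo)
  mask <- array(maskv, dim = dims)
  # clip the hemispherical caps the ball-union test grows past the endpoints:
  # the tube ends flat on the planes normal to the end tangents, so a straight
  # phantom is a true cylinder of volume pi r^2 L
  tan_a <- pts[2, ] - pts[1, ]; tan_a <- tan_a / vnorm(tan_a)
  tan_b <- pts[nrow(pts), ] - pts[nrow(pts) - 1, ]; tan_b <- tan_b / vnorm(tan_b)
  ax <- lo[1] + (seq_len(dims[1]) - 1) * phantom$spacing[1]
  ay <- lo[2] + (seq_len(dims[2]) - 1) * phantom$spacing[2]
  az <- lo[3] + (seq_len(dims[3]) - 1) * phantom$spacing[3]
  a <- pts[1, ]; b <- pts[nrow(pts), ]
  proj_a <- outer(outer((ax - a[1]) * tan_a[1], (ay - a[2]) * tan_a[2], "+"),
                  (az - a[3]) * tan_a[3], "+")
  proj_b <- outer(outer((ax - b[1]) * tan_b[1], (ay - b[2]) * tan_b[2], "+"),
                  (az - b[3]) * tan_b[3], "+")
  mask[proj_a < 0 | proj_b > 0] <- FALSE
  vals <- array(phantom$background_value, dim = dims)
  vals[mask] <- phantom$vessel_value
  if (phantom$noise_sd > 0) {
    noise <- with_seed(substream_seed(seed, "rasterize"),
                       rnorm(length(vals), 0, phantom$noise_sd))
    vals <- vals + array(noise, dim = dims)
  }
  list(
    volume = voxel_volume(vals, spacing = phantom$spacing, origin = lo),
    mask = voxel_volume(mask, spacing = phantom$spacing, origin = lo),
    truth = analytic_features(cv, phantom$radius),
    landmarks_mm = list(start = pts[1, ], end = pts[nrow(pts), ])
  )
}
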