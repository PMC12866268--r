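#' Threshold-based vessel segmentation
#'
#' Segments the lumen by intensity thresholding followed by 26-connected
#' component selection. On contrast-filled phantoms a midway threshold
#' recovers the exact rasterized tube; on noisy volumes it approximates it.
#' When landmarks are given, only components reachable from a landmark (its
#' containing voxel, or the nearest foreground voxel within `snap_mm`) are
#' kept; otherwise the largest component is kept.
#'
#' @param volume a `vt_volume`.
#' @param threshold intensity threshold; voxels `>= threshold` are foreground.
#' @param landmarks optional `vt_landmarks`.
#' @param snap_mm landmark-to-component search radius, mm.
#' @return A logical `vt_volume` mask with attributes `n_components` (count
#'   before selection) and `n_kept`.
#' @export
segment_vessels <- function(volume, threshold, landmarks = NULL, snap_mm = 3) {
  stopifnot(inherits(volume, "vt_volume"))
  fg <- volume$values >= threshold
  if (!any(fg)) stop("empty mask: no voxel reaches the threshold")
  lab_v <- .cc_label(as.vector(fg), dim(fg))
  ncomp <- attr(lab_v, "n_components")
  lab <- array(lab_v, dim = dim(fg))
  if (is.null(landmarks)) {
    keep <- which.max(tabulate(lab[lab > 0]))
  } else {
    keep <- integer(0)
    for (nm in c("cca_bifurcation", "ica_bifurcation", "pre_occlusion")) {
      p <- landmarks[[nm]]
      vox <- snap_to_mask(fg, volume, p, snap_mm = snap_mm)
      if (is.null(vox))
        stop("landmark '", nm, "' lies outside every segmented component")
      keep <- union(keep, lab[vox[1], vox[2], vox[3]])
    }
  }
  mask <- array(lab %in% keep & fg, dim = dim(fg))
  out <- voxel_volume(mask, spacing = volume$spacing, origin = volume$origin)
  attr(out, "n_components") <- ncomp
  attr(out, "n_kept") <- length(keep)
  out
}

# nearest foreground voxel (1-based ijk) within snap_mm of world point p,
# or NULL
snap_to_mask <- function(fg, vol, p, snap_mm = 3) {
  idx <- world_to_index(vol, p)[1, ]
  dims <- dim(fg)
  r_vox <- ceiling(snap_mm / vol$spacing)
  lo <- pmax(1, floor(idx - r_vox))
  hi <- pmin(dims, ceiling(idx + r_vox))
  if (any(lo > hi)) return(NULL)
  sub <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
  on <- fg[cbind(sub$i, sub$j, sub$k)]
  if (!any(on)) return(NULL)
  sub <- sub[on, , drop = FALSE]
  w <- index_to_world(vol, as.matrix(sub))
  d <- sqrt(colSums((t(w) - p)^2))
  if (min(d) > snap_mm) return(NULL)
  as.integer(sub[which.min(d), ])
}

#' Anisotropy-aware Euclidean distance transform
#'
#' Exact Euclidean distance (mm) from each foreground voxel center to the
#' nearest background voxel center, honoring per-axis spacing; zero outside
#' the mask. At a centerline node this is the maximal inscribed sphere radius
#' up to voxelization error.
#'
#' @param mask a logical `vt_volume` (e.g. from [segment_vessels()]).
#' @return A `vt_volume` of distances in mm.
#' @export
distance_map <- function(mask) {
  stopifnot(inherits(mask, "vt_volume"))
  m <- mask$values
  if (!is.logical(m)) m <- m > 0
  if (!any(m)) stop("mask is empty")
  if (all(m)) stop("mask has no background; distances undefined")
  d <- .edt3d(as.vector(m), dim(m), mask$spacing)
  voxel_volume(array(d, dim = dim(m)), spacing = mask$spacing, origin = mask$origin)
}

#' Ordered centerline with inscribed-sphere radii
#'
#' @param nodes n x 3 matrix of world points, mm; first row is the proximal
#'   endpoint A, last row the distal endpoint B.
#' @param radii optional per-node maximal inscribed sphere radius, mm.
#' @return A `vt_centerline` with `nodes`, `radii`, `cum_length` (mm, from 0)
#'   and `chord` (mm).
#' @export
centerline <- function(nodes, radii = NULL) {
  nodes <- as.matrix(nodes)
  if (nrow(nodes) < 2L || ncol(nodes) != 3L)
    stop("centerline needs at least two 3D nodes")
  seg <- sqrt(rowSums((nodes[-1, , drop = FALSE] - nodes[-nrow(nodes), , drop = FALSE])^2))
  if (any(seg <= 0)) stop("cum_length must be strictly increasing (duplicate nodes)")
  if (!is.null(radii)) {
    if (length(radii) != nrow(nodes)) stop("one radius per node required")
    if (any(radii <= 0)) stop("radii must be > 0")
  }
  structure(list(nodes = unname(nodes), radii = radii,
                 cum_length = c(0, cumsum(seg)),
                 chord = vnorm(nodes[nrow(nodes), ] - nodes[1, ])),
            class = "vt_centerline")
}

#' @export
print.vt_centerline <- function(x, ...) {
  cat(sprintf("<vt_centerline: %d nodes, length %.2f mm, chord %.2f mm%s>\n",
              nrow(x$nodes), geodesic_length(x), x$chord,
              if (is.null(x$radii)) "" else
                sprintf(", mean diameter %.2f mm", mean(2 * x$radii))))
  invisible(x)
}

# trilinear interpolation of a volume at world points (n x 3)
trilinear <- function(vol, xyz) {
  idx <- world_to_index(vol, xyz)
  dims <- dim(vol$values)
  out <- numeric(nrow(idx))
  for (n in seq_len(nrow(idx))) {
    p <- pmin(pmax(idx[n, ], 1), dims)
    i0 <- pmin(floor(p), dims - 1)
    f <- p - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
           (if (dz) f[3] else 1 - f[3])
      acc <- acc + w * vol$values[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    out[n] <- acc
  }
  out
}

#' Extract a landmark-delimited centerline from a segmented volume
#'
#' Finds the centrality-weighted minimal-cost path between two landmarks over
#' the 26-connected foreground voxel graph; the edge cost is the step length
#' divided by `(d + eps)` where `d` is the distance-map value at the target
#' voxel, so the optimum hugs the lumen center. The raw voxel path is then
#' smoothed and resampled ([resample_smooth()]) and per-node radii are
#' assigned by trilinear sampling of the distance map.
#'
#' Landmarks snap to the nearest foreground voxel within `snap_mm`; failing
#' that, to the nearest distance-map local maximum within `snap_far_mm`.
#'
#' @param mask logical `vt_volume` from [segment_vessels()].
#' @param dmap distance map from [distance_map()] (computed if missing).
#' @param start_point,end_point world points, mm (A proximal, B distal).
#' @param eps centrality regularizer, mm (default 0.1).
#' @param step_mm resampling step, mm.
#' @param window smoothing window in nodes.
#' @param snap_mm,snap_far_mm landmark snap radii, mm.
#' @return A `vt_centerline` with radii.
#' @export
extract_centerline <- function(mask, dmap = NULL, start_point, end_point,
                               eps = 0.1, step_mm = 0.25, window = 5L,
                               snap_mm = 3, snap_far_mm = 5) {
  stopifnot(inherits(mask, "vt_volume"))
  if (vnorm(start_point - end_point) < 1e-9)
    stop("start and end landmarks coincide")
  m <- mask$values
  if (!is.logical(m)) m <- m > 0
  if (is.null(dmap)) dmap <- distance_map(mask)
  snap <- function(p, label) {
    v <- snap_to_mask(m, mask, p, snap_mm = snap_mm)
    if (!is.null(v)) return(v)
    v <- snap_to_dmap_max(dmap, p, snap_far_mm)
    if (!is.null(v)) return(v)
    stop("landmark '", label, "' could not be snapped to the vessel mask")
  }
  a <- snap(start_point, "start")
  b <- snap(end_point, "end")
  dims <- dim(m)
  lin <- function(v) (v[3] - 1) * dims[1] * dims[2] + (v[2] - 1) * dims[1] + (v[1] - 1)
  path <- .center_path(as.vector(m), as.vector(dmap$values), dims, mask$spacing,
                       lin(a), lin(b), eps)
  if (!length(path)) stop("endpoints lie in disconnected components of the mask")
  k <- path - 1L
  ijk <- cbind(k %% dims[1], (k %/% dims[1]) %% dims[2], k %/% (dims[1] * dims[2])) + 1
  nodes <- index_to_world(mask, ijk)
  # the landmarks are the true segment endpoints A and B; the voxel path only
  # reaches their containing voxel centers, so anchor the ends exactly
  if (vnorm(nodes[1, ] - start_point) > 1e-9)
    nodes <- rbind(start_point, nodes)
  if (vnorm(nodes[nrow(nodes), ] - end_point) > 1e-9)
    nodes <- rbind(nodes, end_point)
  cl <- centerline(nodes)
  cl <- resample_smooth(cl, step_mm = step_mm, window = window)
  radii <- trilinear(dmap, cl$nodes)
  radii <- pmax(radii, min(mask$spacing) / 4) # clamp boundary-snapped endpoints
  centerline(cl$nodes, radii)
}

# nearest local maximum of the distance map within search_mm of p
snap_to_dmap_max <- function(dmap, p, search_mm) {
  vox <- snap_to_mask(dmap$values > 0, dmap, p, snap_mm = search_mm)
  if (is.null(vox)) return(NULL)
  # hill-climb from the nearest foreground voxel
  dims <- dim(dmap$values)
  cur <- vox
  repeat {
    lo <- pmax(1, cur - 1); hi <- pmin(dims, cur + 1)
    nb <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    vals <- dmap$values[nb]
    best <- nb[which.max(vals), ]
    if (all(best == cur)) break
    cur <- as.integer(best)
  }
  if (vnorm(index_to_world(dmap, matrix(cur, 1))[1, ] - p) > search_mm) return(NULL)
  cur
}

#' Smooth and uniformly resample a centerline
#'
#' Moving-average smoothing of interior nodes (endpoints preserved exactly)
#' followed by arc-length resampling at a fixed step; stabilizes length and
#' bending-length estimates against voxel-grid jitter.
#'
#' @param cl a `vt_centerline`.
#' @param step_mm resampling step, mm (> 0); default 0.25.
#' @param window moving-average window in nodes (odd; default 5). `window <= 1`
#'   disables smoothing.
#' @return A resampled `vt_centerline` (radii, if present, are interpolated).
#' @export
resample_smooth <- function(cl, step_mm = 0.25, window = 5L) {
  stopifnot(inherits(cl, "vt_centerline"))
  if (step_mm <= 0) stop("step_mm must be > 0")
  nodes <- cl$nodes
  n <- nrow(nodes)
  if (window > 1L && n > 2L) {
    half <- floor(window / 2)
    sm <- nodes
    for (i in 2:(n - 1)) {
      j <- max(1, i - half):min(n, i + half)
      sm[i, ] <- colMeans(nodes[j, , drop = FALSE])
    }
    nodes <- sm
  }
  seg <- sqrt(rowSums((nodes[-1, , drop = FALSE] - nodes[-n, , drop = FALSE])^2))
  keep <- c(TRUE, seg > 1e-12)
  nodes <- nodes[keep, , drop = FALSE]
  radii <- if (is.null(cl$radii)) NULL else cl$radii[keep]
  n <- nrow(nodes)
  seg <- sqrt(rowSums((nodes[-1, , drop = FALSE] - nodes[-n, , drop = FALSE])^2))
  al <- c(0, cumsum(seg))
  total <- al[n]
  if (step_mm >= total) {
    warning("resampling step exceeds centerline length; keeping endpoints only")
    return(centerline(nodes[c(1, n), , drop = FALSE],
                      if (is.null(radii)) NULL else radii[c(1, n)]))
  }
  s <- seq(0, total, by = step_mm)
  if (total - s[length(s)] > 1e-9) s <- c(s, total) else s[length(s)] <- total
  res <- cbind(approx(al, nodes[, 1], xout = s)$y,
               approx(al, nodes[, 2], xout = s)$y,
               approx(al, nodes[, 3], xout = s)$y)
  res[1, ] <- nodes[1, ]; res[nrow(res), ] <- nodes[n, ]
  rres <- if (is.null(radii)) NULL else approx(al, radii, xout = s)$y
  centerline(res, rres)
}
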