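#' Parametric center curves for vessel phantoms
#'
#' Builds a densely sampled 3D parametric curve used as the centerline of a
#' synthetic vessel. Supported kinds:
#' \describe{
#'   \item{straight}{`length` (mm); optional unit `direction` (default +x) and
#'     `origin`.}
#'   \item{arc}{planar circular arc with `radius` (mm) and `sweep` (radians);
#'     starts at the origin with tangent +x, bending towards +y.}
#'   \item{helix}{`radius` (mm), `pitch` (axial advance in mm per radian) and
#'     `sweep` (radians) around the +z axis.}
#'   \item{sinusoid}{`amplitude` (mm), `period` (mm) and `extent` (mm) along
#'     +x, displaced in +y.}
#'   \item{composite}{`components`: a list of curve specs
#'     (`list(kind=, params=)`) joined end to end by translation.}
#' }
#'
#' @param kind curve kind, one of `"straight"`, `"arc"`, `"helix"`,
#'   `"sinusoid"`, `"composite"`.
#' @param params named list of kind-specific parameters (see Details).
#' @param n_samples number of samples of the parameter grid (>= 2).
#' @return An object of class `vt_curve`: the sampled `points` (n x 3, mm),
#'   the parameter grid `t`, cumulative arc length `arclen`, and a generator
#'   closure `fun` for re-evaluation at arbitrary parameter values.
#' @export
#' @examples
#' cv <- make_curve("arc", list(radius = 10, sweep = pi))
#' curve_chord_length(cv) # 20, the diameter
make_curve <- function(kind, params = list(), n_samples = 2001L) {
  stopifnot(is.list(params))
  if (n_samples < 2L) stop("n_samples must be >= 2")
  kind <- match.arg(kind, c("straight", "arc", "helix", "sinusoid", "composite"))
  fun <- switch(kind,
    straight = {
      len <- params$length
      if (is.null(len) || len <= 0) stop("straight curve needs length > 0")
      dir <- params$direction %||% c(1, 0, 0)
      if (vnorm(dir) == 0) stop("direction must be non-zero")
      dir <- dir / vnorm(dir)
      org <- params$origin %||% c(0, 0, 0)
      t_max <- len
      function(t) cbind(org[1] + t * dir[1], org[2] + t * dir[2], org[3] + t * dir[3])
    },
    arc = {
      r <- params$radius
      sweep <- params$sweep
      if (is.null(r) || r <= 0) stop("arc needs radius > 0")
      if (is.null(sweep) || sweep <= 0 || sweep > 2 * pi + 1e-12)
        stop("arc sweep must be in (0, 2*pi]")
      t_max <- sweep
      function(t) cbind(r * sin(t), r * (1 - cos(t)), 0)
    },
    helix = {
      r <- params$radius
      pitch <- params$pitch
      sweep <- params$sweep
      if (is.null(r) || r <= 0) stop("helix needs radius > 0")
      if (is.null(pitch) || pitch <= 0) stop("helix needs pitch > 0 (mm/radian)")
      if (is.null(sweep) || sweep <= 0) stop("helix needs sweep > 0")
      t_max <- sweep
      function(t) cbind(r * (cos(t) - 1), r * sin(t), pitch * t)
    },
    sinusoid = {
      amp <- params$amplitude
      per <- params$period
      ext <- params$extent %||% params$period
      if (is.null(amp) || amp < 0) stop("sinusoid needs amplitude >= 0")
      if (is.null(per) || per <= 0) stop("sinusoid needs period > 0")
      if (ext <= 0) stop("sinusoid needs extent > 0")
      t_max <- ext
      function(t) cbind(t, amp * sin(2 * pi * t / per), 0)
    },
    composite = {
      comps <- params$components
      if (is.null(comps) || !length(comps)) stop("composite needs components")
      subs <- lapply(comps, function(cc)
        make_curve(cc$kind, cc$params, n_samples = max(101L, n_samples %/% length(comps))))
      lens <- vapply(subs, function(s) s$t_max, 0)
      offs <- cumsum(c(0, lens[-length(lens)]))
      t_max <- sum(lens)
      function(t) {
        out <- matrix(0, length(t), 3)
        shift <- c(0, 0, 0)
        for (i in seq_along(subs)) {
          sel <- t >= offs[i] - 1e-12 & t <= offs[i] + lens[i] + 1e-12
          p0 <- subs[[i]]$fun(0)[1, ]
          if (any(sel)) {
            loc <- pmin(pmax(t[sel] - offs[i], 0), lens[i])
            out[sel, ] <- sweep(subs[[i]]$fun(loc), 2, p0 - shift)
          }
          pe <- subs[[i]]$fun(lens[i])[1, ]
          shift <- shift + (pe - p0)
        }
        out
      }
    }
  )
  t_max <- environment(fun)$t_max
  tg <- seq(0, t_max, length.out = n_samples)
  pts <- fun(tg)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  structure(
    list(kind = kind, params = params, t = tg, t_max = t_max,
         points = pts, arclen = c(0, cumsum(seg)), fun = fun),
    class = "vt_curve"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vt_curve <- function(x, ...) {
  cat(sprintf("<vt_curve: %s, %d samples, arc length %.3f mm, chord %.3f mm>\n",
              x$kind, length(x$t), curve_arc_length(x), curve_chord_length(x)))
  invisible(x)
}

#' Arc length of a sampled curve
#' @param curve a `vt_curve`.
#' @return Total arc length in mm (dense polygonal approximation).
#' @export
curve_arc_length <- function(curve) curve$arclen[length(curve$arclen)]

#' Chord length of a curve (endpoint separation)
#' @param curve a `vt_curve`.
#' @return Euclidean distance between the curve endpoints in mm.
#' @export
curve_chord_length <- function(curve) {
  vnorm(curve$points[nrow(curve$points), ] - curve$points[1, ])
}

#' Vessel radius profile along a centerline
#'
#' Radius in mm as a function of normalized arc length u in \[0, 1\].
#'
#' @param mode `"constant"`, `"linear_taper"` or `"piecewise"`.
#' @param value radius for `"constant"` (mm).
#' @param from,to endpoint radii for `"linear_taper"` (mm).
#' @param breaks,values knots for `"piecewise"` (u in \[0,1\] and radii, mm);
#'   interpolated linearly.
#' @return A `vt_radius_profile` with a quantile-style accessor `r(u)`.
#' @export
radius_profile <- function(mode = c("constant", "linear_taper", "piecewise"),
                           value = NULL, from = NULL, to = NULL,
                           breaks = NULL, values = NULL) {
  mode <- match.arg(mode)
  r <- switch(mode,
    constant = {
      if (is.null(value) || value <= 0) stop("constant profile needs value > 0")
      function(u) rep(value, length(u))
    },
    linear_taper = {
      if (is.null(from) || is.null(to) || from <= 0 || to <= 0)
        stop("linear_taper needs from > 0 and to > 0")
      function(u) from + (to - from) * u
    },
    piecewise = {
      if (is.null(breaks) || is.null(values) || length(breaks) != length(values))
        stop("piecewise needs matching breaks and values")
      if (any(values <= 0)) stop("radii must be > 0")
      if (is.unsorted(breaks)) stop("breaks must be non-decreasing")
      function(u) approx(breaks, values, xout = pmin(pmax(u, 0), 1), rule = 2)$y
    }
  )
  structure(list(mode = mode, r = r), class = "vt_radius_profile")
}

#' Analytic ground-truth features of a parametric vessel
#'
#' Computes, by dense numerical quadrature on the continuous curve, the same
#' descriptors the image pipeline estimates: geodesic (arc) length, chord
#' length, tortuosity index (arc/chord - 1), bending length (maximal
#' orthogonal distance to the chord axis), mean inscribed diameter and the
#' mean diameter over the distal 10 mm. These serve as the oracle against
#' which the voxel pipeline is validated.
#'
#' @param curve a `vt_curve`.
#' @param radius a `vt_radius_profile` (optional; diameters are `NA` without it).
#' @param n_dense number of dense samples for quadrature/maximization.
#' @return A one-row data.frame of class `vt_truth` with columns
#'   `geodesic_length_mm`, `chord_length_mm`, `tortuosity_index`,
#'   `bending_length_mm`, `mean_diameter_mm`, `distal_10mm_mean_diameter_mm`.
#' @export
#' @examples
#' analytic_features(make_curve("arc", list(radius = 10, sweep = pi)),
#'                   radius_profile("constant", value = 1.5))
analytic_features <- function(curve, radius = NULL, n_dense = 100001L) {
  stopifnot(inherits(curve, "vt_curve"))
  tg <- seq(0, curve$t_max, length.out = n_dense)
  pts <- curve$fun(tg)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  arclen <- c(0, cumsum(seg))
  L <- arclen[n_dense]
  a <- pts[1, ]; b <- pts[n_dense, ]
  chord <- vnorm(b - a)
  if (chord < 1e-6)
    stop("tortuosity index undefined: chord length below tolerance (closed curve)")
  ti <- L / chord - 1
  bl <- max_line_distance(pts, a, b)
  mean_d <- distal_d <- NA_real_
  if (!is.null(radius)) {
    stopifnot(inherits(radius, "vt_radius_profile"))
    # average on a uniform grid in normalized arc length, so parameterization
    # speed cannot bias the mean
    u <- seq(0, 1, length.out = n_dense)
    rr <- radius$r(u)
    if (any(rr <= 0)) stop("radius profile must be positive everywhere")
    mean_d <- mean(2 * rr)
    distal <- u >= (L - min(10, L)) / L
    distal_d <- mean(2 * rr[distal])
  }
  structure(
    data.frame(geodesic_length_mm = L, chord_length_mm = chord,
               tortuosity_index = ti, bending_length_mm = bl,
               mean_diameter_mm = mean_d, distal_10mm_mean_diameter_mm = distal_d),
    class = c("vt_truth", "data.frame")
  )
}
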