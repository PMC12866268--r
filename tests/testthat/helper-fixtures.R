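# Shared phantom fixtures, built once per test run and memoised.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# straight cylinder: length 30 mm, radius 1.5 mm, 0.4 mm voxels, noiseless
fx_cylinder <- function() fx("cylinder", function() {
  rasterize(tube_phantom(make_curve("straight", list(length = 30)),
                         radius_profile("constant", value = 1.5)))
})

# semicircular arc: radius 10 mm, tube radius 1.5 mm, 0.4 mm voxels
fx_semicircle <- function() fx("semicircle", function() {
  rasterize(tube_phantom(make_curve("arc", list(radius = 10, sweep = pi)),
                         radius_profile("constant", value = 1.5)))
})

# default cohort spec at the published sample size (calibration is cached
# inside the package, but memoise the object too)
fx_spec213 <- function() fx("spec213", function() cohort_spec(n = 213, seed = 1))

# extract a centerline end-to-end from a rasterized phantom
extract_from <- function(r, threshold = 100, ...) {
  mask <- segment_vessels(r$volume, threshold)
  extract_centerline(mask, distance_map(mask),
                     r$landmarks_mm$start, r$landmarks_mm$end, ...)
}

# analytic semicircle polyline (no voxels involved)
semi_polyline <- function(r = 10, n = 801) {
  th <- seq(0, pi, length.out = n)
  centerline(cbind(r * sin(th), r * (1 - cos(th)), 0))
}

# random rigid motion: rotation matrix from QR of a Gaussian matrix + shift
random_rigid <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 20))
}

apply_rigid <- function(nodes, rig) sweep(nodes %*% t(rig$R), 2, rig$t, "+")
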