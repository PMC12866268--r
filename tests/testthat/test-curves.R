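test_that("curve constructors reproduce closed-form endpoint geometry", {
  straight <- make_curve("straight", list(length = 30))
  expect_equal(curve_chord_length(straight), 30)
  expect_equal(curve_arc_length(straight), 30, tolerance = 1e-12)

  semi <- make_curve("arc", list(radius = 10, sweep = pi))
  expect_equal(curve_chord_length(semi), 20, tolerance = 1e-9)

  # helix r=5, 1 mm/radian, two turns: endpoints differ only axially by 4*pi
  helix <- make_curve("helix", list(radius = 5, pitch = 1, sweep = 4 * pi))
  expect_equal(curve_chord_length(helix), 4 * pi, tolerance = 1e-9)
})

test_that("invalid curve specifications are rejected", {
  expect_error(make_curve("unknown_kind", list()), "arg")
  expect_error(make_curve("straight", list(length = 0)), "length")
  expect_error(make_curve("arc", list(radius = 0, sweep = 1)), "radius")
  expect_error(make_curve("arc", list(radius = 5, sweep = 0)), "sweep")
  expect_error(make_curve("straight", list(length = 10), n_samples = 1), "n_samples")
})

test_that("dense-sample arc length converges under refinement", {
  for (spec in list(list("arc", list(radius = 10, sweep = pi)),
                    list("helix", list(radius = 5, pitch = 1, sweep = 4 * pi)),
                    list("sinusoid", list(amplitude = 3, period = 20, extent = 40)))) {
    l1 <- curve_arc_length(make_curve(spec[[1]], spec[[2]], n_samples = 40001L))
    l2 <- curve_arc_length(make_curve(spec[[1]], spec[[2]], n_samples = 80001L))
    expect_lt(abs(l2 - l1) / l2, 1e-6)
  }
})

test_that("analytic features match closed forms", {
  const15 <- radius_profile("constant", value = 1.5)

  tr <- analytic_features(make_curve("straight", list(length = 30)), const15)
  expect_equal(tr$tortuosity_index, 0, tolerance = 1e-12)
  expect_equal(tr$bending_length_mm, 0, tolerance = 1e-9)
  expect_equal(tr$mean_diameter_mm, 3.0)

  semi <- analytic_features(make_curve("arc", list(radius = 10, sweep = pi)), const15)
  expect_equal(semi$geodesic_length_mm, 10 * pi, tolerance = 1e-6)
  expect_equal(semi$tortuosity_index, pi / 2 - 1, tolerance = 1e-6)
  expect_equal(semi$bending_length_mm, 10, tolerance = 1e-6)

  sine <- analytic_features(make_curve("sinusoid",
                                       list(amplitude = 3, period = 40, extent = 40)))
  expect_equal(sine$bending_length_mm, 3, tolerance = 1e-6)
})

test_that("composite curves join end to end and lengths are additive", {
  comp <- make_curve("composite", list(components = list(
    list(kind = "straight", params = list(length = 10)),
    list(kind = "arc", params = list(radius = 10, sweep = pi / 2))
  )), n_samples = 4001L)
  expect_equal(curve_arc_length(comp), 10 + 5 * pi, tolerance = 1e-4)
  # continuity at the junction (parameter 10 is the end of the straight part)
  jump <- comp$fun(10 + 1e-9) - comp$fun(10 - 1e-9)
  expect_lt(sqrt(sum(jump^2)), 1e-6)
})

test_that("closed curves yield an undefined-tortuosity error", {
  loop <- make_curve("arc", list(radius = 10, sweep = 2 * pi))
  expect_error(analytic_features(loop), "chord")
})

test_that("radius profiles respect their declared endpoint values", {
  taper <- radius_profile("linear_taper", from = 2, to = 1)
  expect_equal(taper$r(c(0, 1)), c(2, 1))
  pw <- radius_profile("piecewise", breaks = c(0, 0.5, 1), values = c(1, 2, 1))
  expect_equal(pw$r(c(0, 0.25, 0.5, 1)), c(1, 1.5, 2, 1))
  expect_error(radius_profile("constant", value = 0), "value")
  expect_error(radius_profile("piecewise", breaks = c(0, 1), values = c(1, -1)),
               "radii")
})

test_that("geodesic length dominates chord length for all curve kinds", {
  set.seed(11)
  for (k in 1:20) {
    cv <- switch(sample(3, 1),
      make_curve("arc", list(radius = runif(1, 2, 20), sweep = runif(1, 0.2, 5.5))),
      make_curve("helix", list(radius = runif(1, 1, 8), pitch = runif(1, 0.2, 3),
                               sweep = runif(1, 1, 12))),
      make_curve("sinusoid", list(amplitude = runif(1, 0.5, 5),
                                  period = runif(1, 5, 30), extent = runif(1, 10, 60))))
    expect_gte(curve_arc_length(cv), curve_chord_length(cv) - 1e-9)
  }
})

test_that("tortuosity is invariant to rigid motion and scale; lengths scale linearly", {
  set.seed(7)
  base <- make_curve("helix", list(radius = 5, pitch = 1.2, sweep = 7))$points
  cl0 <- centerline(base)
  ti0 <- tortuosity_index(cl0)
  bl0 <- bending_length(cl0)
  len0 <- geodesic_length(cl0)
  for (k in 1:5) {
    rig <- random_rigid()
    s <- runif(1, 0.2, 5)
    cl1 <- centerline(apply_rigid(base, rig))
    expect_equal(tortuosity_index(cl1), ti0, tolerance = 1e-9)
    expect_equal(bending_length(cl1), bl0, tolerance = 1e-9)
    cl2 <- centerline(base * s)
    expect_equal(tortuosity_index(cl2), ti0, tolerance = 1e-9)
    expect_equal(bending_length(cl2), bl0 * s, tolerance = 1e-9)
    expect_equal(geodesic_length(cl2), len0 * s, tolerance = 1e-9)
  }
})
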