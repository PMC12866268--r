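test_that("tortuosity index matches arc/chord closed forms", {
  straight <- centerline(cbind(seq(0, 30, 0.5), 0, 0))
  expect_equal(tortuosity_index(straight), 0, tolerance = 1e-12)
  expect_equal(bending_length(straight), 0, tolerance = 1e-9)

  expect_equal(tortuosity_index(semi_polyline()), pi / 2 - 1, tolerance = 1e-4)

  # three-quarter circle: L = 15*pi, chord = 10*sqrt(2)
  th <- seq(0, 3 * pi / 2, length.out = 2001)
  tq <- centerline(cbind(10 * sin(th), 10 * (1 - cos(th)), 0))
  expect_equal(tortuosity_index(tq), 3 * pi / (2 * sqrt(2)) - 1, tolerance = 1e-4)
})

test_that("geodesic length sums segments and is additive under concatenation", {
  two <- centerline(rbind(c(0, 0, 0), c(30, 0, 0)))
  expect_equal(geodesic_length(two), 30)
  expect_equal(geodesic_length(semi_polyline()), 10 * pi, tolerance = 0.02)

  a <- cbind(seq(0, 10, 0.1), 0, 0)
  b <- cbind(10, seq(0, 5, 0.1), 0)
  joined <- centerline(rbind(a, b[-1, ]))
  expect_equal(geodesic_length(joined),
               geodesic_length(centerline(a)) + geodesic_length(centerline(b)),
               tolerance = 1e-9)
})

test_that("bending length is the max orthogonal distance to the chord axis", {
  expect_equal(bending_length(semi_polyline()), 10, tolerance = 1e-4)
  x <- seq(0, 40, length.out = 2001)
  sine <- centerline(cbind(x, 3 * sin(2 * pi * x / 40), 0))
  expect_equal(bending_length(sine), 3, tolerance = 1e-4)
})

test_that("mean and distal diameters follow the radius profile", {
  n <- 161
  x <- seq(0, 40, length.out = n)
  cl_const <- centerline(cbind(x, 0, 0), radii = rep(1.3, n))
  expect_equal(mean_diameter(centerline(cbind(x, 0, 0), radii = rep(1.5, n))), 3.0)
  expect_equal(diameter_at_occlusion(cl_const), 2.6)

  # taper 2.0 -> 1.0 over 40 mm: mean diameter 3.0; last 10 mm spans
  # radius 1.25 -> 1.0, so distal mean diameter 2.25
  taper <- centerline(cbind(x, 0, 0), radii = 2 - x / 40)
  expect_equal(mean_diameter(taper), 3.0, tolerance = 1e-9)
  expect_equal(diameter_at_occlusion(taper), 2.25, tolerance = 1e-2)

  short <- centerline(cbind(seq(0, 8, 0.25), 0, 0), radii = rep(1, 33))
  expect_warning(d <- diameter_at_occlusion(short), "shorter")
  expect_equal(d, mean_diameter(short))
})

test_that("feature symmetries: reversal and distal anchoring", {
  n <- 161
  x <- seq(0, 40, length.out = n)
  cl <- centerline(cbind(x, 3 * sin(2 * pi * x / 40), 0), radii = 2 - x / 40)
  rev_cl <- centerline(cl$nodes[n:1, ], radii = cl$radii[n:1])
  expect_equal(geodesic_length(rev_cl), geodesic_length(cl), tolerance = 1e-9)
  expect_equal(tortuosity_index(rev_cl), tortuosity_index(cl), tolerance = 1e-9)
  expect_equal(bending_length(rev_cl), bending_length(cl), tolerance = 1e-9)
  expect_equal(mean_diameter(rev_cl), mean_diameter(cl), tolerance = 1e-9)
  # diameter at occlusion is anchored at the distal end, so reversal matters
  expect_gt(abs(diameter_at_occlusion(rev_cl) - diameter_at_occlusion(cl)), 0.5)
})

test_that("feature records assemble with the declared units and round-trip CSV", {
  th <- seq(0, pi, length.out = 801)
  mca <- centerline(cbind(10 * sin(th), 10 * (1 - cos(th)), 0),
                    radii = rep(1.5, 801))
  ica <- centerline(cbind(-30, 0, seq(0, 50, length.out = 201)),
                    radii = rep(2.5, 201))
  rec <- build_feature_record(ica, mca, "P001")
  expect_equal(rec$mca_length_cm, pi, tolerance = 1e-3)
  expect_equal(rec$mca_bl_cm, 1.0, tolerance = 1e-3)
  expect_equal(rec$mca_ti, pi / 2 - 1, tolerance = 1e-3)
  expect_equal(rec$mean_mca_diameter_mm, 3.0)
  expect_equal(rec$ica_ti, 0, tolerance = 1e-9)

  f <- tempfile(fileext = ".csv")
  write_feature_records(rec, f)
  expect_identical(readLines(f, n = 1),
    "\"patient_id\",\"mca_length_cm\",\"mca_bl_cm\",\"mca_ti\",\"mean_mca_diameter_mm\",\"diameter_at_occlusion_mm\",\"ica_ti\"")
  back <- read_feature_records(f)
  for (cn in setdiff(names(rec), "patient_id"))
    expect_equal(back[[cn]], rec[[cn]], tolerance = 1e-6)

  cf <- tempfile(fileext = ".csv")
  write_centerline(mca, cf)
  mca2 <- read_centerline(cf)
  expect_equal(mca2$nodes, mca$nodes, tolerance = 1e-9)
  expect_equal(mca2$radii, mca$radii)
})

test_that("degenerate centerlines are rejected", {
  expect_error(centerline(rbind(c(0, 0, 0))), "two 3D nodes")
  expect_error(centerline(rbind(c(0, 0, 0), c(0, 0, 0))), "increasing")
  expect_error(centerline(rbind(c(0, 0, 0), c(1, 0, 0)), radii = c(1, -1)), "radii")
  loop <- centerline(rbind(c(0, 0, 0), c(1, 0, 0), c(1e-9, 1e-9, 0)))
  expect_error(tortuosity_index(loop), "undefined")
  expect_error(bending_length(loop), "degenerate")
})
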