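test_that("parabolic cluster matches its defining geometry", {
  cl <- parabolic_cluster(1.5, 1, h = 0.05)
  p <- cbind(cl$x, cl$y)
  # apex at (x0, 0), widest extent y = +/- y0/2 at the back
  expect_equal(max(p[, 1]), 1.5, tolerance = 1e-8)
  expect_equal(p[which.max(p[, 1]), 2], 0, tolerance = 1e-8)
  expect_equal(range(p[, 2]), c(-0.5, 0.5), tolerance = 0.02)
  expect_gte(min(p[, 1]), -1e-3)  # corner rounding by the spline resampler
  # every point on the parabola arc satisfies y^2 = (y0/2)^2 (x0-x)/x0
  arc <- p[p[, 1] > 0.02, ]
  expect_lt(max(abs(arc[, 2]^2 - 0.25 * (1.5 - arc[, 1]) / 1.5)), 0.01)
})

test_that("parabolic cluster area converges to (2/3) x0 y0", {
  # closed form: integral of the full width over the length
  cases <- list(c(1.5, 1), c(1, 1), c(2, 0.5), c(0.8, 1.2))
  for (cs in cases) {
    cl <- parabolic_cluster(cs[1], cs[2], h = 0.03)
    expect_equal(polygon_area(cl), 2 / 3 * cs[1] * cs[2], tolerance = 0.01)
  }
  # refinement shrinks the error
  err <- vapply(c(0.1, 0.05, 0.025), function(h)
    abs(polygon_area(parabolic_cluster(1, 1, h)) - 2 / 3), 0)
  expect_true(all(diff(err) < 0))
})

test_that("cluster constructors give CCW, evenly spaced, y-symmetric curves", {
  for (cl in list(parabolic_cluster(1.5, 1, 0.05),
                  elliptical_cluster(1.6, 0.4, 0.05),
                  elliptical_cluster(2, 2, 0.05))) {
    expect_gt(polygon_area(cl), 0)
    seg <- protrusim:::arc_lengths(cl)$seg
    expect_true(all(seg > 0.5 * 0.05 & seg < 2 * 0.05))
    expect_lt(symmetry_error(cl), 0.05 / 10)
  }
})

test_that("elliptical cluster has the documented area and tip convention", {
  expect_equal(polygon_area(elliptical_cluster(2, 2, 0.03)), pi, tolerance = 0.01)
  expect_equal(polygon_area(elliptical_cluster(1.5, 1, 0.03)), pi * 0.75 * 0.5,
               tolerance = 0.01)
  cl <- elliptical_cluster(1.6, 0.4, 0.02)
  expect_equal(max(cl$x), 1.6, tolerance = 1e-6)  # tip at (x0, 0)
  expect_equal(min(cl$x), 0, tolerance = 1e-6)
})

test_that("constructors reject non-positive dimensions", {
  expect_error(parabolic_cluster(-1, 1), "positive")
  expect_error(parabolic_cluster(1, 0), "positive")
  expect_error(elliptical_cluster(1, -2), "positive")
})

test_that("polygon_area is the signed shoelace area", {
  sq <- boundary_curve(c(0, 1, 1, 0), c(0, 0, 1, 1), h = 0.5)
  expect_equal(polygon_area(sq), 1)
  # reversed orientation: negative area, constructor flags it
  expect_lt(polygon_area(cbind(c(0, 0, 1, 1), c(0, 1, 1, 0))), 0)
  expect_error(boundary_curve(c(0, 0, 1, 1), c(0, 1, 1, 0)), "counterclockwise")
  # self-intersecting bowtie is rejected
  expect_error(boundary_curve(c(0, 1, 1, 0), c(0, 1, 0, 1)), "self-intersect")
  cl <- elliptical_cluster(2, 2, 0.02)
  expect_equal(polygon_area(cl), pi, tolerance = 1e-3)
})

test_that("outward normals point away from the interior", {
  d <- disk_fixture(R = 1)
  nrm <- outward_normals(d$curve)
  radial <- cbind(d$curve$x - 1, d$curve$y)
  radial <- radial / sqrt(rowSums(radial^2))
  expect_lt(max(abs(nrm - radial)), 2e-3)
  expect_equal(rowSums(nrm^2), rep(1, nrow(nrm)), tolerance = 1e-12)
  # square edge midpoints: axis-aligned outward normals
  sq <- boundary_curve(c(0, 0.5, 1, 1, 1, 0.5, 0, 0),
                       c(0, 0, 0, 0.5, 1, 1, 1, 0.5), h = 0.5)
  nrm <- outward_normals(sq)
  expect_equal(nrm[2, ], c(0, -1), tolerance = 1e-12)  # bottom midpoint
  expect_equal(nrm[6, ], c(0, 1), tolerance = 1e-12)   # top midpoint
  # parabola apex: by symmetry the normal is +x
  cl <- parabolic_cluster(1.5, 1, 0.05)
  expect_equal(outward_normals(cl)[which.max(cl$x), ], c(1, 0),
               tolerance = 1e-6)
  expect_error(outward_normals(boundary_curve(c(0, 0, 1, 1, 0.5),
                                              c(0, 0, 0, 1, 1),
                                              validate = FALSE)),
               "degenerate")
})

test_that("resampling equalizes spacing and preserves shape", {
  # clustered points on a circle
  th <- sort(c(seq(0, pi, length.out = 150), seq(pi, 2 * pi, length.out = 20)))
  th <- unique(th[-length(th)])
  cl <- boundary_curve(cos(th), sin(th), h = 0.05)
  rs <- resample_boundary(cl, 0.05)
  seg <- protrusim:::arc_lengths(rs)$seg
  expect_lt(sd(seg) / mean(seg), 0.1)
  # arc length preserved within 1%, shape within h
  expect_equal(protrusim:::arc_lengths(rs)$total,
               protrusim:::arc_lengths(cl)$total, tolerance = 0.01)
  expect_lt(curve_to_polyline_distance(rs, cl), 0.05)
  # radius approximately preserved (points stay near the unit circle)
  expect_lt(max(abs(sqrt(rs$x^2 + rs$y^2) - 1)), 5e-3)
  # idempotence: resampling an already-uniform curve moves no point by h/10
  rs2 <- resample_boundary(rs, 0.05)
  expect_lt(point_set_distance(rs2, rs), 0.05 / 10)
  expect_error(resample_boundary(cl, 10), "too large")
})

test_that("interior mesh weights integrate the polygon area", {
  sq <- boundary_curve(c(0, 1, 1, 0), c(0, 0, 1, 1), h = 0.1)
  m <- interior_mesh(sq, 0.1)
  expect_equal(sum(m$weights), 1, tolerance = 0.01)
  expect_true(all(m$weights > 0))

  cl <- parabolic_cluster(1.5, 1, 0.05)
  m <- interior_mesh(cl, 0.05)
  expect_equal(sum(m$weights), polygon_area(cl), tolerance = 1e-6)
  expect_equal(sum(m$weights), 1.0, tolerance = 0.01)  # analytic 1.5*1*2/3
  # all nodes inside the curve
  expect_true(all(protrusim:::cpp_point_in_poly(m$nodes, cl$x, cl$y)))
  # refinement: area error against the analytic value decreases
  err <- vapply(c(0.1, 0.05, 0.025), function(hm)
    abs(sum(interior_mesh(cl, hm)$weights) - polygon_area(cl)), 0)
  expect_true(all(err < 1e-6))
})

test_that("straight and elliptical cuts retain the bulk side", {
  d <- disk_fixture(R = 1, h = 0.03)   # disk centered at (1, 0)
  half <- apply_cut(d$curve, list(type = "straight", x = 1))
  expect_equal(polygon_area(half), pi / 2, tolerance = 0.01)
  expect_lte(max(half$x), 1 + 0.03 / 5)   # corner rounding at the h scale
  expect_gt(polygon_area(half), 0)
  # flat end: the cut line is spanned nearly top to bottom
  atcut <- half$x > 1 - 0.05
  expect_equal(range(half$y[atcut]), c(-1, 1), tolerance = 0.08)

  # a cut rod: the canonical regeneration geometry
  rod <- poly_path(c(0, 4, 4, 0), c(-0.3, -0.3, 0.3, 0.3), h = 0.03)
  # sharpest turning angle over the cut end (x > 1), ignoring the rod's own
  # back corners
  max_turn <- function(cv) {
    p <- cbind(cv$x, cv$y); n <- nrow(p)
    tang <- p[c(2:n, 1), ] - p
    ang <- atan2(tang[, 2], tang[, 1])
    turn <- abs((diff(c(ang, ang[1])) + pi) %% (2 * pi) - pi)
    max(turn[cv$x > 1])
  }
  flat <- apply_cut(rod, list(type = "straight", x = 2))
  expect_equal(polygon_area(flat), 1.2, tolerance = 0.02)
  # elliptical cap bulging toward the removed tip, meeting the sides at a
  # shallow angle: a smooth convex end instead of sharp corners
  cap <- apply_cut(rod, list(type = "elliptical", center = c(2, 0),
                             semi_axes = c(0.5, 0.32)))
  expect_equal(max(cap$x), 2.5, tolerance = 0.03)  # cap apex at xc + a
  expect_gt(polygon_area(cap), polygon_area(flat))
  expect_lt(polygon_area(cap), polygon_area(flat) + pi * 0.5 * 0.32)
  expect_lt(max_turn(cap), 25 * pi / 180)

  expect_error(apply_cut(d$curve, list(type = "straight", x = 5)),
               "does not intersect")
})
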