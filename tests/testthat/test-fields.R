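test_that("Green's kernel has the right value, mass and decay", {
  # K0(1)/(2 pi), with K0(1) = 0.421024...
  expect_equal(greens_kernel(1, 1), besselK(1, 0) / (2 * pi))
  expect_equal(greens_kernel(1, 1), 0.06701, tolerance = 1e-3)
  # total kernel mass: integral of G(r) 2 pi r dr = 1/gamma_r
  for (gr in c(0.2, 1, 2.5)) {
    mass <- stats::integrate(function(r) greens_kernel(r, gr) * 2 * pi * r,
                             0, Inf, rel.tol = 1e-10)$value
    expect_equal(mass, 1 / gr, tolerance = 1e-8)
  }
  expect_equal(greens_kernel(80, 1), 0, tolerance = 1e-30)  # far-field decay
  expect_true(is.infinite(greens_kernel(0, 1)))
  expect_error(greens_kernel(-1, 1), "negative")
})

test_that("uniform disk source matches the closed-form Bessel solution", {
  # analytic: c(r) = mu (1 - R K1(R) I0(r)) inside a disk of radius R, gamma = 1
  d <- disk_fixture(R = 1, h = 0.05)
  mu <- rep(2, nrow(d$mesh$nodes))
  cc <- solve_concentration(d$mesh, mu, gamma_r = 1)
  r <- sqrt((d$mesh$nodes[, 1] - 1)^2 + d$mesh$nodes[, 2]^2)
  exact <- 2 * (1 - besselK(1, 1) * besselI(r, 0))
  expect_lt(max(abs(cc - exact) / exact), 0.01)
  # center value c(0) = mu (1 - K1(1))
  c0 <- solve_concentration(d$mesh, mu, 1, points = rbind(c(1, 0)))
  expect_equal(c0, 2 * (1 - besselK(1, 1)), tolerance = 0.01)
  # refined mesh: max relative error below 0.2%
  m2 <- interior_mesh(d$curve, 0.02)
  cc2 <- solve_concentration(m2, rep(2, nrow(m2$nodes)), 1)
  r2 <- sqrt((m2$nodes[, 1] - 1)^2 + m2$nodes[, 2]^2)
  ex2 <- 2 * (1 - besselK(1, 1) * besselI(r2, 0))
  expect_lt(max(abs(cc2 - ex2) / ex2), 0.002)
})

test_that("concentration solve is linear, positive and bounded", {
  d <- disk_fixture(R = 0.8, h = 0.05)
  n <- nrow(d$mesh$nodes)
  expect_equal(solve_concentration(d$mesh, rep(0, n), 1), rep(0, n))
  set.seed(11)
  src <- runif(n)
  c1 <- solve_concentration(d$mesh, src, 1.5)
  c2 <- solve_concentration(d$mesh, 2 * src, 1.5)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  expect_true(all(c1 >= 0))
  # well-mixed bound for a constant source: c < mu / gamma_r
  cc <- solve_concentration(d$mesh, rep(3, n), 0.5)
  expect_lt(max(cc), 3 / 0.5)
  expect_error(solve_concentration(d$mesh, rep(-1, n), 1), "negative")
  expect_error(solve_concentration(d$mesh, rep(1, 3), 1), "per mesh node")
})

test_that("global mass balance holds on a truncated large domain", {
  # gamma * integral(c) over the plane = integral(mu) over the cluster
  d <- disk_fixture(R = 1, h = 0.06)
  n <- nrow(d$mesh$nodes)
  gr <- 1
  hq <- 0.1
  xs <- seq(-7, 9, by = hq); ys <- seq(-8, 8, by = hq)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  cc <- solve_concentration(d$mesh, rep(2, n), gr, points = pts)
  expect_equal(gr * sum(cc) * hq^2, 2 * sum(d$mesh$weights), tolerance = 0.02)
})

test_that("concentration decays monotonically away from the source", {
  d <- disk_fixture(R = 1, h = 0.05)
  rr <- seq(1.2, 6, by = 0.2)
  cc <- solve_concentration(d$mesh, rep(1, nrow(d$mesh$nodes)), 1,
                            points = cbind(1 + rr, 0))
  expect_true(all(diff(cc) < 0))
  expect_true(all(cc > 0))
})

test_that("circuit fields solve chemicals in dependency order", {
  cl <- parabolic_cluster(1.5, 1, 0.05)
  m <- interior_mesh(cl, 0.05)
  # single chemical: identical to a constant-source solve
  circ <- named_scheme("single_inhibitor", mu_X = 8)
  f <- solve_circuit_fields(circ, m)
  expect_identical(f$values[, "X"],
                   solve_concentration(m, rep(8, nrow(m$nodes)), 1))
  # two inhibitors: Y is sourced only where c_X is below the threshold,
  # a region localized at the cluster tip
  circ <- named_scheme("two_inhibitors", mu_X = 8, mu_Y0 = 65, Ks = 1, gamma_r = 1)
  f <- solve_circuit_fields(circ, m)
  sup <- f$sources[, "Y"] > 0.5 * 65
  expect_gt(sum(sup), 0)
  expect_true(all(f$values[sup, "X"] < 1))
  expect_true(all(f$values[!sup, "X"] > 1 - 1e-6))
  # the front-half support is localized at the tip: none in the mid band
  # (the sharp back corners also dip below threshold, but the bulk does not)
  expect_gt(sum(sup & m$nodes[, 1] > 1.1), 0)
  expect_equal(sum(sup & m$nodes[, 1] > 0.35 & m$nodes[, 1] < 1.05), 0)
  # boundary evaluation agrees with the node solve to quadrature accuracy
  bv <- eval_fields(f, cl)
  expect_true(all(bv >= 0))
  expect_lt(max(bv[, "X"]), max(f$values[, "X"]))
})

test_that("fields export to CSV with one column per chemical", {
  cl <- elliptical_cluster(1, 1, 0.08)
  m <- interior_mesh(cl, 0.08)
  f <- solve_circuit_fields(named_scheme("two_inhibitors", mu_X = 8,
                                         mu_Y0 = 65, Ks = 1, gamma_r = 1), m)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fields_csv(f, path)
  back <- read.csv(path)
  expect_identical(names(back), c("x", "y", "weight", "X", "Y"))
  expect_equal(nrow(back), nrow(m$nodes))
  expect_equal(back$X, unname(f$values[, "X"]), tolerance = 1e-12)
})

test_that("fields inherit the y-symmetry of the cluster and circuit", {
  cl <- parabolic_cluster(1.5, 1, 0.05)
  m <- interior_mesh(cl, 0.05)
  circ <- named_scheme("two_inhibitors", mu_X = 8, mu_Y0 = 65, Ks = 1, gamma_r = 1)
  f <- solve_circuit_fields(circ, m)
  # pair each node with its mirror image and compare concentrations
  key <- paste(round(m$nodes[, 1], 9), round(-m$nodes[, 2], 9))
  own <- paste(round(m$nodes[, 1], 9), round(m$nodes[, 2], 9))
  mirror <- match(key, own)
  ok <- !is.na(mirror)
  expect_gt(mean(ok), 0.9)   # nearly all nodes have an exact mirror node
  for (ch in c("X", "Y"))
    expect_lt(max(abs(f$values[ok, ch] - f$values[mirror[ok], ch])), 1e-7)
})
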