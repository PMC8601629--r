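test_that("hill function matches its closed form and limits", {
  expect_equal(hill(1, 1, 100), 0.5)
  expect_equal(hill(2, 2, -100), 0.5)
  expect_equal(hill(0, 1, -100), 1)   # absent inhibitor: no inhibition
  expect_equal(hill(0, 1, 100), 0)    # absent activator: no activation
  # direct evaluation just above threshold: 1 / (1 + 1.1^100)
  expect_equal(hill(1.1, 1, -100), 1 / (1 + 1.1^100), tolerance = 1e-10)
  expect_equal(hill(1.1, 1, -100), 7.2565e-5, tolerance = 1e-4)
  # n = 0 is the non-participation convention, exactly 1
  expect_identical(hill(c(0, 0.5, 7), 1, 0), c(1, 1, 1))
  # zero effective threshold: inhibitor shuts growth off
  expect_equal(hill(0.5, 0, -100), 0)
  expect_equal(hill(0, 0, -100), 0)
  expect_error(hill(-0.1, 1, 100), "negative")
})

test_that("hill is monotone, bounded, and step-like at |n| = 100", {
  cgrid <- seq(0, 3, by = 0.01)
  for (n in c(2, 100, -2, -100)) {
    v <- hill(cgrid, K = 1, n = n)
    expect_true(all(v >= 0 & v <= 1))
    d <- diff(v)
    if (n > 0) expect_true(all(d >= -1e-12)) else expect_true(all(d <= 1e-12))
  }
  # threshold-function regime: within 1e-2 of the step outside a 10% band
  away <- cgrid[abs(cgrid - 1) > 0.1]
  step_dn <- as.numeric(away < 1)
  expect_lt(max(abs(hill(away, 1, -100) - step_dn)), 1e-2)
  expect_lt(max(abs(hill(away, 1, 100) - (1 - step_dn))), 1e-2)
})

test_that("secretion rates compose baseline, max-regulation and gating", {
  # constant secretion in the single-inhibitor scheme
  circ <- named_scheme("single_inhibitor", mu_X = 8)
  for (cx in c(0, 0.5, 2)) expect_equal(secretion_rate(circ, "X", c(X = cx)), 8)
  # two inhibitors: Y shut off above the secretion threshold
  circ <- named_scheme("two_inhibitors", mu_X = 8, mu_Y0 = 65, Ks = 1, gamma_r = 1)
  expect_lt(secretion_rate(circ, "Y", c(X = 1.2, Y = 0)), 1e-7 * 65)
  expect_equal(secretion_rate(circ, "Y", c(X = 0.5, Y = 0)), 65, tolerance = 1e-10)
  # secretion-max clamp: 1 + b * c = 0 at c = 1.25, b = -0.8
  ch <- chemical("Y", mu0 = 10, secretion_links = list(secretion_link("X", Ks = 2)),
                 secretion_max = list(regulator = "X", b = -0.8))
  circ <- circuit(list(chemical("X", 1), ch), list(growth_link("X")))
  expect_equal(secretion_rate(circ, "Y", c(X = 1.25, Y = 0)), 0)
  expect_gt(secretion_rate(circ, "Y", c(X = 1.0, Y = 0)), 0)
  expect_error(secretion_rate(circ, "Y", c(X = 1)), "missing concentration")
})

test_that("growth rate implements thresholded inhibition with modifiers", {
  circ <- named_scheme("single_inhibitor", mu_X = 8)
  expect_gte(growth_rate(circ, c(X = 0.5)), 1 - 1e-12)
  expect_lt(growth_rate(circ, c(X = 2)), 1e-30)
  # threshold regulator: c_Y = 0.5 halves the effective threshold,
  # so c_X = 0.7 > 0.5 suppresses growth; evaluated directly: H(0.7 | 0.5, -100)
  circ <- named_scheme("threshold_regulator", mu_X = 8, mu_Y0 = 48,
                       Ks = 0.9, gamma_r = 0.2, b = -0.8)
  g <- growth_rate(circ, c(X = 0.7, Y = 0.5))
  expect_equal(g, 1 / (1 + (0.7 / 0.5)^100), tolerance = 1e-8)
  expect_lt(g, 1e-12)
  expect_gt(growth_rate(circ, c(X = 0.4, Y = 0.5)), 1 - 1e-9)
  # clamp: strong modifier drives the threshold to 0 and growth to 0
  expect_equal(growth_rate(circ, c(X = 0.4, Y = 1.5)), 0)
})

test_that("rates are invariant to chemical ordering", {
  chems <- list(
    chemical("X", 8),
    chemical("Y", 65, gamma_r = 1, secretion_links = list(secretion_link("X", 1))))
  links <- list(growth_link("X"), growth_link("Y"))
  c1 <- circuit(chems, links)
  c2 <- circuit(rev(chems), rev(links))
  set.seed(7)
  for (i in 1:20) {
    cv <- c(X = runif(1, 0, 2), Y = runif(1, 0, 2))
    expect_identical(growth_rate(c1, cv), growth_rate(c2, cv))
    expect_identical(secretion_rate(c1, "Y", cv), secretion_rate(c2, "Y", cv))
  }
})

test_that("the empty scheme grows everywhere", {
  circ <- named_scheme("none")
  expect_equal(growth_rate(circ, matrix(0, 3, 0)), c(1, 1, 1))
})

test_that("a two-chemical cascade is exactly the two-inhibitor scheme", {
  casc <- named_scheme("inhibitor_cascade", q = 2, mu = c(8, 65), gamma_r = c(1, 1))
  two <- named_scheme("two_inhibitors", mu_X = 8, mu_Y0 = 65, Ks = 1, gamma_r = 1)
  for (cx in c(0.3, 0.9, 1.1)) for (cy in c(0.2, 1.3)) {
    cv <- c(X = cx, Y = cy)
    expect_identical(growth_rate(casc, cv), growth_rate(two, cv))
    expect_identical(secretion_rate(casc, "Y", cv), secretion_rate(two, "Y", cv))
  }
  # chain gating: chemical 3 requires both upstream inhibitors to be low
  c3 <- named_scheme("inhibitor_cascade", q = 3, mu = c(8, 60, 40))
  expect_equal(secretion_rate(c3, "Z", c(X = 0.5, Y = 0.5, Z = 0)), 40,
               tolerance = 1e-8)
  expect_lt(secretion_rate(c3, "Z", c(X = 0.5, Y = 1.2, Z = 0)), 1e-6 * 40)
  expect_lt(secretion_rate(c3, "Z", c(X = 1.2, Y = 0.5, Z = 0)), 1e-6 * 40)
})

test_that("invalid circuits and schemes are rejected", {
  expect_error(named_scheme("frobnicator"), "arg")
  expect_error(named_scheme("single_inhibitor"), "requires parameter")
  expect_error(named_scheme("single_inhibitor", mu_X = -3), "mu0")
  expect_error(chemical("X", mu0 = 1, gamma_r = 0), "gamma_r")
  expect_error(circuit(list(chemical("Y", 1, secretion_links =
    list(secretion_link("X", 1)))), list()), "unknown regulator")
  # cyclic secretion dependencies are not supported
  expect_error(circuit(list(
    chemical("A", 1, secretion_links = list(secretion_link("B", 1))),
    chemical("B", 1, secretion_links = list(secretion_link("A", 1)))),
    list()), "cyclic")
})
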