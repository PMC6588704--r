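test_that("parameter validation rejects negative rates and sub-unit Hill exponents", {
  expect_error(kinetic_params(alpha1 = -1, alpha3 = 1),
               class = "convflight_domain_error")
  expect_error(kinetic_params(alpha1 = 1, alpha3 = 1, n1 = 0.5),
               class = "convflight_domain_error")
})

test_that("balanced hydrolysis drives lipids to zero and carbohydrate to alpha2", {
  p <- kinetic_params(alpha1 = 10, alpha3 = 10, alpha2 = 5)
  tr <- integrate_fuel(p, init = c(x = 3, y = 2), t_end = 60)
  last <- tr[nrow(tr), ]
  expect_equal(last$x, 0, tolerance = 1e-6)
  expect_equal(last$y, 5, tolerance = 1e-6)
  ss <- steady_state(p)
  expect_equal(c(ss$x, ss$y), c(0, 5), tolerance = 1e-12)
})

test_that("integration reproduces the closed-form fixed point (4, 1, z = 10)", {
  p <- kinetic_params(alpha1 = 18, alpha3 = 10, alpha2 = 5)
  ss <- steady_state(p, method = "closed_form")
  expect_equal(c(ss$x, ss$y, ss$z), c(4, 1, 10), tolerance = 1e-12)
  ssn <- steady_state(p, method = "numeric")
  expect_equal(c(ssn$x, ssn$y), c(4, 1), tolerance = 1e-8)
})

test_that("numeric and closed-form steady states agree across a lattice", {
  set.seed(14)
  for (i in 1:10) {
    p <- kinetic_params(alpha1 = runif(1, 0, 25), alpha3 = runif(1, 0, 12),
                        alpha2 = runif(1, 1, 8))
    cf <- steady_state(p, method = "closed_form")
    nm <- steady_state(p, method = "numeric")
    expect_equal(c(nm$x, nm$y), c(cf$x, cf$y), tolerance = 1e-8)
  }
})

test_that("trajectories stay non-negative and are insensitive to the output step", {
  p <- kinetic_params(alpha1 = 2, alpha3 = 10, alpha2 = 5)  # strong drain
  tr <- integrate_fuel(p, init = c(x = 1, y = 0), t_end = 30, dt = 0.05)
  expect_true(all(tr$x >= 0))
  expect_true(all(tr$y >= 0))
  t1 <- integrate_fuel(p, init = c(x = 1, y = 0), t_end = 10, dt = 0.1)
  t2 <- integrate_fuel(p, init = c(x = 1, y = 0), t_end = 10, dt = 0.05)
  expect_lt(abs(t1$x[nrow(t1)] - t2$x[nrow(t2)]), 1e-6)
  expect_lt(abs(t1$y[nrow(t1)] - t2$y[nrow(t2)]), 1e-6)
})

test_that("steady states respond monotonically to the two activities", {
  a1_grid <- seq(10, 25, by = 3)
  x1 <- vapply(a1_grid, function(a1)
    steady_state(kinetic_params(alpha1 = a1, alpha3 = 10))$x, numeric(1))
  y1 <- vapply(a1_grid, function(a1)
    steady_state(kinetic_params(alpha1 = a1, alpha3 = 10))$y, numeric(1))
  expect_true(all(diff(x1) >= 0))
  expect_true(all(diff(y1) <= 0))
  a3_grid <- seq(1, 10, by = 2)
  x3 <- vapply(a3_grid, function(a3)
    steady_state(kinetic_params(alpha1 = 10, alpha3 = a3))$x, numeric(1))
  y3 <- vapply(a3_grid, function(a3)
    steady_state(kinetic_params(alpha1 = 10, alpha3 = a3))$y, numeric(1))
  expect_true(all(diff(x3) <= 0))
  expect_true(all(diff(y3) >= 0))
})

test_that("the steady state is unique from random starting points", {
  set.seed(9)
  for (p in list(kinetic_params(alpha1 = 18, alpha3 = 10),
                 kinetic_params(alpha1 = 12, alpha3 = 6))) {
    ref <- steady_state(p, method = "closed_form")
    for (i in 1:20) {
      init <- c(x = runif(1, 0, 10), y = runif(1, 0, 10))
      nm <- steady_state(p, method = "numeric", init = init)
      expect_equal(c(nm$x, nm$y), c(ref$x, ref$y), tolerance = 1e-6)
    }
  }
})

test_that("ATP output uses the 2.25 lipid coefficient and partitions energy", {
  expect_equal(atp_output(1, 0)$z, 2.25)
  expect_equal(atp_output(0, 0)$z, 0)
  out <- atp_output(4, 1)
  expect_equal(out$z, 10)
  expect_equal(out$lipid_share, 0.9)
  expect_equal(out$carb_share, 0.1)
  expect_error(atp_output(-1, 0), class = "convflight_domain_error")
})

test_that("activity sweeps trace monotone fuel curves and locate the switch", {
  base <- kinetic_params(alpha1 = 25, alpha3 = 10, alpha2 = 5)
  sw <- sweep_activity(base, "alpha1", grid = seq(25, 10, by = -1))
  expect_true(all(diff(sw$lipid_energy) < 0))   # decreasing along 25 -> 10
  expect_true(all(diff(sw$carb_energy) > 0))
  expect_equal(sw$dominant[1], "lipid")
  expect_equal(sw$dominant[nrow(sw)], "carbohydrate")
  expect_equal(sum(diff(as.integer(factor(sw$dominant))) != 0), 1)
  expect_false(is.na(attr(sw, "threshold")))

  sw3 <- sweep_activity(kinetic_params(alpha1 = 10, alpha3 = 1),
                        "alpha3", grid = seq(1, 10, by = 1))
  expect_true(all(diff(sw3$lipid_energy) < 0))
  expect_true(all(diff(sw3$carb_energy) > 0))
  expect_equal(sum(diff(as.integer(factor(sw3$dominant))) != 0), 1)

  # grid entirely on the lipid-dominant side: no switch
  sw_no <- sweep_activity(base, "alpha1", grid = seq(25, 20, by = -1))
  expect_true(is.na(attr(sw_no, "threshold")))
  expect_false(glance(sw_no)$switched)
})

test_that("the concentration criterion switches exactly where net influx equals alpha2", {
  # x* = y* iff alpha1 - alpha3 = alpha2 (symmetry of the fixed-point system)
  sw <- sweep_activity(kinetic_params(alpha1 = 25, alpha3 = 10, alpha2 = 5),
                       "alpha1", grid = seq(25, 10, by = -1),
                       criterion = "concentration")
  expect_equal(attr(sw, "threshold"), 15)  # delta = alpha2 = 5 at alpha1 = 15
  at15 <- dplyr::filter(sw, value == 15)
  expect_equal(at15$x_star, at15$y_star, tolerance = 1e-10)
})

test_that("the as-printed carbohydrate equation extinguishes the carbohydrate pool", {
  # with dy/dt = -beta2 x + alpha2/(1+x^n2) the carbohydrate drain tracks x,
  # so a healthy lipid flux (delta = 8) drives y to zero instead of a
  # balanced steady state -- the behaviour that motivates the corrected form
  p <- kinetic_params(alpha1 = 18, alpha3 = 10, variant = "as_printed")
  expect_error(steady_state(p, method = "closed_form"), "corrected")
  tr <- integrate_fuel(p, init = c(x = 0, y = 0), t_end = 30)
  last <- tr[nrow(tr), ]
  expect_equal(last$y, 0, tolerance = 1e-6)
  expect_equal(last$x, 8, tolerance = 1e-6)
  # under the corrected variant the same parameters keep both fuels positive
  cf <- steady_state(kinetic_params(alpha1 = 18, alpha3 = 10))
  expect_gt(cf$y, 0)
})
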