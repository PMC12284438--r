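test_that("fiber invariant follows the fiber-stretch formula", {
  id <- stretch_state(lambda_theta = 1, lambda_z = 1)
  for (b in c(0, 30, 48.2, 90))
    expect_equal(fiber_invariant(id, b), 0)
  st <- stretch_state(lambda_theta = 1.1, lambda_z = 1.3)
  expect_equal(fiber_invariant(st, 90), 1.3^2 - 1)  # 0.69
  # at 45 degrees the invariant is symmetric under swapping the in-plane
  # stretches
  sw <- stretch_state(lambda_theta = 1.3, lambda_z = 1.1)
  expect_equal(fiber_invariant(st, 45), fiber_invariant(sw, 45))
})

test_that("isochoric stresses are trace-free for random admissible states", {
  st <- random_stretches(1000)
  s <- isochoric_stress(st, ctl_params())
  scale <- max(abs(unlist(s)))
  expect_lt(max(abs(s$rr + s$theta + s$zz)) / scale, 1e-12)
  # identity state gives zero stress
  s0 <- isochoric_stress(stretch_state(lambda_theta = 1, lambda_z = 1),
                         ctl_params())
  expect_equal(unlist(s0), c(rr = 0, theta = 0, zz = 0))
})

test_that("uniaxial response reduces to incompressible neo-Hooke when k1 = 0", {
  p <- ho_params(10, 1e-12, 5.3, 48.2)  # vanishing fiber stiffness
  lam <- seq(1, 1.5, length.out = 11)
  for (d in c("circumferential", "longitudinal")) {
    got <- uniaxial_response(d, lam, p)$stress
    expect_equal(got, 10 * (lam^2 - 1 / lam), tolerance = 1e-8)
  }
  expect_equal(uniaxial_response("longitudinal", 1.5, p)$stress,
               15.8333333, tolerance = 1e-6)
})

test_that("45-degree fibers give identical circumferential and longitudinal curves", {
  p <- ho_params(10, 100.2, 5.3, 45)
  lam <- seq(1, 1.5, length.out = 21)
  rc <- uniaxial_response("circumferential", lam, p)
  rl <- uniaxial_response("longitudinal", lam, p)
  expect_equal(rc$stress, rl$stress, tolerance = 1e-9)
})

test_that("uniaxial solve satisfies the zero-lateral-stress conditions", {
  p <- ctl_params()
  r <- uniaxial_response("longitudinal", c(1.2, 1.4), p)
  s <- isochoric_stress(r$state, p)
  # sigma_rr + p = 0 and sigma_theta + p = 0 with p = -sigma_bar_rr
  expect_lt(max(abs(s$theta - s$rr)), 1e-8)
  expect_equal(r$state$p, -s$rr)
})

test_that("Cauchy to 2nd-PK conversion and Green strain", {
  expect_equal(cauchy_to_second_pk(15.8333333, 1.5), 7.037037,
               tolerance = 1e-6)
  expect_equal(cauchy_to_second_pk(0, 1.23), 0)
  expect_error(cauchy_to_second_pk(1, -1))
  expect_equal(green_strain(1.5), 0.625)  # ~50% stretch is ~60% strain
  expect_equal(stretch_from_green(0.625), 1.5)
})

test_that("tube law passes through the reference state and is monotone", {
  p <- ctl_params()
  g <- wall_geometry(0.13, 0.013)
  A0 <- pi * 0.13^2
  expect_equal(transmural_pressure(A0, g, p), 0)
  As <- A0 * seq(0.5, 2, length.out = 60)
  P <- transmural_pressure(As, g, p)
  expect_true(all(diff(P) > 0))
})

test_that("thin-wall tube law matches the Laplace estimate", {
  p <- ctl_params()
  g <- wall_geometry(0.13, 0.0013)     # h0/r0 = 0.01
  A <- 1.2 * pi * 0.13^2
  Pn <- transmural_pressure(A, g, p)
  # Laplace: (sigma_theta - sigma_rr) at mid-wall times h/r
  ri <- sqrt(A / pi); Rm <- 0.13 + 0.0013 / 2
  rm_ <- sqrt(ri^2 + (Rm^2 - 0.13^2))
  lt <- rm_ / Rm
  st <- stretch_state(lambda_theta = lt, lambda_z = 1)
  s <- isochoric_stress(st, p)
  h_def <- sqrt(ri^2 + ((0.13 + 0.0013)^2 - 0.13^2)) - ri
  Plap <- kpa_to_mmhg((s$theta - s$rr) * h_def / rm_)
  expect_equal(Pn, Plap, tolerance = 0.03)
})

test_that("tube law inverts and round-trips", {
  p <- ctl_params()
  g <- wall_geometry(0.13, 0.013)
  A0 <- pi * 0.13^2
  expect_equal(area_from_pressure(0, g, p), A0, tolerance = 1e-10)
  As <- A0 * c(0.8, 1.1, 1.6)
  P <- transmural_pressure(As, g, p)
  expect_equal(area_from_pressure(P, g, p), As, tolerance = 1e-8)
})

test_that("pressure is homogeneous of degree 1 in (c, k1): stiffness scaling", {
  p <- ctl_params()
  p2 <- apply_stiffness_scaling(p, 2)
  expect_equal(p2$c_kpa, 20)
  expect_equal(p2$k1_kpa, 200.4)
  expect_equal(p2$k2, p$k2)
  expect_equal(p2$beta_deg, p$beta_deg)
  expect_identical(apply_stiffness_scaling(p, 1), p)
  expect_error(apply_stiffness_scaling(p, -1))
  g <- wall_geometry(0.13, 0.013)
  As <- pi * 0.13^2 * c(0.7, 1.2, 1.8)
  expect_equal(transmural_pressure(As, g, p2),
               2 * transmural_pressure(As, g, p), tolerance = 1e-12)
  # at fixed positive pressure, a stiffer wall admits a smaller area
  expect_lt(area_from_pressure(10, g, p2), area_from_pressure(10, g, p))
})

test_that("slope-matched linear law agrees for small deformation, underestimates at large", {
  p <- ctl_params()
  g <- wall_geometry(0.13, 0.013)
  A0 <- pi * 0.13^2
  K <- tube_law_tangent(g, p)
  expect_equal(linear_tube_law(A0, g, K), 0)
  Pl <- linear_tube_law(1.01 * A0, g, K)
  Pn <- transmural_pressure(1.01 * A0, g, p)
  expect_equal(Pl, Pn, tolerance = 0.02)
  expect_gt(transmural_pressure(1.5 * A0, g, p),
            linear_tube_law(1.5 * A0, g, K))
})

test_that("fiber exponent overflow fails loudly with the offending stretch", {
  p <- ho_params(10, 100, 80, 48.2)
  st <- stretch_state(lambda_theta = 6, lambda_z = 6)
  expect_error(isochoric_stress(st, p), "overflow")
})

test_that("constructors enforce invariants", {
  expect_error(ho_params(-1, 1, 1, 45))
  expect_error(ho_params(1, 1, 1, 95))
  expect_error(stretch_state(lambda_r = 2, lambda_theta = 2, lambda_z = 2),
               "incompressibility")
  expect_error(wall_geometry(0.1, 0.2))
  st <- stretch_state(lambda_theta = 1.2, lambda_z = 1.1)
  expect_equal(st$lambda_r * st$lambda_theta * st$lambda_z, 1)
})
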