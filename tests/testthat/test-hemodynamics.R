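test_that("boundary layer thickness follows sqrt(nu T / 2 pi)", {
  expect_equal(boundary_layer_thickness(0.049, 0.5), 0.062445,
               tolerance = 1e-4)
  expect_equal(boundary_layer_thickness(0, 1), 0)
  expect_equal(boundary_layer_thickness(0.046, 0.4) /
                 boundary_layer_thickness(0.046, 0.2), sqrt(2))
})

test_that("waveforms interpolate periodically and integrate exactly", {
  wf <- generate_inflow(300, 0.33)
  expect_equal(wf_interp(wf, wf$period + 0.013), wf_interp(wf, 0.013))
  expect_equal(wf_interp(wf, wf$time), wf$values)
  expect_equal(wf_cycle_integral(wf), mean(wf$values) * wf$period)
  expect_error(waveform(c(0, 0.1, 0.15, 0.4), c(1, 2, 3, 4)), "uniform")
})

test_that("lumped Windkessel has the analytic steady state and decay", {
  T_ <- 0.5
  wf <- waveform(seq(0, T_, length.out = 513)[1:512], rep(1, 512), T_)
  wk <- windkessel_params(R1 = 1, R2 = 1, Cd = 0.05)
  P <- windkessel_response(wf, wk, n_cycles = 60)
  expect_equal(mean(P$values), 2, tolerance = 1e-6)   # Q (R1 + R2)
  # doubling both resistances doubles the steady pressure
  P2 <- windkessel_response(wf, windkessel_params(2, 2, 0.05), n_cycles = 60)
  expect_equal(mean(P2$values), 2 * mean(P$values), tolerance = 1e-6)
  # zero flow: exponential decay with time constant R2 Cd
  wf0 <- waveform(wf$time, rep(0, 512), T_)
  Pd <- windkessel_response(wf0, wk, n_cycles = 1, P0 = 10)
  tau_fit <- -1 / coef(lm(log(Pd$values) ~ Pd$time))[2]
  expect_equal(unname(tau_fit), wk$R2 * wk$Cd, tolerance = 0.01)
})

test_that("a resting tree with no inflow stays exactly at rest", {
  s <- simulate_tree(single_tube(), ctl_params(),
                     constant_inflow(0, 0.05),
                     windkessel_params(0, 0, 1e9),
                     sim_config(n_out = 64, n_cycles_max = 5))
  expect_lt(max(abs(s$fields$t1$P)), 1e-10)
  expect_lt(max(abs(s$fields$t1$Q)), 1e-10)
})

test_that("steady tube + RCR reaches the analytic outlet pressure", {
  s <- simulate_tree(single_tube(), ctl_params(), constant_inflow(1, 0.05),
                     windkessel_params(1, 1, 0.005),
                     sim_config(n_out = 64, n_cycles_max = 200,
                                periodicity_tol = 1e-9))
  Pout <- s$fields$t1$P[nrow(s$fields$t1$P), ]
  expect_equal(mean(Pout), 2, tolerance = 0.005)   # Q (R1 + R2)
  expect_true(s$converged)
})

test_that("near-rigid constant-flow run matches the analytic friction drop", {
  T_ <- 0.01
  stiff <- apply_stiffness_scaling(ctl_params(), 100)
  s <- simulate_tree(single_tube(), stiff, constant_inflow(1, T_),
                     windkessel_params(0, 0, 1e9),
                     sim_config(n_out = 64, n_cycles_max = 100,
                                periodicity_tol = 1e-9, dx_cm = 0.025))
  P <- s$fields$t1$P[, ncol(s$fields$t1$P)]
  rho <- 1.055e3; nu <- 0.046e-4
  delta <- sqrt(nu * T_ / (2 * pi))
  r <- 0.13e-2; A <- pi * r^2
  drop_analytic <- rho * 2 * pi * nu * r * 1e-2 * 1e-6 /
    (delta * A^2) / 133.322387415
  expect_equal(P[1] - P[length(P)], drop_analytic, tolerance = 0.01)
  # profile is linear along the tube
  x <- seq_along(P)
  expect_gt(summary(lm(P ~ x))$r.squared, 0.999)
})

test_that("junctions conserve mass and split symmetric daughters evenly", {
  tr <- generate_tree(tree_gen_config(n_generations = 2, asymmetry = 0))
  qin <- generate_inflow(300, 0.33)
  wk <- pulsedecon:::.wk_map_from(tr, 10, 600)
  s <- simulate_tree(tr, ctl_params(), qin, wk)
  expect_lt(s$diagnostics$max_mass_defect_ml_s, 1e-10)
  ch <- tr$children[[tr$root]]
  expect_equal(s$fields[[ch[1]]]$Q, s$fields[[ch[2]]]$Q)
  # root inlet flow reproduces the imposed inflow
  wf <- extract_waveforms(s, position = "proximal")
  expect_equal(wf$Q$values, wf_interp(qin, s$time), tolerance = 1e-10)
})

test_that("asymmetric daughters split steady flow roughly by lumen area", {
  seg <- data.frame(
    id = c("p", "c1", "c2"), parent_id = c(NA, "p", "p"),
    length_cm = c(1, 0.6, 0.6), radius_cm = c(0.13, 0.10, 0.07))
  tr <- vascular_tree(seg)
  s <- simulate_tree(tr, ctl_params(), constant_inflow(1, 0.05),
                     windkessel_params(0.5, 0.5, 0.01),
                     sim_config(n_out = 64, n_cycles_max = 200,
                                periodicity_tol = 1e-9))
  q1 <- mean(s$fields$c1$Q[1, ]); q2 <- mean(s$fields$c2$Q[1, ])
  area_ratio <- 0.10^2 / 0.07^2
  expect_equal(q1 / q2, area_ratio, tolerance = 0.35)
  expect_gt(q1, q2)
})

test_that("halving the grid spacing changes systolic MPA pressure by < 1%", {
  tr <- generate_tree(tree_gen_config(n_generations = 2, asymmetry = 0))
  qin <- generate_inflow(300, 0.33)
  wk <- pulsedecon:::.wk_map_from(tr, 10, 600)
  s1 <- simulate_tree(tr, ctl_params(), qin, wk)
  s2 <- simulate_tree(tr, ctl_params(), qin, wk,
                      sim_config(dx_cm = 0.05, n_grid_min = 5))
  sys1 <- max(extract_waveforms(s1)$P$values)
  sys2 <- max(extract_waveforms(s2)$P$values)
  expect_equal(sys1, sys2, tolerance = 0.01)
})

test_that("systolic pressure decreases monotonically with generation", {
  tr <- generate_tree(tree_gen_config(n_generations = 4, asymmetry = 0))
  qin <- generate_inflow(300, 0.33)
  wk <- pulsedecon:::.wk_map_from(tr, 10, 600)
  s <- simulate_tree(tr, ctl_params(), qin, wk)
  sys_gen <- sapply(0:4, function(g) {
    ids <- tr$segments$id[tr$segments$generation == g]
    mean(sapply(ids, function(id) max(s$fields[[id]]$P[1, ])))
  })
  expect_true(all(diff(sys_gen) < 0))
  # distal pressure of the last generation stays at or above the
  # Windkessel back-pressure (zero reference here)
  term_P <- sapply(tr$terminals, function(id)
    min(s$fields[[id]]$P[nrow(s$fields[[id]]$P), ]))
  expect_true(all(term_P > -1e-6))
})

test_that("doubling every terminal resistance raises systolic MPA pressure", {
  tr <- generate_tree(tree_gen_config(n_generations = 2, asymmetry = 0))
  qin <- generate_inflow(300, 0.33)
  wk1 <- pulsedecon:::.wk_map_from(tr, 10, 600)
  wk2 <- wk1; wk2$R1 <- 2 * wk2$R1; wk2$R2 <- 2 * wk2$R2
  s1 <- simulate_tree(tr, ctl_params(), qin, wk1)
  s2 <- simulate_tree(tr, ctl_params(), qin, wk2)
  expect_gt(max(extract_waveforms(s2)$P$values),
            max(extract_waveforms(s1)$P$values))
})

test_that("tree and windkessel files round-trip through CSV", {
  tr <- generate_tree(tree_gen_config(n_generations = 3, asymmetry = 0.2,
                                      seed = 4))
  path <- tempfile(fileext = ".csv")
  write_tree_csv(tr, path)
  tr2 <- read_tree_csv(path)
  expect_equal(tr2$segments$radius_cm, tr$segments$radius_cm)
  expect_equal(tr2$terminals, tr$terminals)
  wk <- pulsedecon:::.wk_map_from(tr, 10, 600)
  wpath <- tempfile(fileext = ".csv")
  write_windkessel_csv(wk, wpath)
  wk2 <- read_windkessel_csv(wpath)
  expect_equal(wk2$R1, wk$R1)
})

test_that("tree validation rejects malformed inputs", {
  expect_error(vascular_tree(data.frame(
    id = c("a", "b"), parent_id = c(NA, NA),
    length_cm = 1, radius_cm = 0.1)), "exactly one root")
  expect_error(vascular_tree(data.frame(
    id = c("a", "b"), parent_id = c(NA, "a"),
    length_cm = 1, radius_cm = 0.1)), "exactly 2 children")
  expect_error(vascular_tree(data.frame(
    id = c("a", "b", "c"), parent_id = c(NA, "a", "x"),
    length_cm = 1, radius_cm = 0.1)), "unknown")
})
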