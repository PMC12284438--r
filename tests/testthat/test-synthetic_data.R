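test_that("symmetric binary tree has the expected counts and radii", {
  tr <- generate_tree(tree_gen_config(n_generations = 4, asymmetry = 0,
                                      radius_ratio = 0.8, root_radius = 1))
  expect_equal(nrow(tr$segments), 31)
  expect_equal(length(tr$terminals), 16)
  r3 <- tr$segments$radius_cm[tr$segments$generation == 3]
  expect_equal(unique(round(r3, 12)), 0.8^3)   # 0.512 * root radius
  # lengths follow the length-to-radius rule below the root
  sub <- tr$segments[tr$segments$generation > 0, ]
  expect_equal(sub$length_cm, 6 * sub$radius_cm)
})

test_that("tree generation is a pure function of config + seed", {
  cfg <- tree_gen_config(n_generations = 4, asymmetry = 0.2, seed = 7)
  t1 <- generate_tree(cfg)
  t2 <- generate_tree(cfg)
  expect_identical(t1$segments, t2$segments)
  t3 <- generate_tree(tree_gen_config(n_generations = 4, asymmetry = 0.2,
                                      seed = 8))
  expect_false(identical(t1$segments$radius_cm, t3$segments$radius_cm))
  # generated trees always satisfy the tree invariants (constructor ran)
  expect_s3_class(t1, "vascular_tree")
})

test_that("hypertensive remodeling prunes terminal pairs and narrows distal vessels", {
  tr <- generate_tree(tree_gen_config(n_generations = 4, asymmetry = 0))
  same <- apply_ph_remodeling(tr, ph_remodel_config(0, 1, 0.04))
  expect_equal(same$segments$radius_cm, tr$segments$radius_cm)
  expect_equal(nrow(same$segments), nrow(tr$segments))

  half <- apply_ph_remodeling(tr, ph_remodel_config(0.5, 1, 1e-9, seed = 3))
  # 8 pruning events on 16 terminals: each removes a sibling pair and
  # re-terminates the parent, so 8 fewer terminals and 16 fewer segments
  expect_equal(length(half$terminals), 8)
  expect_equal(nrow(half$segments), 15)

  expect_error(apply_ph_remodeling(tr, ph_remodel_config(0.95, 1, 0.04)),
               "over-pruning")
})

test_that("remodeled morphometry shifts mass away from the smallest radii", {
  tr <- generate_tree(tree_gen_config(n_generations = 5, asymmetry = 0.1))
  ph <- apply_ph_remodeling(tr, ph_remodel_config(0.3, 0.8, 0.04, seed = 2))
  breaks <- seq(0, max(tr$segments$radius_cm) * 1.001, length.out = 11)
  mc <- tree_morphometry(tr, radius_breaks = breaks)
  mp <- tree_morphometry(ph, radius_breaks = breaks)
  expect_equal(sum(mc$radius$fraction), 1, tolerance = 1e-12)
  expect_equal(sum(mp$length$fraction), 1, tolerance = 1e-12)
  # pruning + narrowing reduces the small-radius fraction relative to the
  # large-radius fraction
  small_c <- sum(mc$radius$fraction[1:2]); small_p <- sum(mp$radius$fraction[1:2])
  large_c <- sum(mc$radius$fraction[6:10]); large_p <- sum(mp$radius$fraction[6:10])
  expect_gt(large_p, large_c)
  expect_lt(small_p - large_p, small_c - large_c)
})

test_that("independent uniaxial oracle agrees with the plane-stress reduction", {
  withr::with_seed(11, {
    for (i in 1:5) {
      p <- ho_params(runif(1, 5, 40), runif(1, 20, 400),
                     runif(1, 2, 14), runif(1, 25, 65))
      lam <- seq(1.001, 1.5, length.out = 8)
      for (d in c("circumferential", "longitudinal")) {
        oracle <- pulsedecon:::.oracle_uniaxial_cauchy(d, lam, p)
        reduction <- uniaxial_response(d, lam, p)$stress
        expect_lt(max(abs(oracle - reduction)) / max(abs(reduction)), 1e-6)
      }
    }
  })
})

test_that("synthetic uniaxial datasets are anisotropic off 45 degrees and vanish at rest", {
  d <- generate_uniaxial_data(ctl_params())
  expect_equal(d$circumferential$stress[1], 0, tolerance = 1e-10)
  expect_equal(d$longitudinal$stress[1], 0, tolerance = 1e-10)
  expect_gt(max(abs(d$circumferential$stress - d$longitudinal$stress)), 1)
  # noise is seeded and reproducible
  n1 <- generate_uniaxial_data(ctl_params(), noise_sd_rel = 0.02, seed = 5)
  n2 <- generate_uniaxial_data(ctl_params(), noise_sd_rel = 0.02, seed = 5)
  expect_identical(n1$circumferential$stress, n2$circumferential$stress)
  expect_false(identical(n1$circumferential$stress,
                         d$circumferential$stress))
})

test_that("generated inflow integrates to the stroke volume with no regurgitation", {
  wf <- generate_inflow(heart_rate = 300, stroke_volume = 0.33,
                        ejection_fraction_of_cycle = 0.5)
  expect_equal(wf$period, 0.2)
  expect_equal(wf_cycle_integral(wf), 0.33, tolerance = 1e-10)
  expect_true(all(wf$values >= 0))
  wf2 <- generate_inflow(heart_rate = 150, stroke_volume = 0.5)
  expect_equal(wf2$period, 0.4)
  expect_equal(wf_cycle_integral(wf2), 0.5, tolerance = 1e-10)
})

test_that("trees and wall parameters round-trip through JSON", {
  tr <- generate_tree(tree_gen_config(n_generations = 3, asymmetry = 0.2,
                                      seed = 9))
  path <- tempfile(fileext = ".json")
  write_tree_json(tr, path)
  tr2 <- read_tree_json(path)
  expect_equal(sort(tr2$segments$id), sort(tr$segments$id))
  m <- match(tr$segments$id, tr2$segments$id)
  expect_equal(tr2$segments$radius_cm[m], tr$segments$radius_cm)
  expect_equal(tr2$segments$parent_id[m], tr$segments$parent_id)
  p <- ho_params(12.5, 210, 7.7, 51)
  ppath <- tempfile(fileext = ".json")
  write_ho_params_json(p, ppath)
  expect_equal(read_ho_params_json(ppath), p)
})
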