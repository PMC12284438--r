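# shared fixtures: wall parameters for healthy and hypertensive tissue
# (as estimated from mean uniaxial curves), and small simulation setups
ctl_params <- function() ho_params(10, 100.2, 5.3, 48.2)
ph_params <- function() ho_params(20, 310, 15.2, 46.2)

single_tube <- function(length_cm = 1, radius_cm = 0.13, wall_ratio = 0.1) {
  vascular_tree(data.frame(id = "t1", parent_id = NA_character_,
                           length_cm = length_cm, radius_cm = radius_cm,
                           wall_ratio = wall_ratio))
}

constant_inflow <- function(q_ml_s = 1, T_s = 0.01, n = 64) {
  waveform(seq(0, T_s, length.out = n + 1)[1:n], rep(q_ml_s, n), T_s)
}

# random admissible stretch states (vectorized fields), fixed seed
random_stretches <- function(n, seed = 42) {
  withr::with_seed(seed, {
    lt <- runif(n, 0.7, 1.5)
    lz <- runif(n, 0.7, 1.5)
    structure(list(lambda_r = 1 / (lt * lz), lambda_theta = lt,
                   lambda_z = lz, p = NA_real_),
              class = "stretch_state")
  })
}
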