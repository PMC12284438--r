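mk_wf <- function(vals, T_ = 0.2) {
  n <- length(vals)
  waveform(seq(0, T_, length.out = n + 1)[1:n], vals, T_)
}

test_that("pulse-pressure waveform subtracts the diastolic baseline", {
  t <- seq(0, 0.2, length.out = 65)[1:64]
  P <- mk_wf(15 + 10 * sin(2 * pi * t / 0.2)^2)
  pp <- pulse_pressure_waveform(P)
  expect_equal(min(pp$values), 0)
  P2 <- mk_wf(P$values + 7.3)
  expect_equal(pulse_pressure_waveform(P2)$values, pp$values)
  expect_equal(pulse_pressure_waveform(mk_wf(rep(5, 64)))$values, rep(0, 64))
})

test_that("pulse pressure amplitude is max minus min and baseline-invariant", {
  t <- seq(0, 0.2, length.out = 65)[1:64]
  P <- mk_wf(15 + 12.5 * (1 + sin(2 * pi * t / 0.2)))  # 40 / 15
  expect_equal(delta_mpa_pressure(P), 25)
  expect_equal(delta_mpa_pressure(mk_wf(P$values + 100)), 25)
  expect_equal(delta_mpa_pressure(mk_wf(rep(3, 64))), 0)
})

test_that("proportional waveforms give a flat real impedance", {
  t <- seq(0, 0.2, length.out = 129)[1:128]
  Q <- mk_wf(2 + sin(2 * pi * t / 0.2) + 0.3 * sin(4 * pi * t / 0.2) +
               0.2 * sin(6 * pi * t / 0.2))
  P <- mk_wf(3 * Q$values)
  spec <- impedance_spectrum(P, Q)
  expect_equal(z0(spec), 3)
  ok <- !spec$masked
  expect_equal(Mod(spec$Z[ok]), rep(3, sum(ok)), tolerance = 1e-10)
  expect_equal(zc(spec), 3, tolerance = 1e-10)
  # doubling the flow halves the impedance everywhere
  spec2 <- impedance_spectrum(P, mk_wf(2 * Q$values))
  expect_equal(Mod(spec2$Z[!spec2$masked]),
               Mod(spec$Z[!spec$masked]) / 2, tolerance = 1e-10)
})

test_that("a phase-shifted single harmonic shows up in amplitude and phase", {
  t <- seq(0, 0.2, length.out = 257)[1:256]
  phi <- 0.6
  Q <- mk_wf(2 + 1.5 * sin(2 * pi * t / 0.2))
  P <- mk_wf(10 + 4.5 * sin(2 * pi * t / 0.2 - phi))
  spec <- impedance_spectrum(P, Q)
  expect_equal(Mod(spec$Z[2]), 3, tolerance = 1e-8)     # amplitude ratio
  expect_equal(Arg(spec$Z[2]), -phi, tolerance = 1e-8)  # pressure lags
})

test_that("Z0 conventions: baseline moves Z0 but never Zc", {
  t <- seq(0, 0.2, length.out = 257)[1:256]
  Q <- mk_wf(2 + 1.5 * sin(2 * pi * t / 0.2) + 0.4 * sin(4 * pi * t / 0.2) +
               0.3 * sin(6 * pi * t / 0.2))
  P <- mk_wf(12 + 5 * sin(2 * pi * t / 0.2 - 0.4))
  full <- impedance_spectrum(P, Q)
  pulse <- impedance_spectrum(pulse_pressure_waveform(P), Q)
  expect_gt(z0(full), z0(pulse))
  expect_equal(zc(full), zc(pulse), tolerance = 1e-10)
})

test_that("Zc masks weak flow harmonics and needs enough of them", {
  t <- seq(0, 0.2, length.out = 257)[1:256]
  Q <- mk_wf(2 + sin(2 * pi * t / 0.2))  # only harmonic 1 present
  P <- mk_wf(5 + 2 * sin(2 * pi * t / 0.2))
  spec <- impedance_spectrum(P, Q)
  expect_true(all(spec$masked[3:10]))
  expect_error(zc(spec), "harmonics")
})

test_that("harmonic reconstruction returns the pulse-pressure waveform", {
  # simulate a short physiological run and check Parseval-consistency.
  # The ejection window is set off the half-cycle mark: a half-cycle
  # half-sine has exact spectral nulls at odd harmonics, where a
  # nonlinear system still produces pressure that no Z * Q_hat product
  # can represent.
  s <- simulate_tree(single_tube(0.5), ctl_params(),
                     generate_inflow(300, 0.33,
                                     ejection_fraction_of_cycle = 0.45),
                     windkessel_params(3, 3, 0.002),
                     sim_config(n_out = 256))
  wf <- extract_waveforms(s, position = "proximal")
  Ppp <- pulse_pressure_waveform(wf$P)
  # no magnitude floor here: the identity P_hat = Z * Q_hat holds only
  # when every harmonic is kept
  spec <- impedance_spectrum(Ppp, wf$Q, floor_rel = 1e-15)
  n <- length(Ppp$values)
  Qh <- stats::fft(wf$Q$values) / n
  keep <- seq_len(floor(n / 2) + 1L)
  Ph_rec <- rep(0 + 0i, n)
  Zs <- spec$Z; Zs[spec$masked] <- 0
  Ph_rec[keep] <- Zs * Qh[keep]
  # rebuild the conjugate-symmetric upper half and invert
  if (n %% 2 == 0) {
    Ph_rec[(n / 2 + 2):n] <- Conj(Ph_rec[(n / 2):2])
  } else {
    Ph_rec[((n + 1) / 2 + 1):n] <- Conj(Ph_rec[((n + 1) / 2):2])
  }
  P_rec <- Re(stats::fft(Ph_rec, inverse = TRUE))
  expect_equal(P_rec, Ppp$values, tolerance = 1e-8)
})

test_that("single-tube RCR run: Z0 equals the total resistance, Zc its high-frequency limit", {
  # short wide near-rigid tube so the terminal RCR dominates the input
  # impedance at all harmonics
  tube <- single_tube(length_cm = 0.1, radius_cm = 0.2)
  stiff <- apply_stiffness_scaling(ctl_params(), 100)
  wk <- windkessel_params(R1 = 5, R2 = 5, Cd = 0.01)
  s <- simulate_tree(tube, stiff, generate_inflow(300, 0.33), wk,
                     sim_config(n_out = 512, periodicity_tol = 1e-7))
  wf <- extract_waveforms(s, position = "proximal")
  spec <- impedance_spectrum(wf$P, wf$Q)
  expect_equal(z0(spec), 10, tolerance = 0.01)
  sel <- spec$freq_hz >= 150 & spec$freq_hz <= 250 & !spec$masked
  expect_equal(mean(Mod(spec$Z[sel])), wk$R1, tolerance = 0.05)
  # pure-resistance outlet: flat impedance, Zc matches Z0
  sres <- simulate_tree(tube, stiff, generate_inflow(300, 0.33),
                        windkessel_params(5, 5, Cd = Inf),
                        sim_config(n_out = 512, periodicity_tol = 1e-7))
  wfr <- extract_waveforms(sres, position = "proximal")
  specr <- impedance_spectrum(wfr$P, wfr$Q)
  expect_equal(zc(specr), z0(specr), tolerance = 0.05)
})
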