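test_that("natural frequency draws respect range, size and seed", {
  expect_error(draw_natural_frequencies(1), "invalid network")

  omega <- draw_natural_frequencies(100, seed = 7)
  expect_length(omega, 100)
  expect_true(all(omega > 0 & omega < 1))

  expect_identical(draw_natural_frequencies(2, seed = 42),
                   draw_natural_frequencies(2, seed = 42))

  # law-of-large-numbers check against the U(0,1) mean
  expect_lt(abs(mean(draw_natural_frequencies(10000, seed = 3)) - 0.5), 0.02)
})

test_that("coupling_strength evaluates the plasticity formula", {
  # symmetric terms cancel exactly when forced onto the same draw
  sig <- plasticity_signature(8, 8)
  expect_identical(coupling_strength(sig, 0.3, 0.3), 0)

  # direct scalar evaluation oracle
  expect_equal(coupling_strength(plasticity_signature(8, 0), 0.5, 0.5),
               8 * exp(0.25))

  # depotentiation dominates -> negative coupling
  expect_lt(coupling_strength(plasticity_signature(0.001, 8), 0.2, 0.9), 0)

  expect_error(coupling_strength(sig, 0, 0.5), "open interval")
  expect_error(plasticity_signature(-1, 0), "alpha_p")
  expect_error(plasticity_signature(1, 1, tau_p = 0), "tau_p")
})

test_that("build_coupling_matrix yields a symmetric static matrix", {
  sig1 <- plasticity_signature(8, 0.001)
  cm <- build_coupling_matrix(sig1, n = 100, seed = 11)

  expect_identical(dim(cm$strengths), c(100L, 100L))
  expect_identical(cm$strengths, t(cm$strengths))
  expect_identical(diag(cm$strengths), rep(0, 100))

  off <- upper.tri(cm$strengths)
  # min possible K under condition 1 is 8*exp(0) - 0.001*exp(0.5) > 0
  expect_true(all(cm$strengths[off] > 0))
  expect_true(all(cm$draws_r1[off] > 0 & cm$draws_r1[off] < 1))
  expect_true(all(cm$draws_r2[off] > 0 & cm$draws_r2[off] < 1))
  expect_true(all(cm$draws_r1[off] != cm$draws_r2[off]))
  # entries equal coupling_strength at the stored draws
  expect_equal(cm$strengths[off],
               coupling_strength(sig1, cm$draws_r1[off], cm$draws_r2[off]))

  expect_identical(build_coupling_matrix(sig1, 10, seed = 5)$strengths,
                   build_coupling_matrix(sig1, 10, seed = 5)$strengths)

  cm0 <- build_coupling_matrix(plasticity_signature(0, 0), 10, seed = 1)
  expect_identical(cm0$strengths, matrix(0, 10, 10))

  expect_error(build_coupling_matrix(sig1, 1), "invalid network")
})

test_that("dbs_waveform gates a 130 Hz rectangular train on the global clock", {
  spec <- stimulus_spec()

  expect_identical(dbs_waveform(spec, 0:50, dbs_on = FALSE), rep(0, 51))

  drive <- dbs_waveform(spec, 0:1999, dbs_on = TRUE)
  expect_identical(sort(unique(drive)), c(0, 3))
  expect_identical(sum(drive > 0), 260L)  # floor(2 s * 130 Hz) onsets
  expect_identical(count_pulse_onsets(spec, 2000),
                   oracle_onset_count(130, 1, 2000))

  # pulse accounting holds within +/- 1 for other specs and windows
  for (f in c(50, 97, 130, 200)) {
    for (start in c(0, 1234)) {
      sp <- stimulus_spec(frequency_hz = f)
      cnt <- count_pulse_onsets(sp, 1500, start = start)
      expect_identical(cnt, oracle_onset_count(f, 1, 1500, start = start))
      expect_lte(abs(cnt - floor(1.5 * f)), 1)
    }
  }

  # width > 1 widens each pulse without adding onsets
  spw <- stimulus_spec(pulse_width_iterations = 3L)
  drive_w <- dbs_waveform(spw, 0:1999, dbs_on = TRUE)
  expect_identical(sum(drive_w > 0), 3L * 260L)
  expect_identical(count_pulse_onsets(spw, 2000), 260L)

  expect_error(stimulus_spec(pulse_width_iterations = 8L), "overlap")
  expect_error(stimulus_spec(frequency_hz = 0), "frequency_hz")
  expect_error(dbs_waveform(spec, -1, TRUE), "iteration")
})

test_that("euler_step matches the scalar oracle and closed forms", {
  # pure linear advance with no coupling and no drive
  sig0 <- plasticity_signature(0, 0)
  cm0 <- build_coupling_matrix(sig0, 3, seed = 1)
  ens <- oscillator_ensemble(rep(0.1, 3), rep(0, 3))
  st <- euler_step(simulation_state(ens), cm0, drive = 0)
  expect_identical(st$ensemble$phases, rep(0.1, 3))
  expect_identical(st$iteration, 1L)

  # n = 3 hand-specified instance vs the independent scalar oracle
  K <- matrix(c(0, 2, -1, 2, 0, 0.5, -1, 0.5, 0), 3, 3)
  cm <- build_coupling_matrix(plasticity_signature(1, 1), 3, seed = 2)
  cm$strengths <- K
  omega <- c(0.2, 0.5, 0.8)
  phases <- c(0.1, 2.5, 4.0)
  drive <- c(3, 0, 3)
  st2 <- euler_step(
    simulation_state(oscillator_ensemble(omega, phases)), cm, drive = drive)
  expect_equal(st2$ensemble$phases,
               oracle_euler_step(phases, omega, K, drive),
               tolerance = 1e-12)

  # identical phases, frequencies and drive stay identical (coupling vanishes)
  ens_eq <- oscillator_ensemble(rep(0.4, 3), rep(1.3, 3))
  st3 <- euler_step(simulation_state(ens_eq), cm, drive = 2)
  expect_equal(st3$ensemble$phases, rep(1.3 + 0.4 + 2, 3), tolerance = 1e-12)
  expect_lt(diff(range(st3$ensemble$phases)), 1e-14)

  # repulsive convention flips the coupling term's sign
  st_att <- euler_step(
    simulation_state(oscillator_ensemble(omega, phases)), cm, drive = 0)
  st_rep <- euler_step(
    simulation_state(oscillator_ensemble(omega, phases)), cm, drive = 0,
    sign_convention = "repulsive")
  coup_att <- st_att$ensemble$phases - phases - omega
  coup_rep <- st_rep$ensemble$phases - phases - omega
  expect_equal(coup_att, -coup_rep, tolerance = 1e-12)

  # dimension mismatch and overflow diagnostics
  cm5 <- build_coupling_matrix(sig0, 5, seed = 1)
  expect_error(euler_step(simulation_state(ens_eq), cm5, drive = 0),
               "configuration error")
  expect_error(euler_step(simulation_state(ens_eq), cm, drive = 1e12),
               "overflow")
})

test_that("integrate_block records, chains and preserves the coupling", {
  sig <- plasticity_signature(8, 0.001)
  spec <- stimulus_spec()
  n <- 20L

  make_state <- function() {
    set.seed(99)
    omega <- draw_natural_frequencies(n)
    cm <- build_coupling_matrix(sig, n)
    phases0 <- draw_initial_phases(n)
    list(state = simulation_state(oscillator_ensemble(omega, phases0)),
         cm = cm)
  }

  # exactly n_iterations recorded steps
  s <- make_state()
  res <- integrate_block(s$state, s$cm, spec, dbs_on = TRUE,
                         n_iterations = 2000)
  expect_identical(dim(res$trajectory$phases), c(2000L, n))
  expect_identical(res$state$iteration, 2000L)

  # static plasticity: coupling unchanged by integration
  s2 <- make_state()
  before <- s2$cm$strengths
  invisible(integrate_block(s2$state, s2$cm, spec, TRUE, 100))
  expect_identical(s2$cm$strengths, before)

  # chaining two 1000-iteration blocks is bit-identical to one 2000 block
  sA <- make_state(); sB <- make_state()
  one <- integrate_block(sA$state, sA$cm, spec, TRUE, 2000)
  h1 <- integrate_block(sB$state, sB$cm, spec, TRUE, 1000)
  h2 <- integrate_block(h1$state, sB$cm, spec, TRUE, 1000)
  expect_identical(one$trajectory$phases,
                   rbind(h1$trajectory$phases, h2$trajectory$phases))
  expect_identical(one$state$ensemble$phases, h2$state$ensemble$phases)

  expect_error(integrate_block(make_state()$state, s$cm, spec, TRUE, 0),
               "n_iterations")
})

test_that("zero coupling and no drive follow the exact linear solution", {
  # dyadic-rational parameters make repeated addition exact in binary
  n <- 4
  omega_dyadic <- c(0.125, 0.25, 0.5, 0.375)
  phases0 <- c(0.5, 1, 2, 0.25)
  cm0 <- build_coupling_matrix(plasticity_signature(0, 0), n, seed = 1)
  ens <- oscillator_ensemble(omega_dyadic, phases0)
  res <- integrate_block(simulation_state(ens), cm0, stimulus_spec(),
                         dbs_on = FALSE, n_iterations = 2000)
  expected <- outer(1:2000, omega_dyadic) + rep(phases0, each = 2000)
  expect_identical(res$trajectory$phases, unname(expected))

  # generic frequencies agree to accumulated rounding error
  set.seed(4)
  omega <- draw_natural_frequencies(n)
  res2 <- integrate_block(
    simulation_state(oscillator_ensemble(omega, phases0)), cm0,
    stimulus_spec(), FALSE, 2000)
  expect_equal(res2$trajectory$phases,
               unname(outer(1:2000, omega) + rep(phases0, each = 2000)),
               tolerance = 1e-10)
})
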