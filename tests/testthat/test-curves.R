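test_that("activation delay is zero for a mono-exponential rise", {
  t <- seq(0, 40, 0.05)
  i <- ifelse(t < 5, 0, 10 * (1 - exp(-(t - 5) / 3)))
  res <- activation_delay_and_tau(t, i, t_pulse_start = 5)
  expect_equal(res$delay, 0, tolerance = 1e-6)
  expect_equal(res$tau_late, 3, tolerance = 1e-4)
})

test_that("multi-gate activation produces a positive delay matching a brute-force oracle", {
  # m^4 rise with per-gate tau 2 ms, computed analytically
  t <- seq(0, 40, 0.01)
  tau_m <- 2
  i <- 10 * (1 - exp(-t / tau_m))^4
  res <- activation_delay_and_tau(t, i, t_pulse_start = 0)
  expect_gt(res$delay, 0)
  # oracle: independent grid-search exponential fit of the late phase,
  # zero-intercept found numerically
  i_ss <- 10
  late <- which(i >= 0.5 * i_ss)
  orc <- oracle_exponential(t[late], i[late])
  f <- function(tt) orc$i_i + orc$a * exp(-(tt - t[late[1]]) / orc$tau)
  t_zero <- stats::uniroot(f, c(-20, t[late[1]]))$root
  expect_equal(res$delay, t_zero, tolerance = 0.02)
  # delay grows with the number of gates
  delays <- vapply(c(1, 2, 4), function(n) {
    ii <- 10 * (1 - exp(-t / tau_m))^n
    activation_delay_and_tau(t, ii, 0)$delay
  }, numeric(1))
  expect_true(all(diff(delays) > 0))
  expect_equal(delays[[1]], 0, tolerance = 1e-6)
})

test_that("tail back-extrapolation recovers the conductance at step end", {
  fx <- kv_fixture("NvShak5", truncated = TRUE)
  sols <- symmetrical_k_solutions()
  p <- build_protocol("gv_tail", step_start = -20, step_increment = 0, n_sweeps = 1)
  rec <- simulate_sweeps(fx, p, solutions = sols, keep_state = TRUE)
  po_end <- rec$gating[1, max(which(rec$time < 105))]
  ta <- tail_amplitude(rec$time, rec$currents[1, ], t_repol = 105)
  expect_equal(ta$amplitude, fx$g_max * po_end * (-100 - 0), tolerance = 0.01 * abs(ta$amplitude))
  # amplitude scales linearly with maximal conductance
  fx2 <- kv_fixture("NvShak5", truncated = TRUE, g_max = 3)
  rec2 <- simulate_sweeps(fx2, p, solutions = sols)
  ta2 <- tail_amplitude(rec2$time, rec2$currents[1, ], t_repol = 105)
  expect_equal(ta2$amplitude / ta$amplitude, 3, tolerance = 1e-3)
  # a closed channel leaves no tail
  pc <- build_protocol("gv_tail", step_start = -90, step_increment = 0, n_sweeps = 1)
  rec3 <- simulate_sweeps(kv_fixture("NvShak2"), pc, solutions = sols)
  ta3 <- tail_amplitude(rec3$time, rec3$currents[1, ], t_repol = 105)
  expect_equal(ta3$amplitude, 0, tolerance = 1e-6)
})

test_that("GV curve from isochronal tails recovers configured Boltzmann parameters", {
  cells <- lapply(1:5, function(ci) {
    simulate_sweeps(kv_fixture("NvShak5", truncated = TRUE),
                    build_protocol("gv_tail"),
                    solutions = symmetrical_k_solutions())
  })
  gv <- build_gv_curve(cells)
  expect_equal(gv$v50, -30.1, tolerance = 0.01)
  expect_equal(gv$s, 4.3, tolerance = 0.01)
  expect_equal(max(gv$data$mean), 1)
  expect_equal(gv$data$sem, rep(0, nrow(gv$data)))
  expect_equal(unique(gv$data$n), 5)
  # normalization idempotence: re-normalizing the normalized per-cell data
  # and refitting changes nothing
  pc <- gv$per_cell[gv$per_cell$cell == 1, ]
  renorm <- pc$g_norm / max(pc$g_norm)
  refit <- fit_boltzmann(pc$voltage, renorm, normalized = TRUE)
  expect_equal(refit$v50, pc$v50[[1]], tolerance = 1e-9)
})

test_that("SSI curve recovers configured parameters and is monotone", {
  rec <- simulate_sweeps(kv_fixture("NvShak5"), build_protocol("ssi"))
  ssi <- build_ssi_curve(rec)
  expect_equal(ssi$v50, -59.0, tolerance = 0.01)
  expect_equal(ssi$s, 6.1, tolerance = 0.01)
  # most hyperpolarized pre-pulse leaves full availability
  expect_equal(ssi$data$mean[[1]], 1)
  expect_true(all(diff(ssi$data$mean) <= 1e-9))
  # single cell: SEM reported absent
  expect_true(all(is.na(ssi$data$sem)))
})

test_that("deactivation tau curve matches its closed form and rank order", {
  # closed form: tau_deact_ref 5 ms at -100 mV, e-fold per 40 mV
  fx <- kv_fixture("NvShak3")
  fx$deactivation <- deactivation_params(tau_deact_ref = 5, tau_deact_vslope = 40)
  sols <- symmetrical_k_solutions()
  rec <- simulate_sweeps(fx, build_protocol("deactivation_tails"), solutions = sols)
  tc <- deactivation_tau_curve(rec)
  expect_equal(tc$tau[tc$voltage == -160], 5 * exp(-60 / 40), tolerance = 0.01)
  expect_equal(tc$tau[tc$voltage == -160], 1.12, tolerance = 0.01)
  expect_equal(tc$tau[tc$voltage == -80], 8.24, tolerance = 0.01)
  expect_gt(attr(tc, "loglinear_r2"), 0.999)
  # configured 10-fold slow/fast ratio at -100 mV is recovered within 2%
  slow <- deactivation_tau_curve(simulate_sweeps(
    kv_fixture("NvShak1", truncated = TRUE),
    build_protocol("deactivation_tails"), solutions = sols))
  fast <- suppressWarnings(deactivation_tau_curve(simulate_sweeps(
    kv_fixture("NvShak6"), build_protocol("deactivation_tails"), solutions = sols)))
  ratio <- slow$tau[slow$voltage == -100] / fast$tau[fast$voltage == -100]
  expect_equal(ratio, 10, tolerance = 0.02)
})

test_that("pre-pulse subtraction isolates the heteromeric current", {
  expect_error(isolate_inactivating_component(1:5, 1:4), "mismatch")
  pp <- build_protocol("heteromer_prepulse", step_start = -100, test_duration = 500)
  hom <- kv_heteromer_homomer()
  het <- kv_heteromer_preset("NvShakR8")$heteromer
  f <- 0.6
  # oracle comparison in instantaneous-activation mode, where the
  # non-inactivating background cancels exactly between the two sweeps
  mix_rec <- simulate_sweeps(heteromer_mix(hom, het, f), pp,
                             mode = "instantaneous_activation")
  dp <- prepulse_difference(mix_rec)
  het_alone <- simulate_sweeps(het, pp, mode = "instantaneous_activation")
  dp_het <- prepulse_difference(het_alone)
  expect_equal(dp$difference, f * dp_het$difference,
               tolerance = 0.01 * max(abs(dp$difference)))
  # the difference decays to ~0 while the depolarized-pre-pulse trace does not
  n <- nrow(dp)
  late <- seq(n - 20, n)
  expect_lt(max(abs(dp$difference[late])), 0.01 * max(dp$difference))
  expect_gt(min(abs(dp$i_depol[late])), 10 * max(abs(dp$difference[late])))
  # no heteromers, no difference
  mix0 <- simulate_sweeps(heteromer_mix(hom, het, 0), pp,
                          mode = "instantaneous_activation")
  dp0 <- prepulse_difference(mix0)
  expect_lt(max(abs(dp0$difference)), 1e-9 * max(abs(dp0$i_hyper)))
})
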