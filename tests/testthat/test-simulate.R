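test_that("Nernst potential matches the closed form", {
  expect_equal(nernst_potential(solution_pair(140, 140)), 0)
  expect_equal(nernst_potential(solution_pair(140, 2, 295)), -108.0, tolerance = 1e-3)
  expect_equal(nernst_potential(solution_pair(140, 4, 295)), -90.4, tolerance = 1e-3)
  expect_error(solution_pair(-1, 2), "positive")
  expect_error(solution_pair(140, 0), "positive")
})

test_that("no ionic current flows at the reversal potential", {
  sols <- symmetrical_k_solutions()
  p <- build_protocol("activation_family", step_start = 0, step_increment = 0,
                      n_sweeps = 1, holding = 0, tail_voltage = 0)
  rec <- simulate_sweeps(kv_fixture("NvShak2"), p, solutions = sols)
  expect_lt(max(abs(rec$currents)), 1e-12)
})

test_that("high-threshold channel first conducts at -10 mV in the step family", {
  rec <- simulate_sweeps(kv_fixture("NvShak2"), build_protocol("activation_family"),
                         solutions = standard_solutions())
  # steady conductance per step, relative to the +60 mV step
  t <- rec$time
  idx <- which(t >= 95 & t < 105)
  e_k <- nernst_potential(rec$solutions)
  g <- vapply(1:13, function(sw) {
    v <- epoch_voltages(rec$protocol, sw)[[2]]
    mean(rec$currents[sw, idx]) / (v - e_k)
  }, numeric(1))
  v_steps <- seq(-60, 60, 10)
  first <- min(v_steps[g >= 0.01 * g[[13]]])
  expect_equal(first, -10)
})

test_that("instantaneous-activation decay follows the configured exponential", {
  rec <- simulate_sweeps(
    kv_fixture("NvShak1"),
    build_protocol("activation_family", step_start = 60, n_sweeps = 1),
    solutions = standard_solutions(), mode = "instantaneous_activation")
  idx <- which(rec$time >= 5 & rec$time < 105)
  tr <- rec$time[idx] - 5
  i <- rec$currents[1, idx]
  expect_lt(max(abs(i / i[[1]] - exp(-tr / 2.4))), 1e-8)
})

test_that("gating state is conserved and current reverses across E_K", {
  rec <- simulate_sweeps(kv_fixture("NvShak4"), build_protocol("activation_family"),
                         solutions = standard_solutions(), keep_state = TRUE)
  expect_true(all(rec$gating >= 0 & rec$gating <= 1))
  # fully activated channel: current sign tracks driving force
  sols <- solution_pair(140, 20)
  e_k <- nernst_potential(sols)
  p <- build_protocol("activation_family", holding = 40, step_start = -60,
                      n_sweeps = 13, tail_voltage = 40)
  rec2 <- simulate_sweeps(kv_fixture("NvShak2"), p, solutions = sols,
                          keep_state = TRUE)
  idx <- which(rec2$time >= 95 & rec2$time < 105)
  for (sw in c(1, 7, 13)) {
    v <- epoch_voltages(p, sw)[[2]]
    po <- mean(rec2$gating[sw, idx])
    if (po > 0.5 && abs(v - e_k) > 1) {
      expect_equal(sign(mean(rec2$currents[sw, idx])), sign(v - e_k))
    }
  }
})

test_that("identical seeds give bit-identical noisy recordings", {
  p <- build_protocol("activation_family", n_sweeps = 3)
  a <- simulate_sweeps(kv_fixture("NvShak3"), p,
                       artifacts = artifact_params(noise_sd = 0.5, seed = 42))
  b <- simulate_sweeps(kv_fixture("NvShak3"), p,
                       artifacts = artifact_params(noise_sd = 0.5, seed = 42))
  d <- simulate_sweeps(kv_fixture("NvShak3"), p,
                       artifacts = artifact_params(noise_sd = 0.5, seed = 43))
  expect_identical(a$currents, b$currents)
  expect_false(identical(a$currents, d$currents))
  # the simulator does not disturb the caller's RNG stream
  set.seed(7); x1 <- runif(1)
  set.seed(7)
  invisible(simulate_sweeps(kv_fixture("NvShak3"), p,
                            artifacts = artifact_params(noise_sd = 0.5, seed = 9)))
  expect_identical(runif(1), x1)
})

test_that("heteromer current is the weighted sum of its components", {
  hom <- kv_fixture("NvShak3")
  het <- kv_fixture("NvShak2")
  p <- build_protocol("activation_family", n_sweeps = 5)
  f <- 0.3
  mix <- simulate_sweeps(heteromer_mix(hom, het, f), p)
  ih <- simulate_sweeps(hom, p)
  ie <- simulate_sweeps(het, p)
  expect_equal(mix$currents, (1 - f) * ih$currents + f * ie$currents,
               tolerance = 1e-12)
})

test_that("coarse sampling triggers a warning", {
  p <- build_protocol("activation_family", dt = 2)
  expect_warning(simulate_sweeps(kv_fixture("NvShak1"), p), "coarse")
})

test_that("P/N subtraction removes linear leak and capacitive transients", {
  p <- build_protocol("activation_family")
  model <- kv_fixture("NvShak1", truncated = TRUE)
  art <- artifact_params(g_leak = 0.3, e_leak = -5, c_mem = 0.1)
  # leak-only input (vanishing channel conductance)
  leak_model <- kv_fixture("NvShak2", g_max = 1e-12)
  rec_leak <- simulate_sweeps(leak_model, p, artifacts = art)
  sub_leak <- pn_leak_subtract(rec_leak)
  expect_lt(max(abs(sub_leak$currents)), 1e-9)
  # leak + channel: subtraction recovers the artifact-free simulation
  rec <- simulate_sweeps(model, p, artifacts = art)
  clean <- simulate_sweeps(model, p)
  sub <- pn_leak_subtract(rec)
  e_k <- nernst_potential(rec$solutions)
  bound <- 1e-6 * model$g_max * max(abs(c(-60, 60, -100) - e_k))
  expect_lt(max(abs(sub$currents - clean$currents)), bound)
  # linearity: doubling the leak leaves the subtracted output unchanged
  rec2 <- simulate_sweeps(model, p, artifacts = artifact_params(
    g_leak = 0.6, e_leak = -5, c_mem = 0.1))
  sub2 <- pn_leak_subtract(rec2)
  expect_equal(sub2$currents, sub$currents, tolerance = 1e-9)
})

test_that("P/N warns when sub-pulses reach activating voltages", {
  model <- kv_fixture("NvShak5", truncated = TRUE)
  p <- build_protocol("activation_family")
  rec <- simulate_sweeps(model, p, artifacts = artifact_params(g_leak = 0.2))
  # sub-holding near the activation range opens channels in the sub-sweeps
  expect_warning(pn_leak_subtract(rec, sub_hold = -20), "linear")
})

test_that("mechanistic mode with one gate reproduces the macroscopic relaxation", {
  fx <- kv_fixture("NvShak2")
  fx$activation$n_gates <- 1L
  p <- build_protocol("activation_family", n_sweeps = 5)
  m1 <- simulate_sweeps(fx, p, mode = "mechanistic")
  m2 <- simulate_sweeps(fx, p, mode = "macroscopic")
  expect_equal(m1$currents, m2$currents, tolerance = 1e-12)
})
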