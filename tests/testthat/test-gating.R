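test_that("steady-state activation follows the Boltzmann relation", {
  act <- activation_params(v50 = 2.1, s = 3.3)
  # midpoint
  expect_equal(steady_state_activation(act, 2.1), 0.5)
  # high-threshold channel barely open at -20 mV (closed-form value)
  expect_equal(steady_state_activation(act, -20), 1 / (1 + exp(22.1 / 3.3)))
  expect_lt(steady_state_activation(act, -20), 2e-3)
  # step-function limit for vanishing slope
  steep <- activation_params(v50 = 0, s = 1e-6)
  expect_gt(steady_state_activation(steep, 1), 1 - 1e-9)
  # strictly increasing on a broad grid
  grid <- seq(-160, 60, by = 2)
  po <- steady_state_activation(act, grid)
  expect_true(all(diff(po) > 0))
  expect_true(all(po > 0 & po < 1))
})

test_that("steady-state availability sums components over a pedestal", {
  one <- list(inact_component("N_type", tau_inact = 2.4, fraction = 1,
                              v50 = -20.3, s = 3.3))
  expect_equal(steady_state_availability(one, -200), 1, tolerance = 1e-9)
  expect_equal(steady_state_availability(one, -20.3), 0.5)
  # partial inactivation leaves a pedestal at depolarized voltages
  part <- list(inact_component("intrinsic", tau_inact = 150, fraction = 0.6,
                               v50 = -46.2, s = 3.1))
  expect_equal(steady_state_availability(part, 60), 0.4, tolerance = 1e-9)
  # non-increasing over the voltage grid
  av <- steady_state_availability(part, seq(-160, 60, 2))
  expect_true(all(diff(av) <= 0))
  # fractions must not exceed 1
  bad <- list(inact_component("N_type", 5, 0.7, -30, 3),
              inact_component("C_type", 50, 0.6, -30, 3))
  expect_error(steady_state_availability(bad, 0), "sum to > 1")
})

test_that("truncation removes N-type components and leaves the rest", {
  m <- gating_params(
    "test", activation = activation_params(-20, 5),
    inactivation = list(
      inact_component("N_type", 3, 0.3, -30, 3),
      inact_component("C_type", 100, 0.3, -30, 3),
      inact_component("intrinsic", 150, 0.3, -40, 3)
    ))
  expect_length(effective_inactivation(m), 3)
  m$truncated <- TRUE
  eff <- effective_inactivation(m)
  expect_length(eff, 2)
  expect_false(any(vapply(eff, `[[`, character(1), "mechanism") == "N_type"))
  # the fixture registry honours the same rule
  expect_length(effective_inactivation(kv_fixture("NvShak1", truncated = TRUE)), 0)
  expect_length(effective_inactivation(kv_fixture("NvShak4", truncated = TRUE)), 1)
})

test_that("kinetic rates expand time constants consistently", {
  m <- kv_fixture("NvShak4")
  # C-type rate falls to <= 4% of its zero-K+ value in 140 mM external K+
  r0 <- kinetic_rates(m, 60, k_out = 1e-9)
  r140 <- kinetic_rates(m, 60, k_out = 140)
  ct0 <- r0$rate_fwd[which(r0$component == "C_type_2")]
  ct140 <- r140$rate_fwd[which(r140$component == "C_type_2")]
  expect_lte(ct140 / ct0, 0.04)
  # N-type rates do not depend on external K+
  nt0 <- r0$rate_fwd[which(r0$component == "N_type_1")]
  nt140 <- r140$rate_fwd[which(r140$component == "N_type_1")]
  expect_equal(nt0, nt140)
  # forward + backward gate rates equal 1/tau at the +60 mV reference
  gate <- kinetic_rates(m, 60)[1, ]
  expect_equal(gate$rate_fwd + gate$rate_back, 1 / m$activation$tau_act_ref)
  # all rates non-negative
  expect_true(all(kinetic_rates(m, -40)$rate_fwd >= 0))
})

test_that("model constructors enforce their invariants", {
  expect_error(activation_params(v50 = 0, s = -1), "> 0")
  expect_error(inact_component("N_type", tau_inact = 3, fraction = 1.2,
                               v50 = -30, s = 3), "fraction")
  expect_error(gating_params("x", g_max = -1,
                             activation = activation_params(0, 5)), "g_max")
  expect_error(heteromer_mix(kv_fixture("NvShak3"), kv_fixture("NvShak2"),
                             het_fraction = 1.5), "het_fraction")
  expect_error(kv_fixture("NoSuchChannel"), "Unknown fixture")
})

test_that("fixture registry carries the published parameter values", {
  fx <- kv_fixture("NvShak5")
  expect_equal(fx$activation$v50, -30.1)
  expect_equal(fx$activation$s, 4.3)
  expect_equal(fx$inactivation[[1]]$tau_inact, 14.1)
  expect_equal(fx$inactivation[[1]]$v50, -59.0)
  expect_equal(fx$inactivation[[1]]$s, 6.1)
  expect_length(kv_fixture("NvShak3")$inactivation, 0)
  reg <- kv_fixtures()
  expect_true(all(paste0("NvShak", 1:6) %in% reg$name))
  expect_true(all(reg$authority[reg$name %in% paste0("NvShak", 1:6)] == "acceptance"))
  expect_equal(reg$authority[reg$name == "Kv1.2like"], "illustrative")
})
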