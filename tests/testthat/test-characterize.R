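test_that("threshold classification splits channels at 0 mV", {
  expect_equal(classify_threshold(2.1), "high")
  expect_equal(classify_threshold(-19.5), "low")
  expect_equal(classify_threshold(0), "high")
  expect_equal(classify_threshold(c(-0.8, 5)), c("low", "high"))
})

# shared noiseless bundles for the summary tests
make_bundle <- function(name, n_cells = 2) {
  fx <- kv_fixture(name)
  has_ntype <- any(vapply(fx$inactivation, function(cp) cp$mechanism == "N_type",
                          logical(1)))
  act <- simulate_sweeps(fx, build_protocol("activation_family",
                                            step_start = 60, n_sweeps = 1,
                                            step_duration = 600),
                         mode = "instantaneous_activation")
  gv <- lapply(seq_len(n_cells), function(ci) {
    simulate_sweeps(kv_fixture(name, truncated = has_ntype),
                    build_protocol("gv_tail"),
                    solutions = symmetrical_k_solutions())
  })
  ssi <- if (length(fx$inactivation)) {
    lapply(seq_len(n_cells), function(ci) {
      simulate_sweeps(fx, build_protocol("ssi"))
    })
  }
  list(activation_family = act, gv_tail = gv, ssi = ssi)
}

test_that("channel summaries reproduce the published table rows", {
  s1 <- summarize_channel(make_bundle("NvShak1"), name = "NvShak1")
  expect_equal(s1$tau_inact[[1]]$tau, 2.4, tolerance = 0.02 * 2.4)
  expect_equal(s1$ssi_v50, -20.3, tolerance = 0.5)
  expect_equal(s1$ssi_slope, 3.3, tolerance = 0.2)
  expect_equal(s1$gv_v50, -19.5, tolerance = 0.5)
  expect_equal(s1$gv_slope, 5.7, tolerance = 0.2)
  expect_equal(s1$threshold_class, "low")
  expect_equal(s1$inactivation_class, "fast")

  s2 <- summarize_channel(make_bundle("NvShak2"), name = "NvShak2")
  expect_true(is.null(s2$tau_inact[[1]]))
  expect_true(is.na(s2$ssi_v50))
  expect_equal(s2$gv_v50, 2.1, tolerance = 0.5)
  expect_equal(s2$gv_slope, 3.3, tolerance = 0.2)
  expect_equal(s2$threshold_class, "high")
  expect_equal(s2$inactivation_class, "none")

  s4 <- summarize_channel(make_bundle("NvShak4"), name = "NvShak4")
  tt <- s4$tau_inact[[1]]
  expect_equal(nrow(tt), 2)
  expect_equal(sort(tt$tau), c(33.5, 153.6), tolerance = 0.02)
  expect_equal(tt$fraction[order(tt$tau)], c(0.32, 0.68), tolerance = 0.02)
  expect_equal(s4$inactivation_class, "slow")

  s6 <- summarize_channel(make_bundle("NvShak6"), name = "NvShak6")
  expect_equal(s6$inactivation_class, "partial")
  expect_equal(s6$ssi_v50, -46.2, tolerance = 0.5)
})

test_that("summaries are deterministic across identical bundles", {
  a <- summarize_channel(make_bundle("NvShak5", n_cells = 1))
  b <- summarize_channel(make_bundle("NvShak5", n_cells = 1))
  expect_identical(a$gv_v50, b$gv_v50)
  expect_identical(a$ssi_v50, b$ssi_v50)
  expect_identical(a$tau_inact[[1]], b$tau_inact[[1]])
  expect_error(summarize_channel(list(ssi = NULL)), "missing")
})

test_that("heteromer comparison reproduces the qualitative phenotype flags", {
  hom <- kv_heteromer_homomer()
  fam_p <- build_protocol("heteromer_family")
  pp_p <- build_protocol("heteromer_prepulse", step_start = -100,
                         test_duration = 1000)
  hom_fam <- simulate_sweeps(hom, fam_p)
  run <- function(nm, family = TRUE, prepulse = TRUE) {
    mixm <- kv_heteromer_preset(nm)
    mix <- list()
    if (family) mix$family <- suppressWarnings(simulate_sweeps(mixm, fam_p))
    if (prepulse) mix$prepulse <- suppressWarnings(simulate_sweeps(mixm, pp_p))
    compare_heteromer(mix, list(family = hom_fam))
  }
  # inactivating subunit with large shift and slowed deactivation;
  # activation obscured by the fast heteromeric inactivation
  r8 <- run("NvShakR8")
  expect_equal(r8$inactivation, "fast")
  expect_equal(r8$threshold_shift, "large")
  expect_equal(r8$activation_rate, "undetermined")
  expect_equal(r8$deactivation_rate, "slow")
  # slowed activation is the only change for this subunit
  r7 <- run("NvShakR7")
  expect_equal(r7$inactivation, "none")
  expect_equal(r7$threshold_shift, "none")
  expect_equal(r7$activation_rate, "slow")
  expect_equal(r7$deactivation_rate, "none")
  # slow and very fast inactivation classes from pre-pulse runs alone
  r1 <- run("NvShakR1", family = FALSE)
  expect_equal(r1$inactivation, "slow")
  expect_equal(r1$threshold_shift, "undetermined")
  r11 <- run("NvShakR11", family = FALSE)
  expect_equal(r11$inactivation, "very_fast")
  # hyperpolarizing-shift grades
  expect_equal(run("NvShakR2")$threshold_shift, "medium")
  expect_equal(run("NvShakR4")$threshold_shift, "small")
  r5 <- run("NvShakR5")
  expect_equal(r5$threshold_shift, "large")
  expect_equal(r5$activation_rate, "fast")
  expect_equal(r5$deactivation_rate, "none")
  # no heteromers: all flags none
  mix0 <- heteromer_mix(hom, kv_heteromer_preset("NvShakR8")$heteromer, 0)
  r0 <- compare_heteromer(
    list(family = simulate_sweeps(mix0, fam_p),
         prepulse = simulate_sweeps(mix0, pp_p)),
    list(family = hom_fam))
  expect_equal(unlist(r0[1, 1:4]), c(inactivation = "none", threshold_shift = "none",
                                     activation_rate = "none", deactivation_rate = "none"))
  # family recording without a homomeric control is an error
  expect_error(compare_heteromer(list(family = hom_fam), list()), "control")
})
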