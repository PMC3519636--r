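test_that("Boltzmann fit recovers generating parameters on noiseless data", {
  v <- seq(-60, 60, 10)
  # normalized increasing (GV form), published low-threshold parameters
  g <- 1 / (1 + exp(-(v - -19.5) / 5.7))
  fit <- fit_boltzmann(v, g, normalized = TRUE)
  expect_equal(fit$v50, -19.5, tolerance = 1e-6)
  expect_equal(fit$s, 5.7, tolerance = 1e-6)
  expect_true(fit$converged)
  # general 4-parameter form with scaled amplitudes
  g2 <- (0.1 - 2.3) / (1 + exp((v - 5) / 4)) + 2.3
  fit2 <- fit_boltzmann(v, g2)
  expect_equal(fit2$v50, 5, tolerance = 1e-6)
  expect_equal(fit2$s, 4, tolerance = 1e-6)
  expect_equal(fit2$a1, 0.1, tolerance = 1e-6)
  expect_equal(fit2$a2, 2.3, tolerance = 1e-6)
  # midpoint identity on the fitted curve
  expect_equal(predict(fit2, fit2$v50), (fit2$a1 + fit2$a2) / 2)
  # direction inference: decreasing availability data
  av <- 0.3 + 0.7 / (1 + exp((v - -37) / 2.2))
  fit3 <- fit_boltzmann(v, av, normalized = TRUE)
  expect_equal(fit3$direction, "decreasing")
  expect_equal(fit3$v50, -37, tolerance = 1e-6)
  expect_equal(fit3$a2, 0.3, tolerance = 1e-6)
  expect_error(fit_boltzmann(c(-10, 0, 10), c(0.1, 0.5, 0.9)), "at least 4")
})

test_that("Boltzmann fit is unbiased under moderate noise", {
  v <- seq(-60, 60, 10)
  g0 <- 1 / (1 + exp(-(v - -19.5) / 5.7))
  set.seed(101)
  v50s <- replicate(200, {
    fit <- fit_boltzmann(v, g0 + rnorm(length(v), 0, 0.02), normalized = TRUE)
    fit$v50
  })
  expect_lt(abs(mean(v50s) - -19.5), 0.3)
})

test_that("fitters agree with an independent grid-search oracle", {
  set.seed(11)
  for (rep in 1:5) {
    v50 <- runif(1, -45, 10); s <- runif(1, 2, 9)
    v <- seq(-60, 60, 10)
    g <- 1 / (1 + exp(-(v - v50) / s))
    fit <- fit_boltzmann(v, g, normalized = TRUE)
    orc <- oracle_boltzmann(v, g, normalized = TRUE, increasing = TRUE)
    expect_equal(fit$v50, orc$v50, tolerance = 0.02)
    expect_equal(fit$s, orc$s, tolerance = 0.02)
  }
  for (rep in 1:5) {
    tau <- runif(1, 1, 50); a <- runif(1, 1, 20); off <- runif(1, -2, 2)
    tr <- make_decay(tau, a, off)
    fit <- fit_exponential(tr$t, tr$i)
    orc <- oracle_exponential(tr$t, tr$i)
    expect_equal(fit$tau, orc$tau, tolerance = 0.01 * tau)
    expect_equal(fit$a, orc$a, tolerance = 0.01 * a)
  }
})

test_that("single-exponential fit recovers published time constants", {
  fast <- make_decay(2.4, a = 10)
  expect_equal(fit_exponential(fast$t, fast$i)$tau, 2.4, tolerance = 1e-6)
  slow <- make_decay(14.1, a = 10)
  expect_equal(fit_exponential(slow$t, slow$i)$tau, 14.1, tolerance = 1e-6)
  # rises carry negative amplitude
  t <- seq(0, 30, 0.05)
  rise <- 8 - 8 * exp(-t / 3)
  frise <- fit_exponential(t, rise)
  expect_lt(frise$a, 0)
  expect_equal(frise$tau, 3, tolerance = 1e-6)
  expect_error(fit_exponential(t, rep(2, length(t))), "flat")
})

test_that("double-exponential fit resolves the published two-component decay", {
  t <- seq(0, 600, 0.2)
  i <- 0.32 * exp(-t / 33.5) + 0.68 * exp(-t / 153.6)
  fit <- fit_double_exponential(t, i)
  expect_equal(fit$tau1, 33.5, tolerance = 1e-4)
  expect_equal(fit$tau2, 153.6, tolerance = 1e-4)
  expect_equal(fit$f1, 0.32, tolerance = 1e-4)
  expect_equal(fit$f2, 0.68, tolerance = 1e-4)
  expect_equal(fit$f1 + fit$f2, 1)
  expect_lt(fit$tau1, fit$tau2)
  # a pure single exponential is absorbed by one dominant component
  one <- make_decay(20, a = 5, t_max = 150)
  fone <- fit_double_exponential(one$t, one$i)
  expect_gte(max(fone$f1, fone$f2), 0.99)
})

test_that("model selection distinguishes one from two exponential components", {
  t <- seq(0, 600, 0.2)
  # two well-separated components with substantial amplitudes -> 2
  two <- 0.32 * exp(-t / 33.5) + 0.68 * exp(-t / 153.6)
  expect_equal(select_inactivation_model(t, two)$n_components, 2L)
  # a single component -> 1
  one <- exp(-t / 33.5)
  expect_equal(select_inactivation_model(t, one)$n_components, 1L)
  # a 1%-amplitude second component is not declared a second phase
  tiny <- 0.99 * exp(-t / 30) + 0.01 * exp(-t / 150)
  expect_equal(select_inactivation_model(t, tiny)$n_components, 1L)
  # poorly separated time constants are not declared two phases
  close <- 0.5 * exp(-t / 30) + 0.5 * exp(-t / 60)
  expect_equal(select_inactivation_model(t, close)$n_components, 1L)
})

test_that("tidy and glance expose fit parameters in broom style", {
  tr <- make_decay(5, a = 3, i_i = 1)
  fit <- fit_exponential(tr$t, tr$i)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "tau"], 5, tolerance = 1e-6)
  gl <- glance(fit)
  expect_true(gl$converged)
  v <- seq(-60, 60, 10)
  bf <- fit_boltzmann(v, 1 / (1 + exp(-(v + 10) / 5)), normalized = TRUE)
  expect_equal(tidy(bf)$estimate[tidy(bf)$term == "v50"], -10, tolerance = 1e-6)
  expect_equal(glance(bf)$n, 13)
})
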