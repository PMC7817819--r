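pars <- muscle_params(f_max = 1000, l_opt = 0.1, l_slack = 0.2,
                      alpha_opt = 0)

test_that("resting excitation keeps activation at rest", {
  a <- excitation_to_activation(rep(0, 200), pars, rate = 1000)
  expect_true(all(a == 0))
})

test_that("step excitation gives monotone saturating activation without overshoot", {
  u <- c(rep(0, 50), rep(1, 950))
  a <- excitation_to_activation(u, pars, rate = 1000, a0 = 0)
  expect_true(all(diff(a) >= -1e-12))
  expect_true(all(a <= 1))
  expect_gt(a[length(a)], 0.99)
})

test_that("backward Euler at 1 kHz matches a fine-step integration oracle", {
  # oracle: forward Euler of the same ODE at 100 kHz. A first-order-accurate
  # scheme can only track the continuous solution this closely for smooth
  # excitation, so the probe is a slow sinusoid (envelope-like input).
  rate <- 1000
  t <- seq(0, 2, by = 1 / rate)
  u <- 0.5 + 0.3 * sin(2 * pi * 0.5 * t)
  a_pkg <- excitation_to_activation(u, pars, rate, a0 = u[1],
                                    nonlinearity = FALSE)
  fine <- 100
  dt <- 1 / (rate * fine)
  a <- u[1]
  a_or <- numeric(length(u))
  a_or[1] <- a
  for (k in seq_len(length(u) - 1L)) {
    u0 <- u[k]; u1 <- u[k + 1L]
    for (j in seq_len(fine)) {
      uu <- u0 + (u1 - u0) * j / fine
      tau <- if (uu > a) pars$tau_act * (0.5 + 1.5 * a)
             else pars$tau_deact / (0.5 + 1.5 * a)
      a <- a + dt * (uu - a) / tau
      a <- min(max(a, 0), 1)
    }
    a_or[k + 1L] <- a
  }
  expect_lt(max(abs(a_pkg - a_or)), 1e-3)
})

test_that("activation stays in [0, 1] for arbitrary bounded excitation", {
  for (seed in 1:10) {
    set.seed(seed)
    u <- runif(300)
    a <- excitation_to_activation(u, pars, rate = 500, a0 = runif(1))
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("tendon force matches closed-form anchor points", {
  l_at <- function(lt) pars$l_slack + lt * pars$l_opt  # alpha = 0
  expect_equal(tendon_force(pars, 0, l_at(0.9)), 0)
  expect_equal(tendon_force(pars, 1, l_at(1)), 1000)
  expect_equal(tendon_force(pars, 0.5, l_at(1)), 500)
  expect_error(tendon_force(pars, 0, pars$l_slack), "slack")
  expect_error(tendon_force(pars, 1.2, l_at(1)), "activation")
})

test_that("tendon force is continuous in length and nondecreasing in activation", {
  l <- seq(pars$l_slack + 0.05 * pars$l_opt, pars$l_slack + 1.5 * pars$l_opt,
           length.out = 400)
  f <- tendon_force(pars, 0.6, l)
  expect_true(all(abs(diff(f)) < 30))  # no jumps on a fine grid
  a <- seq(0, 1, 0.05)
  f_a <- tendon_force(pars, a, rep(pars$l_slack + 0.95 * pars$l_opt,
                                   length(a)))
  expect_true(all(diff(f_a) >= 0))
})

test_that("force slope is zero at the active-curve peak and in the slack inactive state", {
  # lengths chosen exactly representable in binary so l_tilde is exactly 1
  p2 <- muscle_params(f_max = 1000, l_opt = 0.25, l_slack = 0.25,
                      alpha_opt = 0)
  expect_equal(tendon_force_slope(p2, 1, 0.5), 0)
  expect_equal(tendon_force_slope(p2, 0, 0.25 + 0.875 * 0.25), 0)
})

test_that("analytic force slope matches central differences over random states", {
  h <- 1e-7
  for (seed in 1:25) {
    set.seed(seed)
    p <- muscle_params(f_max = runif(1, 300, 3000),
                       l_opt = runif(1, 0.06, 0.15),
                       l_slack = runif(1, 0.05, 0.3),
                       alpha_opt = runif(1, 0, 0.4))
    a <- runif(1)
    lt <- runif(1, 0.6, 1.5)
    l_mt <- p$l_slack +
      sqrt(pmax((lt * p$l_opt)^2 - (p$l_opt * sin(p$alpha_opt))^2, 1e-8))
    fd <- (tendon_force(p, a, l_mt + h) - tendon_force(p, a, l_mt - h)) /
      (2 * h)
    an <- tendon_force_slope(p, a, l_mt)
    expect_equal(an, fd, tolerance = 1e-4)
  }
})

test_that("physiologically inconsistent parameters are rejected", {
  expect_error(muscle_params(1000, 0.1, 0.2, tau_act = 0.08,
                             tau_deact = 0.05), "tau_act")
  expect_error(muscle_params(-5, 0.1, 0.2))
})
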