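test_that("preset topologies have the frozen structure", {
  pe <- flux_model("pm_er")
  expect_length(pe$compartments, 2)
  expect_equal(nrow(pe$edges), 2)

  m1a <- flux_model("1a")
  expect_length(m1a$compartments, 5)
  expect_equal(nrow(m1a$edges), 7)
  expect_false(m1a$content_decay)

  m1b <- flux_model("1b")
  expect_true(all(rate_names(m1a) %in% rate_names(m1b)))
  expect_equal(nrow(m1b$edges), 10)

  expect_true(flux_model("2a")$content_decay)
  expect_true("k_Endo_PM" %in% rate_names(flux_model("3a")))
  # in the b-family the recycling edge is already an anterograde leg
  expect_setequal(rate_names(flux_model("3b")), rate_names(flux_model("2b")))

  expect_error(flux_model("9z"), "Valid presets")
})

test_that("simulate_flux handles degenerate inputs", {
  m <- flux_model("1a")
  tr <- simulate_flux(m, rates_for(m, 0), times = c(0, 10, 100))
  # all rates zero: state frozen at x0
  pm <- dplyr::filter(tr, organelle == "PM")
  expect_equal(pm$fraction, rep(1, 3))
  expect_equal(dplyr::filter(tr, organelle != "PM")$fraction, rep(0, 12))

  expect_error(simulate_flux(m, rates_for(m, -0.1), times = 0:1),
               "non-negative")
  expect_error(simulate_flux(m, rates_for(m)[-1], times = 0:1), "Missing")
  expect_error(simulate_flux(m, rates_for(m), times = c(3, 1)), "sorted")
})

test_that("pm_er relaxation matches symmetry and the closed form", {
  m <- flux_model("pm_er")
  # equal rates from all-PM: equilibrium at 1/2
  tr <- simulate_flux(m, c(k_PM_ER = 0.1, k_ER_PM = 0.1), times = c(0, 1e5))
  expect_equal(dplyr::filter(tr, organelle == "PM")$fraction[2], 0.5,
               tolerance = 1e-10)

  # closed form x_PM(t) = 1/3 + (2/3) exp(-0.3 t) for k1 = 0.2, k2 = 0.1
  times <- c(0, 0.5, 2, 10, 50, 200)
  tr <- simulate_flux(m, pm_er_rates, times = times)
  pm <- dplyr::filter(tr, organelle == "PM")$fraction
  expect_equal(pm, 1 / 3 + (2 / 3) * exp(-0.3 * times), tolerance = 1e-10)
})

test_that("analytic_pm_er oracle behaves and agrees with the solver", {
  expect_equal(analytic_pm_er(0.3, 0.1, 0.8, 0), 0.8)
  expect_equal(analytic_pm_er(0.2, 0.1, 1, 1e9), 1 / 3)  # k1 = 2 k2
  expect_equal(analytic_pm_er(0, 0, 0.4, c(0, 7)), c(0.4, 0.4))

  m <- flux_model("pm_er")
  set.seed(11)
  for (i in 1:20) {
    k <- 10^runif(2, -3, 0.5)
    t <- sort(runif(4, 0, 500))
    tr <- simulate_flux(m, c(k_PM_ER = k[1], k_ER_PM = k[2]), times = t)
    pm <- dplyr::filter(tr, organelle == "PM")$fraction
    expect_equal(pm, analytic_pm_er(k[1], k[2], 1, t), tolerance = 1e-8)
  }
})

test_that("solver agrees with matrix-exponential and stiff-ODE oracles", {
  skip_if_not_installed("deSolve")
  set.seed(21)
  for (preset in c("1a", "1b", "pm_er")) {
    m <- flux_model(preset)
    rates <- setNames(10^runif(length(rate_names(m)), -3, 0),
                      rate_names(m))
    x0 <- x0_pulse(m)
    times <- c(0, 4, 30, 120, 1440)
    got <- lipoflux:::simulate_flux_matrix(m, rates, x0, times)
    # direct matrix exponential
    A <- lipoflux:::flux_matrix(m, rates)
    expm_ref <- t(vapply(times, function(t) {
      as.numeric(Matrix::expm(A * t) %*% x0)
    }, numeric(length(x0))))
    expect_lt(max(abs(got - expm_ref)), 1e-8)
    # independent stiff integrator
    ode_ref <- desolve_solution(m, rates, x0, times)
    expect_lt(max(abs(got - ode_ref)), 1e-7)
  }
})

test_that("mass is conserved and fractions stay non-negative", {
  set.seed(31)
  times <- seq(0, 1440, by = 60)
  for (preset in c("1a", "1b", "2a", "2b", "3a", "3b", "pm_er")) {
    m <- flux_model(preset)
    rates <- setNames(10^runif(length(rate_names(m)), -3, 0),
                      rate_names(m))
    tr <- simulate_flux(m, rates, times = times)  # no content decay
    sums <- tapply(tr$fraction, tr$time_min, sum)
    expect_lt(max(abs(sums - 1)), 1e-8)
    expect_gt(min(tr$fraction), -1e-10)
  }
})

test_that("content decay scales totals exponentially", {
  m <- flux_model("2a")
  rates <- rates_for(m, 0.05)
  tr <- simulate_flux(m, rates, times = c(0, 100, 1440),
                      content_decay_rate = 0.001)
  sums <- tapply(tr$fraction, tr$time_min, sum)
  expect_equal(as.numeric(sums), exp(-0.001 * c(0, 100, 1440)),
               tolerance = 1e-8)
  # presets without decay ignore the rate with a warning
  expect_warning(
    simulate_flux(flux_model("1a"), rates_1a, times = c(0, 10),
                  content_decay_rate = 0.001),
    "ignored"
  )
})

test_that("pm_er relaxation from all-PM is strictly monotone", {
  times <- seq(0, 40, by = 2)  # within the relaxation window
  tr <- simulate_flux(flux_model("pm_er"), pm_er_rates, times = times)
  pm <- dplyr::filter(tr, organelle == "PM")$fraction
  expect_true(all(diff(pm) < 0))
  expect_true(all(pm > 1 / 3))  # approaches x_eq from above
})

test_that("quasi-equilibrium constant and non-vesicular share", {
  expect_equal(quasi_equilibrium(c(k_PM_ER = 0.1, k_ER_PM = 0.1)), 1)
  expect_equal(quasi_equilibrium(c(k_PM_ER = 0.22, k_ER_PM = 0.10)), 2.2)
  expect_error(quasi_equilibrium(c(k_PM_ER = 0.1, k_ER_PM = 0)),
               "undefined")

  expect_equal(nonvesicular_share(c(k_PM_ER = 0.1, k_PM_Endo = 0.1)), 0.5)
  expect_equal(nonvesicular_share(c(k_PM_ER = 0.11, k_PM_Endo = 0.01)),
               11 / 12)
  expect_equal(nonvesicular_share(c(k_PM_ER = 0.1, k_PM_Endo = 0)), 1)
  expect_error(nonvesicular_share(c(k_PM_ER = 0, k_PM_Endo = 0)),
               "undefined")
})

test_that("MC-sample routes of derived constants match brute force", {
  fit <- structure(
    list(
      point_estimate = c(k_PM_ER = 0.2, k_ER_PM = 0.1, k_PM_Endo = 0.02),
      mc_samples = cbind(
        k_PM_ER = c(0.18, 0.2, 0.22, 0.21),
        k_ER_PM = c(0.09, 0.1, 0.11, 0.10),
        k_PM_Endo = c(0.02, 0.025, 0.015, 0.02)
      )
    ),
    class = "flux_fit"
  )
  K <- quasi_equilibrium(fit)
  ks <- fit$mc_samples[, 1] / fit$mc_samples[, 2]
  expect_equal(K$mc_mean, mean(ks))
  expect_equal(K$mc_sd, sd(ks))
  sh <- nonvesicular_share(fit)
  ss <- fit$mc_samples[, 1] / (fit$mc_samples[, 1] + fit$mc_samples[, 3])
  expect_equal(sh$mc_mean, mean(ss))
  expect_equal(sh$mc_sd, sd(ss))
})
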