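test_that("objective matches brute-force arithmetic and scales with sd", {
  m <- flux_model("pm_er")
  tc <- sim_timecourse(m, pm_er_rates, noise_sd = 0, seed = 1)
  tc$sd <- 0.02
  # model equals the data -> objective 0
  expect_equal(flux_objective(tc, m, pm_er_rates), 0, tolerance = 1e-12)

  # hand-computed toy: 2 timepoints x 2 compartments
  toy <- tibble::tibble(
    time_min = c(0, 0, 10, 10),
    organelle = c("PM", "ER", "PM", "ER"),
    mean = c(0.95, 0.05, 0.60, 0.40),
    sd = c(0.02, 0.02, 0.05, 0.05),
    n = 5
  )
  pred <- analytic_pm_er(0.2, 0.1, 0.95, c(0, 10))
  by_hand <- sum(((c(pred[1], 1 - pred[1] - 0, pred[2], 1 - pred[2] - 0) -
                     c(0.95, 0.05, 0.60, 0.40)) /
                    c(0.02, 0.02, 0.05, 0.05))^2)
  # x0 for the objective comes from the t = 0 means: (0.95, 0.05),
  # so compute the expected trajectory with that start
  A <- lipoflux:::flux_matrix(m, pm_er_rates)
  x0 <- c(PM = 0.95, ER = 0.05)
  pred2 <- t(vapply(c(0, 10), function(t) {
    as.numeric(Matrix::expm(A * t) %*% x0)
  }, numeric(2)))
  by_hand2 <- sum(((c(pred2[1, 1], pred2[1, 2], pred2[2, 1], pred2[2, 2]) -
                      c(0.95, 0.05, 0.60, 0.40)) /
                     c(0.02, 0.02, 0.05, 0.05))^2)
  expect_equal(flux_objective(toy, m, pm_er_rates), by_hand2,
               tolerance = 1e-10)

  # doubling every sd scales the objective by exactly 1/4
  toy2 <- toy
  toy2$sd <- toy$sd * 2
  expect_equal(flux_objective(toy2, m, pm_er_rates),
               flux_objective(toy, m, pm_er_rates) / 4, tolerance = 1e-10)
})

test_that("objective excludes organelles the model does not contain", {
  m <- flux_model("pm_er")
  tc <- sim_timecourse(m, pm_er_rates, noise_sd = 0, seed = 1)
  tc$sd <- 0.02
  extra <- dplyr::bind_rows(tc, tibble::tibble(
    time_min = 0, organelle = "LD", mean = 0.1, sd = 0.02, n = 5
  ))
  expect_message(
    val <- flux_objective(extra, m, pm_er_rates),
    "Excluding organelles"
  )
  expect_equal(val, flux_objective(tc, m, pm_er_rates))
  no_overlap <- tibble::tibble(time_min = 0, organelle = "LD",
                               mean = 1, sd = 0.1, n = 5)
  expect_error(suppressMessages(flux_objective(no_overlap, m, pm_er_rates)),
               "No overlap")
})

test_that("noiseless pm_er data are recovered within 1% relative", {
  m <- flux_model("pm_er")
  tc <- sim_timecourse(m, pm_er_rates, noise_sd = 0, seed = 1)
  fit <- suppressMessages(fit_flux(tc, m, n_starts = 8, seed = 2))
  rel <- abs(fit$point_estimate - pm_er_rates) / pm_er_rates
  expect_lt(max(rel), 0.01)
  expect_lt(fit$objective, 1e-10)
})

test_that("fits are invariant to row order and organelle name case", {
  m <- flux_model("pm_er")
  tc <- sim_timecourse(m, pm_er_rates, noise_sd = 0.02, seed = 3)
  fit1 <- suppressMessages(fit_flux(tc, m, n_starts = 5, seed = 9))
  shuffled <- tc[sample(nrow(tc)), ]
  fit2 <- suppressMessages(fit_flux(shuffled, m, n_starts = 5, seed = 9))
  expect_equal(fit1$point_estimate, fit2$point_estimate, tolerance = 1e-10)
  lower <- tc
  lower$organelle <- tolower(lower$organelle)
  fit3 <- suppressMessages(fit_flux(lower, m, n_starts = 5, seed = 9))
  expect_equal(fit1$point_estimate, fit3$point_estimate, tolerance = 1e-10)
})

test_that("MC uncertainty is deterministic and degenerates with sd = 0", {
  m <- flux_model("pm_er")
  tc <- sim_timecourse(m, pm_er_rates, noise_sd = 0, seed = 1)  # sd = 0
  fit <- suppressMessages(fit_flux(tc, m, n_starts = 5, seed = 2))
  mc1 <- suppressMessages(mc_uncertainty(fit, n_mc = 5, seed = 4,
                                         n_starts = 1))
  # perturbations draw from Normal(mean, 0): every run identical
  expect_equal(unname(apply(mc1$mc_samples, 2, sd)), c(0, 0),
               tolerance = 1e-8)

  tc2 <- sim_timecourse(m, pm_er_rates, noise_sd = 0.02, seed = 5)
  fit2 <- suppressMessages(fit_flux(tc2, m, n_starts = 5, seed = 2))
  a <- suppressMessages(mc_uncertainty(fit2, n_mc = 8, seed = 11))
  b <- suppressMessages(mc_uncertainty(fit2, n_mc = 8, seed = 11))
  expect_identical(a$mc_samples, b$mc_samples)
  expect_equal(a$mc_summary$mc_mean, unname(colMeans(a$mc_samples)))
  expect_equal(a$mc_summary$mc_sd, unname(apply(a$mc_samples, 2, sd)))
  expect_error(mc_uncertainty(fit2, n_mc = 1), "n_mc")
})

test_that("weakly constrained anterograde legs are flagged by MC CV", {
  # data generated from 1a dynamics carry no information on the explicit
  # anterograde legs of 1b; their MC coefficient of variation must exceed
  # the identifiability threshold
  m1a <- flux_model("1a")
  m1b <- flux_model("1b")
  tc <- sim_timecourse(m1a, rates_1a, noise_sd = 0.02, seed = 21)
  fit <- suppressMessages(fit_flux(tc, m1b, x0 = x0_pulse(m1b),
                                   n_starts = 10, seed = 22))
  fit <- suppressMessages(suppressWarnings(
    mc_uncertainty(fit, n_mc = 30, seed = 23)
  ))
  legs <- c("k_ER_Golgi", "k_Golgi_Endo", "k_Endo_PM")
  flagged <- dplyr::filter(fit$mc_summary, rate %in% legs)$poorly_identified
  expect_true(any(flagged))
})

test_that("cohens_d matches the pooled-s.d. formula and is symmetric", {
  a <- c(1.0, 1.2, 1.4)
  b <- c(2.0, 2.5, 3.0)
  sp <- sqrt(((3 - 1) * sd(a)^2 + (3 - 1) * sd(b)^2) / (3 + 3 - 2))
  expect_equal(cohens_d(a, b)$d, abs(mean(a) - mean(b)) / sp)
  expect_equal(cohens_d(a, b)$d, cohens_d(b, a)$d)

  same <- cohens_d(a, a)
  expect_equal(same$d, 0)
  expect_equal(same$category, "negligible")

  degen <- cohens_d(c(1, 1), c(2, 2))
  expect_true(degen$d_infinite)
  expect_equal(degen$category, "huge")
  expect_error(cohens_d(1, a), "at least 2")
})

test_that("effect-size categories follow the printed thresholds", {
  expect_equal(
    effect_size_category(c(0.005, 0.01, 0.05, 0.27, 0.6, 1.0, 1.5, 2.3)),
    c("negligible", "negligible", "very small", "small", "medium",
      "large", "very large", "huge")
  )
  # boundary values belong to the lower category (half-open intervals)
  expect_equal(effect_size_category(c(0.2, 0.5, 0.8, 1.2, 2.0)),
               c("very small", "small", "medium", "large", "very large"))
})

test_that("fold change: identity, fixed ratio, and propagation vs MC", {
  mk_fit <- function(samples) {
    structure(list(mc_samples = samples,
                   point_estimate = colMeans(samples)),
              class = "flux_fit")
  }
  set.seed(33)
  base <- cbind(k_PM_ER = rnorm(100, 0.2, 0.02))
  fit_a <- mk_fit(base)
  expect_equal(fold_change(fit_a, fit_a, "k_PM_ER")$fold_change, 1)

  # a = 0.57 b by construction
  fit_b <- mk_fit(cbind(k_PM_ER = base[, 1] / 0.57))
  expect_equal(fold_change(fit_a, fit_b, "k_PM_ER")$fold_change, 0.57,
               tolerance = 1e-9)

  # first-order propagation against the empirical ratio distribution
  set.seed(34)
  sa <- cbind(k_PM_ER = rnorm(2000, 0.2, 0.02))   # CV 0.1
  sb <- cbind(k_PM_ER = rnorm(2000, 0.1, 0.01))
  fc <- fold_change(mk_fit(sa), mk_fit(sb), "k_PM_ER")
  ratios <- sample(sa[, 1]) / sample(sb[, 1])
  expect_equal(fc$sd, sd(ratios), tolerance = 0.1)
  expect_error(fold_change(fit_a, fit_b, "k_ER_PM"), "not present")
})

test_that("tidy and glance expose fit results", {
  m <- flux_model("pm_er")
  tc <- sim_timecourse(m, pm_er_rates, noise_sd = 0.02, seed = 6)
  fit <- suppressMessages(fit_flux(tc, m, n_starts = 5, seed = 7))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, rate_names(m))
  gl <- glance(fit)
  expect_equal(gl$preset, "pm_er")
  expect_true(gl$converged)
  fit <- suppressMessages(mc_uncertainty(fit, n_mc = 5, seed = 8))
  expect_true(all(c("mc_mean", "mc_sd") %in% names(tidy(fit))))
})
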