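# Shared fixtures: small rate sets, time courses and toy images built in code.

pm_er_rates <- c(k_PM_ER = 0.2, k_ER_PM = 0.1)

rates_1a <- c(
  k_PM_Endo = 0.02, k_Endo_Golgi = 0.05, k_Golgi_ER = 0.05,
  k_PM_ER = 0.15, k_ER_PM = 0.08, k_ER_Mito = 0.03, k_Mito_ER = 0.05
)

rates_for <- function(model, value = 0.05) {
  setNames(rep(value, length(rate_names(model))), rate_names(model))
}

x0_pulse <- function(model) {
  x0 <- setNames(rep(0, length(model$compartments)), model$compartments)
  x0["PM"] <- 1
  x0
}

# Reference ODE solution via deSolve (independent numeric oracle).
desolve_solution <- function(model, rates, x0, times, decay = 0) {
  A <- lipoflux:::flux_matrix(model, rates, decay)
  out <- deSolve::lsoda(
    y = x0, times = times,
    func = function(t, y, p) list(as.vector(A %*% y)),
    atol = 1e-12, rtol = 1e-10
  )
  unname(as.matrix(out[, -1, drop = FALSE]))
}

# Two-organelle toy field with a controllable overlap fraction of each
# region; regions are 16 x 32 side-by-side blocks inside a 64 x 64 frame.
two_org_layout <- function(overlap_cols = 8) {
  d <- c(64, 64)
  list(
    ER = rect_mask(d, 17:48, 5:(32 + overlap_cols)),
    Mito = rect_mask(d, 17:48, 33:60)
  )
}
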