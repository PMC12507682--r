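#' Weighted sum-of-squares objective for a compartment model
#'
#' Sum over timepoints and organelles of ((model - mean) / sd)^2. Organelles
#' in the data that are not compartments of the model (for example lipid
#' droplets) are excluded with a message. Observations with sd = 0 get a
#' floor (`sd_floor`) so weights stay finite.
#'
#' @param timecourse Data frame with columns `time_min`, `organelle`,
#'   `mean`, `sd` (and optionally `n`). Organelle names are normalized via
#'   [normalize_organelle()].
#' @param model A `flux_model`.
#' @param rates Named numeric vector of rate constants.
#' @param x0 Initial fractions; default: taken from the t = 0 means,
#'   normalized (see [fit_flux()]).
#' @param content_decay_rate Fixed content-decay rate (min^-1) for presets
#'   with content decay.
#' @param sd_floor Replacement for zero standard deviations (fraction
#'   units), default 1e-3.
#' @return The scalar weighted SSR.
#' @export
#' @examples
#' m <- flux_model("pm_er")
#' tc <- sim_timecourse(m, c(k_PM_ER = 0.1, k_ER_PM = 0.05), noise_sd = 0)
#' flux_objective(tc, m, c(k_PM_ER = 0.1, k_ER_PM = 0.05))
flux_objective <- function(timecourse, model, rates, x0 = NULL,
                           content_decay_rate = 0, sd_floor = 1e-3) {
  prep <- prepare_fit_data(timecourse, model, sd_floor)
  x0 <- resolve_fit_x0(model, prep, x0)
  sum(flux_residuals(check_rates(model, rates), prep, model, x0,
                     content_decay_rate)^2)
}

# Validate and reshape a time course for fitting: normalized organelles,
# model-overlap check, sd floor, index vectors for fast residuals.
prepare_fit_data <- function(timecourse, model, sd_floor = 1e-3) {
  tc <- tibble::as_tibble(timecourse)
  need <- c("time_min", "organelle", "mean", "sd")
  if (!all(need %in% names(tc))) {
    abort(paste0("timecourse is missing columns: ",
                 paste(setdiff(need, names(tc)), collapse = ", ")))
  }
  tc$organelle <- normalize_organelle(tc$organelle)
  drop <- setdiff(unique(tc$organelle), model$compartments)
  if (length(drop) > 0) {
    inform(paste0("Excluding organelles absent from model ", model$preset,
                  ": ", paste(drop, collapse = ", ")))
    tc <- dplyr::filter(tc, .data$organelle %in% model$compartments)
  }
  if (nrow(tc) == 0) {
    abort("No overlap between timecourse organelles and model compartments.")
  }
  tc <- dplyr::arrange(tc, .data$time_min, .data$organelle)
  wsd <- tc$sd
  nz <- wsd <= 0
  if (any(nz)) {
    inform(paste0(sum(nz), " observation(s) with sd <= 0 floored at ",
                  sd_floor, " for weighting."))
    wsd[nz] <- sd_floor  # weights only; the data's sd column stays raw
  }
  times <- sort(unique(tc$time_min))
  list(
    tc = tc,
    wsd = wsd,
    times = times,
    t_idx = match(tc$time_min, times),
    c_idx = match(tc$organelle, model$compartments)
  )
}

flux_residuals <- function(rates, prep, model, x0, content_decay_rate) {
  xt <- simulate_flux_matrix(model, rates, x0, prep$times, content_decay_rate)
  pred <- xt[cbind(prep$t_idx, prep$c_idx)]
  (pred - prep$tc$mean) / prep$wsd
}

# x0 default: t = 0 means normalized to sum 1; all-PM if no t = 0 rows.
resolve_fit_x0 <- function(model, prep, x0) {
  if (!is.null(x0)) return(resolve_x0(model, x0))
  t0 <- dplyr::filter(prep$tc, .data$time_min == 0)
  if (nrow(t0) == 0 || sum(t0$mean) <= 0) return(resolve_x0(model, NULL))
  x0 <- setNames(rep(0, length(model$compartments)), model$compartments)
  x0[t0$organelle] <- t0$mean
  x0 / sum(x0)
}

#' Fit a compartment model to an organelle time course
#'
#' Bounded least-squares estimation of all rate constants by
#' Levenberg-Marquardt minimization of the weighted SSR (see
#' [flux_objective()]), restarted from `n_starts` log-uniform random
#' initializations over \[1e-4, k_max\] min^-1; the best converged start
#' wins. Deterministic given `seed`.
#'
#' @inheritParams flux_objective
#' @param k_max Upper bound on every rate constant (min^-1), default 10.
#' @param n_starts Number of random multi-starts, default 20.
#' @param seed Integer seed for the random starts.
#' @param start Optional named vector used as the first start (warm start).
#' @param weighting `"pooled"` (default) weights all residuals by one
#'   pooled standard deviation, sqrt(mean(sd^2)); `"observed"` uses each
#'   observation's own sd. Standard deviations estimated from a handful of
#'   fields of view are noisy, and raw inverse-variance weights then
#'   misweight the data badly; pooling is the stable default, while
#'   `"observed"` is appropriate when per-observation noise genuinely
#'   differs.
#' @return A `flux_fit` object with elements `point_estimate` (named
#'   vector), `objective` (weighted SSR at the optimum), `convergence`
#'   (per-start info), `model`, `x0`, `data` and fit settings. Add Monte
#'   Carlo uncertainty with [mc_uncertainty()].
#' @export
#' @examples
#' m <- flux_model("pm_er")
#' tc <- sim_timecourse(m, c(k_PM_ER = 0.1, k_ER_PM = 0.05),
#'                      noise_sd = 0.01, seed = 1)
#' fit <- fit_flux(tc, m, n_starts = 5, seed = 1)
#' fit$point_estimate
fit_flux <- function(timecourse, model, x0 = NULL, content_decay_rate = 0,
                     k_max = 10, n_starts = 20, seed = NULL,
                     sd_floor = 1e-3, start = NULL,
                     weighting = c("pooled", "observed")) {
  stopifnot(inherits(model, "flux_model"))
  weighting <- match.arg(weighting)
  if (n_starts < 1) abort("n_starts must be >= 1.")
  prep <- prepare_fit_data(timecourse, model, sd_floor)
  # weights used in the residuals; the data's own sd column is untouched
  # (Monte Carlo perturbations always draw from the observed sd)
  if (weighting == "pooled") {
    prep$wsd <- rep(sqrt(mean(prep$wsd^2)), nrow(prep$tc))
  }
  x0 <- resolve_fit_x0(model, prep, x0)
  rn <- rate_names(model)
  np <- length(rn)

  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  starts <- matrix(10^runif(n_starts * np, -4, log10(k_max)), n_starts, np)
  if (!is.null(start)) starts[1, ] <- pmin(pmax(start[rn], 0), k_max)

  resfun <- function(p) {
    names(p) <- rn
    flux_residuals(p, prep, model, x0, content_decay_rate)
  }
  best <- NULL
  info <- integer(n_starts)
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[s, ], lower = rep(0, np), upper = rep(k_max, np),
        fn = resfun,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      info[s] <- -1L
      next
    }
    info[s] <- fit$info
    ssr <- sum(fit$fvec^2)
    if (fit$info %in% 1:4 && (is.null(best) || ssr < best$ssr)) {
      best <- list(par = fit$par, ssr = ssr, info = fit$info)
    }
  }
  if (is.null(best)) {
    abort(paste0("No fit start converged; per-start info codes: ",
                 paste(info, collapse = ", ")))
  }
  est <- setNames(pmax(best$par, 0), rn)
  structure(
    list(
      point_estimate = est,
      objective = best$ssr,
      convergence = info,
      model = model,
      x0 = x0,
      data = prep$tc,
      content_decay_rate = content_decay_rate,
      k_max = k_max,
      n_starts = n_starts,
      weighting = weighting,
      seed = seed,
      mc_samples = NULL,
      mc_summary = NULL
    ),
    class = "flux_fit"
  )
}

#' Monte Carlo uncertainty for fitted rate constants
#'
#' Parametric Monte Carlo: each run redraws every observation from
#' Normal(mean, sd), refits the model (warm-started at the point estimate
#' plus `n_starts - 1` random starts), and collects the estimates. The
#' reported per-rate mean and s.d. are sample statistics over the runs.
#' Runs that fail to converge are dropped with a warning; more than
#' `max_fail_frac` failures is an error.
#'
#' @param fit A `flux_fit` from [fit_flux()].
#' @param n_mc Number of Monte Carlo runs, default 100.
#' @param seed Integer seed; all perturbation draws flow from it.
#' @param n_starts Starts per MC refit (default 3; the first is the point
#'   estimate).
#' @param max_fail_frac Maximum tolerated fraction of non-converged runs
#'   (default 0.2).
#' @param cv_flag Coefficient-of-variation threshold above which a rate is
#'   flagged as poorly identified in the summary (default 0.5).
#' @return The `flux_fit` with `mc_samples` (n_mc x n_rates matrix) and
#'   `mc_summary` (tibble: `rate`, `mc_mean`, `mc_sd`, `cv`,
#'   `poorly_identified`) filled in.
#' @export
mc_uncertainty <- function(fit, n_mc = 100, seed = NULL, n_starts = 3,
                           max_fail_frac = 0.2, cv_flag = 0.5) {
  stopifnot(inherits(fit, "flux_fit"))
  if (n_mc < 2) abort("n_mc must be >= 2.")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  rn <- rate_names(fit$model)
  samples <- matrix(NA_real_, n_mc, length(rn), dimnames = list(NULL, rn))
  tc <- fit$data
  for (i in seq_len(n_mc)) {
    pert <- tc
    pert$mean <- rnorm(nrow(tc), tc$mean, tc$sd)
    sub <- tryCatch(
      suppressMessages(fit_flux(
        pert, fit$model, x0 = fit$x0,
        content_decay_rate = fit$content_decay_rate,
        k_max = fit$k_max, n_starts = n_starts,
        sd_floor = 1e-3, start = fit$point_estimate,
        weighting = fit$weighting %||% "pooled"
      )),
      error = function(e) NULL
    )
    if (!is.null(sub)) samples[i, ] <- sub$point_estimate
  }
  failed <- !complete.cases(samples)
  if (mean(failed) > max_fail_frac) {
    abort(paste0(sum(failed), " of ", n_mc, " MC runs failed to converge."))
  }
  if (any(failed)) {
    warn(paste0("Dropped ", sum(failed), " non-converged MC run(s)."))
    samples <- samples[!failed, , drop = FALSE]
  }
  mc_mean <- colMeans(samples)
  mc_sd <- apply(samples, 2, sd)
  cv <- ifelse(mc_mean > 0, mc_sd / mc_mean, Inf)
  fit$mc_samples <- samples
  fit$mc_n_failed <- sum(failed)
  fit$mc_summary <- tibble::tibble(
    rate = rn,
    mc_mean = unname(mc_mean),
    mc_sd = unname(mc_sd),
    cv = unname(cv),
    poorly_identified = unname(cv > cv_flag)
  )
  fit
}

#' @export
print.flux_fit <- function(x, ...) {
  cat("<flux_fit> preset", x$model$preset, "- weighted SSR",
      format(x$objective, digits = 5), "\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.flux_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = names(x$point_estimate),
    estimate = unname(x$point_estimate)
  )
  if (!is.null(x$mc_summary)) {
    out <- dplyr::left_join(out, x$mc_summary, by = c(term = "rate"))
  }
  out
}

#' @export
glance.flux_fit <- function(x, ...) {
  tibble::tibble(
    preset = x$model$preset,
    objective = x$objective,
    n_obs = nrow(x$data),
    n_rates = length(x$point_estimate),
    n_starts = x$n_starts,
    n_mc = if (is.null(x$mc_samples)) 0L else nrow(x$mc_samples),
    converged = any(x$convergence %in% 1:4)
  )
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller's
# RNG stream.
get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
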