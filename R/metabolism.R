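# Monoisotopic atomic masses (most abundant isotope), 6 decimals.
.monoisotopic_masses <- c(
  H = 1.007825, D = 2.014102, C = 12.000000, N = 14.003074, O = 15.994915,
  P = 30.973762, S = 31.972071, Na = 22.989770, K = 38.963707,
  Cl = 34.968853, F = 18.998403, Li = 7.016004, Si = 27.976927
)

# "C44H84NO8P" -> named integer counts.
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1 || !nzchar(formula)) {
    abort("Formula must be a single non-empty string.")
  }
  f <- gsub("\\s", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  if (sum(attr(m, "match.length")) != nchar(f)) {
    abort(paste0("Cannot parse formula: ", formula))
  }
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Za-z]+", "", toks))
  n[is.na(n)] <- 1L
  unknown <- setdiff(el, names(.monoisotopic_masses))
  if (length(unknown) > 0) {
    abort(paste0("Unknown element symbol(s): ",
                 paste(unknown, collapse = ", ")))
  }
  tapply(n, factor(el, levels = unique(el)), sum)
}

#' Monoisotopic mass of a chemical formula
#'
#' @param formula Chemical sum formula, e.g. `"C44H84NO8P"`.
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("N2")
#' monoisotopic_mass("C2H4")
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(.monoisotopic_masses[names(counts)] * as.numeric(counts))
}

#' Exact-mass difference between two formula units
#'
#' The basis for discriminating bifunctional probe lipids from native
#' species in ultra-high-resolution spectra: replacing two CH2 groups by the
#' two nitrogen atoms of a diazirine shifts a species by
#' m(C2H4) - m(N2) = 28.0313 - 28.0061 = 0.0252 Da, a few-millidalton
#' doublet resolvable only at high mass resolution.
#'
#' @param formula_a,formula_b Chemical sum formulas.
#' @return Signed mass difference m(a) - m(b) in Da, rounded to 4 decimals.
#' @export
#' @examples
#' mass_delta("C2H4", "N2")  # the diazirine/CH2 doublet spacing
mass_delta <- function(formula_a, formula_b) {
  round(monoisotopic_mass(formula_a) - monoisotopic_mass(formula_b), 4)
}

#' Minimum resolving power to separate a mass doublet
#'
#' R = m/z divided by the peak spacing (FWHM definition). Optionally checks
#' whether a given instrument resolving power suffices.
#'
#' @param mz Mass-to-charge ratio of the doublet (> 0).
#' @param delta_m Doublet spacing in Da (> 0).
#' @param instrument_resolution Optional instrument resolving power at
#'   this m/z.
#' @return One-row tibble: `mz`, `delta_m`, `required`, and `sufficient`
#'   when an instrument resolution is supplied.
#' @export
#' @examples
#' required_resolving_power(800, mass_delta("C2H4", "N2"))
required_resolving_power <- function(mz, delta_m,
                                     instrument_resolution = NULL) {
  if (mz <= 0) abort("mz must be > 0.")
  if (delta_m <= 0) abort("delta_m must be > 0.")
  out <- tibble::tibble(mz = mz, delta_m = delta_m, required = mz / delta_m)
  if (!is.null(instrument_resolution)) {
    out$instrument <- instrument_resolution
    out$sufficient <- instrument_resolution > out$required
  }
  out
}

check_species_table <- function(table) {
  tab <- tibble::as_tibble(table)
  need <- c("species", "bifunctional", "supplied", "mol_pct", "time_min",
            "replicate")
  if (!all(need %in% names(tab))) {
    abort(paste0("Species table is missing columns: ",
                 paste(setdiff(need, names(tab)), collapse = ", ")))
  }
  if (nrow(tab) == 0) abort("Species table is empty.")
  if (any(tab$mol_pct < 0)) abort("mol_pct must be >= 0.")
  tab
}

#' Fraction of the supplied species among bifunctional lipids
#'
#' Per replicate, divides the supplied species' mol% by the summed mol% of
#' all bifunctional species at the same timepoint, then summarizes across
#' replicates as mean with a t-based 95% confidence interval. This fraction
#' decays mono-exponentially with the apparent metabolic rate constant and
#' is the input to [fit_monoexponential()].
#'
#' @param table Species table with columns `species`, `bifunctional`,
#'   `supplied`, `mol_pct`, `time_min`, `replicate`.
#' @param conf_level Confidence level, default 0.95.
#' @return Tibble per timepoint: `time_min`, `fraction`, `ci_lo`, `ci_hi`,
#'   `n_rep`, `undefined` (TRUE where a replicate had zero bifunctional
#'   total).
#' @export
fraction_supplied <- function(table, conf_level = 0.95) {
  tab <- check_species_table(table)
  per_rep <- tab |>
    dplyr::filter(.data$bifunctional) |>
    dplyr::group_by(.data$time_min, .data$replicate) |>
    dplyr::summarise(
      total_bif = sum(.data$mol_pct),
      supplied_mol = sum(.data$mol_pct[.data$supplied]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      frac = ifelse(.data$total_bif > 0,
                    .data$supplied_mol / .data$total_bif, NA_real_)
    )
  if (nrow(per_rep) == 0) abort("No bifunctional records in table.")
  summarize_replicates(per_rep, conf_level)
}

summarize_replicates <- function(per_rep, conf_level) {
  per_rep |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(
      undefined = any(is.na(.data$frac)),
      n_rep = sum(!is.na(.data$frac)),
      fraction = mean(.data$frac, na.rm = TRUE),
      se = dplyr::if_else(
        n_rep > 1,
        sd(.data$frac[!is.na(.data$frac)]) / sqrt(n_rep),
        NA_real_
      ),
      tcrit = qt(1 - (1 - conf_level) / 2, pmax(n_rep - 1, 1)),
      ci_lo = fraction - tcrit * se,
      ci_hi = fraction + tcrit * se,
      .groups = "drop"
    ) |>
    dplyr::select("time_min", "fraction", "se", "ci_lo", "ci_hi",
                  "n_rep", "undefined")
}

#' Bifunctional fraction of the total lipidome
#'
#' Per replicate, the summed mol% of bifunctional species divided by the
#' summed mol% of all species — the probe-retention readout; summarized
#' across replicates like [fraction_supplied()].
#'
#' @inheritParams fraction_supplied
#' @return Tibble per timepoint: `time_min`, `fraction`, `ci_lo`, `ci_hi`,
#'   `n_rep`, `undefined`.
#' @export
fraction_bifunctional <- function(table, conf_level = 0.95) {
  tab <- check_species_table(table)
  per_rep <- tab |>
    dplyr::group_by(.data$time_min, .data$replicate) |>
    dplyr::summarise(
      total = sum(.data$mol_pct),
      bif = sum(.data$mol_pct[.data$bifunctional]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      frac = ifelse(.data$total > 0, .data$bif / .data$total, NA_real_)
    )
  summarize_replicates(per_rep, conf_level)
}

#' Mono-exponential turnover fit
#'
#' Fits f(t) = f0 exp(-k_met t) to fraction-versus-time data by nonlinear
#' least squares. When the total decline over the observation window is
#' below `decline_threshold` (the nearly-inert case, e.g. sphingomyelin),
#' no rate is fitted; a linear interpolation of the data is returned
#' instead. Increasing data clip k_met at 0 with a warning.
#'
#' @param data Data frame with columns `time_min` and `fraction` (such as
#'   the output of [fraction_supplied()]). If an `se` column is present
#'   (replicate standard errors), the fit is weighted by 1/se^2 by default:
#'   replicate noise on fractions is strongly heteroscedastic (the supplied
#'   fraction is pinned near 1 at t = 0 and near 0 late), and an unweighted
#'   covariance then understates the rate uncertainty severalfold.
#' @param decline_threshold Minimum relative decline required to fit,
#'   default 0.05.
#' @param weights Optional explicit per-point weights; overrides the
#'   se-based default. Set `weights = FALSE` to force an unweighted fit.
#' @param se_floor Floor applied to `se` before weighting (fraction units),
#'   default 1e-4, so exactly-replicated points cannot get infinite weight.
#' @return A `metabolism_fit`: list with `k_met` (min^-1), `se`, `f0`,
#'   `fitted` (logical), `method` (`"mono-exponential"` or
#'   `"interpolation"`), `decline`, `data`, and for the interpolation case
#'   an `interpolate` function.
#' @export
#' @examples
#' t <- c(0, 30, 120, 480, 1440)
#' fit_monoexponential(data.frame(time_min = t, fraction = exp(-0.01 * t)))
fit_monoexponential <- function(data, decline_threshold = 0.05,
                                weights = NULL, se_floor = 1e-4) {
  df <- tibble::as_tibble(data)
  if (!all(c("time_min", "fraction") %in% names(df))) {
    abort("data needs columns time_min and fraction.")
  }
  df <- dplyr::arrange(dplyr::filter(df, !is.na(.data$fraction)),
                       .data$time_min)
  known_var <- FALSE
  if (is.null(weights) && "se" %in% names(df) &&
      any(is.finite(df$se) & df$se > 0)) {
    se_w <- pmax(df$se, se_floor)
    se_w[!is.finite(se_w)] <- se_floor
    weights <- 1 / se_w^2
    known_var <- TRUE  # weights are true inverse variances, not relative
  } else if (isFALSE(weights)) {
    weights <- NULL
  }
  if (nrow(df) < 3) abort("Need at least 3 timepoints.")
  f_first <- df$fraction[1]
  f_last <- df$fraction[nrow(df)]
  decline <- if (f_first > 0) (f_first - f_last) / f_first else 0

  base <- list(data = df, decline = decline)
  if (decline < decline_threshold) {
    if (decline < 0) {
      warn("Fractions increase over time; k_met clipped at 0.")
      return(structure(c(base, list(
        k_met = 0, se = NA_real_, f0 = f_first, fitted = FALSE,
        method = "clipped", interpolate = NULL
      )), class = "metabolism_fit"))
    }
    inform(paste0("Total decline ", signif(decline * 100, 3),
                  "% < ", decline_threshold * 100,
                  "%; returning linear interpolation, no rate fitted."))
    return(structure(c(base, list(
      k_met = NA_real_, se = NA_real_, f0 = f_first, fitted = FALSE,
      method = "interpolation",
      interpolate = stats::approxfun(df$time_min, df$fraction, rule = 2)
    )), class = "metabolism_fit"))
  }

  # log-linear start values
  pos <- df$fraction > 0
  k0 <- if (sum(pos) >= 2) {
    max(-coef(lm(log(df$fraction[pos]) ~ df$time_min[pos]))[2], 1e-6)
  } else 1e-3
  args <- list(
    formula = fraction ~ f0 * exp(-k * time_min),
    data = df,
    start = list(f0 = f_first, k = unname(k0)),
    lower = c(0, 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!is.null(weights)) args$weights <- weights
  fit <- do.call(minpack.lm::nlsLM, args)
  est <- coef(fit)
  se <- tryCatch({
    v <- diag(stats::vcov(fit))[["k"]]
    # with known per-point variances the covariance is (J' W J)^-1 and the
    # few-df residual variance factor only adds noise: divide it back out
    if (known_var) v <- v / summary(fit)$sigma^2
    sqrt(v)
  }, error = function(e) NA_real_)
  structure(c(base, list(
    k_met = unname(est[["k"]]), se = se, f0 = unname(est[["f0"]]),
    fitted = TRUE, method = "mono-exponential", nls = fit,
    interpolate = NULL
  )), class = "metabolism_fit")
}

#' @export
print.metabolism_fit <- function(x, ...) {
  cat("<metabolism_fit>", x$method, "\n")
  if (isTRUE(x$fitted)) {
    cat("  k_met =", format(x$k_met, digits = 4), "min^-1  (s.e.",
        format(x$se, digits = 3), "),  f0 =", format(x$f0, digits = 4), "\n")
  } else {
    cat("  decline", signif(x$decline * 100, 3), "% — no rate fitted\n")
  }
  invisible(x)
}

#' @export
tidy.metabolism_fit <- function(x, ...) {
  tibble::tibble(
    term = c("f0", "k_met"),
    estimate = c(x$f0, x$k_met),
    std.error = c(NA_real_, x$se)
  )
}

#' @export
glance.metabolism_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    fitted = isTRUE(x$fitted),
    decline = x$decline,
    n_obs = nrow(x$data)
  )
}

#' Ratio of transport to metabolic rate constants
#'
#' k_PM_ER / k_met with first-order error propagation — the time-scale
#' separation between interorganelle transport and metabolic conversion
#' (roughly one order of magnitude, 10-60x, for the probes studied).
#'
#' @param k_transport Transport rate constant (min^-1), or a `flux_fit`
#'   with MC samples (its `k_PM_ER` MC mean and s.d. are used).
#' @param k_met Metabolic rate constant (min^-1), or a `metabolism_fit`.
#' @param sd_transport,se_met Uncertainties; filled automatically from fit
#'   objects.
#' @return One-row tibble: `ratio`, `sd`, `infinite`.
#' @export
#' @examples
#' transport_metabolism_ratio(0.15, 0.005)
transport_metabolism_ratio <- function(k_transport, k_met,
                                       sd_transport = 0, se_met = 0) {
  if (inherits(k_transport, "flux_fit")) {
    fit <- k_transport
    if (!is.null(fit$mc_summary)) {
      row <- dplyr::filter(fit$mc_summary, .data$rate == "k_PM_ER")
      k_transport <- row$mc_mean
      sd_transport <- row$mc_sd
    } else {
      k_transport <- fit$point_estimate[["k_PM_ER"]]
    }
  }
  if (inherits(k_met, "metabolism_fit")) {
    mf <- k_met
    if (!isTRUE(mf$fitted)) abort("metabolism_fit carries no fitted rate.")
    k_met <- mf$k_met
    se_met <- if (is.na(mf$se)) 0 else mf$se
  }
  if (k_met < 0) abort("k_met must be >= 0.")
  if (k_met == 0) {
    return(tibble::tibble(ratio = Inf, sd = NA_real_, infinite = TRUE))
  }
  rp <- ratio_error_prop(k_transport, sd_transport, k_met, se_met)
  tibble::tibble(ratio = rp$ratio, sd = rp$sd, infinite = FALSE)
}

#' Correlate transport and metabolism rate constants across species
#'
#' Ordinary least-squares regression of the transport rate on the metabolic
#' rate across lipid species, with the Pearson correlation and its
#' two-sided p-value.
#'
#' @param data Data frame with columns `k_met` and `k_transport`, one row
#'   per species.
#' @return One-row tibble: `slope`, `intercept`, `r`, `p_value`, `n`.
#' @export
correlate_rates <- function(data) {
  df <- tibble::as_tibble(data)
  if (!all(c("k_met", "k_transport") %in% names(df))) {
    abort("data needs columns k_met and k_transport.")
  }
  df <- dplyr::filter(df, !is.na(.data$k_met), !is.na(.data$k_transport))
  if (nrow(df) < 3) abort("Need at least 3 species.")
  fit <- lm(k_transport ~ k_met, data = df)
  ct <- suppressWarnings(cor.test(df$k_met, df$k_transport))
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = nrow(df)
  )
}
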