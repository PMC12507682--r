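#' Cohen's d effect size with categorical interpretation
#'
#' Computes the standardized difference of two sample means in pooled
#' standard-deviation units,
#' d = |mean_a - mean_b| / s_pooled,
#' s_pooled = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2)),
#' and classifies it on the conventional scale used for rate-constant
#' comparisons: negligible (d <= 0.01), very small (> 0.01), small
#' (> 0.20), medium (> 0.50), large (> 0.80), very large (> 1.20), huge
#' (> 2.00); intervals are half-open, (threshold, next].
#'
#' Typical inputs are the Monte Carlo sample sets of one rate constant under
#' two conditions (see [mc_uncertainty()]).
#'
#' @param samples_a,samples_b Numeric vectors, each of length >= 2.
#' @return A one-row tibble with columns `d`, `category` and `d_infinite`
#'   (`TRUE` when the pooled s.d. is zero but the means differ).
#' @export
#' @examples
#' cohens_d(rnorm(100, 0.2, 0.02), rnorm(100, 0.25, 0.02))
cohens_d <- function(samples_a, samples_b) {
  a <- as.numeric(samples_a)
  b <- as.numeric(samples_b)
  if (length(a) < 2 || length(b) < 2) {
    abort("Each sample must contain at least 2 values.")
  }
  na <- length(a)
  nb <- length(b)
  sp <- sqrt(((na - 1) * sd(a)^2 + (nb - 1) * sd(b)^2) / (na + nb - 2))
  diff <- abs(mean(a) - mean(b))
  if (sp == 0) {
    if (diff == 0) {
      return(tibble::tibble(d = 0, category = "negligible", d_infinite = FALSE))
    }
    return(tibble::tibble(d = Inf, category = "huge", d_infinite = TRUE))
  }
  d <- diff / sp
  tibble::tibble(d = d, category = effect_size_category(d), d_infinite = FALSE)
}

#' Effect-size category for a Cohen's d magnitude
#'
#' @param d Non-negative numeric vector of |d| values.
#' @return Character vector of categories.
#' @export
#' @examples
#' effect_size_category(c(0.005, 0.27, 2.3))
effect_size_category <- function(d) {
  if (any(d < 0, na.rm = TRUE)) abort("d must be a magnitude (>= 0).")
  brk <- c(-Inf, 0.01, 0.20, 0.50, 0.80, 1.20, 2.00, Inf)
  lab <- c("negligible", "very small", "small", "medium", "large",
           "very large", "huge")
  as.character(cut(d, breaks = brk, labels = lab, right = TRUE))
}

#' Fold change of a rate constant between two fitted conditions
#'
#' Ratio of the Monte Carlo mean rate constants of two fits, with a
#' first-order error-propagation standard deviation
#' sd(ratio) = ratio * sqrt((s_a/a)^2 + (s_b/b)^2), and the Cohen's d
#' comparison of the underlying MC sample sets.
#'
#' @param fit_a,fit_b `flux_fit` objects carrying MC samples
#'   ([mc_uncertainty()]).
#' @param rate Rate-constant name present in both fits.
#' @return One-row tibble: `rate`, `fold_change`, `sd`, `d`, `category`.
#' @export
fold_change <- function(fit_a, fit_b, rate) {
  for (f in list(fit_a, fit_b)) {
    if (!inherits(f, "flux_fit") || is.null(f$mc_samples)) {
      abort("fold_change needs flux_fit objects with MC samples.")
    }
    if (!rate %in% colnames(f$mc_samples)) {
      abort(paste0("Rate ", rate, " is not present in both fits."))
    }
  }
  a <- fit_a$mc_samples[, rate]
  b <- fit_b$mc_samples[, rate]
  if (mean(b) <= 0) abort("Denominator rate mean must be > 0.")
  rp <- ratio_error_prop(mean(a), sd(a), mean(b), sd(b))
  es <- cohens_d(a, b)
  tibble::tibble(
    rate = rate,
    fold_change = rp$ratio,
    sd = rp$sd,
    d = es$d,
    category = es$category
  )
}

# First-order (delta-method) error propagation for a ratio a/b.
ratio_error_prop <- function(a, sd_a, b, sd_b) {
  if (b <= 0) abort("Denominator must be > 0.")
  r <- a / b
  list(ratio = r, sd = abs(r) * sqrt((sd_a / a)^2 + (sd_b / b)^2))
}
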