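#' Build a compartmental lipid-transport model
#'
#' Constructs one of the frozen preset topologies describing interorganelle
#' lipid transport between the plasma membrane (PM), endosomes (Endo), the
#' Golgi apparatus, the endoplasmic reticulum (ER) and mitochondria (Mito).
#' All models are linear first-order compartment systems; every edge carries
#' one rate constant in min^-1.
#'
#' The preset family:
#' \describe{
#'   \item{`"1a"`}{Retrograde vesicular chain PM -> Endo -> Golgi -> ER,
#'     direct non-vesicular exchange PM <-> ER (the ER -> PM leg is a summary
#'     anterograde rate covering both vesicular and non-vesicular modes), and
#'     ER <-> Mito exchange. 5 compartments, 7 edges.}
#'   \item{`"1b"`}{Model 1a plus explicit anterograde vesicular legs
#'     ER -> Golgi -> Endo -> PM. The summary anterograde rate `k_ER_PM` is
#'     retained so that the 1b rate set is a superset of 1a.}
#'   \item{`"2a"`, `"2b"`}{Same topologies as 1a/1b with a uniform first-order
#'     content-decay term that scales total probe content, normally fixed from
#'     the mass-spectrometry total-bifunctional-content fit.}
#'   \item{`"3a"`, `"3b"`}{The 2-variants with an endosome-recycling edge
#'     Endo -> PM. For the b-family that edge is already part of the
#'     anterograde legs, so 3b shares the 2b topology.}
#'   \item{`"pm_er"`}{The reduced two-compartment exchange model
#'     PM <-> ER used for perturbation experiments.}
#' }
#'
#' @param preset One of `"1a"`, `"1b"`, `"2a"`, `"2b"`, `"3a"`, `"3b"`,
#'   `"pm_er"`.
#' @return A `flux_model` object: list with `preset`, `compartments`
#'   (character), `edges` (tibble with columns `from`, `to`, `rate`) and
#'   `content_decay` (logical).
#' @export
#' @examples
#' m <- flux_model("1a")
#' m$edges
#' rate_names(m)
flux_model <- function(preset = c("1a", "1b", "2a", "2b", "3a", "3b", "pm_er")) {
  valid <- c("1a", "1b", "2a", "2b", "3a", "3b", "pm_er")
  if (length(preset) != 1 || !preset %in% valid) {
    abort(paste0(
      "Unknown model preset ", deparse(preset[1]),
      ". Valid presets: ", paste(valid, collapse = ", "), "."
    ))
  }
  edge <- function(from, to) {
    tibble::tibble(from = from, to = to, rate = paste0("k_", from, "_", to))
  }
  if (preset == "pm_er") {
    edges <- dplyr::bind_rows(edge("PM", "ER"), edge("ER", "PM"))
    comps <- c("PM", "ER")
  } else {
    edges <- dplyr::bind_rows(
      edge("PM", "Endo"), edge("Endo", "Golgi"), edge("Golgi", "ER"),
      edge("PM", "ER"), edge("ER", "PM"),
      edge("ER", "Mito"), edge("Mito", "ER")
    )
    if (preset %in% c("1b", "2b", "3b")) {
      edges <- dplyr::bind_rows(
        edges, edge("ER", "Golgi"), edge("Golgi", "Endo"), edge("Endo", "PM")
      )
    }
    if (preset == "3a") {
      edges <- dplyr::bind_rows(edges, edge("Endo", "PM"))
    }
    comps <- .compartments
  }
  structure(
    list(
      preset = preset,
      compartments = comps,
      edges = edges,
      content_decay = preset %in% c("2a", "2b", "3a", "3b")
    ),
    class = "flux_model"
  )
}

#' @export
print.flux_model <- function(x, ...) {
  cat("<flux_model> preset", x$preset, "\n")
  cat("  compartments:", paste(x$compartments, collapse = ", "), "\n")
  cat("  edges:", nrow(x$edges),
      if (x$content_decay) " (+ content decay)" else "", "\n")
  for (i in seq_len(nrow(x$edges))) {
    cat("   ", x$edges$from[i], "->", x$edges$to[i],
        paste0("(", x$edges$rate[i], ")"), "\n")
  }
  invisible(x)
}

#' Rate-constant names of a model
#'
#' @param model A `flux_model`.
#' @return Character vector of rate names, one per edge.
#' @export
rate_names <- function(model) {
  stopifnot(inherits(model, "flux_model"))
  model$edges$rate
}

# Check a named rate vector against a model; returns the validated vector.
check_rates <- function(model, rates) {
  need <- rate_names(model)
  if (is.null(names(rates)) || !all(need %in% names(rates))) {
    abort(paste0(
      "Missing rate constants: ",
      paste(setdiff(need, names(rates)), collapse = ", ")
    ))
  }
  r <- as.numeric(rates[need])
  if (any(!is.finite(r))) abort("Rate constants must be finite.")
  if (any(r < 0)) abort("Rate constants must be non-negative.")
  names(r) <- need
  r
}

# Build the system matrix A of dx/dt = A x: off-diagonal A[to, from] gains the
# edge rate, the diagonal loses the sum of outgoing rates plus content decay.
flux_matrix <- function(model, rates, content_decay_rate = 0) {
  r <- check_rates(model, rates)
  nc <- length(model$compartments)
  A <- matrix(0, nc, nc, dimnames = list(model$compartments, model$compartments))
  for (i in seq_len(nrow(model$edges))) {
    from <- model$edges$from[i]
    to <- model$edges$to[i]
    k <- r[[model$edges$rate[i]]]
    A[to, from] <- A[to, from] + k
    A[from, from] <- A[from, from] - k
  }
  if (content_decay_rate != 0) {
    if (content_decay_rate < 0) abort("content_decay_rate must be >= 0.")
    diag(A) <- diag(A) - content_decay_rate
  }
  A
}

# Dense solution x(t) for all times: eigen path with an expm fallback for
# (near-)defective matrices. Returns a length(times) x n matrix.
solve_linear_ode <- function(A, x0, times) {
  n <- nrow(A)
  out <- matrix(NA_real_, length(times), n, dimnames = list(NULL, rownames(A)))
  eg <- eigen(A)
  V <- eg$vectors
  c0 <- tryCatch(solve(V, x0 + 0i), error = function(e) NULL)
  # defective or ill-conditioned eigenbasis -> fall back to expm
  ok <- !is.null(c0) && max(abs(Re(V %*% c0) - x0)) < 1e-9
  if (ok) {
    for (i in seq_along(times)) {
      out[i, ] <- Re(V %*% (exp(eg$values * times[i]) * c0))
    }
  } else {
    for (i in seq_along(times)) {
      out[i, ] <- as.numeric(Matrix::expm(A * times[i]) %*% x0)
    }
  }
  if (any(!is.finite(out))) {
    abort(paste0(
      "Non-finite model solution; max |eigenvalue| = ",
      format(max(abs(eg$values))), ", t_max = ", format(max(times)), "."
    ))
  }
  out
}

#' Simulate a compartmental transport model
#'
#' Solves the linear system dx/dt = A x exactly (eigendecomposition, with a
#' matrix-exponential fallback) and returns the compartment fractions over
#' time in long (tidy) form.
#'
#' @param model A `flux_model`.
#' @param rates Named numeric vector of rate constants (min^-1) covering
#'   every edge of the model.
#' @param x0 Named numeric vector of initial fractions per compartment;
#'   must sum to 1 (tolerance 1e-6). Defaults to everything in the PM, the
#'   pulse-chase initial condition.
#' @param times Numeric vector of times in minutes, non-negative and sorted.
#' @param content_decay_rate Uniform first-order loss applied to all
#'   compartments (min^-1), used by the 2/3 preset families to account for
#'   declining total probe content; ignored (with a warning) for presets
#'   without content decay unless `force_decay = TRUE`.
#' @param force_decay Apply `content_decay_rate` even for presets that do not
#'   declare content decay.
#' @return A tibble with columns `time_min`, `organelle`, `fraction`, and —
#'   when content decay is active — `total`, the surviving fraction of the
#'   initial content at that time.
#' @export
#' @examples
#' m <- flux_model("pm_er")
#' simulate_flux(m, c(k_PM_ER = 0.2, k_ER_PM = 0.1), times = c(0, 5, 30))
simulate_flux <- function(model, rates, x0 = NULL, times,
                          content_decay_rate = 0, force_decay = FALSE) {
  stopifnot(inherits(model, "flux_model"))
  if (any(!is.finite(times)) || any(times < 0)) {
    abort("times must be finite and non-negative.")
  }
  if (is.unsorted(times)) abort("times must be sorted increasingly.")
  x0 <- resolve_x0(model, x0)
  decay <- if (model$content_decay || force_decay) content_decay_rate else {
    if (content_decay_rate != 0) {
      warn(paste0("Preset ", model$preset,
                  " has no content decay; content_decay_rate ignored."))
    }
    0
  }
  A <- flux_matrix(model, rates, decay)
  xt <- solve_linear_ode(A, x0, times)
  out <- tibble::tibble(
    time_min = rep(times, times = length(model$compartments)),
    organelle = rep(model$compartments, each = length(times)),
    fraction = as.vector(xt)
  )
  if (decay != 0) out$total <- exp(-decay * out$time_min)
  out
}

# Initial state: user-supplied named vector or the pulse-chase default
# (all probe at the PM).
resolve_x0 <- function(model, x0) {
  comps <- model$compartments
  if (is.null(x0)) {
    x0 <- setNames(rep(0, length(comps)), comps)
    x0["PM"] <- 1
    return(x0)
  }
  if (is.null(names(x0)) || !all(comps %in% names(x0))) {
    abort(paste0("x0 must be named and cover compartments: ",
                 paste(comps, collapse = ", ")))
  }
  x0 <- as.numeric(x0[comps])
  names(x0) <- comps
  if (any(x0 < 0) || abs(sum(x0) - 1) > 1e-6) {
    abort("x0 fractions must be non-negative and sum to 1.")
  }
  x0
}

# Wide solver used by the fitting code: rows = times, cols = compartments.
simulate_flux_matrix <- function(model, rates, x0, times, content_decay_rate = 0) {
  A <- flux_matrix(model, rates, content_decay_rate)
  solve_linear_ode(A, x0, times)
}

#' Closed-form solution of the two-compartment PM/ER exchange model
#'
#' For the reduced model PM <-> ER with forward rate `k1` (PM -> ER) and
#' reverse rate `k2` (ER -> PM), the PM fraction relaxes mono-exponentially:
#' x_PM(t) = x_eq + (x0_pm - x_eq) exp(-(k1 + k2) t), with
#' x_eq = k2 / (k1 + k2). Serves as the analytic oracle for the numeric
#' solver.
#'
#' @param k1 PM -> ER rate constant (min^-1).
#' @param k2 ER -> PM rate constant (min^-1).
#' @param x0_pm Initial PM fraction.
#' @param t Time(s) in minutes.
#' @return Numeric vector of PM fractions, one per `t`.
#' @export
#' @examples
#' analytic_pm_er(0.2, 0.1, 1, c(0, 10, 1e6))
analytic_pm_er <- function(k1, k2, x0_pm, t) {
  if (k1 < 0 || k2 < 0) abort("Rate constants must be non-negative.")
  if (k1 + k2 == 0) return(rep(x0_pm, length(t)))
  x_eq <- k2 / (k1 + k2)
  x_eq + (x0_pm - x_eq) * exp(-(k1 + k2) * t)
}

#' Quasi-equilibrium constant of PM-ER exchange
#'
#' The ratio K = k_PM_ER / k_ER_PM of the opposing first-order rate
#' constants, describing the steady-state partitioning of a lipid between
#' the plasma membrane and the ER. Applied to a fitted model with Monte
#' Carlo samples it also returns the MC mean and s.d. of K.
#'
#' @param x Either a named numeric vector containing `k_PM_ER` and
#'   `k_ER_PM`, or a `flux_fit` object.
#' @return For a numeric vector: the scalar K. For a `flux_fit`: a one-row
#'   tibble with `K`, and `mc_mean`, `mc_sd` when MC samples are present.
#' @export
#' @examples
#' quasi_equilibrium(c(k_PM_ER = 0.22, k_ER_PM = 0.10))
quasi_equilibrium <- function(x) {
  if (inherits(x, "flux_fit")) {
    K <- quasi_equilibrium(x$point_estimate)
    out <- tibble::tibble(K = K)
    if (!is.null(x$mc_samples)) {
      ks <- x$mc_samples[, "k_PM_ER"] / x$mc_samples[, "k_ER_PM"]
      out$mc_mean <- mean(ks)
      out$mc_sd <- sd(ks)
    }
    return(out)
  }
  if (!all(c("k_PM_ER", "k_ER_PM") %in% names(x))) {
    abort("Need rates k_PM_ER and k_ER_PM.")
  }
  if (x[["k_ER_PM"]] <= 0) {
    abort("Quasi-equilibrium constant undefined: k_ER_PM must be > 0.")
  }
  unname(x[["k_PM_ER"]] / x[["k_ER_PM"]])
}

#' Non-vesicular share of retrograde transport out of the PM
#'
#' Fraction of retrograde lipid flux leaving the plasma membrane that takes
#' the direct (non-vesicular) PM -> ER route rather than the endocytic
#' PM -> Endo route: k_PM_ER / (k_PM_ER + k_PM_Endo).
#'
#' @param x Named numeric vector containing `k_PM_ER` and `k_PM_Endo`, or a
#'   `flux_fit` object (then the MC mean and s.d. of the share are added).
#' @return Scalar share, or a one-row tibble for a `flux_fit`.
#' @export
#' @examples
#' nonvesicular_share(c(k_PM_ER = 0.22, k_PM_Endo = 0.02))
nonvesicular_share <- function(x) {
  if (inherits(x, "flux_fit")) {
    s <- nonvesicular_share(x$point_estimate)
    out <- tibble::tibble(share = s)
    if (!is.null(x$mc_samples)) {
      ss <- x$mc_samples[, "k_PM_ER"] /
        (x$mc_samples[, "k_PM_ER"] + x$mc_samples[, "k_PM_Endo"])
      out$mc_mean <- mean(ss)
      out$mc_sd <- sd(ss)
    }
    return(out)
  }
  if (!all(c("k_PM_ER", "k_PM_Endo") %in% names(x))) {
    abort("Need rates k_PM_ER and k_PM_Endo.")
  }
  tot <- x[["k_PM_ER"]] + x[["k_PM_Endo"]]
  if (tot <= 0) abort("Share undefined: k_PM_ER + k_PM_Endo must be > 0.")
  unname(x[["k_PM_ER"]] / tot)
}
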