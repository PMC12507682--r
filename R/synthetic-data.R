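#' Simulate an organelle-fraction time course with replicate noise
#'
#' Generates the fitting target of the imaging pipeline: per-timepoint,
#' per-organelle mean fractions with field-of-view replicate noise around
#' the exact solution of a compartment model. Each of `n_fields` fields
#' draws the true fraction plus Gaussian noise (truncated to \[0, 1\]); the
#' recorded mean, s.d. and n are the sample statistics across fields. Raw
#' sums over organelles are left as generated — never renormalized after
#' noise.
#'
#' @param model A `flux_model`.
#' @param rates Named numeric vector of true rate constants (min^-1).
#' @param x0 True initial fractions (default: all probe in the PM).
#' @param noise_sd Per-observation Gaussian s.d. on fractions, default 0.02.
#' @param n_fields Fields of view per timepoint, default 5.
#' @param timepoints Minutes; default `c(0, 4, 30, 120, 1440)`, bracketing
#'   the early (4/30 min) readouts and the 24 h endpoint.
#' @param content_decay_rate Content decay (min^-1) for presets that scale
#'   total probe content.
#' @param seed Integer seed; identical inputs and seed give identical
#'   output.
#' @return Tibble with columns `time_min`, `organelle`, `mean`, `sd`, `n`;
#'   attribute `"truth"` holds the noiseless trajectory tibble.
#' @export
#' @examples
#' m <- flux_model("pm_er")
#' sim_timecourse(m, c(k_PM_ER = 0.1, k_ER_PM = 0.05), seed = 1)
sim_timecourse <- function(model, rates, x0 = NULL, noise_sd = 0.02,
                           n_fields = 5, timepoints = c(0, 4, 30, 120, 1440),
                           content_decay_rate = 0, seed = 1) {
  stopifnot(inherits(model, "flux_model"))
  if (noise_sd < 0) abort("noise_sd must be >= 0.")
  if (n_fields < 1) abort("n_fields must be >= 1.")
  if (timepoints[1] != 0 || is.unsorted(timepoints, strictly = TRUE)) {
    abort("timepoints must be strictly increasing and start at 0.")
  }
  truth <- simulate_flux(model, rates, x0, timepoints,
                         content_decay_rate = content_decay_rate,
                         force_decay = content_decay_rate > 0)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  draws <- vapply(truth$fraction, function(f) {
    pmin(pmax(rnorm(n_fields, f, noise_sd), 0), 1)
  }, numeric(n_fields))
  draws <- matrix(draws, nrow = n_fields)  # n_fields x n_obs
  out <- tibble::tibble(
    time_min = truth$time_min,
    organelle = truth$organelle,
    mean = colMeans(draws),
    sd = if (n_fields > 1) apply(draws, 2, sd) else rep(0, ncol(draws)),
    n = n_fields
  )
  attr(out, "truth") <- truth
  out
}

#' Rectangular region helper for synthetic images
#'
#' @param dim Image dimension `c(rows, cols)`.
#' @param rows,cols Integer ranges (inclusive) covered by the region.
#' @return Logical matrix of the requested dimension.
#' @export
rect_mask <- function(dim, rows, cols) {
  if (min(rows) < 1 || max(rows) > dim[1] ||
      min(cols) < 1 || max(cols) > dim[2]) {
    abort("Region exceeds image bounds.")
  }
  m <- matrix(FALSE, dim[1], dim[2])
  m[rows, cols] <- TRUE
  m
}

#' Simulate a lipid channel plus organelle probability maps
#'
#' Builds a toy field of view for the signal-partition stage: each organelle
#' occupies a region (logical mask); where regions overlap, every pixel is
#' attributed to one true owner at random, so overlap pixels carry the
#' intensity statistics of a single organelle — the situation the
#' distribution-based partitioning resolves. The lipid value of a pixel is
#' its owner's mean intensity plus noise; probability maps are high
#' (`p_in`) inside a region and low (`p_out`) outside.
#'
#' @param layout Named list of logical matrices (identical dimension), the
#'   true region of each organelle; see [rect_mask()].
#' @param intensities Named numeric vector, mean lipid intensity per
#'   organelle (>= 0); names must match `layout`.
#' @param noise `"gaussian"` (s.d. = `noise_sd_frac` of the local mean),
#'   `"poisson"`, or `"none"`.
#' @param noise_sd_frac Gaussian noise s.d. as a fraction of the local mean
#'   intensity, default 0.1.
#' @param p_in,p_out Probability-map values inside/outside a region.
#' @param background Mean background intensity outside all regions,
#'   default 0.
#' @param seed Integer seed.
#' @return List with `lipid` (matrix), `prob_maps` (named list of
#'   matrices), `truth` (tibble: `organelle`, `intensity`, `fraction` —
#'   ground-truth totals by pixel ownership) and `owner` (integer matrix of
#'   true owners, 0 = background).
#' @export
sim_organelle_images <- function(layout, intensities,
                                 noise = c("gaussian", "poisson", "none"),
                                 noise_sd_frac = 0.1, p_in = 0.9,
                                 p_out = 0.05, background = 0, seed = 1) {
  noise <- match.arg(noise)
  if (!is.list(layout) || length(layout) == 0 || is.null(names(layout))) {
    abort("layout must be a non-empty named list of logical matrices.")
  }
  orgs <- names(layout)
  if (!all(orgs %in% names(intensities))) {
    abort("intensities must name every organelle in layout.")
  }
  if (any(intensities[orgs] < 0)) abort("Intensities must be >= 0.")
  d <- dim(layout[[1]])
  if (!all(vapply(layout, function(m) identical(dim(m), d), logical(1)))) {
    abort("All layout masks must share one dimension.")
  }

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  cover_mat <- vapply(layout, as.vector, logical(prod(d)))
  n_cover <- rowSums(cover_mat)
  owner <- integer(prod(d))  # 0 = background
  single <- which(n_cover == 1)
  owner[single] <- max.col(cover_mat[single, , drop = FALSE])
  multi <- which(n_cover >= 2)
  for (px in multi) {
    owner[px] <- sample(which(cover_mat[px, ]), 1)
  }

  mean_img <- rep(background, prod(d))
  mean_img[owner > 0] <- intensities[orgs][owner[owner > 0]]
  value <- switch(
    noise,
    none = mean_img,
    gaussian = pmax(rnorm(length(mean_img), mean_img,
                          noise_sd_frac * mean_img), 0),
    poisson = rpois(length(mean_img), mean_img)
  )
  lipid <- matrix(value, d[1], d[2])

  truth_int <- vapply(seq_along(orgs), function(i) {
    sum(value[owner == i])
  }, numeric(1))
  truth <- tibble::tibble(
    organelle = orgs,
    intensity = truth_int,
    fraction = if (sum(truth_int) > 0) truth_int / sum(truth_int) else NA_real_
  )

  prob_maps <- lapply(layout, function(m) {
    matrix(ifelse(as.vector(m), p_in, p_out), d[1], d[2])
  })

  list(
    lipid = lipid,
    prob_maps = prob_maps,
    truth = truth,
    owner = matrix(owner, d[1], d[2])
  )
}

#' Simulate a species-resolved lipidomics table
#'
#' Emulates the mass-spectrometry readout of a pulse-chase experiment: a
#' single supplied bifunctional species decays mono-exponentially (rate
#' `k_met`) into product bifunctional species of other classes, while the
#' total bifunctional share of the lipidome declines with
#' `content_decay_rate` from an initial `loading_frac` (the typical probe
#' loading is 1-3 mol% of the lipidome). Native species make up the
#' remainder. Replicates get multiplicative Gaussian noise of coefficient
#' of variation `noise_cv`, truncated at 0.
#'
#' @param k_met Metabolic conversion rate of the supplied species (min^-1).
#' @param content_decay_rate Decay rate of total bifunctional content
#'   (min^-1).
#' @param loading_frac Initial bifunctional fraction of the lipidome,
#'   default 0.02.
#' @param supplied_species Name of the supplied species.
#' @param supplied_class Lipid class of the supplied species.
#' @param product_classes Classes receiving the converted bifunctional acyl
#'   chain.
#' @param timepoints Minutes, starting at 0.
#' @param n_bio,n_tech Biological x technical replicates (default 3 x 2).
#' @param noise_cv Replicate noise CV on mol%, default 0.1.
#' @param seed Integer seed.
#' @return Tibble with columns `species`, `class`, `bifunctional`,
#'   `supplied`, `mol_pct`, `time_min`, `replicate`; attribute `"truth"`
#'   records the generating parameters.
#' @export
#' @examples
#' tab <- sim_ms_table(k_met = 0.005, seed = 1)
#' head(tab)
sim_ms_table <- function(k_met = 0.005, content_decay_rate = 5e-4,
                         loading_frac = 0.02,
                         supplied_species = "PC(Y/18:1)",
                         supplied_class = "PC",
                         product_classes = c("PE", "PA", "TAG"),
                         timepoints = c(0, 4, 30, 120, 1440),
                         n_bio = 3, n_tech = 2, noise_cv = 0.1, seed = 1) {
  if (k_met < 0 || content_decay_rate < 0) {
    abort("k_met and content_decay_rate must be >= 0.")
  }
  if (loading_frac <= 0 || loading_frac >= 1) {
    abort("loading_frac must be in (0, 1).")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  prod_species <- paste0(product_classes, "(Y/prod)")
  native_classes <- unique(c(supplied_class, product_classes))
  native_species <- paste0(native_classes, "(34:1)")

  grid <- tidyr::expand_grid(
    time_min = timepoints,
    bio = seq_len(n_bio),
    tech = seq_len(n_tech)
  )
  rows <- purrr::pmap_dfr(grid, function(time_min, bio, tech) {
    bif_total <- 100 * loading_frac * exp(-content_decay_rate * time_min)
    f_sup <- exp(-k_met * time_min)
    sup_mol <- bif_total * f_sup
    n_prod <- length(prod_species)
    prod_mol <- rep(bif_total * (1 - f_sup) / n_prod, n_prod)
    native_total <- 100 - bif_total
    nat_mol <- rep(native_total / length(native_species),
                   length(native_species))
    tibble::tibble(
      species = c(supplied_species, prod_species, native_species),
      class = c(supplied_class, product_classes, native_classes),
      bifunctional = c(TRUE, rep(TRUE, n_prod),
                       rep(FALSE, length(native_species))),
      supplied = c(TRUE, rep(FALSE, n_prod + length(native_species))),
      mol_pct = pmax(rnorm(
        1 + n_prod + length(native_species),
        mean = c(sup_mol, prod_mol, nat_mol),
        sd = noise_cv * c(sup_mol, prod_mol, nat_mol)
      ), 0),
      time_min = time_min,
      replicate = paste0("b", bio, "t", tech)
    )
  })
  attr(rows, "truth") <- list(
    k_met = k_met, content_decay_rate = content_decay_rate,
    loading_frac = loading_frac, supplied_species = supplied_species,
    seed = seed
  )
  rows
}
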