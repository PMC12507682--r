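#' Binarize organelle probability maps
#'
#' Thresholds per-pixel classifier probability maps into boolean organelle
#' masks. A pixel belongs to an organelle's mask when its probability is at
#' least `threshold`; pixels claimed by two or more masks are the ambiguous
#' (overlap) pixels handled downstream by [partition_signal()].
#'
#' @param prob_maps Named list of numeric matrices in \[0, 1\], one per
#'   organelle, all the same dimension.
#' @param threshold Probability cutoff in (0, 1), default 0.5.
#' @return Named list of logical matrices.
#' @export
threshold_maps <- function(prob_maps, threshold = 0.5) {
  check_prob_maps(prob_maps)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    abort("threshold must be a single number in (0, 1).")
  }
  lapply(prob_maps, function(p) p >= threshold)
}

check_prob_maps <- function(prob_maps) {
  if (!is.list(prob_maps) || length(prob_maps) == 0 ||
      is.null(names(prob_maps)) || any(names(prob_maps) == "")) {
    abort("prob_maps must be a non-empty named list of matrices.")
  }
  dims <- lapply(prob_maps, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    abort("All probability maps must be matrices of identical dimension.")
  }
  rng <- range(unlist(prob_maps))
  if (rng[1] < 0 || rng[2] > 1) abort("Probabilities must lie in [0, 1].")
  invisible(TRUE)
}

check_masks <- function(lipid, masks) {
  if (!is.matrix(lipid) || !is.numeric(lipid)) {
    abort("lipid must be a numeric matrix.")
  }
  if (!is.list(masks) || length(masks) == 0 || is.null(names(masks))) {
    abort("masks must be a non-empty named list of logical matrices.")
  }
  ok <- vapply(masks, function(m) {
    is.logical(m) && identical(dim(m), dim(lipid))
  }, logical(1))
  if (!all(ok)) abort("Every mask must be a logical matrix matching lipid.")
  invisible(TRUE)
}

#' Per-organelle lipid intensity distributions from unambiguous pixels
#'
#' For each organelle, collects the lipid intensities of pixels belonging to
#' exactly one mask and estimates their distribution as a fixed-bin
#' histogram density with add-one smoothing. These distributions are the
#' weights used to partition the lipid signal where masks overlap.
#'
#' @param lipid Numeric matrix: the lipid fluorescence channel.
#' @param masks Named list of logical matrices (see [threshold_maps()]).
#' @param n_bins Number of histogram bins over the full lipid intensity
#'   range, default 64.
#' @param min_pixels Organelles with fewer unambiguous pixels are flagged
#'   (default 50); organelles with none are excluded from overlap weighting
#'   with a warning.
#' @return An object of class `intensity_distributions`: list with `breaks`
#'   (bin edges), `density` (organelle x bin matrix, rows sum to 1),
#'   `n_unambiguous` (named counts) and `flagged` (organelles below
#'   `min_pixels`).
#' @export
intensity_distributions <- function(lipid, masks, n_bins = 64,
                                    min_pixels = 50) {
  check_masks(lipid, masks)
  cover <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  rng <- range(lipid)
  if (rng[1] == rng[2]) rng[2] <- rng[1] + 1  # constant image: one wide bin
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  dens <- matrix(NA_real_, length(masks), n_bins,
                 dimnames = list(names(masks), NULL))
  n_un <- setNames(integer(length(masks)), names(masks))
  for (org in names(masks)) {
    sel <- masks[[org]] & cover == 1
    n_un[org] <- sum(sel)
    cnt <- if (n_un[org] > 0) {
      tabulate(bin_index(lipid[sel], breaks), nbins = n_bins)
    } else {
      rep(0L, n_bins)
    }
    dens[org, ] <- (cnt + 1) / (sum(cnt) + n_bins)  # add-one smoothing
  }
  flagged <- names(masks)[n_un < min_pixels]
  if (any(n_un == 0)) {
    warn(paste0("No unambiguous pixels for: ",
                paste(names(masks)[n_un == 0], collapse = ", "),
                "; excluded from overlap weighting."))
  }
  structure(
    list(breaks = breaks, density = dens, n_unambiguous = n_un,
         flagged = flagged, usable = names(masks)[n_un > 0]),
    class = "intensity_distributions"
  )
}

bin_index <- function(x, breaks) {
  n_bins <- length(breaks) - 1
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), n_bins)
}

#' Partition a lipid channel between overlapping organelle masks
#'
#' Assigns the full intensity of unambiguous pixels (exactly one mask) to
#' their organelle; splits each ambiguous pixel's intensity I among its
#' overlapping organelles o with likelihood weights
#' w_o = f_o(I) / sum over o' of f_o'(I),
#' where f_o is the organelle's intensity density learned from unambiguous
#' pixels. Total intensity is conserved; pixels outside every mask are
#' counted as unassigned and excluded from the fractions.
#'
#' @inheritParams intensity_distributions
#' @param distributions An `intensity_distributions` object; computed from
#'   `lipid` and `masks` when `NULL`.
#' @param method `"fractional"` (default) splits ambiguous intensity by the
#'   weights; `"winner"` assigns each ambiguous pixel entirely to the
#'   maximum-likelihood organelle (ties split equally).
#' @return A `partition_result`: tibble with one row per organelle
#'   (`organelle`, `assigned_intensity`, `fraction`, `n_unambiguous`) and
#'   attributes `n_ambiguous`, `n_unassigned`, `unassigned_intensity`,
#'   `total_intensity`.
#' @export
partition_signal <- function(lipid, masks, distributions = NULL,
                             method = c("fractional", "winner")) {
  method <- match.arg(method)
  check_masks(lipid, masks)
  if (is.null(distributions)) {
    distributions <- suppressWarnings(intensity_distributions(lipid, masks))
  }
  orgs <- names(masks)
  mask_mat <- vapply(masks, as.vector, logical(length(lipid)))
  cover <- rowSums(mask_mat)
  I <- as.vector(lipid)

  assigned <- setNames(numeric(length(orgs)), orgs)
  n_un <- setNames(integer(length(orgs)), orgs)
  for (org in orgs) {
    sel <- mask_mat[, org] & cover == 1
    assigned[org] <- sum(I[sel])
    n_un[org] <- sum(sel)
  }

  amb <- which(cover >= 2)
  n_unassigned_extra <- 0L
  equal_split_pixels <- 0L
  if (length(amb) > 0) {
    bins <- bin_index(I[amb], distributions$breaks)
    for (j in seq_along(amb)) {
      px <- amb[j]
      here <- orgs[mask_mat[px, ]]
      usable <- intersect(here, distributions$usable)
      if (length(usable) == 0) {
        n_unassigned_extra <- n_unassigned_extra + 1L
        next
      }
      f <- distributions$density[usable, bins[j]]
      if (sum(f) == 0) {
        w <- rep(1 / length(usable), length(usable))
        equal_split_pixels <- equal_split_pixels + 1L
      } else {
        w <- f / sum(f)
      }
      if (method == "winner") {
        top <- which(w == max(w))
        w <- replace(numeric(length(w)), top, 1 / length(top))
      }
      assigned[usable] <- assigned[usable] + I[px] * w
    }
  }
  if (equal_split_pixels > 0) {
    inform(paste0(equal_split_pixels,
                  " ambiguous pixel(s) had zero density everywhere; ",
                  "split equally."))
  }

  outside <- cover == 0
  total_assigned <- sum(assigned)
  # ambiguous pixels with no usable distribution stay unassigned
  unassigned_intensity <- sum(I[outside]) +
    (sum(I[cover >= 1]) - total_assigned)

  total <- total_assigned
  fractions <- if (total > 0) assigned / total else assigned * NA_real_

  out <- tibble::tibble(
    organelle = orgs,
    assigned_intensity = unname(assigned),
    fraction = unname(fractions),
    n_unambiguous = unname(n_un)
  )
  structure(
    out,
    n_ambiguous = length(amb),
    n_unassigned = sum(outside) + n_unassigned_extra,
    unassigned_intensity = unassigned_intensity,
    total_intensity = sum(I),
    method = method,
    class = c("partition_result", class(out))
  )
}

#' Run mask building, distribution learning and signal partitioning
#'
#' Convenience wrapper: thresholds the probability maps, learns per-organelle
#' intensity distributions from unambiguous pixels, and partitions the lipid
#' channel.
#'
#' @param lipid Numeric matrix, the lipid channel.
#' @param prob_maps Named list of probability maps.
#' @param threshold Mask probability cutoff, default 0.5.
#' @param ... Passed on to [partition_signal()].
#' @return A `partition_result`.
#' @export
partition_image <- function(lipid, prob_maps, threshold = 0.5, ...) {
  masks <- threshold_maps(prob_maps, threshold)
  dists <- suppressWarnings(intensity_distributions(lipid, masks))
  partition_signal(lipid, masks, dists, ...)
}
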