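#' Separate touching nuclei by distance-transform watershed
#'
#' Connected foreground in the thresholded nuclei mask is split along the
#' ridges of the negated exact Euclidean distance transform. Seeds are local
#' maxima of the Gaussian-smoothed distance transform (default sigma 1 px),
#' greedily thinned so that no two seeds are closer than `min_seed_sep`
#' pixels (default 5 px); the flood then assigns every foreground pixel to
#' exactly one seed, so foreground is conserved pixel-for-pixel. A convex
#' object yields a single seed and is not oversegmented; two touching nuclei
#' whose distance-transform peaks are farther apart than `min_seed_sep` are
#' split.
#'
#' @param mask `binary_mask` (or logical matrix) from the nuclei channel.
#' @param sigma Gaussian smoothing of the distance transform before seed
#'   detection, pixels.
#' @param min_seed_sep minimum Euclidean distance between seeds, pixels.
#' @return a `label_map` with contiguous labels 1..N (N = 0 for empty mask).
#' @export
separate_nuclei <- function(mask, sigma = 1, min_seed_sep = 5) {
  m <- unclass(mask)
  stopifnot(is.logical(m), is.matrix(m))
  if (!any(m)) return(label_map(matrix(0L, nrow(m), ncol(m))))
  dist <- cpp_edt(m)
  sm <- cpp_gaussian_blur(dist, sigma)
  # candidate seeds: foreground pixels that attain the local max of the
  # smoothed distance within a Chebyshev window of min_seed_sep
  mx <- cpp_max_filter(sm, as.integer(ceiling(min_seed_sep)))
  cand <- which(m & sm >= mx - 1e-12, arr.ind = TRUE)
  vals <- sm[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])  # deterministic
  cand <- cand[ord, , drop = FALSE]
  keep_r <- numeric(0)
  keep_c <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    if (length(keep_r) == 0 ||
        all((keep_r - r)^2 + (keep_c - c)^2 >= min_seed_sep^2)) {
      keep_r <- c(keep_r, r)
      keep_c <- c(keep_c, c)
    }
  }
  markers <- matrix(0L, nrow(m), ncol(m))
  markers[cbind(keep_r, keep_c)] <- seq_along(keep_r)
  lab <- cpp_watershed(-dist, markers, m)
  relabel_contiguous(lab)
}

# Re-index nonzero labels to contiguous 1..N preserving first-seen order.
relabel_contiguous <- function(lab) {
  u <- unique(lab[lab > 0])
  if (length(u) == 0) return(label_map(matrix(0L, nrow(lab), ncol(lab))))
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- lut[lab[nz]]
  label_map(out)
}

#' Remove large inseparable objects from a label map
#'
#' Objects whose area exceeds `max_area_px` (default 900 px, the maximum
#' retained size) are removed; nuclei clusters the watershed could not
#' separate are thereby excluded from counting. Remaining labels are
#' re-indexed 1..M and the number of removed objects is recorded in the
#' `"n_removed"` attribute.
#'
#' @param labels a `label_map`.
#' @param max_area_px largest retained object area; objects strictly greater
#'   are removed.
#' @return filtered `label_map` with attribute `n_removed`.
#' @export
filter_large_objects <- function(labels, max_area_px = 900) {
  n <- max(labels, 0L)
  if (n == 0) {
    out <- label_map(matrix(0L, nrow(labels), ncol(labels)))
    attr(out, "n_removed") <- 0L
    return(out)
  }
  area <- tabulate(labels[labels > 0], nbins = n)
  drop_ <- which(area > max_area_px)
  lab <- unclass(labels)
  if (length(drop_) > 0) lab[lab %in% drop_] <- 0L
  out <- relabel_contiguous(lab)
  attr(out, "n_removed") <- length(drop_)
  out
}
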