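#' Automatic histogram thresholding (Li and Triangle methods)
#'
#' Computes a global threshold on a 256-bin histogram and returns the
#' foreground mask (pixels strictly above the threshold), reproducing the
#' thresholding step of the micrograph quantification script.
#'
#' * **Li**: minimum cross-entropy threshold. For a candidate threshold `T`
#'   splitting the histogram into background (`g <= T`) and foreground
#'   (`g > T`) with class mean intensities `mu0`, `mu1`, the cross entropy
#'   `-sum_bg(h*g)*log(mu0) - sum_fg(h*g)*log(mu1)` is minimised by an
#'   exhaustive vectorised scan over all candidate bins.
#' * **Triangle**: geometric method for unimodal histograms with a long tail.
#'   A chord is drawn from the histogram peak to the last nonzero bin (the
#'   chord is mirrored to the first nonzero bin when the peak sits at the
#'   upper end); the threshold is the bin with maximal perpendicular
#'   distance below the chord, after normalising the count axis to the peak.
#'
#' Non-8-bit inputs are min--max scaled onto 256 bins first, so the same
#' histogram machinery covers 8-bit RGB planes and 16-bit stacks. A constant
#' channel has no splitting threshold: the result is an empty mask with the
#' `"constant_channel"` flag set (a warning state, not an error, for batch
#' robustness).
#'
#' @param channel a `channel_image` or numeric matrix.
#' @param method `"li"` or `"triangle"`.
#' @return list with `mask` (`binary_mask`), `threshold_bin` (bin value in
#'   0..255; background is `<= threshold_bin`), `threshold` (same cutoff on
#'   the original intensity scale), `method` and `flags` (character vector,
#'   possibly empty).
#' @export
threshold <- function(channel, method = c("li", "triangle")) {
  method <- match.arg(method)
  x <- unclass(channel)
  stopifnot(is.matrix(x), length(x) > 0)
  rng <- range(x)
  flags <- character(0)
  if (rng[1] == rng[2]) {
    return(list(mask = binary_mask(matrix(FALSE, nrow(x), ncol(x))),
                threshold_bin = NA_integer_, threshold = NA_real_,
                method = method, flags = "constant_channel"))
  }
  # map to bins 0..255: 8-bit integer data is used as-is so bin == intensity
  eightbit <- rng[1] >= 0 && rng[2] <= 255 && all(x == floor(x))
  if (eightbit) {
    bins <- x
    to_original <- function(t) t
  } else {
    bins <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * 256), 255)
    to_original <- function(t) rng[1] + (t + 1) * (rng[2] - rng[1]) / 256
  }
  h <- tabulate(as.integer(bins) + 1L, nbins = 256L)
  t_bin <- switch(method,
                  li = li_threshold_bin(h),
                  triangle = triangle_threshold_bin(h))
  if (is.na(t_bin)) {
    return(list(mask = binary_mask(matrix(FALSE, nrow(x), ncol(x))),
                threshold_bin = NA_integer_, threshold = NA_real_,
                method = method, flags = "degenerate_histogram"))
  }
  mask <- matrix(bins > t_bin, nrow(x), ncol(x))
  list(mask = binary_mask(mask), threshold_bin = t_bin,
       threshold = to_original(t_bin), method = method, flags = flags)
}

# Exhaustive minimum-cross-entropy scan; h = 256 counts for bins 0..255.
# Returns the bin value (0-based) of the last background bin, or NA.
li_threshold_bin <- function(h) {
  g <- 0:255
  cum0 <- cumsum(h)
  cum1 <- cumsum(h * g)
  n <- cum0[256]
  s <- cum1[256]
  m0a <- cum0
  m1a <- cum1
  m0b <- n - m0a
  m1b <- s - m1a
  valid <- m0a > 0 & m0b > 0
  if (!any(valid)) return(NA_real_)
  mua <- ifelse(m0a > 0, m1a / m0a, 0)
  mub <- ifelse(m0b > 0, m1b / m0b, 0)
  nu <- -ifelse(m1a > 0, m1a * log(mua), 0) -
    ifelse(m1b > 0, m1b * log(mub), 0)
  nu[!valid] <- Inf
  which.min(nu) - 1L
}

# Triangle threshold; chord from the histogram peak to the far nonzero bin.
triangle_threshold_bin <- function(h) {
  nz <- which(h > 0)
  if (length(nz) < 2) return(NA_real_)
  hn <- h / max(h)
  p <- which.max(h)          # peak bin (first on ties)
  e <- nz[length(nz)]        # last nonzero bin
  if (p == e) e <- nz[1]     # peak at the top end: mirror to the first
  lo <- min(p, e)
  hi <- max(p, e)
  if (hi - lo < 2) return(lo - 1L)
  b <- (lo + 1):(hi - 1)
  # signed area cross-product: positive where the histogram dips below the
  # peak->far chord; maximise the perpendicular drop
  cross <- (e - p) * (hn[b] - hn[p]) - (b - p) * (hn[e] - hn[p])
  drop_ <- cross * sign(e - p) * -1
  as.integer(b[which.max(drop_)] - 1L)
}
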