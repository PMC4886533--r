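# Independent brute-force oracles used to check the implementation paths.

# Exhaustive minimum-cross-entropy threshold: explicit loop over every
# candidate bin, computing class sums from scratch (independent of the
# package's cumulative-sum formulation).
oracle_li_bin <- function(counts) {
  g <- 0:255
  best <- Inf
  best_t <- NA
  for (t in 0:254) {
    bg <- which(g <= t)
    fg <- which(g > t)
    m0a <- sum(counts[bg])
    m0b <- sum(counts[fg])
    if (m0a == 0 || m0b == 0) next
    m1a <- sum(counts[bg] * g[bg])
    m1b <- sum(counts[fg] * g[fg])
    nu <- 0
    if (m1a > 0) nu <- nu - m1a * log(m1a / m0a)
    if (m1b > 0) nu <- nu - m1b * log(m1b / m0b)
    if (nu < best) {
      best <- nu
      best_t <- t
    }
  }
  best_t
}

# Exhaustive triangle threshold: per-bin perpendicular point-to-line
# distance from the explicit line equation (the package uses a
# cross-product form), signed so that only dips below the chord count.
oracle_triangle_bin <- function(counts) {
  nz <- which(counts > 0)
  if (length(nz) < 2) return(NA_integer_)
  hn <- counts / max(counts)
  p <- which.max(counts)
  e <- nz[length(nz)]
  if (p == e) e <- nz[1]
  lo <- min(p, e)
  hi <- max(p, e)
  if (hi - lo < 2) return(lo - 1L)
  x1 <- p; y1 <- hn[p]; x2 <- e; y2 <- hn[e]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  best <- -Inf
  best_b <- NA
  for (b in (lo + 1):(hi - 1)) {
    chord_y <- y1 + (y2 - y1) * (b - x1) / (x2 - x1)
    d <- (chord_y - hn[b]) * abs(x2 - x1) / len  # >0 below the chord
    if (d > best) {
      best <- d
      best_b <- b
    }
  }
  as.integer(best_b - 1L)
}

hist256 <- function(img) tabulate(as.integer(img) + 1L, nbins = 256L)

# random two-population 8-bit image (background-dominated histogram)
random_bimodal_image <- function() {
  n <- 4000
  wfg <- runif(1, 0.05, 0.40)
  nfg <- round(n * wfg)
  bg <- rnorm(n - nfg, runif(1, 20, 80), runif(1, 4, 18))
  fg <- rnorm(nfg, runif(1, 130, 230), runif(1, 4, 18))
  v <- round(pmin(pmax(c(bg, fg), 0), 255))
  matrix(v, 50, 80)
}

# pure-R 8-connected component labelling (queue flood fill), independent of
# the compiled labelling used by the package
r_label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr
        c2 <- c + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        i2 <- r2 + (c2 - 1L) * nr
        if (mask[i2] && lab[i2] == 0L) {
          lab[i2] <- nxt
          queue <- c(queue, i2)
        }
      }
    }
  }
  lab
}

# enumerate true indices from a scene's ground truth using the pure-R
# labelling and direct membership counting
oracle_indices_from_truth <- function(truth) {
  lab <- r_label_components(unclass(truth$marker_mask))
  n <- nrow(truth$nucleus_centroids)
  comp <- integer(n)
  if (n > 0) {
    pix <- cbind(floor(truth$nucleus_centroids$row + 0.5) + 1,
                 floor(truth$nucleus_centroids$col + 0.5) + 1)
    comp <- lab[pix]
  }
  per <- tabulate(comp[comp > 0], nbins = max(lab, 0L))
  in_marker <- sum(per)
  myo <- sum(per[per >= 2])
  list(differentiation_index = if (n > 0) in_marker / n else 0,
       fusion_index = if (in_marker > 0) myo / in_marker else 0,
       myotube_count = sum(per >= 2),
       nuclei_in_marker = in_marker)
}

# two-group F statistic via R's model machinery (closed-form oracle)
oracle_anova_p <- function(x, g) {
  stats::anova(stats::lm(x ~ factor(g)))[["Pr(>F)"]][1]
}

# permutation distribution of the F statistic over all label assignments
oracle_permutation_p <- function(x, g) {
  g <- as.character(g)
  n1 <- sum(g == unique(g)[1])
  idx <- utils::combn(length(x), n1)
  fstat <- function(lab) {
    a <- stats::anova(stats::lm(x ~ factor(lab)))
    a[["F value"]][1]
  }
  f_obs <- fstat(g)
  f_perm <- apply(idx, 2, function(i) {
    lab <- rep("b", length(x))
    lab[i] <- "a"
    fstat(lab)
  })
  mean(f_perm >= f_obs - 1e-12)
}

# small synthetic label map: discs on a grid
disc_mask <- function(h, w, centers, r) {
  m <- matrix(FALSE, h, w)
  for (k in seq_len(nrow(centers))) {
    for (i in 1:h) for (j in 1:w)
      if ((i - 1 - centers[k, 1])^2 + (j - 1 - centers[k, 2])^2 <= r^2)
        m[i, j] <- TRUE
  }
  m
}
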