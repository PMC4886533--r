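#' Parameters for the synthetic micrograph generator
#'
#' Describes a two-channel fluorescence scene: DAPI-like nuclei (rendered as
#' filled ellipses with axis ratio in \[0.7, 1\]) and a marker channel (MyHC,
#' laminin, elastase or Ly6G) containing multinucleated myotubes (capsule
#' shapes), mononucleated marker-positive cells (discs) and nothing else.
#' A stated fraction of the background nuclei is placed as touching pairs at
#' centre distance `1.6 * radius`, so they merge under thresholding and
#' exercise the watershed split.
#'
#' `n_nuclei` counts *all* nuclei in the scene; the generator places
#' `nuclei_per_myotube` in each myotube, one in each mononucleated marker
#' cell, and the remainder on the background (of which
#' `frac_touching_pairs` worth are paired).
#'
#' @param image_height_px,image_width_px image size, pixels.
#' @param n_nuclei total number of nuclei.
#' @param nucleus_radius_px length-2 vector `c(mean, spread)` in pixels.
#' @param frac_touching_pairs fraction in \[0,1\] of nuclei placed as
#'   touching pairs.
#' @param n_myotubes,myotube_length_px,myotube_width_px myotube count and
#'   capsule geometry, pixels.
#' @param nuclei_per_myotube nuclei placed along each myotube axis.
#' @param n_mono_myhc_cells mononucleated marker-positive cells.
#' @param mono_cell_radius_px disc radius of mononucleated marker cells.
#' @param noise_sd additive Gaussian noise, 8-bit intensity units.
#' @param background_level,foreground_level 8-bit intensity levels
#'   (`foreground_level > background_level`).
#' @param seed integer RNG seed.
#' @return validated parameter list of class `image_sim_params`.
#' @export
image_sim_params <- function(image_height_px = 256, image_width_px = 256,
                             n_nuclei = 40,
                             nucleus_radius_px = c(7, 1),
                             frac_touching_pairs = 0.2,
                             n_myotubes = 3,
                             myotube_length_px = 110,
                             myotube_width_px = 20,
                             nuclei_per_myotube = 3,
                             n_mono_myhc_cells = 3,
                             mono_cell_radius_px = 11,
                             noise_sd = 8,
                             background_level = 30,
                             foreground_level = 200,
                             seed = 1L) {
  p <- list(image_height_px = as.integer(image_height_px),
            image_width_px = as.integer(image_width_px),
            n_nuclei = as.integer(n_nuclei),
            nucleus_radius_px = as.numeric(nucleus_radius_px),
            frac_touching_pairs = frac_touching_pairs,
            n_myotubes = as.integer(n_myotubes),
            myotube_length_px = myotube_length_px,
            myotube_width_px = myotube_width_px,
            nuclei_per_myotube = as.integer(nuclei_per_myotube),
            n_mono_myhc_cells = as.integer(n_mono_myhc_cells),
            mono_cell_radius_px = mono_cell_radius_px,
            noise_sd = noise_sd,
            background_level = background_level,
            foreground_level = foreground_level,
            seed = as.integer(seed))
  stopifnot(p$image_height_px > 0, p$image_width_px > 0,
            p$n_nuclei >= 0, length(p$nucleus_radius_px) == 2,
            p$nucleus_radius_px[1] > 0, p$nucleus_radius_px[2] >= 0,
            p$frac_touching_pairs >= 0, p$frac_touching_pairs <= 1,
            p$n_myotubes >= 0, p$myotube_length_px > 0,
            p$myotube_width_px > 0, p$nuclei_per_myotube >= 0,
            p$n_mono_myhc_cells >= 0, p$mono_cell_radius_px > 0,
            p$noise_sd >= 0)
  if (p$foreground_level <= p$background_level)
    stop("image_sim_params: foreground_level must exceed background_level")
  if (p$n_nuclei < p$n_myotubes * p$nuclei_per_myotube + p$n_mono_myhc_cells)
    stop("image_sim_params: n_nuclei smaller than the nuclei required by ",
         "myotubes and mononucleated marker cells")
  dmin <- min(p$image_height_px, p$image_width_px)
  if (p$n_myotubes > 0 && p$myotube_length_px + p$myotube_width_px + 8 > dmin)
    stop("image_sim_params: myotube geometry does not fit inside the image")
  if (2 * p$nucleus_radius_px[1] + 8 > dmin)
    stop("image_sim_params: nucleus geometry does not fit inside the image")
  class(p) <- "image_sim_params"
  p
}

#' Simulate a ground-truthed fluorescence micrograph
#'
#' Renders the scene described by `params` and returns both image dialects
#' (8-bit RGB with blue = nuclei / green = marker, and a 2-plane 16-bit
#' stack) together with the exact ground truth: noise-free masks, nucleus
#' centroids, per-marker-object nucleus memberships, and the true myogenesis
#' indices computed by enumeration of those memberships. Additive Gaussian
#' noise (clipped to \[0, 255\]) is applied to the intensity channels only;
#' the ground-truth masks are the rendered geometry.
#'
#' @param params an `image_sim_params` object.
#' @return list with `rgb` (h x w x 3 array), `stack` (h x w x 2 array,
#'   16-bit scale, plane 1 = nuclei, plane 2 = marker), and `truth` (list:
#'   `nucleus_centroids` data.frame of 0-based `row`,`col`, `pair_id`,
#'   `nucleus_mask`, `marker_mask`, `memberships` list per marker component,
#'   `component_kind`, `touching_pairs` data.frame, `true_indices`).
#' @export
simulate_image <- function(params = image_sim_params()) {
  stopifnot(inherits(params, "image_sim_params"))
  set.seed(params$seed)
  h <- params$image_height_px
  w <- params$image_width_px
  rmu <- params$nucleus_radius_px[1]
  rsd <- params$nucleus_radius_px[2]
  gap <- 3  # minimum clearance between marker objects / marker and nuclei

  marker <- matrix(FALSE, h, w)
  nucmask <- matrix(FALSE, h, w)
  myotube_axes <- list()
  mono_centers <- list()

  blocked <- matrix(FALSE, h, w)
  place_marker_object <- function(px) {
    if (any(blocked[px])) return(FALSE)
    marker[px] <<- TRUE
    blocked <<- cpp_max_filter(marker * 1, as.integer(gap)) > 0
    TRUE
  }

  # --- myotubes: capsules at random orientation -------------------------
  half <- params$myotube_width_px / 2
  for (i in seq_len(params$n_myotubes)) {
    ok <- FALSE
    for (try in 1:300) {
      th <- runif(1, 0, pi)
      d <- c(sin(th), cos(th))
      ext <- abs(d) * params$myotube_length_px / 2 + half + 2
      if (2 * ext[1] >= h || 2 * ext[2] >= w) next
      ctr <- c(runif(1, ext[1], h - 1 - ext[1]),
               runif(1, ext[2], w - 1 - ext[2]))
      p1 <- ctr - d * params$myotube_length_px / 2
      p2 <- ctr + d * params$myotube_length_px / 2
      px <- capsule_pixels(h, w, p1, p2, half)
      if (place_marker_object(px)) {
        myotube_axes[[i]] <- list(p1 = p1, p2 = p2)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("simulate_image: placement error (myotube ", i, ")")
  }

  # --- mononucleated marker-positive cells: discs -----------------------
  rmono <- params$mono_cell_radius_px
  for (i in seq_len(params$n_mono_myhc_cells)) {
    ok <- FALSE
    for (try in 1:300) {
      ctr <- c(runif(1, rmono + 2, h - 3 - rmono),
               runif(1, rmono + 2, w - 3 - rmono))
      px <- ellipse_pixels(h, w, ctr[1], ctr[2], rmono, rmono, 0)
      if (place_marker_object(px)) {
        mono_centers[[i]] <- ctr
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("simulate_image: placement error (mono marker cell ", i, ")")
  }

  # distance from any pixel to the nearest marker pixel (Inf if no marker)
  dist_to_marker <- if (any(marker)) cpp_edt(!marker) else
    matrix(Inf, h, w)

  draw_radius <- function(lim = Inf) {
    r <- rnorm(1, rmu, rsd)
    max(2, min(r, rmu + 3 * rsd, lim))
  }

  centers <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  pair_id <- integer(0)
  add_nucleus <- function(ctr, a, b, ang, pid) {
    px <- ellipse_pixels(h, w, ctr[1], ctr[2], a, b, ang)
    nucmask[px] <<- TRUE
    centers <<- rbind(centers, ctr)
    radii <<- c(radii, max(a, b))
    pair_id <<- c(pair_id, pid)
  }

  # --- nuclei inside myotubes (evenly spaced along the axis) ------------
  for (i in seq_len(params$n_myotubes)) {
    ax <- myotube_axes[[i]]
    k <- params$nuclei_per_myotube
    for (j in seq_len(k)) {
      f <- j / (k + 1)
      ctr <- ax$p1 + f * (ax$p2 - ax$p1)
      r <- draw_radius(lim = half - 1)
      ratio <- runif(1, 0.7, 1)
      add_nucleus(ctr, r, r * ratio, runif(1, 0, pi), 0L)
    }
  }

  # --- one nucleus at the centre of each mononucleated marker cell ------
  for (ctr in mono_centers) {
    r <- draw_radius(lim = rmono - 1.5)
    ratio <- runif(1, 0.7, 1)
    add_nucleus(ctr, r, r * ratio, runif(1, 0, pi), 0L)
  }

  # --- background nuclei: touching pairs then singles -------------------
  n_bg <- params$n_nuclei - nrow(centers)
  n_pairs <- floor(params$frac_touching_pairs * params$n_nuclei / 2)
  n_pairs <- min(n_pairs, n_bg %/% 2)
  sep <- 4  # clearance between non-pair nuclei
  clear_of_others <- function(ctr, r, ignore = 0L) {
    if (dist_to_marker[floor(ctr[1] + 0.5) + 1, floor(ctr[2] + 0.5) + 1] <=
        r + gap) return(FALSE)
    if (nrow(centers) == 0) return(TRUE)
    keep <- seq_len(nrow(centers))
    if (ignore > 0) keep <- keep[keep != ignore]
    if (length(keep) == 0) return(TRUE)
    d2 <- (centers[keep, 1] - ctr[1])^2 + (centers[keep, 2] - ctr[2])^2
    all(d2 >= (radii[keep] + r + sep)^2)
  }

  for (i in seq_len(n_pairs)) {
    ok <- FALSE
    for (try in 1:500) {
      r <- draw_radius()
      m <- 2 * r + 2.6 * r  # margin: own radius + partner offset
      ctr1 <- c(runif(1, m, h - 1 - m), runif(1, m, w - 1 - m))
      phi <- runif(1, 0, 2 * pi)
      ctr2 <- ctr1 + 1.6 * r * c(sin(phi), cos(phi))
      if (!clear_of_others(ctr1, 1.6 * r + r) ||
          !clear_of_others(ctr2, 1.6 * r + r)) next
      # touching pair: circles (axis ratio 1) at centre distance 1.6 r,
      # guaranteed to merge under thresholding
      add_nucleus(ctr1, r, r, 0, i)
      add_nucleus(ctr2, r, r, 0, i)
      ok <- TRUE
      break
    }
    if (!ok) stop("simulate_image: placement error (touching pair ", i, ")")
  }
  for (i in seq_len(n_bg - 2 * n_pairs)) {
    ok <- FALSE
    for (try in 1:500) {
      r <- draw_radius()
      ctr <- c(runif(1, r + 2, h - 3 - r), runif(1, r + 2, w - 3 - r))
      if (!clear_of_others(ctr, r)) next
      ratio <- runif(1, 0.7, 1)
      add_nucleus(ctr, r, r * ratio, runif(1, 0, pi), 0L)
      ok <- TRUE
      break
    }
    if (!ok) stop("simulate_image: placement error (background nucleus)")
  }

  # --- ground-truth memberships from the rendered geometry --------------
  comp <- cpp_label_components(marker, 8L)
  n_comp <- max(comp, 0L)
  centroids <- if (nrow(centers) > 0)
    data.frame(row = centers[, 1], col = centers[, 2], pair_id = pair_id)
  else data.frame(row = numeric(0), col = numeric(0), pair_id = integer(0))
  nuc_comp <- integer(nrow(centroids))
  if (nrow(centroids) > 0) {
    pix <- cbind(floor(centroids$row + 0.5) + 1, floor(centroids$col + 0.5) + 1)
    nuc_comp <- comp[pix]
  }
  memberships <- lapply(seq_len(n_comp), function(l) which(nuc_comp == l))
  kind <- character(n_comp)
  for (ax in myotube_axes) {
    ctr <- (ax$p1 + ax$p2) / 2
    kind[comp[floor(ctr[1] + 0.5) + 1, floor(ctr[2] + 0.5) + 1]] <- "myotube"
  }
  for (ctr in mono_centers)
    kind[comp[floor(ctr[1] + 0.5) + 1, floor(ctr[2] + 0.5) + 1]] <- "mono"

  truth <- list(
    nucleus_centroids = centroids,
    nucleus_mask = binary_mask(nucmask),
    marker_mask = binary_mask(marker),
    memberships = memberships,
    component_kind = kind,
    touching_pairs = centroids[centroids$pair_id > 0, , drop = FALSE],
    true_indices = indices_from_memberships(memberships, nrow(centroids),
                                            marker),
    params = params
  )

  # --- render intensity channels ----------------------------------------
  bg <- params$background_level
  fg <- params$foreground_level
  nuc_ch <- bg + (fg - bg) * nucmask
  mark_ch <- bg + (fg - bg) * marker
  if (params$noise_sd > 0) {
    nuc_ch <- nuc_ch + matrix(rnorm(h * w, 0, params$noise_sd), h, w)
    mark_ch <- mark_ch + matrix(rnorm(h * w, 0, params$noise_sd), h, w)
  }
  nuc_ch <- round(pmin(pmax(nuc_ch, 0), 255))
  mark_ch <- round(pmin(pmax(mark_ch, 0), 255))
  rgb <- array(0, c(h, w, 3))
  rgb[, , 2] <- mark_ch
  rgb[, , 3] <- nuc_ch
  stack <- array(0, c(h, w, 2))
  stack[, , 1] <- nuc_ch * 257  # 16-bit dialect of the same scene
  stack[, , 2] <- mark_ch * 257

  list(rgb = rgb, stack = stack, truth = truth)
}

#' True myogenesis indices by enumeration of nucleus memberships
#'
#' Computes the ground-truth record the same way the quantification defines
#' the indices: differentiation index = nuclei inside marker components over
#' all nuclei; a myotube is a component holding >= 2 nuclei; fusion index =
#' nuclei in myotubes over nuclei in any marker component (nucleus-as-cell
#' convention).
#'
#' @param memberships list: per marker component, the nucleus indices inside.
#' @param total_nuclei total nucleus count of the scene.
#' @param marker_mask logical matrix (for the area fields).
#' @return `myogenesis_indices` list.
#' @export
indices_from_memberships <- function(memberships, total_nuclei, marker_mask) {
  per_comp <- lengths(memberships)
  in_marker <- sum(per_comp)
  myo <- which(per_comp >= 2)
  flags <- character(0)
  di <- if (total_nuclei > 0) in_marker / total_nuclei else {
    flags <- c(flags, "no_nuclei"); 0
  }
  fi <- if (in_marker > 0) sum(per_comp[myo]) / in_marker else {
    flags <- c(flags, "no_marker_cells"); 0
  }
  structure(list(
    total_nuclei = as.integer(total_nuclei),
    nuclei_in_marker = as.integer(in_marker),
    myotube_nuclei = as.integer(sum(per_comp[myo])),
    marker_positive_cell_count = as.integer(in_marker),
    myotube_count = length(myo),
    myotube_area_px = sum(marker_mask),
    marker_area_px = sum(marker_mask),
    marker_area_fraction = sum(marker_mask) / length(marker_mask),
    differentiation_index = di,
    fusion_index = fi,
    flags = flags
  ), class = "myogenesis_indices")
}

# pixel indices (1-based matrix index pairs) of a filled rotated ellipse
# centred at 0-based (r0, c0) with semi-axes a (along angle) and b
ellipse_pixels <- function(h, w, r0, c0, a, b, theta) {
  rmax <- max(a, b)
  rows <- max(1, floor(r0 - rmax) + 1):min(h, ceiling(r0 + rmax) + 1)
  cols <- max(1, floor(c0 - rmax) + 1):min(w, ceiling(c0 + rmax) + 1)
  dr <- (rows - 1) - r0
  dc <- (cols - 1) - c0
  DR <- matrix(dr, length(rows), length(cols))
  DC <- matrix(dc, length(rows), length(cols), byrow = TRUE)
  u <- DR * cos(theta) + DC * sin(theta)
  v <- -DR * sin(theta) + DC * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(rows[idx[, 1]], cols[idx[, 2]])
}

# pixel indices within halfwidth of the segment p1-p2 (capsule / stadium)
capsule_pixels <- function(h, w, p1, p2, halfwidth) {
  rows <- max(1, floor(min(p1[1], p2[1]) - halfwidth) + 1):
    min(h, ceiling(max(p1[1], p2[1]) + halfwidth) + 1)
  cols <- max(1, floor(min(p1[2], p2[2]) - halfwidth) + 1):
    min(w, ceiling(max(p1[2], p2[2]) + halfwidth) + 1)
  DR <- matrix((rows - 1), length(rows), length(cols))
  DC <- matrix((cols - 1), length(rows), length(cols), byrow = TRUE)
  v <- p2 - p1
  L2 <- sum(v^2)
  t <- ((DR - p1[1]) * v[1] + (DC - p1[2]) * v[2]) / L2
  t <- pmin(pmax(t, 0), 1)
  d2 <- (DR - (p1[1] + t * v[1]))^2 + (DC - (p1[2] + t * v[2]))^2
  idx <- which(d2 <= halfwidth^2, arr.ind = TRUE)
  cbind(rows[idx[, 1]], cols[idx[, 2]])
}
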