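#' Marker-positive area of a thresholded mask
#'
#' Total foreground pixel count and fraction of the image, the quantity
#' reported per image for laminin, elastase and MyHC stainings.
#'
#' @param mask a `binary_mask`.
#' @return list with `area_px` (integer) and `area_fraction` in \[0,1\].
#' @export
marker_area <- function(mask) {
  m <- unclass(mask)
  stopifnot(is.logical(m), is.matrix(m))
  list(area_px = sum(m), area_fraction = sum(m) / length(m))
}

#' Count marker-positive cells by nuclear centroid
#'
#' A nuclear object counts as marker-positive when its centroid pixel lies
#' inside the marker foreground (used e.g. for Ly6G+ neutrophil counts).
#'
#' @param nuclei a `label_map` of separated nuclei.
#' @param marker a `binary_mask` on the same pixel grid.
#' @return integer count.
#' @export
count_marker_positive_cells <- function(nuclei, marker) {
  check_same_grid(nuclei, marker)
  st <- label_stats(nuclei)
  if (nrow(st) == 0) return(0L)
  px <- centroid_pixels(st, dim(marker))
  sum(unclass(marker)[px])
}

#' Myogenesis indices from nucleus labels and a marker mask
#'
#' The marker foreground is partitioned into connected components (the
#' marker-positive "cells"); each nucleus is assigned to the component that
#' contains its centroid pixel (`assignment = "centroid"`, default) or to the
#' component with the largest pixel overlap (`assignment = "overlap"`).
#' A *myotube* is a marker component containing at least 2 nuclei. Under the
#' default nucleus-as-cell convention:
#'
#' * differentiation index = nuclei in marker components / total nuclei;
#' * fusion index = nuclei in myotubes / nuclei in all marker components.
#'
#' With `fusion_convention = "components"` the fusion index instead counts
#' each marker component as one cell: myotube components / all components
#' that contain at least one nucleus. Degenerate denominators give index 0
#' with the corresponding flag (`no_nuclei`, `no_marker_cells`).
#'
#' @param nuclei a `label_map` of separated, size-filtered nuclei.
#' @param marker a `binary_mask` on the same grid.
#' @param assignment nucleus-to-component rule, `"centroid"` or `"overlap"`.
#' @param fusion_convention `"nuclei"` (default) or `"components"`.
#' @return a `myogenesis_indices` list: `total_nuclei`, `nuclei_in_marker`,
#'   `myotube_nuclei`, `marker_positive_cell_count`, `myotube_count`,
#'   `myotube_area_px`, `marker_area_px`, `marker_area_fraction`,
#'   `differentiation_index`, `fusion_index`, `flags`.
#' @export
compute_indices <- function(nuclei, marker,
                            assignment = c("centroid", "overlap"),
                            fusion_convention = c("nuclei", "components")) {
  assignment <- match.arg(assignment)
  fusion_convention <- match.arg(fusion_convention)
  check_same_grid(nuclei, marker)
  comp <- cpp_label_components(unclass(marker), 8L)
  n_nuc <- count_objects(nuclei)
  n_comp <- max(comp, 0L)
  flags <- character(0)

  if (n_nuc == 0) {
    assign_comp <- integer(0)
  } else if (assignment == "centroid") {
    st <- label_stats(nuclei)
    assign_comp <- comp[centroid_pixels(st, dim(marker))]
  } else {
    # majority-overlap: component claiming the most pixels of each nucleus
    nz <- unclass(nuclei) > 0 & comp > 0
    if (!any(nz)) {
      assign_comp <- integer(n_nuc)
    } else {
      tab <- table(factor(unclass(nuclei)[nz], levels = seq_len(n_nuc)),
                   comp[nz])
      assign_comp <- ifelse(rowSums(tab) > 0,
                            as.integer(colnames(tab))[max.col(tab, "first")],
                            0L)
    }
  }

  nuclei_per_comp <- tabulate(assign_comp[assign_comp > 0], nbins = n_comp)
  nuclei_in_marker <- sum(assign_comp > 0)
  myotube_comps <- which(nuclei_per_comp >= 2)
  myotube_nuclei <- sum(nuclei_per_comp[myotube_comps])
  area <- marker_area(marker)

  if (n_nuc == 0) {
    di <- 0
    flags <- c(flags, "no_nuclei")
  } else {
    di <- nuclei_in_marker / n_nuc
  }
  if (fusion_convention == "nuclei") {
    if (nuclei_in_marker == 0) {
      fi <- 0
      flags <- c(flags, "no_marker_cells")
    } else {
      fi <- myotube_nuclei / nuclei_in_marker
    }
  } else {
    occupied <- sum(nuclei_per_comp > 0)
    if (occupied == 0) {
      fi <- 0
      flags <- c(flags, "no_marker_cells")
    } else {
      fi <- length(myotube_comps) / occupied
    }
  }

  structure(list(
    total_nuclei = n_nuc,
    nuclei_in_marker = as.integer(nuclei_in_marker),
    myotube_nuclei = as.integer(myotube_nuclei),
    marker_positive_cell_count = as.integer(nuclei_in_marker),
    myotube_count = length(myotube_comps),
    myotube_area_px = area$area_px,
    marker_area_px = area$area_px,
    marker_area_fraction = area$area_fraction,
    differentiation_index = di,
    fusion_index = fi,
    flags = flags
  ), class = "myogenesis_indices")
}

#' End-to-end quantification of one micrograph
#'
#' Runs the full script on one image: channel split, per-channel automatic
#' thresholding (Li on nuclei, Triangle on the marker by default), watershed
#' separation of nuclei, the 900-px size filter, and the index computation.
#' The result carries a provenance record (threshold values, removed-object
#' count, parameters used).
#'
#' @param image 3-D array (RGB or multi-plane stack) or list of planes.
#' @param config list as produced by [image_config()].
#' @return `myogenesis_indices` with an additional `provenance` element.
#' @export
quantify_image <- function(image, config = image_config()) {
  config <- utils::modifyList(image_config(), config)
  ch <- split_channels(image, config$channel_map)
  th_n <- threshold(ch$nuclei, config$threshold_methods[["nuclei"]])
  th_m <- threshold(ch$marker, config$threshold_methods[["marker"]])
  labs <- separate_nuclei(th_n$mask, sigma = config$watershed_sigma,
                          min_seed_sep = config$min_seed_sep)
  labs <- filter_large_objects(labs, config$max_area_px)
  res <- compute_indices(labs, th_m$mask,
                         assignment = config$assignment,
                         fusion_convention = config$fusion_convention)
  res$flags <- unique(c(res$flags, th_n$flags, th_m$flags))
  res$provenance <- list(
    threshold_nuclei = th_n$threshold_bin,
    threshold_marker = th_m$threshold_bin,
    threshold_methods = config$threshold_methods,
    n_large_removed = attr(labs, "n_removed"),
    max_area_px = config$max_area_px,
    watershed_sigma = config$watershed_sigma,
    min_seed_sep = config$min_seed_sep,
    assignment = config$assignment,
    fusion_convention = config$fusion_convention
  )
  res
}

#' Default configuration for image quantification
#'
#' @param channel_map named vector mapping roles to plane indices.
#' @param threshold_methods named list: method per channel role.
#' @param max_area_px size-filter cutoff (largest retained nucleus area).
#' @param watershed_sigma,min_seed_sep watershed seed parameters, pixels.
#' @param assignment nucleus-to-component rule.
#' @param fusion_convention cell-counting convention for the fusion index.
#' @return config list for [quantify_image()].
#' @export
image_config <- function(channel_map = c(nuclei = 3L, marker = 2L),
                         threshold_methods = list(nuclei = "li",
                                                  marker = "triangle"),
                         max_area_px = 900,
                         watershed_sigma = 1,
                         min_seed_sep = 5,
                         assignment = "centroid",
                         fusion_convention = "nuclei") {
  list(channel_map = channel_map, threshold_methods = threshold_methods,
       max_area_px = max_area_px, watershed_sigma = watershed_sigma,
       min_seed_sep = min_seed_sep, assignment = assignment,
       fusion_convention = fusion_convention)
}

#' @export
print.myogenesis_indices <- function(x, ...) {
  cat("Myogenesis indices:\n")
  cat(sprintf("  nuclei: %d total, %d in marker, %d in myotubes\n",
              x$total_nuclei, x$nuclei_in_marker, x$myotube_nuclei))
  cat(sprintf("  myotubes: %d (marker area %d px, %.1f%% of image)\n",
              x$myotube_count, x$marker_area_px,
              100 * x$marker_area_fraction))
  cat(sprintf("  differentiation index: %.3f   fusion index: %.3f\n",
              x$differentiation_index, x$fusion_index))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("pixel grids differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

# 1-based matrix indices of rounded (0-based) centroids
centroid_pixels <- function(st, dims) {
  r <- pmin(pmax(floor(st$centroid_row + 0.5) + 1, 1), dims[1])
  c <- pmin(pmax(floor(st$centroid_col + 0.5) + 1, 1), dims[2])
  cbind(r, c)
}
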