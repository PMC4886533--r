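#' Raster containers for fluorescence image quantification
#'
#' A `channel_image` is a single fluorescence plane (matrix of non-negative
#' intensities) tagged with its biological role; a `binary_mask` is a logical
#' matrix of foreground pixels; a `label_map` is an integer matrix whose
#' nonzero values are contiguous object labels 1..N. All three share the same
#' pixel grid; coordinates are 0-based (row, col) and areas are in pixels.
#'
#' @param pixels numeric matrix of intensities (all >= 0).
#' @param channel_role `"nuclei"` or `"marker"`.
#' @param bit_depth nominal bit depth of the source data (8 or 16).
#' @return A `channel_image` object (a matrix with attributes).
#' @export
channel_image <- function(pixels, channel_role = c("nuclei", "marker"),
                          bit_depth = 8L) {
  channel_role <- match.arg(channel_role)
  stopifnot(is.matrix(pixels), nrow(pixels) > 0, ncol(pixels) > 0)
  if (any(pixels < 0)) stop("channel_image: intensities must be non-negative")
  structure(pixels, class = c("channel_image", "matrix"),
            channel_role = channel_role, bit_depth = as.integer(bit_depth))
}

#' @rdname channel_image
#' @export
binary_mask <- function(pixels) {
  stopifnot(is.matrix(pixels), is.logical(pixels))
  structure(pixels, class = c("binary_mask", "matrix"))
}

#' @rdname channel_image
#' @param source_dim optional c(nrow, ncol) to validate against.
#' @export
label_map <- function(pixels, source_dim = NULL) {
  stopifnot(is.matrix(pixels))
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0)) stop("label_map: labels must be non-negative")
  n <- max(pixels, 0L)
  if (n > 0 && !all(seq_len(n) %in% pixels))
    stop("label_map: labels must be contiguous 1..N")
  if (!is.null(source_dim) && !identical(dim(pixels), as.integer(source_dim)))
    stop("label_map: dimension mismatch with source")
  structure(pixels, class = c("label_map", "matrix"), n_objects = as.integer(n))
}

#' Split a multi-channel raster into role-tagged channel images
#'
#' Mirrors the first step of the quantification script: an RGB micrograph (or
#' a 2-plane stack) is split into the nuclei plane (DAPI, conventionally blue)
#' and the marker plane (MyHC, laminin, elastase or Ly6G; conventionally
#' green). Each output is the unmodified plane of the input.
#'
#' @param image a 3-D array `[height, width, channels]` or a plain matrix
#'   (single plane).
#' @param mapping named integer vector giving, for each role, the plane index;
#'   default `c(nuclei = 3, marker = 2)` (blue = nuclei, green = marker).
#' @param bit_depth bit depth metadata propagated to the outputs; guessed from
#'   the data range when `NULL`.
#' @return list with elements `nuclei` and `marker`, both `channel_image`.
#' @export
split_channels <- function(image, mapping = c(nuclei = 3L, marker = 2L),
                           bit_depth = NULL) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  stopifnot(length(dim(image)) == 3)
  if (is.null(names(mapping)) ||
      !all(c("nuclei", "marker") %in% names(mapping)))
    stop("split_channels: mapping must name channels 'nuclei' and 'marker'")
  nch <- dim(image)[3]
  bad <- mapping[mapping > nch | mapping < 1]
  if (length(bad) > 0)
    stop("split_channels: requested channel ", paste(bad, collapse = ", "),
         " but image has ", nch, " plane(s)")
  if (is.null(bit_depth)) bit_depth <- if (max(image) > 255) 16L else 8L
  list(
    nuclei = channel_image(image[, , mapping[["nuclei"]]], "nuclei", bit_depth),
    marker = channel_image(image[, , mapping[["marker"]]], "marker", bit_depth)
  )
}

#' Per-object areas and centroids of a label map
#'
#' @param labels a `label_map` (or integer matrix of labels).
#' @return data.frame with columns `label`, `area_px`, `centroid_row`,
#'   `centroid_col` (centroids 0-based).
#' @export
label_stats <- function(labels) {
  n <- max(labels, 0L)
  if (n == 0)
    return(data.frame(label = integer(0), area_px = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  idx <- which(labels > 0, arr.ind = TRUE)
  l <- labels[labels > 0]
  area <- tabulate(l, nbins = n)
  cr <- rowsum(idx[, 1] - 1, l)[, 1] / area
  cc <- rowsum(idx[, 2] - 1, l)[, 1] / area
  data.frame(label = seq_len(n), area_px = area,
             centroid_row = as.numeric(cr), centroid_col = as.numeric(cc))
}

#' Number of labelled objects
#' @param labels a `label_map`.
#' @return integer count of distinct nonzero labels.
#' @export
count_objects <- function(labels) {
  as.integer(max(labels, 0L))
}
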