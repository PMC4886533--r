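#' Plain-text image I/O (PGM/PPM)
#'
#' Writes and reads images as plain-text netpbm files: a single plane as
#' PGM (`P2`), a 3-plane RGB array as PPM (`P3`). Plain-text netpbm is the
#' portable no-dependency raster format used here for on-disk round-trips
#' of simulated micrographs (16-bit maxval supported by PGM).
#'
#' @param image numeric matrix (grey) or h x w x 3 array (RGB) of
#'   non-negative integers.
#' @param path output file.
#' @param maxval maximum intensity value declared in the header; guessed
#'   from the data when `NULL` (255 or 65535).
#' @return `path`, invisibly.
#' @export
write_image_pnm <- function(image, path, maxval = NULL) {
  if (is.null(maxval)) maxval <- if (max(image) > 255) 65535L else 255L
  con <- file(path, "w")
  on.exit(close(con))
  if (is.matrix(image)) {
    writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
               con)
    write(t(image), con, ncolumns = ncol(image))
  } else {
    stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
    writeLines(c("P3", paste(dim(image)[2], dim(image)[1]),
                 as.character(maxval)), con)
    # interleave R,G,B per pixel, row-major
    px <- aperm(image, c(3, 2, 1))
    write(px, con, ncolumns = 3 * dim(image)[2])
  }
  invisible(path)
}

#' @rdname write_image_pnm
#' @export
read_image_pnm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE,
               comment.char = "#")
  magic <- toks[1]
  w <- as.integer(toks[2])
  h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (magic == "P2") {
    matrix(vals, h, w, byrow = TRUE)
  } else if (magic == "P3") {
    px <- array(vals, c(3, w, h))
    aperm(px, c(3, 2, 1))
  } else stop("read_image_pnm: unsupported magic '", magic, "'")
}
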