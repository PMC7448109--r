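#' Read a plain-text PGM (P2) or PPM (P3) image
#'
#' Reads an ASCII portable graymap/pixmap. A PGM becomes a numeric matrix
#' (rows = image rows, values in \[0, maxval\]); a PPM becomes an
#' h-by-w-by-3 numeric array with channels R, G, B.
#'
#' @param path Path to a `.pgm` or `.ppm` file.
#' @return Numeric matrix (grayscale) or 3-d array (RGB).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)               # strip comments
  toks <- unlist(strsplit(paste(raw, collapse = " "), "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  magic <- toks[1]
  if (!magic %in% c("P2", "P3")) stop("unsupported image format: ", magic)
  vals <- suppressWarnings(as.numeric(toks[-1]))
  if (anyNA(vals)) stop("malformed image file: non-numeric token")
  w <- vals[1]; h <- vals[2]; maxval <- vals[3]
  px <- vals[-(1:3)]
  if (magic == "P2") {
    if (length(px) != w * h) stop("malformed PGM: expected ", w * h, " pixels")
    matrix(px, nrow = h, ncol = w, byrow = TRUE)
  } else {
    if (length(px) != 3 * w * h) stop("malformed PPM: expected ", 3 * w * h, " values")
    arr <- array(0, dim = c(h, w, 3))
    m <- matrix(px, ncol = 3, byrow = TRUE)   # one row per pixel, row-major
    for (ch in 1:3) arr[, , ch] <- matrix(m[, ch], nrow = h, ncol = w, byrow = TRUE)
    arr
  }
}

#' Write a grayscale matrix or RGB array as plain-text PGM/PPM
#'
#' Grayscale matrices are written as PGM (P2); h-by-w-by-3 arrays as PPM
#' (P3). Values are rounded and clipped to \[0, 255\].
#'
#' @param img Numeric matrix or h-by-w-by-3 array.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  clip8 <- function(x) pmin(pmax(round(x), 0), 255)   # keeps dim attributes
  if (is.matrix(img)) {
    body <- apply(clip8(img), 1, paste, collapse = " ")
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255", body), path)
  } else if (is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3) {
    h <- dim(img)[1]; w <- dim(img)[2]
    m <- cbind(as.vector(t(img[, , 1])), as.vector(t(img[, , 2])),
               as.vector(t(img[, , 3])))
    flat <- as.vector(t(clip8(m)))           # R G B per pixel, row-major
    rows <- matrix(flat, nrow = h, byrow = TRUE)
    body <- apply(rows, 1, paste, collapse = " ")
    writeLines(c("P3", paste(w, h), "255", body), path)
  } else stop("img must be a matrix or an h-by-w-by-3 array")
  invisible(path)
}

#' Promote a grayscale matrix to an RGB array
#'
#' @param g Numeric matrix.
#' @return h-by-w-by-3 array with all channels equal to `g`.
#' @export
gray_to_rgb <- function(g) {
  stopifnot(is.matrix(g))
  array(rep(g, 3L), dim = c(nrow(g), ncol(g), 3L))
}
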