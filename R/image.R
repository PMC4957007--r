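#' Read a micrograph as a grayscale intensity matrix
#'
#' Reads a TIFF or PNG raster and returns a plain numeric matrix in row/column
#' (y, x) orientation with intensities on `[0, 1]`. RGB images are collapsed to
#' luminance with the standard weights 0.299, 0.587, 0.114.
#'
#' @param path Path to a TIFF or PNG image.
#' @return A numeric matrix (rows = image height, columns = width), values in
#'   `[0, 1]`.
#' @examples
#' \dontrun{
#' img <- read_micrograph("fov_01.tif")
#' }
#' @export
read_micrograph <- function(path) {
  if (!file.exists(path)) {
    stop("image file not found: ", path, call. = FALSE)
  }
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) {
    nc <- dim(dat)[3L]
    if (nc >= 3L) {
      dat <- 0.299 * dat[, , 1L] + 0.587 * dat[, , 2L] + 0.114 * dat[, , 3L]
    } else {
      dat <- dat[, , 1L]
    }
  }
  # EBImage stores (x, y); package convention is (row, col) = (y, x)
  m <- t(dat)
  rng <- range(m, finite = TRUE)
  if (rng[2L] > 1 || rng[1L] < 0) {
    m <- (m - rng[1L]) / max(rng[2L] - rng[1L], .Machine$double.eps)
  }
  validate_gray(m)
  m
}

#' Write a grayscale matrix to a raster file
#'
#' Values are clamped to `[0, 1]` and written as 16-bit TIFF or PNG depending
#' on the file extension.
#'
#' @param img Numeric matrix in (row, col) orientation.
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  m <- pmin(pmax(img, 0), 1)
  type <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png" else "tiff"
  EBImage::writeImage(EBImage::Image(t(m)), path, type = type,
                      bits.per.sample = 16L)
  invisible(path)
}

# shared input validation: finite numeric matrix
validate_gray <- function(img, min_dim = 1L) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(img))) {
    stop("image contains non-finite pixel values", call. = FALSE)
  }
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    stop("image must be at least ", min_dim, "x", min_dim, call. = FALSE)
  }
  invisible(img)
}

# matrix <-> EBImage helpers (EBImage uses x,y order)
as_ebimage <- function(m) EBImage::Image(t(m))
from_ebimage <- function(img) t(EBImage::imageData(img))
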