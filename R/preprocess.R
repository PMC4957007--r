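#' Sobel derivative kernels
#'
#' The two 3x3 Sobel kernels: `"v"` enhances vertical contrast (responds to
#' horizontal intensity steps), `"h"` enhances horizontal contrast. Every row
#' of the vertical kernel and every column of the horizontal kernel sums to
#' zero, so constant regions map to zero response.
#'
#' @param which `"v"` or `"h"`.
#' @return A 3x3 numeric matrix.
#' @examples
#' sobel_kernel("v")
#' @export
sobel_kernel <- function(which = c("v", "h")) {
  which <- match.arg(which)
  if (which == "v") {
    matrix(c(-1, 0, 1,
             -2, 0, 2,
             -1, 0, 1), nrow = 3, byrow = TRUE)
  } else {
    matrix(c( 1,  2,  1,
              0,  0,  0,
             -1, -2, -1), nrow = 3, byrow = TRUE)
  }
}

#' Discrete 2D convolution with zero padding
#'
#' True convolution (the kernel is index-reversed relative to correlation)
#' of an intensity matrix with an odd-sized kernel, with values outside the
#' image treated as zero and output the same size as the input. For the Sobel
#' pair the choice of convolution versus correlation only flips the sign of
#' the directional responses and leaves the recombined gradient magnitude
#' unchanged.
#'
#' @param img Numeric matrix with finite values.
#' @param kernel Numeric matrix with odd height and width, no larger than
#'   `img` in either dimension.
#' @return Matrix of the same dimensions as `img`.
#' @examples
#' img <- matrix(7, 5, 5)
#' convolve2d(img, sobel_kernel("v"))[2:4, 2:4]  # all zero
#' @export
convolve2d <- function(img, kernel) {
  validate_gray(img)
  if (!is.matrix(kernel) || !is.numeric(kernel) || any(!is.finite(kernel))) {
    stop("kernel must be a finite numeric matrix", call. = FALSE)
  }
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr %% 2L == 0L || kc %% 2L == 0L) {
    stop("kernel dimensions must be odd", call. = FALSE)
  }
  if (kr > nrow(img) || kc > ncol(img)) {
    stop("kernel larger than image", call. = FALSE)
  }
  nr <- nrow(img); nc <- ncol(img)
  rr <- (kr - 1L) %/% 2L
  rc <- (kc - 1L) %/% 2L
  # zero-pad the image, then accumulate shifted copies:
  # h(n) = sum_m g(m) f(n - m), m = offset from kernel center
  pad <- matrix(0, nr + 2L * rr, nc + 2L * rc)
  pad[(rr + 1L):(rr + nr), (rc + 1L):(rc + nc)] <- img
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    di <- i - 1L - rr
    for (j in seq_len(kc)) {
      dj <- j - 1L - rc
      w <- kernel[i, j]
      if (w == 0) next
      out <- out + w * pad[(rr + 1L - di):(rr + nr - di),
                           (rc + 1L - dj):(rc + nc - dj)]
    }
  }
  out
}

#' Sobel gradient magnitude of an image
#'
#' Convolves the image with both Sobel kernels and recombines the directional
#' responses as `H = sqrt(h_v^2 + h_h^2)`, the edge-energy image that drives
#' segmentation. `H` is insensitive to the sign convention of the kernels and
#' suppresses, in a single operation, both the smooth background gradient and
#' the low absolute contrast typical of bright-field micrographs.
#'
#' @param img Numeric matrix, at least 3x3, finite values.
#' @return An object of class `gradient_image`: a list with matrices `h_v`,
#'   `h_h` and `H`, all the same size as `img`.
#' @examples
#' img <- matrix(rep(0:9, each = 10) / 9, 10, 10)
#' g <- sobel_magnitude(img)
#' range(g$H)
#' @export
sobel_magnitude <- function(img) {
  validate_gray(img, min_dim = 3L)
  h_v <- convolve2d(img, sobel_kernel("v"))
  h_h <- convolve2d(img, sobel_kernel("h"))
  structure(
    list(h_v = h_v, h_h = h_h, H = sqrt(h_v^2 + h_h^2)),
    class = "gradient_image"
  )
}

#' @export
print.gradient_image <- function(x, ...) {
  cat("<gradient_image> ", nrow(x$H), "x", ncol(x$H),
      " px, H range [", signif(min(x$H), 4), ", ", signif(max(x$H), 4),
      "]\n", sep = "")
  invisible(x)
}

#' Rescale a gradient magnitude to the unit interval
#'
#' Linear rescale of `H` to `[0, 1]` so that thresholds are portable across
#' images. A constant (e.g. all-zero) input maps to all zeros.
#'
#' @param grad A `gradient_image` or a numeric matrix.
#' @return A numeric matrix with values in `[0, 1]`.
#' @export
normalize_gradient <- function(grad) {
  H <- if (inherits(grad, "gradient_image")) grad$H else grad
  validate_gray(H)
  lo <- min(H); hi <- max(H)
  if (hi - lo <= 0) {
    return(matrix(0, nrow(H), ncol(H)))
  }
  (H - lo) / (hi - lo)
}
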