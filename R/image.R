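#' Grayscale image matrix
#'
#' Wraps a real-valued pixel matrix together with its nominal display range.
#' All solver and metric functions accept either an `image_matrix` or a bare
#' numeric matrix (a bare matrix is assumed to live on the 0--255 scale).
#'
#' @param values Numeric matrix of pixel intensities (rows x columns).
#' @param intensity_range Length-2 numeric, the nominal display range
#'   `(lo, hi)`. Defaults to `c(0, 255)`, the 8-bit convention used by the
#'   PSNR peak constant.
#'
#' @return An object of class `"image_matrix"`: the matrix with an
#'   `intensity_range` attribute.
#' @examples
#' img <- image_matrix(matrix(runif(16, 0, 255), 4, 4))
#' dim(img)
#' @export
image_matrix <- function(values, intensity_range = c(0, 255)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("image contains non-finite values", call. = FALSE)
  }
  if (length(intensity_range) != 2L || !is.numeric(intensity_range) ||
      !all(is.finite(intensity_range)) ||
      intensity_range[2] <= intensity_range[1]) {
    stop("`intensity_range` must be a finite increasing pair (lo, hi)",
         call. = FALSE)
  }
  structure(values,
            intensity_range = as.numeric(intensity_range),
            class = c("image_matrix", "matrix", "array"))
}

#' @export
print.image_matrix <- function(x, ...) {
  r <- attr(x, "intensity_range")
  cat(sprintf("<image_matrix> %d x %d, intensity range [%g, %g]\n",
              nrow(x), ncol(x), r[1], r[2]))
  cat(sprintf("  pixel values in [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

# Coerce anything matrix-like to a plain numeric matrix; returns the matrix
# and the intensity range (defaulting bare matrices to 0-255).
as_pixels <- function(x) {
  if (inherits(x, "image_matrix")) {
    list(values = unclass_matrix(x), range = attr(x, "intensity_range"))
  } else if (is.matrix(x) && is.numeric(x)) {
    if (!all(is.finite(x))) stop("image contains non-finite values", call. = FALSE)
    if (nrow(x) < 1L || ncol(x) < 1L) stop("empty matrix", call. = FALSE)
    list(values = x, range = c(0, 255))
  } else {
    stop("expected an image_matrix or numeric matrix", call. = FALSE)
  }
}

unclass_matrix <- function(x) {
  attr(x, "intensity_range") <- NULL
  class(x) <- NULL
  x
}

#' Clamp pixel values to the declared intensity range
#'
#' Used only at export time; the solver never clips internally, because
#' clipping would bias the Gaussian-noise model and the PSNR computation.
#'
#' @param img An `image_matrix` or numeric matrix.
#' @return An `image_matrix` with values clipped to the range.
#' @export
clamp_image <- function(img) {
  p <- as_pixels(img)
  v <- pmin(pmax(p$values, p$range[1]), p$range[2])
  image_matrix(v, p$range)
}
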