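#' Phantom specification
#'
#' Describes a synthetic test image with known ground-truth decomposition:
#' a low-rank background `H*`, impulsive sparse corruption `S*` and additive
#' Gaussian noise `E*`.  The *clean* image is `H*`; `S*` and `E*` are
#' degradations, matching the robust-PCA reading in which the sparse
#' component carries gross errors/artifacts and the restored image is the
#' low-rank part.
#'
#' @param rows,cols Image dimensions (>= 1).
#' @param rank Target numerical rank of the background (0 allowed).
#' @param sparse_fraction Fraction of impulsive entries, in `[0, 0.5)`.
#' @param sparse_amplitude Magnitude of the impulses (intensity units).
#' @param noise_sigma Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed; the phantom is a pure function of the spec.
#' @param style `"lowrank"` (random low-rank background) or `"prostate"`
#'   (piecewise-constant central gland + peripheral-zone crescent, for
#'   visual demos).
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(rows = 64, cols = 64, rank = 3,
                         sparse_fraction = 0.05, sparse_amplitude = 50,
                         noise_sigma = 0, seed = 1L,
                         style = c("lowrank", "prostate")) {
  style <- match.arg(style)
  stopifnot(rows >= 1, cols >= 1)
  if (rank < 0 || rank > min(rows, cols)) {
    stop("`rank` must lie in [0, min(rows, cols)]", call. = FALSE)
  }
  if (sparse_fraction < 0 || sparse_fraction >= 0.5) {
    stop("`sparse_fraction` must lie in [0, 0.5)", call. = FALSE)
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (!is.finite(sparse_amplitude)) stop("`sparse_amplitude` must be finite", call. = FALSE)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 rank = as.integer(rank),
                 sparse_fraction = sparse_fraction,
                 sparse_amplitude = sparse_amplitude,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 style = style),
            class = "phantom_spec")
}

# Rank-exact random low-rank background on the 0-255 range.  The constant
# component is embedded in the factors (first column/row of ones) so that
# the affine rescale to 0-255 stays inside the column/row space and the
# realized rank equals `rank` exactly.
lowrank_background <- function(rows, cols, rank) {
  if (rank == 0L) return(matrix(0, rows, cols))
  A <- cbind(rep(1, rows),
             if (rank > 1L) matrix(stats::rnorm(rows * (rank - 1L)), rows) else NULL)
  B <- rbind(rep(1, cols),
             if (rank > 1L) matrix(stats::rnorm(cols * (rank - 1L)), ncol = cols) else NULL)
  H <- A %*% B
  lo <- min(H); hi <- max(H)
  if (hi > lo) (H - lo) / (hi - lo) * 255 else matrix(127.5, rows, cols)
}

# Piecewise-constant anatomy-like demo image: dark background, elliptical
# central gland, bright crescent-shaped peripheral zone.
prostate_background <- function(rows, cols) {
  H <- matrix(30, rows, cols)
  cy <- (rows + 1) / 2; cx <- (cols + 1) / 2
  ry <- rows / 3.2; rx <- cols / 2.8
  yy <- matrix(seq_len(rows), rows, cols)
  xx <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  inside <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
  H[inside] <- 120
  # peripheral zone: lower crescent of a slightly larger ellipse
  outer_e <- ((yy - cy) / (ry * 1.35))^2 + ((xx - cx) / (rx * 1.1))^2 <= 1
  H[outer_e & !inside & yy > cy] <- 200
  H
}

#' Generate a seeded phantom with exact ground truth
#'
#' @param spec A [phantom_spec].
#' @return A list with elements:
#' \describe{
#'   \item{clean}{[image_matrix], the noise-free background `H*`.}
#'   \item{degraded}{[image_matrix], `H* + S* + E*`.}
#'   \item{truth}{[decomposition_result] holding the exact triple.}
#'   \item{spec}{the input spec.}
#' }
#' @examples
#' ph <- make_phantom(phantom_spec(rows = 32, cols = 32, rank = 2, seed = 7))
#' Matrix_rank <- sum(svd(ph$clean)$d > 1e-8)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    H <- switch(spec$style,
                lowrank = lowrank_background(spec$rows, spec$cols, spec$rank),
                prostate = prostate_background(spec$rows, spec$cols))
    S <- matrix(0, spec$rows, spec$cols)
    k <- round(spec$sparse_fraction * spec$rows * spec$cols)
    if (k > 0) {
      support <- sample(spec$rows * spec$cols, k)  # without replacement
      S[support] <- spec$sparse_amplitude *
        sample(c(-1, 1), k, replace = TRUE)
    }
    E <- if (spec$noise_sigma > 0) {
      matrix(stats::rnorm(spec$rows * spec$cols, 0, spec$noise_sigma),
             spec$rows, spec$cols)
    } else {
      matrix(0, spec$rows, spec$cols)
    }
  })
  list(clean = image_matrix(H),
       degraded = image_matrix(H + S + E, intensity_range = c(0, 255)),
       truth = decomposition_result(H = H, S = S, E = E,
                                    iterations = 0L, residual = 0,
                                    converged = TRUE),
       spec = spec)
}

#' Add i.i.d. Gaussian noise to an image
#'
#' Values are *not* clipped to the intensity range: clipping would bias the
#' Gaussian model and the PSNR computation.  The same seed always yields
#' the identical noisy image; the caller's RNG state is left untouched.
#'
#' @param image An [image_matrix] or numeric matrix.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return An [image_matrix] with the same intensity range.
#' @export
add_gaussian_noise <- function(image, sigma, seed) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("`sigma` must be >= 0", call. = FALSE)
  }
  p <- as_pixels(image)
  if (sigma == 0) return(image_matrix(p$values, p$range))
  noise <- withr::with_seed(as.integer(seed),
                            matrix(stats::rnorm(length(p$values), 0, sigma),
                                   nrow(p$values), ncol(p$values)))
  image_matrix(p$values + noise, p$range)
}
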