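#' Peak signal-to-noise ratio
#'
#' `10 * log10(255^2 / MSE)` with the peak fixed at 255 (8-bit convention).
#' Identical images (zero MSE) return `Inf`.
#'
#' @param reference,reconstructed Conformable image matrices on the 0--255
#'   scale.
#' @return PSNR in decibels (possibly `Inf`).
#' @examples
#' x <- matrix(0, 2, 2)
#' psnr(x, matrix(c(255, 0, 0, 0), 2, 2))  # 10*log10(4) ~ 6.0206
#' @export
psnr <- function(reference, reconstructed) {
  a <- as_pixels(reference)$values
  b <- as_pixels(reconstructed)$values
  if (!identical(dim(a), dim(b))) stop("shape mismatch", call. = FALSE)
  m <- mean((a - b)^2)
  if (m == 0) return(Inf)
  10 * log10(255^2 / m)
}

# population (1/n) moments used by both SSIM modes
image_moments <- function(a, b) {
  n <- length(a)
  mx <- mean(a); my <- mean(b)
  list(mx = mx, my = my,
       vx = sum((a - mx)^2) / n,
       vy = sum((b - my)^2) / n,
       cxy = sum((a - mx) * (b - my)) / n)
}

#' Structural similarity index (global statistics)
#'
#' Whole-image SSIM with population variances; no sliding window.
#'
#' Mode `"eq5"` is the simplified closed form
#' \deqn{\mathrm{SSIM} = \frac{4\mu_x\mu_y\sigma_{xy}}
#'   {(\mu_x^2+\mu_y^2)(\sigma_x^2+\sigma_y^2)}}
#' which is undefined when both means are zero or both variances are zero;
#' such degenerate inputs raise an error.  Mode `"stabilized"` is the
#' standard three-component product `l * c * s` with
#' `C1 = (0.01*255)^2`, `C2 = (0.03*255)^2`, `C3 = C2/2`, defined for all
#' inputs and agreeing with `"eq5"` when means and variances dominate the
#' stabilising constants.
#'
#' @param x,y Conformable image matrices (at least 2 pixels).
#' @param mode `"eq5"` or `"stabilized"`.
#' @return SSIM value; `"eq5"` mode lies in `[-1, 1]`.
#' @export
ssim <- function(x, y, mode = c("eq5", "stabilized")) {
  mode <- match.arg(mode)
  a <- as_pixels(x)$values
  b <- as_pixels(y)$values
  if (!identical(dim(a), dim(b))) stop("shape mismatch", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 pixels", call. = FALSE)
  mo <- image_moments(a, b)
  if (mode == "eq5") {
    den <- (mo$mx^2 + mo$my^2) * (mo$vx + mo$vy)
    if (den == 0) {
      stop("SSIM (eq5 mode) undefined: zero mean pair or constant images",
           call. = FALSE)
    }
    4 * mo$mx * mo$my * mo$cxy / den
  } else {
    C1 <- (0.01 * 255)^2
    C2 <- (0.03 * 255)^2
    C3 <- C2 / 2
    sx <- sqrt(mo$vx); sy <- sqrt(mo$vy)
    l <- (2 * mo$mx * mo$my + C1) / (mo$mx^2 + mo$my^2 + C1)
    cc <- (2 * sx * sy + C2) / (mo$vx + mo$vy + C2)
    s <- (mo$cxy + C3) / (sx * sy + C3)
    l * cc * s
  }
}

#' Bundle PSNR, SSIM and components into one report
#'
#' @param reference,reconstructed Conformable image matrices (0--255 scale).
#' @param ssim_mode Mode passed to [ssim()].
#' @return A list of class `"quality_report"` with fields `psnr_db`, `ssim`,
#'   `mse`, and the luminance / contrast / structure components of the
#'   stabilised SSIM.
#' @export
quality_report <- function(reference, reconstructed,
                           ssim_mode = c("eq5", "stabilized")) {
  ssim_mode <- match.arg(ssim_mode)
  a <- as_pixels(reference)$values
  b <- as_pixels(reconstructed)$values
  if (!identical(dim(a), dim(b))) stop("shape mismatch", call. = FALSE)
  mo <- image_moments(a, b)
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2; C3 <- C2 / 2
  sx <- sqrt(mo$vx); sy <- sqrt(mo$vy)
  structure(list(
    psnr_db = psnr(a, b),
    ssim = ssim(a, b, mode = ssim_mode),
    mse = mean((a - b)^2),
    luminance = (2 * mo$mx * mo$my + C1) / (mo$mx^2 + mo$my^2 + C1),
    contrast = (2 * sx * sy + C2) / (mo$vx + mo$vy + C2),
    structure = (mo$cxy + C3) / (sx * sy + C3)
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> PSNR %.4g dB | SSIM %.4f | MSE %.4g\n",
              x$psnr_db, x$ssim, x$mse))
  cat(sprintf("  luminance %.4f  contrast %.4f  structure %.4f\n",
              x$luminance, x$contrast, x$structure))
  invisible(x)
}
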