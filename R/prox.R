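#' Weighted singular-value thresholding
#'
#' Proximal operator of the weighted nuclear norm: solves
#' \deqn{\arg\min_X \tfrac12\|X - Y\|_F^2 + \tau \sum_j w_j\,\sigma_j(X)}
#' by soft-thresholding each singular value of `Y` with its own threshold
#' `tau * w_j`.  With non-descending weights (larger singular values get
#' smaller thresholds) the problem separates across singular values and the
#' shrunk spectrum stays non-ascending; `weights` are therefore sorted
#' ascending before pairing with the non-ascending singular values.
#'
#' @param Y Numeric matrix.
#' @param weights Non-negative weights, one per singular value of `Y`
#'   (recycled if scalar).
#' @param tau Positive threshold scale.
#' @return Matrix of the same shape with shrunk singular values.
#' @examples
#' weighted_svt(diag(c(5, 1)), weights = c(1, 1), tau = 2)  # diag(3, 0)
#' @export
weighted_svt <- function(Y, weights, tau) {
  if (!is.matrix(Y) || !is.numeric(Y)) stop("`Y` must be a numeric matrix", call. = FALSE)
  if (nrow(Y) < 1L || ncol(Y) < 1L) stop("empty matrix", call. = FALSE)
  if (!all(is.finite(Y))) stop("`Y` contains non-finite values", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("`tau` must be a positive scalar", call. = FALSE)
  }
  k <- min(dim(Y))
  if (length(weights) == 1L) weights <- rep(weights, k)
  if (length(weights) != k) {
    stop("`weights` must have one entry per singular value", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("`weights` must be finite and non-negative", call. = FALSE)
  }
  sv <- svd_fixed(Y)
  d <- pmax(sv$d - tau * sort(weights), 0)
  sv$u %*% (d * t(sv$v))
}

#' Entrywise weighted soft-thresholding
#'
#' Proximal operator of the weighted L1 norm: each entry is mapped to
#' `sign(y) * max(|y| - tau * w, 0)`.
#'
#' @param Y Numeric matrix.
#' @param weights Non-negative matrix conformable with `Y` (or a scalar).
#' @param tau Positive threshold scale.
#' @return Matrix of the same shape.
#' @examples
#' weighted_soft_threshold(matrix(c(5, -1.5), 1), weights = 1, tau = 2)
#' @export
weighted_soft_threshold <- function(Y, weights, tau) {
  if (!is.matrix(Y) || !is.numeric(Y)) stop("`Y` must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(Y))) stop("`Y` contains non-finite values", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("`tau` must be a positive scalar", call. = FALSE)
  }
  if (length(weights) == 1L) weights <- matrix(weights, nrow(Y), ncol(Y))
  if (!identical(dim(weights), dim(Y))) {
    stop("`weights` must be conformable with `Y`", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("`weights` must be finite and non-negative", call. = FALSE)
  }
  sign(Y) * pmax(abs(Y) - tau * weights, 0)
}

#' Closed-form update of the Gaussian-noise component
#'
#' Minimiser of \eqn{\lambda_2\|E\|_F^2 + (\mu/2)\|E - R\|_F^2}, namely
#' `E = mu / (mu + 2*lambda2) * R`.  `lambda2 = 0` returns `R` unchanged;
#' `lambda2 = Inf` returns the zero matrix (the noise term is switched off).
#'
#' @param R Numeric matrix (current residual the noise term may absorb).
#' @param lambda2 Non-negative Gaussian penalty weight (may be `Inf`).
#' @param mu Positive penalty parameter.
#' @return The updated noise matrix.
#' @export
update_noise_term <- function(R, lambda2, mu) {
  if (!is.matrix(R) || !all(is.finite(R))) {
    stop("`R` must be a finite numeric matrix", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0) {
    stop("`mu` must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(lambda2) || length(lambda2) != 1L || is.na(lambda2) || lambda2 < 0) {
    stop("`lambda2` must be non-negative (possibly Inf)", call. = FALSE)
  }
  if (is.infinite(lambda2)) {
    return(matrix(0, nrow(R), ncol(R)))
  }
  (mu / (mu + 2 * lambda2)) * R
}

#' Reweighting rule for the low-rank and sparse penalties
#'
#' Computes the inverse-magnitude weights used by the weighted decomposition:
#' one weight per singular value of `H`, `w_j = c / (sigma_j(H) + epsilon)`,
#' and one weight per entry of `S`, `w_ij = c / (|S_ij| + epsilon)`.  Larger
#' components receive smaller weights and are therefore shrunk less.
#'
#' @param decomposition A [decomposition_result] (or any list with matrices
#'   `H` and `S`).
#' @param c_weight Positive scale constant.
#' @param epsilon Positive stabiliser guarding the division.
#' @return List with `w_H` (numeric vector) and `w_S` (matrix), all finite
#'   and positive.
#' @examples
#' d <- list(H = diag(c(10, 0)), S = matrix(0, 2, 2))
#' update_weights(d, c_weight = 1, epsilon = 0.1)$w_H  # 1/10.1, 1/0.1
#' @export
update_weights <- function(decomposition, c_weight = 2.5, epsilon = 1e-2) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("`epsilon` must be strictly positive (division hazard)", call. = FALSE)
  }
  if (!is.numeric(c_weight) || length(c_weight) != 1L || c_weight <= 0) {
    stop("`c_weight` must be strictly positive", call. = FALSE)
  }
  H <- decomposition$H
  S <- decomposition$S
  if (!is.matrix(H) || !is.matrix(S)) {
    stop("`decomposition` must carry matrices H and S", call. = FALSE)
  }
  sigma <- svd(H, nu = 0, nv = 0)$d
  list(w_H = c_weight / (sigma + epsilon),
       w_S = c_weight / (abs(S) + epsilon))
}

# SVD with a deterministic sign convention: the largest-magnitude entry of
# each left singular vector is made positive (ties broken by first index).
svd_fixed <- function(Y) {
  sv <- svd(Y)
  if (length(sv$d)) {
    for (j in seq_along(sv$d)) {
      i <- which.max(abs(sv$u[, j]))
      if (sv$u[i, j] < 0) {
        sv$u[, j] <- -sv$u[, j]
        sv$v[, j] <- -sv$v[, j]
      }
    }
  }
  sv
}
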