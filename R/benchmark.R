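#' Registered denoising algorithms
#'
#' The benchmark refers to algorithms by name.  Each entry maps a degraded
#' image plus a [solver_config] to a restored image:
#' * `"rlre"` -- weighted decomposition, restored image = `H`;
#' * `"rl"` -- unweighted robust-PCA baseline, restored image = `H`;
#' * `"identity"` -- returns the input unchanged (pass-through control).
#'
#' @return Named list of functions `(D, config) -> matrix`.
#' @export
benchmark_algorithms <- function() {
  list(
    rlre = function(D, config) solve_rlre(D, config)$H,
    rl = function(D, config) solve_rl(D, config)$H,
    identity = function(D, config) as_pixels(D)$values
  )
}

# Per-cell noise seed: a pure function of (phantom seed, sigma), so adding
# or removing a noise level never shifts the noise stream of other cells.
cell_noise_seed <- function(seed, sigma) {
  as.integer((as.numeric(seed) * 131071 + round(100 * sigma)) %% 2147483629)
}

#' Full-factorial denoising benchmark
#'
#' For every combination of noise level, seed and algorithm: generate a
#' seeded phantom (low-rank background plus impulsive corruption), add
#' Gaussian noise at the given level, run the algorithm, and score the
#' restored image against the clean background with [psnr()] and [ssim()]
#' (stabilised mode, defined for all inputs).  The whole table is a pure
#' function of its arguments.
#'
#' @param noise_levels Numeric vector of noise standard deviations.
#' @param seeds Integer vector of phantom seeds.
#' @param algorithms Character vector of names from [benchmark_algorithms()].
#' @param rows,cols,rank,sparse_fraction,sparse_amplitude Phantom geometry
#'   passed to [phantom_spec()].
#' @param config [solver_config] shared by all solver runs.
#' @return A `data.frame` with columns `algorithm`, `noise_sigma`, `seed`,
#'   `psnr_db`, `ssim`, of class `"benchmark_result"`.
#' @export
run_benchmark <- function(noise_levels = c(5, 10, 15, 20, 25),
                          seeds = 1:10,
                          algorithms = c("rlre", "rl"),
                          rows = 64, cols = 64, rank = 3,
                          sparse_fraction = 0.05, sparse_amplitude = 50,
                          config = solver_config()) {
  if (!length(noise_levels) || !length(seeds) || !length(algorithms)) {
    stop("need at least one noise level, seed and algorithm", call. = FALSE)
  }
  registry <- benchmark_algorithms()
  unknown <- setdiff(algorithms, names(registry))
  if (length(unknown)) {
    stop(sprintf("unknown algorithm(s) %s; registered: %s",
                 paste(unknown, collapse = ", "),
                 paste(names(registry), collapse = ", ")), call. = FALSE)
  }
  rows_out <- list()
  for (s in seeds) {
    ph <- make_phantom(phantom_spec(rows = rows, cols = cols, rank = rank,
                                    sparse_fraction = sparse_fraction,
                                    sparse_amplitude = sparse_amplitude,
                                    noise_sigma = 0, seed = s))
    for (sg in noise_levels) {
      degraded <- add_gaussian_noise(ph$degraded, sigma = sg,
                                     seed = cell_noise_seed(s, sg))
      for (alg in algorithms) {
        restored <- suppressWarnings(registry[[alg]](degraded, config))
        rows_out[[length(rows_out) + 1L]] <- data.frame(
          algorithm = alg, noise_sigma = sg, seed = s,
          psnr_db = psnr(ph$clean, restored),
          ssim = ssim(ph$clean, restored, mode = "stabilized"))
      }
    }
  }
  out <- do.call(rbind, rows_out)
  class(out) <- c("benchmark_result", "data.frame")
  out
}

#' Per-cell summary of a benchmark table
#'
#' @param result A table from [run_benchmark()].
#' @return `data.frame` with mean and sd of PSNR and SSIM per
#'   algorithm x noise level.
#' @export
benchmark_summary <- function(result) {
  stopifnot(is.data.frame(result),
            all(c("algorithm", "noise_sigma", "psnr_db", "ssim") %in%
                  names(result)))
  agg <- function(v) {
    stats::aggregate(v, by = list(algorithm = result$algorithm,
                                  noise_sigma = result$noise_sigma),
                     FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  }
  a <- agg(result$psnr_db); b <- agg(result$ssim)
  out <- data.frame(algorithm = a$algorithm, noise_sigma = a$noise_sigma,
                    psnr_mean = a$x[, "mean"], psnr_sd = a$x[, "sd"],
                    ssim_mean = b$x[, "mean"], ssim_sd = b$x[, "sd"])
  out[order(out$algorithm, out$noise_sigma), ]
}
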