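#' Read a grayscale image file
#'
#' Supported formats: plain-text PGM (`.pgm`, P2, 8- or 16-bit) always, and
#' grayscale PNG (`.png`, 8- or 16-bit) when the optional \pkg{png} package
#' is installed.  RGB inputs are rejected with a message suggesting
#' grayscale conversion.  The bit depth determines the recorded intensity
#' range (0--255 or 0--65535).
#'
#' @param path File path.
#' @return An [image_matrix].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pgm = read_pgm(path),
         png = read_png_gray(path),
         stop("unsupported image format '.", ext,
              "' (supported: .pgm always, .png with the png package)",
              call. = FALSE))
}

#' Write a grayscale image file
#'
#' Values are clamped to the intensity range and rounded to integers at
#' export (the solver itself never clips).
#'
#' @param img An [image_matrix] or numeric matrix.
#' @param path Output path (`.pgm` or `.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  p <- as_pixels(clamp_image(img))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pgm = write_pgm(p$values, path, maxval = round(p$range[2])),
         png = write_png_gray(p$values, path, maxval = round(p$range[2])),
         stop("unsupported image format '.", ext, "'", call. = FALSE))
  invisible(path)
}

# -- plain-text PGM (P2) ----------------------------------------------------
# Deliberately hand-rolled: no pre-installed R package parses PGM, and the
# format is a whitespace-separated token stream with '#' comments.

read_pgm <- function(path) {
  raw_txt <- readLines(path, warn = FALSE)
  raw_txt <- sub("#.*$", "", raw_txt)
  tok <- scan(text = paste(raw_txt, collapse = "\n"), what = character(),
              quiet = TRUE)
  if (length(tok) < 4L || tok[1] != "P2") {
    stop("not a plain (P2) PGM file: ", path, call. = FALSE)
  }
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxv <- as.integer(tok[4])
  px <- as.numeric(tok[-(1:4)])
  if (length(px) != w * h || anyNA(px)) {
    stop("corrupt PGM pixel data in ", path, call. = FALSE)
  }
  # raster order: row-major
  image_matrix(matrix(px, nrow = h, ncol = w, byrow = TRUE),
               intensity_range = c(0, maxv))
}

write_pgm <- function(values, path, maxval = 255) {
  v <- round(values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(v), nrow(v)), as.character(maxval)), con)
  apply_rows <- apply(v, 1, paste, collapse = " ")
  writeLines(apply_rows, con)
  invisible(path)
}

# -- PNG via the optional png package ---------------------------------------

read_png_gray <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading PNG requires the `png` package; install it or use PGM",
         call. = FALSE)
  }
  a <- png::readPNG(path, info = TRUE)
  depth <- attr(a, "info")$bit.depth
  if (is.null(depth)) depth <- 8
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) {
      stop("RGB PNG not supported; convert to grayscale first", call. = FALSE)
    }
    a <- a[, , 1]  # gray + alpha: drop alpha
  }
  maxv <- 2^depth - 1
  image_matrix(round(a * maxv), intensity_range = c(0, maxv))
}

write_png_gray <- function(values, path, maxval = 255) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("writing PNG requires the `png` package; install it or use PGM",
         call. = FALSE)
  }
  bits <- if (maxval > 255) 16L else 8L
  png::writePNG(round(values) / maxval, target = path)
  invisible(path)
}

# -- decomposition export ----------------------------------------------------

# tiny FNV-1a hash so output metadata can carry a config fingerprint
# without a hashing dependency
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Export a decomposition as images plus a JSON sidecar
#'
#' Writes `<prefix>_H.pgm` (restored image, clamped to the intensity
#' range), optionally `<prefix>_S.pgm` and `<prefix>_E.pgm` (shifted by
#' half the range so negative values remain visible), and
#' `<prefix>.json` holding the configuration, iteration count, residual,
#' objective trace and a config fingerprint.
#'
#' @param result A [decomposition_result].
#' @param prefix Output path prefix.
#' @param components Which matrices to write.
#' @param intensity_range Display range used for clamping.
#' @return Character vector of files written, invisibly.
#' @export
export_decomposition <- function(result, prefix,
                                 components = c("H", "S", "E"),
                                 intensity_range = c(0, 255)) {
  stopifnot(inherits(result, "decomposition_result"))
  components <- match.arg(components, several.ok = TRUE)
  files <- character()
  mid <- mean(intensity_range)
  for (comp in components) {
    v <- result[[comp]]
    if (comp != "H") v <- v + mid  # center zero at mid-gray
    f <- paste0(prefix, "_", comp, ".pgm")
    write_image(image_matrix(v, intensity_range), f)
    files <- c(files, f)
  }
  meta <- list(
    package = "rlre",
    version = as.character(utils::packageVersion("rlre")),
    iterations = result$iterations,
    residual = result$residual,
    converged = result$converged,
    noise_sigma_used = result$noise_sigma_used,
    objective_trace = result$objective_trace,
    config = result$config[!vapply(result$config, is.null, logical(1))],
    config_hash = fnv1a(result$config))
  jf <- paste0(prefix, ".json")
  jsonlite::write_json(meta, jf, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, jf))
}
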