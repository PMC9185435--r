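## Full-reference image quality metrics.

#' Metric configuration
#'
#' @param max_val Dynamic range `L` (1.0 for normalized images).
#' @param k1,k2 SSIM stabilization constants (defaults 0.01 and 0.03);
#'   `c1 = (k1 L)^2`, `c2 = (k2 L)^2`.
#' @param window `"gaussian"` for the de-facto standard 11x11 Gaussian
#'   (sigma 1.5) local window, `"global"` for a single whole-image statistic.
#' @param window_size,window_sigma Gaussian window parameters.
#' @return A `metric_config` list.
#' @export
metric_config <- function(max_val = 1.0, k1 = 0.01, k2 = 0.03,
                          window = c("gaussian", "global"),
                          window_size = 11L, window_sigma = 1.5) {
  window <- match.arg(window)
  if (max_val <= 0 || k1 <= 0 || k2 <= 0) {
    stop("`max_val`, `k1`, `k2` must be positive", call. = FALSE)
  }
  structure(list(max_val = max_val, k1 = k1, k2 = k2, window = window,
                 window_size = as.integer(window_size),
                 window_sigma = window_sigma),
            class = "metric_config")
}

#' Peak signal-to-noise ratio
#'
#' `20 log10(MAX / sqrt(MSE))` in decibels after clipping both images to
#' `[0, max_val]`. Identical images give `Inf`.
#'
#' @param ref,test Matrices of identical shape (reference first).
#' @param max_val Dynamic range.
#' @return PSNR in dB (`Inf` if the images agree exactly after clipping).
#' @examples
#' a <- matrix(0.5, 16, 16)
#' psnr(a, a + 0.1)  # exactly 20 dB
#' @export
psnr <- function(ref, test, max_val = 1.0) {
  assert_gray(ref); assert_gray(test)
  check_shapes(ref, test)
  r <- clip_gray(ref, 0, max_val)
  t2 <- clip_gray(test, 0, max_val)
  mse <- mean((r - t2)^2)
  if (mse == 0) return(Inf)
  20 * log10(max_val / sqrt(mse))
}

## Separable valid-mode filtering with a 1-D kernel g (odd length).
filter_valid <- function(img, g) {
  k <- length(g)
  H <- nrow(img); W <- ncol(img)
  # filter columns (vertical), then rows
  outv <- matrix(0, H - k + 1L, W)
  for (t in seq_len(k)) {
    outv <- outv + g[t] * img[t:(H - k + t), , drop = FALSE]
  }
  out <- matrix(0, H - k + 1L, W - k + 1L)
  for (t in seq_len(k)) {
    out <- out + g[t] * outv[, t:(W - k + t), drop = FALSE]
  }
  out
}

#' Structural similarity index
#'
#' Local means, variances and covariance are taken over a Gaussian window
#' (11x11, sigma 1.5 by default) and the SSIM expression
#' `(2 mu_x mu_y + c1)(2 sigma_xy + c2) /
#'  ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))`
#' is averaged over all valid window positions. `window = "global"` computes
#' the expression once from whole-image statistics instead. Both images are
#' clipped to `[0, max_val]` first.
#'
#' @param ref,test Matrices of identical shape.
#' @param config A [metric_config()].
#' @return Scalar in \[-1, 1\]; exactly 1 for identical images.
#' @export
ssim <- function(ref, test, config = metric_config()) {
  assert_gray(ref); assert_gray(test)
  check_shapes(ref, test)
  stopifnot(inherits(config, "metric_config"))
  L <- config$max_val
  x <- clip_gray(ref, 0, L)
  y <- clip_gray(test, 0, L)
  c1 <- (config$k1 * L)^2
  c2 <- (config$k2 * L)^2
  if (config$window == "global") {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + c1) * (2 * cxy + c2)) /
             ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  k <- config$window_size
  if (nrow(x) < k || ncol(x) < k) {
    stop(sprintf("images must be at least %d x %d for the windowed SSIM", k, k),
         call. = FALSE)
  }
  half <- (k - 1) / 2
  g <- exp(-((seq_len(k) - 1 - half)^2) / (2 * config$window_sigma^2))
  g <- g / sum(g)
  mx <- filter_valid(x, g)
  my <- filter_valid(y, g)
  mxx <- filter_valid(x * x, g)
  myy <- filter_valid(y * y, g)
  mxy <- filter_valid(x * y, g)
  vx <- mxx - mx^2
  vy <- myy - my^2
  cxy <- mxy - mx * my
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

#' Per-image and mean PSNR/SSIM over two directories
#'
#' Pairs files by name between a directory of reference (clean) images and a
#' directory of test (denoised) images, computes both metrics per pair and
#' appends an unweighted mean row. Errors if any reference image lacks a
#' counterpart.
#'
#' @param clean_dir,test_dir Directories of PNG/TIFF images with matching
#'   filenames.
#' @param config A [metric_config()].
#' @return Data frame with columns `image`, `psnr`, `ssim`; the last row is
#'   `"mean"`.
#' @export
evaluate_pair_table <- function(clean_dir, test_dir, config = metric_config()) {
  files <- sort(list.files(clean_dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE))
  if (!length(files)) stop("no PNG/TIFF images in `clean_dir`", call. = FALSE)
  missing <- files[!file.exists(file.path(test_dir, files))]
  if (length(missing)) {
    stop("missing counterpart image(s) in `test_dir`: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(files, function(f) {
    ref <- read_gray(file.path(clean_dir, f))
    tst <- read_gray(file.path(test_dir, f))
    data.frame(image = f, psnr = psnr(ref, tst, config$max_val),
               ssim = ssim(ref, tst, config))
  })
  tab <- do.call(rbind, rows)
  rbind(tab, data.frame(image = "mean", psnr = mean(tab$psnr),
                        ssim = mean(tab$ssim)))
}

#' Write a metric report as delimited text
#'
#' Tab-separated table preceded by `#` header lines recording the metric
#' configuration, the package version and any extra provenance fields —
#' but nothing time-dependent, so identical runs produce byte-identical
#' reports.
#'
#' @param tab Data frame from [evaluate_pair_table()].
#' @param path Output file.
#' @param config The [metric_config()] used.
#' @param provenance Named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(tab, path, config = metric_config(),
                                provenance = character()) {
  hdr <- c(
    sprintf("# blindspot metric report (package %s)",
            as.character(utils::packageVersion("blindspot"))),
    sprintf("# max_val=%g k1=%g k2=%g window=%s window_size=%d window_sigma=%g",
            config$max_val, config$k1, config$k2, config$window,
            config$window_size, config$window_sigma))
  if (length(provenance)) {
    hdr <- c(hdr, sprintf("# %s=%s", names(provenance), provenance))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(tab, digits = 10), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
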