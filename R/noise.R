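## Noise simulators. Printed noise levels follow the benchmark convention:
## sigma_g and sigma_s are on the 0-255 intensity scale and are divided by 255
## when applied to [0,1] images; the replacement probability d is a fraction
## in [0,1] (papers print it as a percent).

## One user seed expands into independent named substreams so that switching
## one noise component on or off never shifts another component's draws.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  with_preserved_rng({
    set.seed(substream_seed(seed, name))
    expr
  })
}

#' Noise specification
#'
#' Bundles a noise family with its parameters on the conventional printed
#' scales: `sigma_g` and `sigma_s` on 0–255, `d` as a probability in \[0,1\].
#' The same spec applied to the same clean image reproduces the identical
#' noisy image bit for bit.
#'
#' @param family One of `"awgn"`, `"speckle"`, `"salt_pepper"`, `"fusion"`.
#' @param sigma_g Standard deviation of the additive Gaussian component
#'   (0–255 scale), nonnegative.
#' @param sigma_s Standard deviation of the zero-mean uniform multiplicative
#'   component (0–255 scale), nonnegative.
#' @param d Pixel replacement probability of the impulse component, in
#'   \[0,1\].
#' @param seed Integer seed; expanded internally into independent substreams
#'   for the Gaussian, uniform, mask and value draws.
#' @return A `noise_spec` list.
#' @examples
#' sp <- noise_spec("fusion", sigma_g = 25, sigma_s = 5, d = 0.25, seed = 7)
#' img <- make_synthetic_clean("shapes", 32, 32)
#' noisy <- add_noise(img, sp)
#' @export
noise_spec <- function(family = c("awgn", "speckle", "salt_pepper", "fusion"),
                       sigma_g = 0, sigma_s = 0, d = 0, seed = 1L) {
  family <- match.arg(family)
  if (sigma_g < 0) stop("`sigma_g` must be nonnegative", call. = FALSE)
  if (sigma_s < 0) stop("`sigma_s` must be nonnegative", call. = FALSE)
  if (d < 0 || d > 1) stop("`d` must lie in [0,1]", call. = FALSE)
  structure(list(family = family, sigma_g = sigma_g, sigma_s = sigma_s,
                 d = d, seed = as.integer(seed)),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("<noise_spec> family=%s sigma_g=%g sigma_s=%g d=%g seed=%d\n",
              x$family, x$sigma_g, x$sigma_s, x$d, x$seed))
  invisible(x)
}

#' Additive white Gaussian noise
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' `sigma_g / 255` to every pixel. The output is deliberately not clipped to
#' \[0,1\]: clipping would destroy the zero-mean property that makes the
#' self-supervision loss a valid surrogate for the supervised loss.
#'
#' @param img Numeric matrix in nominal \[0,1\].
#' @param sigma_g Noise standard deviation on the 0–255 scale, nonnegative.
#' @param seed Integer seed (Gaussian substream).
#' @return Noisy matrix of the same shape; `img` is unmodified.
#' @export
add_awgn <- function(img, sigma_g, seed = 1L) {
  assert_gray(img)
  if (sigma_g < 0) stop("`sigma_g` must be nonnegative", call. = FALSE)
  if (sigma_g == 0) return(img)
  n <- with_substream(seed, "gaussian",
                      matrix(stats::rnorm(length(img), 0, sigma_g / 255),
                             nrow(img), ncol(img)))
  img + n
}

#' Multiplicative speckle noise
#'
#' Adds `n * x` where `n` is i.i.d. uniform with mean zero and standard
#' deviation `sigma_s / 255`, i.e. uniform on
#' `[-sqrt(3) * sigma, +sqrt(3) * sigma]`. Vanishes identically on zero
#' signal. Output not clipped.
#'
#' @param img Numeric matrix.
#' @param sigma_s Noise standard deviation on the 0–255 scale, nonnegative.
#' @param seed Integer seed (uniform substream).
#' @return Noisy matrix of the same shape.
#' @export
add_speckle <- function(img, sigma_s, seed = 1L) {
  assert_gray(img)
  if (sigma_s < 0) stop("`sigma_s` must be nonnegative", call. = FALSE)
  if (sigma_s == 0) return(img)
  half <- sqrt(3) * sigma_s / 255
  n <- with_substream(seed, "uniform",
                      matrix(stats::runif(length(img), -half, half),
                             nrow(img), ncol(img)))
  img + n * img
}

#' Salt-and-pepper impulse noise
#'
#' Each pixel is independently replaced with probability `d`; a replaced
#' pixel becomes 0 or 1 with equal probability. Because replacement targets
#' the extremes rather than the local value, this noise is not zero-mean on
#' any image whose mean differs from 0.5: the expected perturbation per pixel
#' is `d * (0.5 - x)`, the mechanism behind the brightness-shifting artifact
#' of plain self-supervised training.
#'
#' @param img Numeric matrix.
#' @param d Replacement probability in \[0,1\].
#' @param seed Integer seed (mask and value substreams).
#' @return Noisy matrix of the same shape.
#' @export
add_salt_pepper <- function(img, d, seed = 1L) {
  assert_gray(img)
  if (d < 0 || d > 1) stop("`d` must lie in [0,1]", call. = FALSE)
  if (d == 0) return(img)
  mask <- with_substream(seed, "mask", stats::runif(length(img)) < d)
  vals <- with_substream(seed, "value",
                         as.numeric(stats::runif(length(img)) < 0.5))
  out <- img
  out[mask] <- vals[mask]
  out
}

#' Fusion noise: Gaussian, then speckle, then impulse replacement
#'
#' Composite corruption for the "unknown statistics" regime:
#' `fspn((x + ng) + ns * (x + ng), d)` — additive Gaussian first, then
#' zero-mean uniform multiplicative noise applied to the already-Gaussian
#' image, then salt-and-pepper replacement. The three components draw from
#' independent substreams of `spec$seed`, so disabling any subset leaves the
#' remaining components' draws unchanged (fusion with two components off is
#' bit-identical to the corresponding single-noise call).
#'
#' @param img Numeric matrix.
#' @param spec A [noise_spec()] with `family = "fusion"`.
#' @return Noisy matrix of the same shape.
#' @export
add_fusion <- function(img, spec) {
  assert_gray(img)
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$family != "fusion") {
    stop("`spec$family` must be \"fusion\"", call. = FALSE)
  }
  x <- add_awgn(img, spec$sigma_g, spec$seed)
  x <- add_speckle(x, spec$sigma_s, spec$seed)
  add_salt_pepper(x, spec$d, spec$seed)
}

#' Apply any noise specification
#'
#' Dispatches on `spec$family` to the matching simulator.
#'
#' @param img Numeric matrix.
#' @param spec A [noise_spec()].
#' @return Noisy matrix of the same shape.
#' @export
add_noise <- function(img, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  switch(spec$family,
    awgn = add_awgn(img, spec$sigma_g, spec$seed),
    speckle = add_speckle(img, spec$sigma_s, spec$seed),
    salt_pepper = add_salt_pepper(img, spec$d, spec$seed),
    fusion = add_fusion(img, spec))
}
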