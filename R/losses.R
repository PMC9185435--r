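## Self-supervision loss family. All losses are means over every pixel of
## the batch; gradients (w.r.t. the prediction) are provided alongside for
## the trainer.

#' Loss specification
#'
#' @param family `"l2"`, `"adss"` or `"clipped"`.
#' @param lambda Focusing parameter of the adaptive loss, >= 0. `lambda = 0`
#'   makes the adaptive loss identical to plain L2.
#' @param alpha Total-variation weight, >= 0 (0 disables TV).
#' @param epsilon Clip threshold for the clipped family, > 0, on squared
#'   normalized-intensity units.
#' @param detach_weights Treat the adaptive per-pixel weights as constants
#'   during differentiation (default TRUE): the weight then purely rescales
#'   the L2 gradient, i.e. suppresses backpropagation from outlier pixels.
#' @return A `loss_spec` list.
#' @export
loss_spec <- function(family = c("adss", "l2", "clipped"), lambda = 10,
                      alpha = 0, epsilon = 0.2, detach_weights = TRUE) {
  family <- match.arg(family)
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be nonnegative", call. = FALSE)
  if (family == "clipped" && epsilon <= 0) {
    stop("`epsilon` must be positive", call. = FALSE)
  }
  structure(list(family = family, lambda = lambda, alpha = alpha,
                 epsilon = epsilon, detach_weights = isTRUE(detach_weights)),
            class = "loss_spec")
}

check_shapes <- function(pred, noisy) {
  if (!identical(dim(pred), dim(noisy))) {
    stop("`pred` and `noisy` must have identical shapes", call. = FALSE)
  }
}

#' Plain self-supervision (L2) loss
#'
#' Mean squared residual between the prediction and the *noisy* input
#' itself. For a J-invariant network under zero-mean noise its expectation
#' equals the supervised loss plus the (constant) noise variance, so
#' minimizing it minimizes the supervised loss.
#'
#' @param pred,noisy Arrays/matrices of identical shape.
#' @return Nonnegative scalar.
#' @export
loss_l2 <- function(pred, noisy) {
  check_shapes(pred, noisy)
  mean((pred - noisy)^2)
}

#' Adaptive per-pixel weights
#'
#' `w = 1 / (1 + lambda * |residual|)`: close to 1 where the prediction
#' agrees with the input, small where the input looks like a gross outlier
#' (an impulse pixel). All weights lie in (0, 1].
#'
#' @param residual Per-pixel residuals `pred - noisy`.
#' @param lambda Focusing parameter >= 0.
#' @return Weights of the same shape as `residual`.
#' @export
adss_weights <- function(residual, lambda) {
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  1 / (1 + lambda * abs(residual))
}

#' Adaptive self-supervision loss
#'
#' Mean of `w_j * (pred_j - noisy_j)^2` with the adaptive weights of
#' [adss_weights()]. With `lambda = 0` this is exactly [loss_l2()]. With
#' `detach_weights` the weights are constants under differentiation, so the
#' gradient at a pixel is the L2 gradient scaled by `w_j` — backpropagation
#' from pixels that look like noise is suppressed rather than redirected.
#'
#' @inheritParams loss_l2
#' @param lambda Focusing parameter >= 0.
#' @param detach_weights See [loss_spec()].
#' @return Nonnegative scalar (<= the L2 loss for any `lambda > 0`).
#' @export
loss_adss <- function(pred, noisy, lambda, detach_weights = TRUE) {
  check_shapes(pred, noisy)
  r <- pred - noisy
  mean(adss_weights(r, lambda) * r^2)
}

#' Anisotropic total variation
#'
#' Sum of absolute forward differences along both image axes (no
#' wraparound). Zero on constant images; positively homogeneous.
#'
#' @param pred Matrix or `(H, W, B, 1)` batch array.
#' @return Nonnegative scalar (sum, not mean, over the batch).
#' @export
loss_tv <- function(pred) {
  a <- as_batch(if (is.matrix(pred)) pred else pred)
  d <- dim(a)
  tv <- 0
  if (d[1] > 1L) tv <- tv + sum(abs(a[-1L, , , , drop = FALSE] -
                                    a[-d[1], , , , drop = FALSE]))
  if (d[2] > 1L) tv <- tv + sum(abs(a[, -1L, , , drop = FALSE] -
                                    a[, -d[2], , , drop = FALSE]))
  tv
}

#' Adaptive self-supervision loss with total-variation regularization
#'
#' `loss_adss(...) + alpha * loss_tv(pred)`. The TV term damps the
#' pixel-wise/structured artifacts the invariant architecture can leave
#' behind; `alpha` is tiny (default of the trainer: 1e-7) so that the TV
#' scale is comparable to the adaptive loss scale.
#'
#' @inheritParams loss_adss
#' @param alpha TV weight >= 0.
#' @return Nonnegative scalar.
#' @export
loss_adss_tv <- function(pred, noisy, lambda, alpha, detach_weights = TRUE) {
  if (alpha < 0) stop("`alpha` must be nonnegative", call. = FALSE)
  loss_adss(pred, noisy, lambda, detach_weights) +
    alpha * loss_tv(pred)
}

#' Clipped self-supervision loss
#'
#' Per-pixel squared residual clamped above at `epsilon` before averaging:
#' the non-adaptive precursor of the adaptive loss. Equals plain L2 whenever
#' every squared residual is below the threshold; monotone non-decreasing in
#' `epsilon`.
#'
#' @inheritParams loss_l2
#' @param epsilon Clip threshold > 0.
#' @return Nonnegative scalar.
#' @export
loss_clipped <- function(pred, noisy, epsilon) {
  check_shapes(pred, noisy)
  if (epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
  mean(pmin((pred - noisy)^2, epsilon))
}

#' Evaluate a loss specification
#'
#' Dispatch on a [loss_spec()], adding the TV term when `alpha > 0`.
#'
#' @inheritParams loss_l2
#' @param spec A [loss_spec()].
#' @return Nonnegative scalar.
#' @export
loss_eval <- function(pred, noisy, spec) {
  stopifnot(inherits(spec, "loss_spec"))
  base <- switch(spec$family,
    l2 = loss_l2(pred, noisy),
    adss = loss_adss(pred, noisy, spec$lambda, spec$detach_weights),
    clipped = loss_clipped(pred, noisy, spec$epsilon))
  if (spec$alpha > 0) base <- base + spec$alpha * loss_tv(pred)
  base
}

## Gradient of the loss w.r.t. pred; same shape as pred.
loss_grad <- function(pred, noisy, spec) {
  check_shapes(pred, noisy)
  r <- pred - noisy
  n <- length(r)
  g <- switch(spec$family,
    l2 = 2 * r / n,
    adss = {
      w <- adss_weights(r, spec$lambda)
      if (spec$detach_weights) {
        2 * r * w / n
      } else {
        # d/dr [w r^2] = 2 r w - lambda |r| r w^2
        (2 * r * w - spec$lambda * abs(r) * r * w^2) / n
      }
    },
    clipped = 2 * r * (r^2 < spec$epsilon) / n)
  if (spec$alpha > 0) {
    a <- as_batch(pred)
    d <- dim(a)
    gtv <- array(0, d)
    if (d[1] > 1L) {
      s <- sign(a[-1L, , , , drop = FALSE] - a[-d[1], , , , drop = FALSE])
      gtv[-1L, , , ] <- gtv[-1L, , , , drop = FALSE] + s
      gtv[-d[1], , , ] <- gtv[-d[1], , , , drop = FALSE] - s
    }
    if (d[2] > 1L) {
      s <- sign(a[, -1L, , , drop = FALSE] - a[, -d[2], , , drop = FALSE])
      gtv[, -1L, , ] <- gtv[, -1L, , , drop = FALSE] + s
      gtv[, -d[2], , ] <- gtv[, -d[2], , , drop = FALSE] - s
    }
    g <- g + spec$alpha * array(gtv, dim(pred))
  }
  g
}

#' Monte-Carlo check of the self-supervision decomposition
#'
#' For a J-invariant network under zero-mean per-pixel noise, the expected
#' self-supervision loss decomposes exactly into the expected supervised
#' loss plus the noise variance:
#' `E||f(x) - x||^2 = E||f(x) - y||^2 + E||x - y||^2`.
#' This function estimates both sides over `replicates` independent noise
#' draws on a fixed clean image and returns the paired estimates with the
#' standard error of their difference, so a caller can assert agreement (or,
#' for non-zero-mean noise such as salt-and-pepper on a non-mid-gray image,
#' demonstrate the violation that motivates the adaptive loss).
#'
#' @param net A `denoiser` (should be J-invariant for the identity to hold).
#' @param clean Clean image matrix `y`.
#' @param spec A [noise_spec()]; each replicate uses `spec$seed + r`.
#' @param replicates Number of independent noise draws.
#' @return List with per-replicate `lhs`/`rhs`, their means, the mean
#'   difference `gap`, its standard error `se`, and `gap_in_se`.
#' @export
check_loss_decomposition <- function(net, clean, spec, replicates = 200L) {
  assert_gray(clean)
  stopifnot(inherits(spec, "noise_spec"), replicates >= 2L)
  lhs <- rhs <- numeric(replicates)
  for (r in seq_len(replicates)) {
    sp <- spec
    sp$seed <- spec$seed + r
    x <- add_noise(clean, sp)
    fx <- net_apply(net, x)
    lhs[r] <- mean((fx - x)^2)
    rhs[r] <- mean((fx - clean)^2) + mean((x - clean)^2)
  }
  diffs <- lhs - rhs
  se <- stats::sd(diffs) / sqrt(replicates)
  list(lhs = lhs, rhs = rhs,
       lhs_mean = mean(lhs), rhs_mean = mean(rhs),
       gap = mean(diffs), se = se,
       gap_in_se = abs(mean(diffs)) / se)
}
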