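## Empirical certification of J-invariance.

#' Verify J-invariance by perturbation and gradient probes
#'
#' For `trials` random pixels (interior, edge and corner pixels are all
#' eligible) the input is perturbed at exactly that pixel by a large delta
#' and the change of the output *at the same pixel* is measured; in
#' addition the analytic derivative of output(j) with respect to input(j)
#' is computed by backpropagation. The returned value is the worst-case
#' magnitude over all probes: ~0 (numerical noise) for a compliant network,
#' strictly positive for a full-kernel baseline or any dilation violating
#' the structural condition.
#'
#' @param net A `denoiser`.
#' @param img `H x W` test image.
#' @param trials Number of probed pixels (>= 1).
#' @param seed Seed for pixel selection.
#' @param delta Perturbation magnitude.
#' @return Scalar: the largest observed |output change| or |derivative| at a
#'   perturbed pixel, with the per-probe values in attribute `"probes"`.
#' @examples
#' net <- build_network(net_spec(channels = 4, paths = list(c(2, 1))), seed = 1)
#' verify_j_invariance(net, make_synthetic_clean("texture", 32, 32), trials = 3)
#' @export
verify_j_invariance <- function(net, img, trials = 10L, seed = 1L,
                                delta = 1) {
  assert_gray(img)
  stopifnot(trials >= 1L)
  H <- nrow(img); W <- ncol(img)
  pix <- with_preserved_rng({
    set.seed(as.integer(seed))
    # force one corner and one edge probe into the set when room allows
    ij <- cbind(sample.int(H, trials, replace = TRUE),
                sample.int(W, trials, replace = TRUE))
    if (trials >= 2L) ij[1L, ] <- c(1L, 1L)
    if (trials >= 3L) ij[2L, ] <- c(1L, max(1L, W %/% 2L))
    ij
  })
  y0 <- net_apply(net, img)
  probes <- numeric(0)
  for (t in seq_len(trials)) {
    i <- pix[t, 1L]; j <- pix[t, 2L]
    x2 <- img
    x2[i, j] <- x2[i, j] + delta
    y2 <- net_apply(net, x2)
    change <- abs(y2[i, j] - y0[i, j])
    g <- net_pixel_gradient(net, img, i, j)
    probes <- c(probes, change, abs(g[i, j]))
  }
  structure(max(probes), probes = probes)
}

#' Empirical dependency map by single-pixel perturbation
#'
#' Brute-force oracle for [receptive_field()]: on a random probe image, each
#' input pixel within `extent` of the center is perturbed one at a time and
#' the change of the *center* output pixel is recorded. Offsets whose
#' perturbation moves the output belong to the empirical receptive field.
#' Perturbed inputs are batched through a single forward pass per chunk, so
#' the cost is a handful of forward evaluations. The leaky nonlinearity has
#' nonzero slope everywhere, so with random weights a structurally reachable
#' offset registers almost surely; two probe images are used regardless.
#'
#' @param net A `denoiser`.
#' @param extent Radius of the probed square; must cover the analytic
#'   receptive field.
#' @param seed Seed for the probe images.
#' @param delta Perturbation magnitude.
#' @param tol Threshold below which an output change counts as zero.
#' @return An offset set (integer matrix, columns `dy`, `dx`).
#' @export
dependency_map_bruteforce <- function(net, extent, seed = 1L, delta = 0.5,
                                      tol = 1e-9) {
  stopifnot(extent >= 1L)
  side <- 2L * extent + 1L
  ctr <- extent + 1L
  hits <- matrix(FALSE, side, side)
  probes <- with_preserved_rng({
    set.seed(as.integer(seed))
    list(matrix(stats::runif(side * side), side, side),
         matrix(stats::runif(side * side), side, side))
  })
  cand <- which(matrix(TRUE, side, side), arr.ind = TRUE)
  for (base in probes) {
    y0 <- net_apply(net, base)[ctr, ctr]
    chunk <- 256L
    for (start in seq(1L, nrow(cand), by = chunk)) {
      idx <- start:min(start + chunk - 1L, nrow(cand))
      batch <- array(base, c(side, side, length(idx), 1L))
      for (b in seq_along(idx)) {
        batch[cand[idx[b], 1L], cand[idx[b], 2L], b, 1L] <-
          batch[cand[idx[b], 1L], cand[idx[b], 2L], b, 1L] + delta
      }
      yb <- net_forward(net, batch)
      ch <- abs(yb[ctr, ctr, , 1L] - y0) > tol
      hits[cand[idx[ch], , drop = FALSE]] <- TRUE
    }
  }
  grid_to_offsets(hits, extent)
}

#' Analytic receptive-field radius of a specification
#'
#' `floor(K/2) + max over paths of dilation * depth`: the extent needed by
#' [dependency_map_bruteforce()] to cover the whole field.
#'
#' @param spec A [net_spec()].
#' @return Integer radius.
#' @export
receptive_field_radius <- function(spec) {
  stopifnot(inherits(spec, "net_spec"))
  spec$donut_K %/% 2L +
    max(vapply(spec$paths, function(p) p[["dilation"]] * p[["depth"]], 0L))
}
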