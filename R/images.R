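#' @keywords internal
"_PACKAGE"

## Images are plain numeric H x W matrices with intensities nominally in [0,1].
## Noisy images may exceed [0,1]; clipping happens only at metric/export time.

#' Validate a grayscale image
#'
#' Checks that `img` is a numeric matrix with at least one row and column and
#' no missing values. Used at the entry of every operation that consumes an
#' image.
#'
#' @param img Object to check.
#' @param arg Name used in error messages.
#' @return The matrix, invisibly.
#' @keywords internal
assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix (H x W grayscale image)", arg),
         call. = FALSE)
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop(sprintf("`%s` must have at least one row and one column", arg), call. = FALSE)
  }
  if (anyNA(img)) stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  invisible(img)
}

#' Clip intensities to a range
#'
#' @param img Numeric matrix.
#' @param lo,hi Range bounds.
#' @return Matrix with values clamped to `[lo, hi]`.
#' @export
clip_gray <- function(img, lo = 0, hi = 1) {
  pmin(pmax(img, lo), hi)
}

#' Generate a synthetic clean test image
#'
#' Procedural grayscale images covering the structures a denoiser must cope
#' with: flat regions, global gradients, piecewise-constant shapes with sharp
#' edges, checkerboards and band-limited smooth texture. All values lie in
#' \[0,1\] and the output is fully determined by `(kind, height, width, seed)`.
#'
#' * `"flat"`: constant mid-gray image (total variation zero).
#' * `"gradient"`: rows sweep 0 to 1 linearly top to bottom.
#' * `"shapes"`: dark background with overlapping constant-intensity
#'   rectangles and disks — piecewise constant with sharp edges, the fixture
#'   for total-variation and brightness-preservation behavior. Its mean sits
#'   well below 0.5 so impulse noise induces a measurable brightness shift.
#' * `"checker"`: 8-pixel checkerboard.
#' * `"texture"`: smooth band-limited noise (low-frequency random cosine
#'   mixture), rescaled to \[0.1, 0.9\].
#'
#' @param kind One of `"flat"`, `"gradient"`, `"shapes"`, `"checker"`,
#'   `"texture"`.
#' @param height,width Image size in pixels, each at least 16.
#' @param seed Integer seed controlling the random kinds.
#' @return Numeric `height x width` matrix in \[0,1\].
#' @examples
#' img <- make_synthetic_clean("shapes", 64, 64, seed = 1)
#' range(img)
#' @export
make_synthetic_clean <- function(kind, height, width, seed = 1L) {
  kind <- match.arg(kind, c("flat", "gradient", "shapes", "checker", "texture"))
  if (height < 16L || width < 16L) {
    stop("`height` and `width` must be at least 16", call. = FALSE)
  }
  out <- switch(kind,
    flat = matrix(0.5, height, width),
    gradient = matrix(rep(seq(0, 1, length.out = height), width), height, width),
    checker = {
      yy <- (seq_len(height) - 1L) %/% 8L
      xx <- (seq_len(width) - 1L) %/% 8L
      0.15 + 0.7 * outer(yy, xx, function(a, b) (a + b) %% 2L)
    },
    shapes = with_preserved_rng({
      set.seed(seed)
      img <- matrix(0.1, height, width)
      yc <- row(img); xc <- col(img)
      n_shapes <- 6L
      for (k in seq_len(n_shapes)) {
        val <- stats::runif(1, 0.05, 0.9)
        if (stats::runif(1) < 0.5) {
          y0 <- sample.int(height, 1L); x0 <- sample.int(width, 1L)
          h <- sample(seq(4L, max(4L, height %/% 3L)), 1L)
          w <- sample(seq(4L, max(4L, width %/% 3L)), 1L)
          sel <- yc >= y0 & yc < y0 + h & xc >= x0 & xc < x0 + w
        } else {
          cy <- stats::runif(1, 1, height); cx <- stats::runif(1, 1, width)
          r <- stats::runif(1, 3, min(height, width) / 4)
          sel <- (yc - cy)^2 + (xc - cx)^2 <= r^2
        }
        img[sel] <- val
      }
      img
    }),
    texture = with_preserved_rng({
      set.seed(seed)
      img <- matrix(0, height, width)
      yy <- seq_len(height) / height
      xx <- seq_len(width) / width
      for (k in 1:8) {
        fy <- stats::runif(1, 0.5, 4); fx <- stats::runif(1, 0.5, 4)
        ph <- stats::runif(2, 0, 2 * pi)
        amp <- stats::runif(1, 0.2, 1)
        img <- img + amp * outer(cos(2 * pi * fy * yy + ph[1]),
                                 cos(2 * pi * fx * xx + ph[2]))
      }
      rng <- range(img)
      0.1 + 0.8 * (img - rng[1]) / (rng[2] - rng[1])
    })
  )
  assert_gray(out)
  out
}

## Run `expr` without disturbing the caller's RNG stream.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

## ---- dihedral group of the square (8 elements) -----------------------------
## Element k in 0..7: k %% 4 quarter-turns counter-clockwise, then horizontal
## mirror if k >= 4. Inverses are precomputed so TTA can undo each transform.

rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

#' Apply one of the eight dihedral transforms of the square
#'
#' Transform index 0 is the identity, 1–3 are quarter-turn rotations, 4–7 are
#' the mirrored versions. [dihedral_inverse()] gives the index that undoes a
#' transform, so `apply_dihedral(apply_dihedral(m, k), dihedral_inverse(k))`
#' is `m` exactly.
#'
#' @param m Numeric matrix.
#' @param k Transform index in `0:7`.
#' @return Transformed matrix.
#' @export
apply_dihedral <- function(m, k) {
  k <- as.integer(k)
  stopifnot(k >= 0L, k <= 7L)
  if (k >= 4L) m <- m[, ncol(m):1, drop = FALSE]  # horizontal mirror first
  r <- k %% 4L
  for (i in seq_len(r)) m <- rot90_ccw(m)
  m
}

#' @rdname apply_dihedral
#' @param k Transform index in `0:7`.
#' @return For `dihedral_inverse`, the index of the inverse transform.
#' @export
dihedral_inverse <- function(k) {
  k <- as.integer(k)
  stopifnot(k >= 0L, k <= 7L)
  # pure rotations invert to the complementary rotation; every
  # mirror-then-rotate element is an involution
  inv <- c(0L, 3L, 2L, 1L, 4L, 5L, 6L, 7L)
  inv[k + 1L]
}
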