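## Architecture specification for the J-invariant dilated denoiser.
##
## Topology (fully convolutional, single channel in and out):
##   donut front layer (K x K, center weight structurally absent)
##     -> per path: a stack of 3x3 convolutions, all at that path's dilation
##     -> channel concatenation of the paths
##     -> 1x1 merge layer back to `channels` features
##     -> skip addition of the donut-layer features
##     -> `head_depth` pointwise 1x1 layers
##     -> linear 1x1 projection to one channel.
## Everything after the paths is spatially pointwise, so the receptive field
## of the whole network is the union of the path receptive fields; with
## every path dilation d > floor(K/2) the zero offset is excluded and the
## network cannot see the pixel it predicts (J-invariance by construction).

#' Network architecture specification
#'
#' Describes the donut-kernel + dilated-path denoiser completely enough to
#' determine both its parameter shapes and its J-invariance. The invariance
#' condition is strict: every path dilation must satisfy
#' `d > floor(donut_K / 2)` unless `baseline_n2c` (the supervised baseline
#' with a regular full kernel) is requested. `net_spec()` itself accepts
#' non-compliant dilations — they are needed to *demonstrate* the failure
#' mode — and [build_network()] enforces the condition at build time.
#'
#' @param donut_K Odd integer >= 3, side of the first-layer kernel.
#' @param paths List of `c(dilation, depth)` integer pairs, one per parallel
#'   dilated path.
#' @param channels Feature width of every internal layer.
#' @param head_depth Number of pointwise 1x1 layers after the skip addition.
#' @param skip Add the donut-layer features back after the merge layer.
#' @param baseline_n2c Replace the donut kernel with a regular full
#'   `donut_K x donut_K` kernel (supervised baseline; not J-invariant).
#' @return A `net_spec` list.
#' @examples
#' sp <- net_spec(donut_K = 3, paths = list(c(2, 2), c(3, 2)), channels = 16)
#' is_j_invariant_spec(sp)
#' @export
net_spec <- function(donut_K = 3L, paths = list(c(2L, 2L), c(3L, 2L)),
                     channels = 64L, head_depth = 2L, skip = TRUE,
                     baseline_n2c = FALSE) {
  donut_K <- as.integer(donut_K)
  if (donut_K < 3L || donut_K %% 2L == 0L) {
    stop("`donut_K` must be an odd integer >= 3", call. = FALSE)
  }
  if (!length(paths)) stop("at least one dilated path is required", call. = FALSE)
  paths <- lapply(paths, function(p) {
    p <- as.integer(p)
    if (length(p) != 2L || p[1] < 1L || p[2] < 1L) {
      stop("each path must be c(dilation >= 1, depth >= 1)", call. = FALSE)
    }
    c(dilation = p[1], depth = p[2])
  })
  channels <- as.integer(channels)
  head_depth <- as.integer(head_depth)
  if (channels < 1L) stop("`channels` must be positive", call. = FALSE)
  if (head_depth < 0L) stop("`head_depth` must be nonnegative", call. = FALSE)
  structure(list(donut_K = donut_K, paths = paths, channels = channels,
                 head_depth = head_depth, skip = isTRUE(skip),
                 baseline_n2c = isTRUE(baseline_n2c)),
            class = "net_spec")
}

#' @export
print.net_spec <- function(x, ...) {
  pth <- paste(vapply(x$paths, function(p)
    sprintf("(d=%d, depth=%d)", p[1], p[2]), ""), collapse = ", ")
  cat(sprintf("<net_spec> K=%d paths=[%s] channels=%d head=%d skip=%s%s\n",
              x$donut_K, pth, x$channels, x$head_depth, x$skip,
              if (x$baseline_n2c) " [full-kernel supervised baseline]" else ""))
  invisible(x)
}

#' Does a specification satisfy the structural J-invariance condition?
#'
#' TRUE when the first layer is a donut kernel and every path dilation is
#' strictly greater than `floor(donut_K / 2)`, the condition under which the
#' receptive-field recurrence provably never re-introduces the center offset.
#'
#' @param spec A [net_spec()].
#' @return Logical scalar.
#' @export
is_j_invariant_spec <- function(spec) {
  stopifnot(inherits(spec, "net_spec"))
  if (spec$baseline_n2c) return(FALSE)
  r <- spec$donut_K %/% 2L
  all(vapply(spec$paths, function(p) p[["dilation"]] > r, TRUE))
}

#' Donut kernel mask
#'
#' A `K x K` matrix of ones with a single structural zero at the center: the
#' weight pattern of the first layer, which therefore never sees the pixel
#' it predicts.
#'
#' @param K Odd integer >= 3.
#' @return `K x K` 0/1 matrix.
#' @examples
#' donut_mask(3)
#' @export
donut_mask <- function(K) {
  K <- as.integer(K)
  if (K < 3L || K %% 2L == 0L) {
    stop("`K` must be an odd integer >= 3", call. = FALSE)
  }
  m <- matrix(1, K, K)
  c0 <- (K + 1L) %/% 2L
  m[c0, c0] <- 0
  m
}

## ---- offset sets ----------------------------------------------------------

## An offset set is stored as an integer matrix with columns dy, dx, sorted
## lexicographically, with class "offset_set" for printing.

offset_set <- function(mat) {
  mat <- matrix(as.integer(mat), ncol = 2L,
                dimnames = list(NULL, c("dy", "dx")))
  mat <- unique(mat)
  mat <- mat[order(mat[, 1L], mat[, 2L]), , drop = FALSE]
  structure(mat, class = c("offset_set", "matrix", "array"))
}

#' @export
print.offset_set <- function(x, ...) {
  cat(sprintf("<offset_set> %d offsets, radius %d, zero offset %s\n",
              nrow(x), max(abs(x)),
              if (offset_set_contains_zero(x)) "PRESENT" else "absent"))
  invisible(x)
}

#' Does an offset set contain the zero offset?
#'
#' The zero offset present means one output pixel can depend on the input at
#' its own location — the J-invariance violation.
#'
#' @param offsets An offset set as returned by [receptive_field()] or
#'   [dependency_map_bruteforce()].
#' @return Logical scalar.
#' @export
offset_set_contains_zero <- function(offsets) {
  any(offsets[, 1L] == 0L & offsets[, 2L] == 0L)
}

## Logical-grid helpers: an offset grid of radius R is a (2R+1)^2 logical
## matrix with the zero offset at its center.
grid_to_offsets <- function(g, R) {
  idx <- which(g, arr.ind = TRUE)
  offset_set(cbind(idx[, 1L] - R - 1L, idx[, 2L] - R - 1L))
}

## Dilate a logical offset grid by the 3x3 stencil at dilation d
## (the union over shifts {-d, 0, d} in both axes).
dilate_grid <- function(g, d) {
  R <- (nrow(g) - 1L) %/% 2L
  out <- matrix(FALSE, nrow(g), ncol(g))
  for (sy in c(-d, 0L, d)) for (sx in c(-d, 0L, d)) {
    ys <- seq_len(nrow(g)) - sy
    xs <- seq_len(ncol(g)) - sx
    oky <- ys >= 1L & ys <= nrow(g)
    okx <- xs >= 1L & xs <= ncol(g)
    out[which(oky), which(okx)] <-
      out[which(oky), which(okx), drop = FALSE] | g[ys[oky], xs[okx], drop = FALSE]
  }
  out
}

#' Analytic receptive field of the network
#'
#' Enumerates, by the receptive-field recurrence, the set of input offsets on
#' which one output pixel may depend: the recurrence seeds with the donut
#' ring (or the full kernel for the supervised baseline) and each dilated
#' 3x3 layer unions shifts of the previous set by `{-d, 0, d}` along both
#' axes. Pointwise merge/head layers add nothing; the skip connection
#' contributes the donut ring, which is a subset of every path's set. The
#' result is the union over paths (or, with `by_path = TRUE`, a list of
#' per-path sets).
#'
#' @param spec A [net_spec()] (compliance is not required — the function is
#'   the tool used to demonstrate non-compliance).
#' @param by_path Return one offset set per path instead of the union.
#' @return An offset set (integer matrix, columns `dy`, `dx`), or a list of
#'   them when `by_path = TRUE`.
#' @examples
#' rf <- receptive_field(net_spec(paths = list(c(2, 1), c(3, 1)), channels = 4))
#' offset_set_contains_zero(rf)
#' @export
receptive_field <- function(spec, by_path = FALSE) {
  stopifnot(inherits(spec, "net_spec"))
  r0 <- spec$donut_K %/% 2L
  R <- r0 + max(vapply(spec$paths, function(p)
    p[["dilation"]] * p[["depth"]], 0L))
  side <- 2L * R + 1L
  seed <- matrix(FALSE, side, side)
  ctr <- R + 1L
  seed[(ctr - r0):(ctr + r0), (ctr - r0):(ctr + r0)] <- TRUE
  if (!spec$baseline_n2c) seed[ctr, ctr] <- FALSE
  per_path <- lapply(spec$paths, function(p) {
    g <- seed
    for (k in seq_len(p[["depth"]])) g <- dilate_grid(g, p[["dilation"]])
    g
  })
  if (by_path) return(lapply(per_path, grid_to_offsets, R = R))
  g <- Reduce(`|`, per_path)
  if (spec$skip) g <- g | seed  # donut ring; always a subset anyway
  grid_to_offsets(g, R)
}
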