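## Forward/backward engine.
##
## Activations are stored as arrays of dim (H, W, B, C); because R arrays are
## column-major, `matrix(a, ncol = C)` is a free reshape to an (H*W*B) x C
## matrix, so a convolution becomes one BLAS matrix product per stencil
## offset: out += shift(in, offset) %*% W[offset]. Zero padding is implicit
## in the shift (out-of-image samples contribute nothing), which is the one
## padding scheme that provably cannot re-introduce the excluded center
## offset at image borders.

LEAKY_SLOPE <- 0.1

## Shift a (H, W, B, C) array so that out[y, x] = a[y + dy, x + dx], zero
## outside the image.
shift4 <- function(a, dy, dx) {
  d <- dim(a)
  out <- array(0, d)
  ys <- seq_len(d[1]) + dy
  xs <- seq_len(d[2]) + dx
  oky <- ys >= 1L & ys <= d[1]
  okx <- xs >= 1L & xs <= d[2]
  if (any(oky) && any(okx)) {
    out[which(oky), which(okx), , ] <- a[ys[oky], xs[okx], , , drop = FALSE]
  }
  out
}

## Stencil offsets for the three layer flavors.
offsets_donut <- function(K, include_center = FALSE) {
  r <- K %/% 2L
  g <- expand.grid(dy = -r:r, dx = -r:r)
  if (!include_center) g <- g[!(g$dy == 0L & g$dx == 0L), ]
  as.matrix(g)
}
offsets_dilated <- function(d) {
  as.matrix(expand.grid(dy = c(-d, 0L, d), dx = c(-d, 0L, d)))
}
offsets_pointwise <- function() matrix(0L, 1L, 2L, dimnames = list(NULL, c("dy", "dx")))

## A layer is a list: offsets (n x 2), W (Cin x Cout x n), b (Cout), act flag.
make_layer <- function(offsets, cin, cout, act = TRUE) {
  n <- nrow(offsets)
  sd <- sqrt(2 / (cin * n))
  list(offsets = offsets,
       W = array(stats::rnorm(cin * cout * n, 0, sd), c(cin, cout, n)),
       b = numeric(cout),
       act = act)
}

conv_forward <- function(a, layer) {
  d <- dim(a)
  cout <- dim(layer$W)[2]
  outm <- matrix(rep(layer$b, each = d[1] * d[2] * d[3]),
                 ncol = cout)
  off <- layer$offsets
  for (o in seq_len(nrow(off))) {
    if (off[o, 1L] == 0L && off[o, 2L] == 0L) {
      s <- a
    } else {
      s <- shift4(a, off[o, 1L], off[o, 2L])
    }
    Wo <- matrix(layer$W[, , o], dim(layer$W)[1], cout)
    outm <- outm + matrix(s, ncol = d[4]) %*% Wo
  }
  array(outm, c(d[1], d[2], d[3], cout))
}

leaky <- function(z) ifelse(z > 0, z, LEAKY_SLOPE * z)
leaky_grad <- function(z) ifelse(z > 0, 1, LEAKY_SLOPE)

## Backward through one conv layer: returns gradient w.r.t. input and
## accumulates dW, db. `gout` has the layer's output shape (post-activation
## gradient must already be applied by the caller on the pre-activation).
conv_backward <- function(a_in, layer, gout) {
  d <- dim(a_in)
  dout <- dim(gout)
  gm <- matrix(gout, ncol = dout[4])
  dW <- array(0, dim(layer$W))
  din_m <- matrix(0, d[1] * d[2] * d[3], d[4])
  off <- layer$offsets
  for (o in seq_len(nrow(off))) {
    dy <- off[o, 1L]; dx <- off[o, 2L]
    s <- if (dy == 0L && dx == 0L) a_in else shift4(a_in, dy, dx)
    Wo <- matrix(layer$W[, , o], dim(layer$W)[1], dout[4])
    dW[, , o] <- crossprod(matrix(s, ncol = d[4]), gm)
    back <- gm %*% t(Wo)
    if (dy == 0L && dx == 0L) {
      din_m <- din_m + back
    } else {
      din_m <- din_m +
        matrix(shift4(array(back, c(d[1], d[2], d[3], d[4])), -dy, -dx),
               ncol = d[4])
    }
  }
  list(din = array(din_m, d), dW = dW, db = colSums(gm))
}

#' Build a denoiser network from a specification
#'
#' Instantiates the donut-kernel + dilated-path architecture with weights
#' drawn deterministically from `seed` (He-style scaled Gaussians, zero
#' biases). By default the build refuses specifications that violate the
#' structural J-invariance condition (any path dilation
#' `<= floor(donut_K/2)` without `baseline_n2c`); `enforce = FALSE` builds
#' the non-compliant network anyway, which is how the failure mode is
#' demonstrated empirically. The `unmask_center` hook adds the center weight
#' back into the first layer (breaking the donut property) and exists solely
#' so tests can confirm that the verifier catches it.
#'
#' @param spec A [net_spec()].
#' @param seed Integer seed for weight initialization.
#' @param enforce Error on non-J-invariant specs (default TRUE).
#' @param unmask_center Include the center offset in the first layer.
#' @return A `denoiser` object; apply it with [net_apply()].
#' @examples
#' net <- build_network(net_spec(channels = 8, paths = list(c(2, 1), c(3, 1))),
#'                      seed = 1)
#' y <- net_apply(net, make_synthetic_clean("shapes", 32, 32))
#' dim(y)
#' @export
build_network <- function(spec, seed = 1L, enforce = TRUE,
                          unmask_center = FALSE) {
  stopifnot(inherits(spec, "net_spec"))
  if (enforce && !spec$baseline_n2c && !is_j_invariant_spec(spec)) {
    bad <- Filter(function(p) p[["dilation"]] <= spec$donut_K %/% 2L, spec$paths)
    stop(sprintf(paste0(
      "J-invariance violation: path dilation %d does not exceed ",
      "floor(K/2) = %d; the zero offset would enter the receptive field. ",
      "Use a larger dilation, or enforce = FALSE to build deliberately."),
      bad[[1]][["dilation"]], spec$donut_K %/% 2L), call. = FALSE)
  }
  C <- spec$channels
  with_preserved_rng({
    set.seed(as.integer(seed))
    front_off <- offsets_donut(spec$donut_K,
                               include_center = spec$baseline_n2c || unmask_center)
    layers <- list(front = make_layer(front_off, 1L, C, act = TRUE))
    for (p in seq_along(spec$paths)) {
      dpath <- spec$paths[[p]]
      for (k in seq_len(dpath[["depth"]])) {
        layers[[sprintf("path%d_%d", p, k)]] <-
          make_layer(offsets_dilated(dpath[["dilation"]]), C, C, act = TRUE)
      }
    }
    layers[["merge"]] <- make_layer(offsets_pointwise(),
                                    C * length(spec$paths), C, act = TRUE)
    for (k in seq_len(spec$head_depth)) {
      layers[[sprintf("head%d", k)]] <-
        make_layer(offsets_pointwise(), C, C, act = TRUE)
    }
    layers[["out"]] <- make_layer(offsets_pointwise(), C, 1L, act = FALSE)
    structure(list(spec = spec, layers = layers), class = "denoiser")
  })
}

#' @export
print.denoiser <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 0))
  cat(sprintf("<denoiser> %d layers, %d parameters\n", length(x$layers), np))
  print(x$spec)
  invisible(x)
}

## Coerce input to a (H, W, B, 1) batch array.
as_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  stopifnot(length(dim(x)) == 4L)
  x
}

## Full forward pass. With cache = TRUE returns intermediate tensors needed
## by net_backward.
net_forward <- function(net, x, cache = FALSE) {
  spec <- net$spec
  x <- as_batch(x)
  cc <- if (cache) list(input = x) else NULL
  z <- conv_forward(x, net$layers$front)
  a0 <- leaky(z)
  if (cache) { cc$front_pre <- z }
  path_outs <- vector("list", length(spec$paths))
  if (cache) cc$path_pre <- list()
  for (p in seq_along(spec$paths)) {
    a <- a0
    for (k in seq_len(spec$paths[[p]][["depth"]])) {
      nm <- sprintf("path%d_%d", p, k)
      if (cache) cc$path_pre[[nm]] <- list(input = a)
      z <- conv_forward(a, net$layers[[nm]])
      if (cache) cc$path_pre[[nm]]$pre <- z
      a <- leaky(z)
    }
    path_outs[[p]] <- a
  }
  d <- dim(a0)
  cat_a <- array(0, c(d[1], d[2], d[3], d[4] * length(path_outs)))
  for (p in seq_along(path_outs)) {
    cat_a[, , , ((p - 1L) * d[4] + 1L):(p * d[4])] <- path_outs[[p]]
  }
  if (cache) cc$cat_in <- cat_a
  z <- conv_forward(cat_a, net$layers$merge)
  if (cache) cc$merge_pre <- z
  a <- leaky(z)
  if (spec$skip) a <- a + a0
  h_in <- a
  for (k in seq_len(spec$head_depth)) {
    nm <- sprintf("head%d", k)
    if (cache) cc[[paste0(nm, "_in")]] <- h_in
    z <- conv_forward(h_in, net$layers[[nm]])
    if (cache) cc[[paste0(nm, "_pre")]] <- z
    h_in <- leaky(z)
  }
  if (cache) cc$out_in <- h_in
  y <- conv_forward(h_in, net$layers$out)
  if (cache) list(y = y, cache = cc, a0 = a0) else y
}

#' Apply a denoiser to an image or batch
#'
#' Runs the forward pass. A plain `H x W` matrix in gives a matrix of the
#' same size out; a 4-d `(H, W, B, 1)` batch array gives a batch array.
#' The output is not clipped — values may stray outside \[0,1\]; clip at
#' export/metric time with [clip_gray()].
#'
#' @param net A `denoiser` from [build_network()].
#' @param x Matrix or `(H, W, B, 1)` array.
#' @return Denoised output with the shape of the input.
#' @export
net_apply <- function(net, x) {
  was_matrix <- is.matrix(x)
  y <- net_forward(net, x, cache = FALSE)
  if (was_matrix) matrix(y[, , 1L, 1L], dim(y)[1], dim(y)[2]) else y
}

## Backward pass: given dL/dy (same shape as output), returns per-layer
## gradients (same structure as net$layers W/b) and optionally dL/dinput.
net_backward <- function(net, fw, gy, want_input_grad = FALSE) {
  spec <- net$spec
  cc <- fw$cache
  grads <- list()
  # out layer (linear)
  bk <- conv_backward(cc$out_in, net$layers$out, gy)
  grads$out <- bk[c("dW", "db")]
  g <- bk$din
  for (k in rev(seq_len(spec$head_depth))) {
    nm <- sprintf("head%d", k)
    g <- g * leaky_grad(cc[[paste0(nm, "_pre")]])
    bk <- conv_backward(cc[[paste0(nm, "_in")]], net$layers[[nm]], g)
    grads[[nm]] <- bk[c("dW", "db")]
    g <- bk$din
  }
  # skip: gradient flows unchanged both into merge branch and into a0
  g_a0_extra <- if (spec$skip) g else NULL
  g <- g * leaky_grad(cc$merge_pre)
  bk <- conv_backward(cc$cat_in, net$layers$merge, g)
  grads$merge <- bk[c("dW", "db")]
  g_cat <- bk$din
  d <- dim(fw$a0)
  C <- d[4]
  g_a0 <- if (is.null(g_a0_extra)) array(0, d) else g_a0_extra
  for (p in rev(seq_along(spec$paths))) {
    gp <- g_cat[, , , ((p - 1L) * C + 1L):(p * C), drop = FALSE]
    for (k in rev(seq_len(spec$paths[[p]][["depth"]]))) {
      nm <- sprintf("path%d_%d", p, k)
      gp <- gp * leaky_grad(cc$path_pre[[nm]]$pre)
      bk <- conv_backward(cc$path_pre[[nm]]$input, net$layers[[nm]], gp)
      grads[[nm]] <- bk[c("dW", "db")]
      gp <- bk$din
    }
    g_a0 <- g_a0 + gp
  }
  g_front <- g_a0 * leaky_grad(cc$front_pre)
  bk <- conv_backward(cc$input, net$layers$front, g_front)
  grads$front <- bk[c("dW", "db")]
  list(grads = grads,
       dinput = if (want_input_grad) bk$din else NULL)
}

#' Gradient of one output pixel with respect to the input
#'
#' Backpropagates a one-hot seed at output pixel `(i, j)` through the
#' network and returns the full input-gradient map. For a J-invariant
#' network the entry at `(i, j)` is exactly zero; the map's nonzero support
#' is the network's receptive field at that pixel.
#'
#' @param net A `denoiser`.
#' @param img `H x W` matrix.
#' @param i,j Output pixel (row, column), 1-based.
#' @return `H x W` matrix of partial derivatives.
#' @export
net_pixel_gradient <- function(net, img, i, j) {
  x <- as_batch(assert_gray(img))
  fw <- net_forward(net, x, cache = TRUE)
  gy <- array(0, dim(fw$y))
  gy[i, j, 1L, 1L] <- 1
  bk <- net_backward(net, fw, gy, want_input_grad = TRUE)
  matrix(bk$dinput[, , 1L, 1L], dim(x)[1], dim(x)[2])
}
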