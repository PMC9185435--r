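## Image file I/O. Internally everything is a numeric H x W matrix in [0,1];
## multi-channel inputs are reduced by the unweighted channel average.

#' Read a grayscale image
#'
#' Reads PNG or TIFF (8/16-bit integer or float), scales intensities to
#' \[0,1\], and averages channels of multi-channel inputs (an alpha channel,
#' if present as a 2- or 4-channel image, is dropped rather than averaged).
#'
#' @param path PNG or TIFF file.
#' @return Numeric `H x W` matrix.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format (need PNG or TIFF): ", path, call. = FALSE))
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    keep <- if (nc %in% c(2L, 4L)) seq_len(nc - 1L) else seq_len(nc)
    img <- apply(img[, , keep, drop = FALSE], c(1, 2), mean)
  }
  assert_gray(img)
  img
}

#' Write a grayscale image
#'
#' PNG output is 8-bit (values clipped to \[0,1\] and quantized, worst-case
#' round-trip error 1/510); TIFF output is 32-bit float and round-trips
#' bit-exactly, including values outside \[0,1\].
#'
#' @param img Numeric matrix.
#' @param path Output file; the extension selects the format.
#' @param bitdepth 8 (PNG) or 32 (float TIFF); defaults from the extension.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path, bitdepth = NULL) {
  assert_gray(img)
  ext <- tolower(tools::file_ext(path))
  if (is.null(bitdepth)) bitdepth <- if (ext == "png") 8L else 32L
  if (ext == "png") {
    png::writePNG(clip_gray(img), path)
  } else if (ext %in% c("tif", "tiff")) {
    # 32 bits per sample selects float storage in the tiff package
    tiff::writeTIFF(img, path, bits.per.sample = bitdepth)
  } else {
    stop("unsupported image format (need PNG or TIFF): ", path, call. = FALSE)
  }
  invisible(path)
}

#' Denoise with eight-fold dihedral test-time averaging
#'
#' Applies the network to all 8 dihedral transforms (rotations and mirrored
#' rotations) of the image, inverse-transforms each output geometrically,
#' and returns the pixelwise mean. Averaging J-invariant outputs preserves
#' J-invariance, and for an exactly equivariant network the result equals a
#' single pass. No clipping happens inside the average.
#'
#' @param net A `denoiser`, or any function mapping a matrix to a matrix of
#'   the same shape (useful for checking the transform bookkeeping against
#'   an exactly equivariant reference denoiser).
#' @param img `H x W` matrix.
#' @param tta Set FALSE for a plain single forward pass.
#' @return Denoised `H x W` matrix (unclipped).
#' @export
denoise_tta <- function(net, img, tta = TRUE) {
  assert_gray(img)
  fwd <- if (is.function(net)) net else function(m) net_apply(net, m)
  if (!tta) return(fwd(img))
  acc <- matrix(0, nrow(img), ncol(img))
  for (k in 0:7) {
    yk <- fwd(apply_dihedral(img, k))
    acc <- acc + apply_dihedral(yk, dihedral_inverse(k))
  }
  acc / 8
}
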