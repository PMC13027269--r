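# Bilinear resampling, half-pixel-centred (the align_corners = FALSE
# convention): output pixel i (0-based) samples input coordinate
# (i + 0.5) * n_in / n_out - 0.5, clamped to the valid range. The whole
# resample is separable, so each axis is a small (n_out x n_in) linear
# operator and a 2-D resize is U_y %*% X %*% t(U_x).

.bilin_cache <- new.env(parent = emptyenv())

#' One-dimensional bilinear interpolation operator
#'
#' Returns the dense \code{n_out x n_in} matrix that maps samples on an
#' \code{n_in} grid to samples on an \code{n_out} grid under
#' half-pixel-centred bilinear interpolation with edge clamping.
#'
#' @param n_in,n_out input and output grid sizes (positive integers).
#' @return a numeric matrix with rows summing to 1.
#' @export
bilinear_matrix <- function(n_in, n_out) {
  stopifnot(n_in >= 1, n_out >= 1)
  u <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5          # 0-based input coordinate
    f <- floor(src)
    wgt <- src - f
    i0 <- min(max(f, 0), n_in - 1)
    i1 <- min(max(f + 1, 0), n_in - 1)
    u[i, i0 + 1] <- u[i, i0 + 1] + (1 - wgt)
    u[i, i1 + 1] <- u[i, i1 + 1] + wgt
  }
  u
}

# sparse 2-D pixel operator for row-major (y-major) flattened feature maps
pixel_resize_op <- function(h_in, w_in, h_out, w_out) {
  key <- paste(h_in, w_in, h_out, w_out, sep = "_")
  hit <- .bilin_cache[[key]]
  if (!is.null(hit)) return(hit)
  uy <- Matrix::Matrix(bilinear_matrix(h_in, h_out), sparse = TRUE)
  ux <- Matrix::Matrix(bilinear_matrix(w_in, w_out), sparse = TRUE)
  u <- kronecker(uy, ux)
  # small operators are faster dense (plain BLAS, no S4 dispatch)
  if (length(u) <= 2^18) u <- as.matrix(u)
  .bilin_cache[[key]] <- u
  u
}

# resize an H x W x C array (or H x W matrix) to h0 x w0
resample_array <- function(img, h0, w0) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  uy <- bilinear_matrix(dim(img)[1], h0)
  ux <- bilinear_matrix(dim(img)[2], w0)
  out <- array(0, c(h0, w0, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    out[, , ch] <- uy %*% img[, , ch] %*% t(ux)
  }
  out
}
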