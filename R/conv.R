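# Zero-padded 2-D convolution primitives and their exact adjoints.
#
# Every linear image operator used by the losses (orientation kernels, pyramid
# blur/decimation, SSIM windows) is built from these, so reverse-mode gradients
# through the perceptual extractor are exact transposes rather than
# approximations.

#' 2-D correlation with zero padding, output size equal to input ("same")
#' @keywords internal
conv2same <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  xp <- matrix(0, h + 2L * ph, w + 2L * pw)
  xp[(ph + 1L):(ph + h), (pw + 1L):(pw + w)] <- x
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    if (k[i, j] != 0)
      out <- out + k[i, j] * xp[i:(i + h - 1L), j:(j + w - 1L)]
  }
  out
}

# Adjoint of conv2same(. , k): correlation with the 180-degree rotated kernel.
conv2sameT <- function(g, k) conv2same(g, k[nrow(k):1L, ncol(k):1L, drop = FALSE])

# Replicate (edge) padding and its exact adjoint. Used by the perceptual
# extractor so that constant images produce exactly zero gradient responses at
# every pyramid level (zero padding would fabricate edges at the border).
padRep <- function(x, ph, pw) {
  ri <- c(rep(1L, ph), seq_len(nrow(x)), rep(nrow(x), ph))
  ci <- c(rep(1L, pw), seq_len(ncol(x)), rep(ncol(x), pw))
  x[ri, ci, drop = FALSE]
}

padRepT <- function(gp, h, w, ph, pw) {
  ri <- c(rep(1L, ph), seq_len(h), rep(h, ph))
  ci <- c(rep(1L, pw), seq_len(w), rep(w, pw))
  g1 <- rowsum(gp, ri)
  t(rowsum(t(g1), ci))
}

#' 2-D correlation with replicate padding, output size equal to input
#' @keywords internal
conv2rep <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  xp <- padRep(x, ph, pw)
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    if (k[i, j] != 0)
      out <- out + k[i, j] * xp[i:(i + h - 1L), j:(j + w - 1L)]
  }
  out
}

# Adjoint of conv2rep(., k).
conv2repT <- function(g, k) {
  kh <- nrow(k); kw <- ncol(k)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  h <- nrow(g); w <- ncol(g)
  gxp <- matrix(0, h + 2L * ph, w + 2L * pw)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    if (k[i, j] != 0)
      gxp[i:(i + h - 1L), j:(j + w - 1L)] <-
        gxp[i:(i + h - 1L), j:(j + w - 1L)] + k[i, j] * g
  }
  padRepT(gxp, h, w, ph, pw)
}

#' 2-D correlation, valid region only (no padding)
#' @keywords internal
conv2valid <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  h <- nrow(x) - kh + 1L; w <- ncol(x) - kw + 1L
  if (h < 1L || w < 1L) stop("kernel larger than image in conv2valid")
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    if (k[i, j] != 0)
      out <- out + k[i, j] * x[i:(i + h - 1L), j:(j + w - 1L)]
  }
  out
}

# Separable binomial (Gaussian-like) 5x5 blur used by the image pyramid.
blurKernel5 <- function() {
  v <- c(1, 4, 6, 4, 1) / 16
  outer(v, v)
}

# Decimate by 2: keep rows/cols 1,3,5,... Adjoint inserts zeros back.
down2 <- function(x) x[seq(1L, nrow(x), 2L), seq(1L, ncol(x), 2L), drop = FALSE]

down2T <- function(g, h, w) {
  out <- matrix(0, h, w)
  out[seq(1L, h, 2L), seq(1L, w, 2L)] <- g
  out
}

# Gaussian window for SSIM (truncated, renormalized).
gaussianWindow <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}
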