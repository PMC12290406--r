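# Centred Fourier passband support and the low-pass projection, shared by the
# band-limited phantom generator and the Papoulis-Gerchberg intensity prior.

#' Indicator of the centred Fourier passband
#'
#' Returns an H x W logical matrix over unshifted DFT indices marking the kept
#' coefficients: per dimension the signed frequencies -K..K with K chosen so
#' that the kept fraction of coefficients approximates `fraction`
#' ((2K+1)^2 / (H*W), the largest centred square not exceeding it).
#' `fraction = 1` keeps the full spectrum. The set is symmetric under
#' frequency negation, so projecting a real image keeps it real.
#'
#' @param h,w image dimensions.
#' @param fraction fraction of Fourier coefficients to keep, in (0,1].
#' @return logical h x w matrix.
#' @export
passbandIndicator <- function(h, w, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0,1]")
  if (fraction == 1) return(matrix(TRUE, h, w))
  K <- max(0L, floor((sqrt(fraction * h * w) - 1) / 2))
  Kh <- min(K, (h - 1L) %/% 2L)
  Kw <- min(K, (w - 1L) %/% 2L)
  sr <- ifelse(seq_len(h) - 1L <= h %/% 2L, seq_len(h) - 1L, seq_len(h) - 1L - h)
  sc <- ifelse(seq_len(w) - 1L <= w %/% 2L, seq_len(w) - 1L, seq_len(w) - 1L - w)
  outer(abs(sr) <= Kh, abs(sc) <= Kw, FUN = "&")
}

#' Project an image onto the centred passband (ideal low-pass)
#'
#' Zeroes every Fourier coefficient outside [passbandIndicator()] and returns
#' the real part of the inverse transform. Idempotent.
#'
#' @param x numeric matrix.
#' @param fraction passband fraction in (0,1].
#' @return numeric matrix of the same shape.
#' @export
lowpassProject <- function(x, fraction) {
  stopifnotMatrix(x)
  keep <- passbandIndicator(nrow(x), ncol(x), fraction)
  f <- stats::fft(x)
  f[!keep] <- 0
  Re(stats::fft(f, inverse = TRUE)) / length(x)
}
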