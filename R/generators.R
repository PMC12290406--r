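# Differentiable generator contract G(omega) -> image, plus the two reference
# generators: a seeded affine map (closed-form posterior oracle) and a small
# auto-decoder trained on phantom corpora. Both expose exact vector-Jacobian
# products for the inference modules.

#' Apply a generator to a latent code
#'
#' @param model a [GeneratorModel-class].
#' @param omega L x D latent matrix matching `latentShape(model)`.
#' @param ... method-specific arguments (`raw = TRUE` on the linear generator
#'   returns the pre-clamp affine output).
#' @return H x W image matrix.
#' @export
setGeneric("generatorApply", function(model, omega, ...)
  standardGeneric("generatorApply"))

#' Vector-Jacobian product through a generator
#'
#' Returns `t(J) %*% vec(gImage)` reshaped to the latent shape, where J is the
#' Jacobian of `generatorApply` at `omega`. Used by MAP and variational
#' inference to backpropagate image-space loss gradients to the latent code.
#'
#' @param model a [GeneratorModel-class].
#' @param omega L x D latent matrix.
#' @param gImage H x W gradient of a scalar loss with respect to the image.
#' @return L x D gradient matrix.
#' @export
setGeneric("generatorVJP", function(model, omega, gImage)
  standardGeneric("generatorVJP"))

checkLatent <- function(model, omega) {
  if (!is.matrix(omega) || !all(dim(omega) == model@latentShape))
    stop(sprintf("latent code must be a %d x %d matrix",
                 model@latentShape[1L], model@latentShape[2L]))
  if (any(!is.finite(omega))) stop("latent code contains non-finite values")
  invisible(omega)
}

# ---- linear generator -------------------------------------------------------

#' Create a seeded affine reference generator
#'
#' G(omega) = clip(offset + scale * (A vec(omega) + b)) with A, b drawn from a
#' seeded standard normal scaled by 1/sqrt(L*D). With the default `scale` the
#' clamp is essentially never active for latents of prior scale, so the
#' composition of the forward operator with G is affine and the
#' affine-Gaussian posterior has a closed form — the basis of the oracle
#' checks on MAP and variational inference.
#'
#' @param latentShape integer pair (L, D).
#' @param imageShape integer pair (H, W).
#' @param seed integer seed.
#' @param scale,offset intensity map; defaults 0.12 and 0.5.
#' @return a [LinearGenerator-class].
#' @export
linearGenerator <- function(latentShape = c(2L, 8L), imageShape = c(16L, 16L),
                            seed = 1L, scale = 0.12, offset = 0.5) {
  L <- latentShape[1L]; D <- latentShape[2L]
  H <- imageShape[1L]; W <- imageShape[2L]
  sd0 <- 1 / sqrt(L * D)
  withSeed(seed, {
    A <- matrix(stats::rnorm(H * W * L * D, 0, sd0), H * W, L * D)
    b <- stats::rnorm(H * W, 0, sd0)
  })
  new("LinearGenerator", latentShape = c(L, D), imageShape = c(H, W),
      seed = seed, A = A, b = b, scale = scale, offset = offset)
}

#' @rdname generatorApply
#' @param raw return the pre-clamp affine output (linear generator only).
#' @export
setMethod("generatorApply", "LinearGenerator", function(model, omega,
                                                        raw = FALSE) {
  checkLatent(model, omega)
  u <- model@offset + model@scale *
    (as.vector(model@A %*% as.vector(omega)) + model@b)
  img <- matrix(u, model@imageShape[1L], model@imageShape[2L])
  if (raw) img else clip01(img)
})

#' @rdname generatorVJP
#' @export
setMethod("generatorVJP", "LinearGenerator", function(model, omega, gImage) {
  checkLatent(model, omega)
  pre <- generatorApply(model, omega, raw = TRUE)
  interior <- as.numeric(pre > 0 & pre < 1)
  gv <- model@scale *
    as.vector(crossprod(model@A, as.vector(gImage) * interior))
  matrix(gv, model@latentShape[1L], model@latentShape[2L])
})

# ---- decoder generator ------------------------------------------------------

# cached im2col index tables keyed by "h x w"
.convIdxCache <- new.env(parent = emptyenv())

im2colIdx <- function(h, w) {
  key <- paste(h, w, sep = "x")
  if (!is.null(.convIdxCache[[key]])) return(.convIdxCache[[key]])
  hp <- h + 2L
  r <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  idx <- matrix(0L, h * w, 9L)
  o <- 0L
  for (j in 1:3) for (i in 1:3) {
    o <- o + 1L
    idx[, o] <- (r + i - 1L) + hp * (cc + j - 2L)
  }
  .convIdxCache[[key]] <- idx
  idx
}

# Multi-channel zero-padded 3x3 convolution. x3: h x w x cin array;
# K: 3 x 3 x cin x cout; b: length cout. Returns list(out = h x w x cout,
# P = patch matrix kept for the backward pass).
convMC <- function(x3, K, b) {
  h <- dim(x3)[1L]; w <- dim(x3)[2L]; cin <- dim(x3)[3L]
  cout <- dim(K)[4L]
  idx <- im2colIdx(h, w)
  P <- matrix(0, h * w, 9L * cin)
  for (c in seq_len(cin)) {
    xp <- matrix(0, h + 2L, w + 2L)
    xp[2:(h + 1L), 2:(w + 1L)] <- x3[, , c]
    for (o in 1:9) P[, (c - 1L) * 9L + o] <- xp[idx[, o]]
  }
  Kmat <- matrix(K, 9L * cin, cout)
  out <- P %*% Kmat
  out <- sweep(out, 2L, b, "+")
  list(out = array(out, c(h, w, cout)), P = P)
}

# Backward of convMC: dOut is h x w x cout. Returns gradients and dInput.
convMCBackward <- function(P, K, dOut) {
  h <- dim(dOut)[1L]; w <- dim(dOut)[2L]
  cin <- dim(K)[3L]; cout <- dim(K)[4L]
  dOutMat <- matrix(dOut, h * w, cout)
  Kmat <- matrix(K, 9L * cin, cout)
  dK <- array(crossprod(P, dOutMat), dim(K))
  db <- colSums(dOutMat)
  dP <- dOutMat %*% t(Kmat)
  idx <- im2colIdx(h, w)
  dx3 <- array(0, c(h, w, cin))
  for (c in seq_len(cin)) {
    gxp <- matrix(0, h + 2L, w + 2L)
    for (o in 1:9) gxp[idx[, o]] <- gxp[idx[, o]] + dP[, (c - 1L) * 9L + o]
    dx3[, , c] <- gxp[2:(h + 1L), 2:(w + 1L)]
  }
  list(dK = dK, db = db, dInput = dx3)
}

up2 <- function(x3) {
  h <- dim(x3)[1L]; w <- dim(x3)[2L]
  x3[rep(seq_len(h), each = 2L), rep(seq_len(w), each = 2L), , drop = FALSE]
}

up2T <- function(d3) {
  h2 <- dim(d3)[1L]; w2 <- dim(d3)[2L]
  odd <- seq(1L, h2, 2L); evn <- seq(2L, h2, 2L)
  oddc <- seq(1L, w2, 2L); evnc <- seq(2L, w2, 2L)
  d3[odd, oddc, , drop = FALSE] + d3[odd, evnc, , drop = FALSE] +
    d3[evn, oddc, , drop = FALSE] + d3[evn, evnc, , drop = FALSE]
}

sigmoid <- function(x) 1 / (1 + exp(-x))

decoderForward <- function(params, arch, v) {
  h0 <- arch$h0; w0 <- arch$w0; c0 <- arch$c0
  a1 <- as.vector(v %*% params$W1) + params$b1
  h1 <- array(tanh(a1), c(h0, w0, c0))
  u1 <- up2(h1)
  cv2 <- convMC(u1, params$K2, params$b2)
  h2 <- tanh(cv2$out)
  u2 <- up2(h2)
  cv3 <- convMC(u2, params$K3, params$b3)
  out <- sigmoid(cv3$out[, , 1L])
  list(out = out, h1 = h1, P2 = cv2$P, h2 = h2, P3 = cv3$P, a3 = cv3$out)
}

decoderBackward <- function(params, arch, cache, dOut) {
  s <- sigmoid(cache$a3[, , 1L])
  da3 <- array(dOut * s * (1 - s), dim(cache$a3))
  bk3 <- convMCBackward(cache$P3, params$K3, da3)
  dh2 <- up2T(bk3$dInput)
  da2 <- dh2 * (1 - cache$h2^2)
  bk2 <- convMCBackward(cache$P2, params$K2, da2)
  dh1 <- up2T(bk2$dInput)
  da1 <- as.vector(dh1 * (1 - cache$h1^2))
  list(dK3 = bk3$dK, db3 = bk3$db, dK2 = bk2$dK, db2 = bk2$db, da1 = da1)
}

# One Adam step; st holds first/second moments and the step counter.
adamStep <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  if (is.null(st)) st <- list(m = par * 0, v = par * 0, t = 0L)
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), st = st)
}

#' Train a small auto-decoder generator on a phantom corpus
#'
#' Jointly optimizes decoder parameters and one latent code per training image
#' (auto-decoder style) to minimize mean squared reconstruction error, with
#' mini-batch Adam and a small L2 penalty on the latents that keeps them on
#' the unit scale of the standard-normal latent prior. Deterministic given
#' `seed`. Image sides must be multiples of 4 (two 2x upsampling stages).
#'
#' @param corpus list of equal-shape image matrices, length >= 50.
#' @param latentShape integer pair (L, D); default c(4, 16).
#' @param epochs training epochs, >= 1.
#' @param seed integer seed.
#' @param lr Adam learning rate.
#' @param batchSize mini-batch size.
#' @param channels hidden channel count of the convolutional stack.
#' @param latentL2 L2 penalty weight on the per-image latents.
#' @return a [DecoderGenerator-class] (training loss trace in `@trainLoss`).
#' @export
trainDecoder <- function(corpus, latentShape = c(4L, 16L), epochs = 50L,
                         seed = 1L, lr = 0.01, batchSize = 16L,
                         channels = 8L, latentL2 = 1e-3) {
  if (length(corpus) < 50L) stop("corpus must contain at least 50 images")
  if (epochs < 1L) stop("epochs must be >= 1")
  dims <- dim(corpus[[1L]])
  if (!all(vapply(corpus, function(x) identical(dim(x), dims), TRUE)))
    stop("corpus images must all share one shape")
  H <- dims[1L]; W <- dims[2L]
  if (H %% 4L != 0L || W %% 4L != 0L)
    stop("image sides must be multiples of 4")
  L <- latentShape[1L]; D <- latentShape[2L]
  d0 <- L * D
  arch <- list(h0 = H %/% 4L, w0 = W %/% 4L, c0 = as.integer(channels))
  n1 <- arch$h0 * arch$w0 * arch$c0
  n <- length(corpus)

  withSeed(seed, {
    params <- list(
      W1 = matrix(stats::rnorm(d0 * n1, 0, 1 / sqrt(d0)), d0, n1),
      b1 = numeric(n1),
      K2 = array(stats::rnorm(9 * arch$c0 * arch$c0, 0,
                              1 / sqrt(9 * arch$c0)),
                 c(3, 3, arch$c0, arch$c0)),
      b2 = numeric(arch$c0),
      K3 = array(stats::rnorm(9 * arch$c0, 0, 1 / sqrt(9 * arch$c0)),
                 c(3, 3, arch$c0, 1)),
      b3 = 0)
    Z <- matrix(stats::rnorm(n * d0, 0, 0.1), n, d0)
    states <- list(W1 = NULL, b1 = NULL, K2 = NULL, b2 = NULL, K3 = NULL,
                   b3 = NULL, Z = NULL)
    lossTrace <- numeric(epochs)

    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      epochLoss <- 0
      for (start in seq(1L, n, batchSize)) {
        batch <- ord[start:min(start + batchSize - 1L, n)]
        grads <- list(W1 = params$W1 * 0, b1 = params$b1 * 0,
                      K2 = params$K2 * 0, b2 = params$b2 * 0,
                      K3 = params$K3 * 0, b3 = 0)
        gZ <- Z * 0
        for (i in batch) {
          v <- Z[i, ]
          fw <- decoderForward(params, arch, v)
          resid <- fw$out - corpus[[i]]
          epochLoss <- epochLoss + mean(resid^2)
          dOut <- 2 * resid / length(resid)
          bk <- decoderBackward(params, arch, fw, dOut)
          grads$W1 <- grads$W1 + tcrossprod(v, bk$da1)
          grads$b1 <- grads$b1 + bk$da1
          grads$K2 <- grads$K2 + bk$dK2
          grads$b2 <- grads$b2 + bk$db2
          grads$K3 <- grads$K3 + bk$dK3
          grads$b3 <- grads$b3 + bk$db3
          gZ[i, ] <- as.vector(params$W1 %*% bk$da1) + 2 * latentL2 * v
        }
        nb <- length(batch)
        for (nm in names(grads)) {
          up <- adamStep(params[[nm]], grads[[nm]] / nb, states[[nm]], lr)
          params[[nm]] <- up$par
          states[[nm]] <- up$st
        }
        up <- adamStep(Z, gZ, states$Z, lr * 3)
        Z <- up$par
        states$Z <- up$st
      }
      lossTrace[ep] <- epochLoss / n
    }
  })

  if (epochs > 1L && lossTrace[epochs] >= lossTrace[1L])
    warning("decoder training loss did not decrease over the run")
  new("DecoderGenerator", latentShape = c(L, D), imageShape = c(H, W),
      seed = seed, params = params, arch = arch, trainLoss = lossTrace,
      trainLatents = Z)
}

#' @rdname generatorApply
#' @export
setMethod("generatorApply", "DecoderGenerator", function(model, omega) {
  checkLatent(model, omega)
  decoderForward(model@params, model@arch, as.vector(omega))$out
})

#' @rdname generatorVJP
#' @export
setMethod("generatorVJP", "DecoderGenerator", function(model, omega, gImage) {
  checkLatent(model, omega)
  v <- as.vector(omega)
  fw <- decoderForward(model@params, model@arch, v)
  bk <- decoderBackward(model@params, model@arch, fw, gImage)
  matrix(as.vector(model@params$W1 %*% bk$da1),
         model@latentShape[1L], model@latentShape[2L])
})

# ---- checkpointing ----------------------------------------------------------

#' Save / load a generator checkpoint
#'
#' The checkpoint is a self-describing list (kind, shapes, seed, parameters)
#' serialized with `saveRDS`.
#'
#' @param model a [GeneratorModel-class].
#' @param path file path.
#' @export
saveGenerator <- function(model, path) {
  ck <- list(kind = class(model), latentShape = model@latentShape,
             imageShape = model@imageShape, seed = model@seed)
  if (is(model, "LinearGenerator")) {
    ck$A <- model@A; ck$b <- model@b
    ck$scale <- model@scale; ck$offset <- model@offset
  } else {
    ck$params <- model@params; ck$arch <- model@arch
    ck$trainLoss <- model@trainLoss; ck$trainLatents <- model@trainLatents
  }
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname saveGenerator
#' @export
loadGenerator <- function(path) {
  ck <- readRDS(path)
  if (ck$kind == "LinearGenerator")
    new("LinearGenerator", latentShape = ck$latentShape,
        imageShape = ck$imageShape, seed = ck$seed, A = ck$A, b = ck$b,
        scale = ck$scale, offset = ck$offset)
  else
    new("DecoderGenerator", latentShape = ck$latentShape,
        imageShape = ck$imageShape, seed = ck$seed, params = ck$params,
        arch = ck$arch, trainLoss = ck$trainLoss,
        trainLatents = ck$trainLatents)
}
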