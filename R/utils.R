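#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so every seeded operation in the package is a pure
#' function of its arguments and never perturbs the caller's random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

stopifnotMatrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name))
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name))
  invisible(x)
}

checkImage <- function(x, name = "image") {
  stopifnotMatrix(x, name)
  if (nrow(x) < 8L || ncol(x) < 8L)
    stop(sprintf("'%s' must be at least 8x8", name))
  if (min(x) < -1e-9 || max(x) > 1 + 1e-9)
    stop(sprintf("'%s' intensities must lie in [0,1]", name))
  invisible(x)
}

checkMask <- function(m, img = NULL, name = "mask") {
  stopifnotMatrix(m, name)
  if (!all(m %in% c(0, 1)))
    stop(sprintf("'%s' must contain only 0 (missing) and 1 (observed)", name))
  if (!is.null(img) && !all(dim(m) == dim(img)))
    stop(sprintf("'%s' shape does not match the image", name))
  invisible(m)
}

sameDim <- function(a, b, what = "inputs") {
  if (!all(dim(a) == dim(b))) stop(sprintf("shape mismatch between %s", what))
  invisible(TRUE)
}
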