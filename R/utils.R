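# Internal numerical helpers shared across modules.

#' @importFrom stats dnorm rnorm runif median mad quantile pt qt var sd
#' @importFrom stats rbeta dbeta rbinom optim setNames aggregate
NULL

# Normalized 2-D Gaussian kernel with sd `sigma` (pixels); odd side length
# covering +/- 4 sigma so truncation error is negligible.
gaussian_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  half <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- seq(-half, half)
  k1 <- dnorm(x, sd = sigma)
  k <- outer(k1, k1)
  k / sum(k)
}

# Gaussian blur via EBImage::filter2 (FFT), zero-padded boundary.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  EBImage::filter2(mat, gaussian_kernel(sigma), boundary = 0)
}

# Evaluate a function under a locally-seeded RNG, restoring global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

logistic <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a
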