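## Internal numerical helpers shared across modules.

#' Derive a reproducible integer seed from a base seed and a tag path
#'
#' Splits one user-facing seed into independent, order-insensitive streams
#' (per image, per stage, per sampling run) via a small string hash, so that
#' e.g. adding images to a cohort does not perturb the molecular simulation.
#'
#' @param seed base integer seed.
#' @param ... character or numeric tags identifying the stream.
#' @return an integer in [1, 2^31 - 2] suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  tags <- paste(c(format(seed), vapply(list(...), function(x)
    paste(format(x), collapse = "/"), character(1))), collapse = "|")
  h <- 5381
  for (cc in utf8ToInt(tags)) h <- (h * 33 + cc) %% 2147483629
  # (a * b) mod 2^32, exact in doubles via 16-bit split
  mulmod32 <- function(a, b) {
    lo <- a %% 65536; hi <- (a - lo) / 65536
    (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
  }
  # two finalization rounds (multiply + xor-fold) so that adjacent tag
  # strings yield well-separated, decorrelated seeds
  for (k in 1:2) {
    h <- mulmod32(h + 1, 2654435761)
    h <- bitwXor(as.integer(h %% 2147483648), as.integer(h %/% 2097152))
    h <- abs(h)
  }
  as.integer(h %% 2147483646L + 1L)
}

# Evaluate expr with a local RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Truncated Gaussian kernel (radius 3.5 sigma, capped at the axis length).
gauss_kernel <- function(n, sigma) {
  r <- min(n - 1L, as.integer(ceiling(3.5 * sigma)))
  dnorm(-r:r, sd = sigma)
}

# Zero-padded 1-D convolution of every column of x with kernel g (odd
# length), FFT-based via mvfft so large images stay tractable.
conv_cols <- function(x, g) {
  r <- (length(g) - 1L) %/% 2L
  n <- stats::nextn(nrow(x) + 2L * r)   # composite length keeps FFT fast
  G <- stats::fft(c(g, rep(0, n - length(g))))
  out <- matrix(0, nrow(x), ncol(x))
  chunk <- max(1L, as.integer(2e7 %/% n))  # bound complex work buffers
  for (j0 in seq(1L, ncol(x), by = chunk)) {
    jj <- j0:min(j0 + chunk - 1L, ncol(x))
    X <- stats::mvfft(rbind(x[, jj, drop = FALSE],
                            matrix(0, n - nrow(x), length(jj))))
    out[, jj] <- Re(stats::mvfft(X * G, inverse = TRUE)
                    )[(r + 1L):(r + nrow(x)), , drop = FALSE] / n
  }
  out
}

# Separable zero-padded 2-D Gaussian convolution (no normalization).
conv_gauss2d <- function(x, sigma) {
  gy <- gauss_kernel(nrow(x), sigma)
  gx <- gauss_kernel(ncol(x), sigma)
  t(conv_cols(t(conv_cols(x, gy)), gx))
}

#' Mask-normalized separable Gaussian smoothing
#'
#' Convolves `x * mask` and `mask` with the same truncated Gaussian kernel
#' (zero padded at the image border) and returns their ratio, i.e. the local
#' Gaussian-weighted mean of `x` over masked pixels. No intensity is reflected
#' or leaked across the mask boundary. `sigma = Inf` returns the plain mean of
#' `x` over the mask.
#'
#' @param x numeric matrix.
#' @param sigma Gaussian width in pixels (may be `Inf`).
#' @param mask logical/0-1 matrix of analyzed pixels; default all pixels.
#' @return matrix of local means; `NA` where the smoothed mask is zero.
#' @export
gaussian_smooth <- function(x, sigma, mask = NULL) {
  stopifnot(is.matrix(x), sigma > 0)
  if (is.null(mask)) mask <- matrix(1, nrow(x), ncol(x))
  m <- (mask != 0) * 1
  if (!is.finite(sigma)) {
    mu <- sum(x * m) / sum(m)
    out <- matrix(mu, nrow(x), ncol(x))
    if (sum(m) == 0) out[] <- NA_real_
    return(out)
  }
  num <- conv_gauss2d(x * m, sigma)
  den <- conv_gauss2d(m, sigma)
  out <- num / den
  out[den <= .Machine$double.eps] <- NA_real_
  out
}

# Smooth unit-variance random field: white noise blurred at length `sigma`
# then standardized over the whole image. Used by the cohort generator.
smooth_field <- function(h, w, sigma) {
  z <- matrix(rnorm(h * w), h, w)
  f <- gaussian_smooth(z, sigma)
  (f - mean(f)) / max(sd(f), .Machine$double.eps)
}

# Population (divide-by-n) variance.
pvar <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  mean((x - mean(x))^2)
}

relative_rms <- function(err, ref) {
  sqrt(mean(err^2)) / sqrt(mean(ref^2))
}
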