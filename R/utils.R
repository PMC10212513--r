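# Internal helpers: named random streams, hashing, image sampling primitives.

#' @keywords internal
"_PACKAGE"

## Deterministic 31-bit rolling hash of a string; used to derive named child
## RNG streams from a root seed so adding a stream never perturbs others.
str_hash31 <- function(s) {
  h <- 0
  for (b in as.integer(charToRaw(s))) h <- (h * 131 + b) %% 2147483647
  h
}

stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.numeric(seed) %% 2147483647 + str_hash31(name)) %% 2147483647)
}

## Evaluate expr under the RNG stream (seed, name), restoring global RNG state.
with_stream <- function(seed, name, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  expr
}

## Short hex digest of an R object via its canonical JSON form.
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 15, null = "null"))
  sprintf("%08x", str_hash31(s))
}

## Bilinear sampling of matrix `img` at fractional (row, col) positions
## (1-based, matrix convention). Out-of-range positions are clamped to the
## border (replicate padding).
bilinear_sample <- function(img, y, x) {
  nr <- nrow(img); nc <- ncol(img)
  y <- pmin(pmax(y, 1), nr)
  x <- pmin(pmax(x, 1), nc)
  y0 <- pmin(floor(y), nr - 1L); x0 <- pmin(floor(x), nc - 1L)
  fy <- y - y0; fx <- x - x0
  i00 <- (x0 - 1) * nr + y0
  v00 <- img[i00];       v10 <- img[i00 + 1]
  v01 <- img[i00 + nr];  v11 <- img[i00 + nr + 1]
  out <- (1 - fy) * (1 - fx) * v00 + fy * (1 - fx) * v10 +
    (1 - fy) * fx * v01 + fy * fx * v11
  dim(out) <- dim(y)
  out
}

## 2x block-mean downsampling (odd trailing row/col dropped).
downsample2 <- function(img) {
  nr <- 2L * (nrow(img) %/% 2L); nc <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  0.25 * (img[seq(1, nr, 2), seq(1, nc, 2)] + img[seq(2, nr, 2), seq(1, nc, 2)] +
            img[seq(1, nr, 2), seq(2, nc, 2)] + img[seq(2, nr, 2), seq(2, nc, 2)])
}

## Periodic Gaussian blur via FFT; used to synthesise smooth random fields.
gauss_blur_fft <- function(mat, sigma) {
  nr <- nrow(mat); nc <- ncol(mat)
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  ky <- exp(-2 * pi^2 * sigma^2 * fy^2)
  kx <- exp(-2 * pi^2 * sigma^2 * fx^2)
  Re(fft(fft(mat) * outer(ky, kx), inverse = TRUE)) / (nr * nc)
}

## Otsu threshold on a numeric matrix/vector (256-bin histogram); returns the
## threshold value (foreground = x > threshold). Constant input returns max(x)
## so the foreground is empty.
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) return(rng[2])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[nbins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins)
  sigma_b[ok] <- (muT * w0[ok] - mu0[ok])^2 / (w0[ok] * w1[ok])
  br[which.max(sigma_b) + 1L]
}

## ceiling() robust to binary representation of p*n (e.g. 0.064*500).
ceil_frac <- function(fraction, n) as.integer(ceiling(fraction * n - 1e-9))

`%||%` <- function(a, b) if (is.null(a)) b else a
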