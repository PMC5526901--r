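## Internal helpers shared across modules.

## Run `expr` under a local RNG state seeded with `seed`, restoring the
## caller's RNG stream afterwards so package functions never perturb user
## randomness.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

## Derive a reproducible sub-seed (kept within 32-bit integer range).
.subSeed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + 97 * k) %% 2147483647)
}

## Signed shoelace area of a polygon given as x/y vertex vectors (first
## vertex need not be repeated). Returns the absolute enclosed area.
.shoelaceArea <- function(x, y) {
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1
  }
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

## Separable Gaussian smoothing of a matrix with sd `sigma` (in bins),
## truncated at 3 sigma, zero-padded at the borders.
.gaussSmooth2d <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(mat) {
    # convolve each column with k, zero padding
    nr <- nrow(mat)
    out <- matrix(0, nr, ncol(mat))
    for (o in seq(-r, r)) {
      w <- k[o + r + 1]
      src <- seq_len(nr) + o
      ok <- src >= 1 & src <= nr
      out[ok, ] <- out[ok, ] + w * mat[src[ok], , drop = FALSE]
    }
    out
  }
  t(smooth1(t(smooth1(m))))
}

## Even-odd point-in-polygon (boundary counts as inside); thin wrapper
## around the compiled kernel.
.pointInPolygon <- function(px, py, vertices) {
  .pipCpp(as.numeric(px), as.numeric(py),
          as.numeric(vertices[, 1]), as.numeric(vertices[, 2]))
}

## Lognormal draw parametrized by median m and coefficient of variation cv:
## x = m * exp(sigma * Z) with sigma^2 = log(1 + cv^2). The median (the
## generator's location parameter) is exactly m.
.rlnormMedian <- function(n, median, cv) {
  sigma <- sqrt(log(1 + cv^2))
  median * exp(sigma * rnorm(n))
}
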