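# Shared internal helpers: windowed means and seed hygiene.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Truncated (edge-shrinking) windowed sum along rows of a matrix.
# h is the half-width; window at row i covers rows [i-h, i+h] clipped to the
# matrix. Works for numeric and complex input.
.run_sum_rows <- function(M, h) {
  n <- nrow(M)
  if (h == 0L) return(M)
  cs <- rbind(matrix(0, 1L, ncol(M)), apply(M, 2L, cumsum))
  hi <- pmin(seq_len(n) + h, n)
  lo <- pmax(seq_len(n) - h, 1L)
  cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
}

# Centered 2D box mean with window truncation at the edges.
# kernel = c(rows, cols), both odd and no larger than the image.
.box_mean2 <- function(M, kernel) {
  kz <- as.integer(kernel[1L])
  kx <- as.integer(kernel[2L])
  if (kz < 1L || kx < 1L || kz %% 2L == 0L || kx %% 2L == 0L) {
    stop("kernel dimensions must be odd and >= 1", call. = FALSE)
  }
  if (kz > nrow(M) || kx > ncol(M)) {
    stop("kernel larger than image", call. = FALSE)
  }
  hz <- (kz - 1L) %/% 2L
  hx <- (kx - 1L) %/% 2L
  s <- t(.run_sum_rows(t(.run_sum_rows(M, hz)), hx))
  nz <- pmin(seq_len(nrow(M)) + hz, nrow(M)) - pmax(seq_len(nrow(M)) - hz, 1L) + 1L
  nx <- pmin(seq_len(ncol(M)) + hx, ncol(M)) - pmax(seq_len(ncol(M)) - hx, 1L) + 1L
  s / (nz %o% nx)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Complex circular Gaussian draws with total variance sigma2 per element.
.rcnorm <- function(n, sigma2) {
  sd <- sqrt(sigma2 / 2)
  complex(real = stats::rnorm(n, 0, sd), imaginary = stats::rnorm(n, 0, sd))
}
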