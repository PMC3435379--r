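#' Monte-Carlo table of the retardance estimator's noise bias
#'
#' The local-retardance estimator is nonnegative, so additive detection noise
#' biases it upward, most strongly at low SNR and low true retardance. This
#' builds the mean-estimator table used to undo that bias: for every node of a
#' (true retardance, effective SNR) grid it simulates `n_draws` noisy
#' realisations of exactly the production estimator — two cumulative Jones
#' matrices separated by a local retarder, independent additive circular
#' complex Gaussian noise on every element, local matrix by matrix inversion,
#' retardance by polar decomposition — and records the mean estimate.
#'
#' The simulation exploits the unitary invariance of the noise: the measured
#' distribution depends only on the local retardance and the SNR, so the
#' shallow cumulative matrix can be taken as the identity and the retarder
#' orientation randomised.
#'
#' @param ret_grid True retardance nodes in radians, spanning `[0, pi]`.
#' @param snr_grid_db Effective-SNR nodes in dB.
#' @param n_draws Monte-Carlo draws per node (>= 1000).
#' @param rng_seed Integer seed; the table is deterministic given the seed.
#' @return Object of class `bias_table`: grids, matrix `mean_measured`
#'   (retardance nodes x SNR nodes), `n_draws`, `rng_seed`.
#' @export
build_bias_table <- function(ret_grid = seq(0, pi, length.out = 33L),
                             snr_grid_db = seq(5, 40, by = 2.5),
                             n_draws = 2000L,
                             rng_seed = 1L) {
  stopifnot(n_draws >= 1000L, !is.unsorted(ret_grid), !is.unsorted(snr_grid_db))
  nr <- length(ret_grid)
  ns <- length(snr_grid_db)
  mean_measured <- .with_seed(rng_seed, {
    out <- matrix(NA_real_, nr, ns)
    for (k in seq_len(ns)) {
      sigma2 <- 0.5 * 10^(-snr_grid_db[k] / 10)  # per-channel variance, signal power 2
      n <- nr * n_draws
      theta <- stats::runif(n, 0, pi)
      h <- rep(ret_grid, each = n_draws) / 2
      cth <- cos(2 * theta)
      sth <- sin(2 * theta)
      c0 <- cos(h)
      s0 <- sin(h)
      # local retarder applied to J1 = I
      b11 <- complex(real = c0, imaginary = s0 * cth) + .rcnorm(n, sigma2)
      b12 <- complex(real = 0, imaginary = s0 * sth) + .rcnorm(n, sigma2)
      b21 <- complex(real = 0, imaginary = s0 * sth) + .rcnorm(n, sigma2)
      b22 <- complex(real = c0, imaginary = -s0 * cth) + .rcnorm(n, sigma2)
      a11 <- 1 + .rcnorm(n, sigma2)
      a12 <- .rcnorm(n, sigma2)
      a21 <- .rcnorm(n, sigma2)
      a22 <- 1 + .rcnorm(n, sigma2)
      det <- a11 * a22 - a12 * a21
      r <- .jones_retardance_batch(
        (b11 * a22 - b12 * a21) / det,
        (b21 * a22 - b22 * a21) / det,
        (-b11 * a12 + b12 * a11) / det,
        (-b21 * a12 + b22 * a11) / det
      )
      out[, k] <- rowMeans(matrix(r, nr, n_draws, byrow = TRUE), na.rm = TRUE)
    }
    out
  })
  structure(
    list(ret_grid = ret_grid, snr_grid_db = snr_grid_db,
         mean_measured = mean_measured, n_draws = as.integer(n_draws),
         rng_seed = as.integer(rng_seed)),
    class = "bias_table"
  )
}

#' @export
print.bias_table <- function(x, ...) {
  cat(sprintf(
    "<bias_table> %d retardance x %d SNR nodes, %d draws/node, seed %d\n",
    length(x$ret_grid), length(x$snr_grid_db), x$n_draws, x$rng_seed
  ))
  invisible(x)
}

# Package-level cache so the default table is built once per session.
.optrheo_cache <- new.env(parent = emptyenv())

#' Default bias table (built once and cached)
#' @param rng_seed Seed for the table simulation (default 20120906).
#' @export
default_bias_table <- function(rng_seed = 20120906L) {
  key <- sprintf("bias_table_%d", rng_seed)
  if (is.null(.optrheo_cache[[key]])) {
    .optrheo_cache[[key]] <- build_bias_table(rng_seed = rng_seed)
  }
  .optrheo_cache[[key]]
}

# Monotone inverse of one SNR slice of the table. The Monte-Carlo means are
# monotone nondecreasing in true retardance up to simulation noise; enforce
# strict monotonicity (cummax plus a vanishing ramp), then invert with a
# monotone (Hyman-filtered) cubic spline.
.slice_inverse <- function(table, k) {
  ms <- cummax(table$mean_measured[, k])
  ms <- ms + seq_along(ms) * 1e-9
  stats::splinefun(ms, table$ret_grid, method = "hyman")
}

#' Invert the estimator bias on a birefringence map
#'
#' Maps each pixel's measured birefringence back through the Monte-Carlo mean
#' table at that pixel's effective SNR: the measured value is converted to
#' retardance, the table's SNR slices bracketing the pixel SNR are each
#' inverted by monotone cubic interpolation, and the two corrected retardances
#' are blended linearly in SNR. Measured values below the SNR-specific bias
#' floor (the table value at zero true retardance) map to 0 — the bias makes
#' exact zero unreachable, so clamping is the only consistent inverse. Values
#' above the invertible range clamp to the \eqn{\pi}-equivalent birefringence
#' and are counted in attribute `n_overrange`. Pixel SNRs outside the table
#' range use the nearest edge slice.
#'
#' @param dn_map `scalar_map` of measured birefringence (from
#'   [local_birefringence()]).
#' @param snr_map `scalar_map` of effective SNR in dB, co-registered with
#'   `dn_map`.
#' @param table A `bias_table`.
#' @param wavelength Center wavelength in metres.
#' @param sep_depth Axial separation depth in metres.
#' @return A `scalar_map` of corrected birefringence.
#' @export
apply_bias_correction <- function(dn_map, snr_map, table, wavelength, sep_depth) {
  stopifnot(inherits(dn_map, "scalar_map"), inherits(snr_map, "scalar_map"),
            inherits(table, "bias_table"))
  stopifnot(identical(dim(dn_map$values), dim(snr_map$values)))
  to_ret <- 4 * pi * sep_depth / wavelength
  meas <- dn_map$values * to_ret
  snr <- pmin(pmax(snr_map$values, min(table$snr_grid_db)), max(table$snr_grid_db))
  sgrid <- table$snr_grid_db
  lo <- findInterval(snr, sgrid, rightmost.closed = TRUE)
  lo <- pmin(pmax(lo, 1L), length(sgrid) - 1L)
  w <- (snr - sgrid[lo]) / (sgrid[lo + 1L] - sgrid[lo])
  w <- pmin(pmax(w, 0), 1)
  corrected <- array(NA_real_, dim(meas))
  n_over <- 0L
  sel_all <- dn_map$mask & snr_map$mask & is.finite(meas)
  for (k in seq_len(length(sgrid) - 1L)) {
    use <- sel_all & lo == k
    if (!any(use)) next
    for (side in 0:1) {
      kk <- k + side
      inv <- .slice_inverse(table, kk)
      floor_k <- table$mean_measured[1L, kk]
      top_k <- max(table$mean_measured[, kk])
      m <- meas[use]
      r <- inv(pmin(pmax(m, floor_k), top_k))
      r[m <= floor_k] <- 0
      over <- m > top_k
      r[over] <- pi
      if (side == 0L) n_over <- n_over + sum(over)
      wgt <- if (side == 0L) 1 - w[use] else w[use]
      corrected[use] <- (if (side == 0L) 0 else corrected[use]) + wgt * r
    }
  }
  out <- scalar_map(corrected / to_ret, mask = sel_all)
  attr(out, "n_overrange") <- n_over
  out
}
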