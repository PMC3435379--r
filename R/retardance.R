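# Vectorised retardance of batches of 2x2 Jones matrices.
#
# A Mueller matrix derived from a nonsingular Jones matrix is nondepolarizing,
# so its Lu-Chipman retardance equals the eigenvalue phase separation of the
# unitary factor of the Jones matrix's polar decomposition J = U P (P Hermitian
# positive definite). For 2x2 matrices both factors have closed forms:
#   H = J^H J,  s = sqrt(det H),  U  is proportional to  J adj(H + s I),
# and the retardance is |Arg(lambda_1 lambda_2^*)| of U's eigenvalues.
# Agreement with lu_chipman_retardance() on random matrices is asserted in the
# test suite; this path exists because per-pixel 4x4 decompositions are far too
# slow for volumetric maps and Monte-Carlo bias tables.
.jones_retardance_batch <- function(j11, j21, j12, j22) {
  h11 <- Mod(j11)^2 + Mod(j21)^2
  h22 <- Mod(j12)^2 + Mod(j22)^2
  h12 <- Conj(j11) * j12 + Conj(j21) * j22
  detH <- h11 * h22 - Mod(h12)^2
  s <- sqrt(pmax(detH, 0))
  # U proportional to J %*% adj(H + sI); scalar factors do not move eigenphases
  k11 <- h22 + s
  k22 <- h11 + s
  u11 <- j11 * k11 - j12 * Conj(h12)
  u12 <- -j11 * h12 + j12 * k22
  u21 <- j21 * k11 - j22 * Conj(h12)
  u22 <- -j21 * h12 + j22 * k22
  tr <- u11 + u22
  dt <- u11 * u22 - u12 * u21
  disc <- sqrt(tr^2 - 4 * dt)
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  r <- abs(Arg(l1 * Conj(l2)))
  r[!(detH > 0) | !is.finite(r)] <- NA_real_
  r
}

#' Local phase retardance map of a local Jones volume
#'
#' Per-pixel total retardance (radians, in `[0, pi]`) of the local round-trip
#' matrices, equal to the Lu-Chipman retardance of the per-pixel Mueller
#' matrix.
#'
#' @param local A local `jones_volume` from [local_jones()].
#' @return A `scalar_map` of retardance in radians.
#' @export
local_retardance <- function(local) {
  stopifnot(inherits(local, "jones_volume"))
  r <- .jones_retardance_batch(
    local$j[, , , 1L, drop = FALSE], local$j[, , , 2L, drop = FALSE],
    local$j[, , , 3L, drop = FALSE], local$j[, , , 4L, drop = FALSE]
  )
  dim(r) <- dim(local)
  scalar_map(r, mask = is.finite(r) & local$valid)
}

#' Local birefringence map
#'
#' Converts local retardance to birefringence,
#' \eqn{\Delta n = R \lambda_0 / (4 \pi \Delta z)}, where \eqn{R} is the
#' Lu-Chipman retardance of the pixel's local round-trip matrix,
#' \eqn{\lambda_0} the center wavelength and \eqn{\Delta z} the axial
#' separation depth in tissue (the factor 4 reflects the round trip).
#' Birefringence is the refractive-index difference between the
#' eigenpolarizations and is unitless.
#'
#' The estimator is single-valued only while the local retardance stays below
#' \eqn{\pi}; pixels with retardance above `wrap_threshold * pi` are flagged
#' as wrap risks and masked out (their count is in attribute `n_wrap`).
#'
#' @param local A local `jones_volume` from [local_jones()].
#' @param wrap_threshold Fraction of \eqn{\pi} above which a pixel is treated
#'   as wrapped (default 0.995).
#' @return A `scalar_map` of birefringence, with attribute `retardance`
#'   holding the underlying retardance map.
#' @export
local_birefringence <- function(local, wrap_threshold = 0.995) {
  ret <- local_retardance(local)
  dz <- separation_depth(local)
  dn <- ret$values * local$wavelength / (4 * pi * dz)
  wrap <- is.finite(ret$values) & ret$values > wrap_threshold * pi
  out <- scalar_map(dn, mask = ret$mask & !wrap)
  attr(out, "retardance") <- ret
  attr(out, "n_wrap") <- sum(wrap)
  out
}
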