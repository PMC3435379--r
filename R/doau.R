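# Per-pixel optic-axis extraction for a local Jones volume.
# Returns list of arrays q, u, v and logical valid. Eigenpairs are ordered by
# eigenvalue phase (larger principal phase first, modulus as tie-break), the
# first eigenvector is taken, and its Stokes representation is computed as in
# eigenvector_to_stokes(). Near-degenerate pixels are flagged invalid.
.axis_components <- function(local, disambiguate = FALSE) {
  j11 <- local$j[, , , 1L, drop = FALSE]
  j21 <- local$j[, , , 2L, drop = FALSE]
  j12 <- local$j[, , , 3L, drop = FALSE]
  j22 <- local$j[, , , 4L, drop = FALSE]
  tr <- j11 + j22
  dt <- j11 * j22 - j12 * j21
  disc <- sqrt(tr^2 - 4 * dt)
  la <- (tr + disc) / 2
  lb <- (tr - disc) / 2
  sep <- Mod(la - lb)
  degen <- sep < 1e-12 * pmax(Mod(la), Mod(lb), 1e-300)
  pha <- Arg(la)
  phb <- Arg(lb)
  pick_a <- pha > phb | (pha == phb & Mod(la) >= Mod(lb))
  lam <- ifelse(pick_a, la, lb)
  # eigenvector (j12, lam - j11), falling back to (lam - j22, j21)
  v1 <- j12
  v2 <- lam - j11
  n2 <- Mod(v1)^2 + Mod(v2)^2
  alt <- n2 < 1e-24 * pmax(Mod(lam)^2, 1e-300)
  v1[alt] <- (lam - j22)[alt]
  v2[alt] <- j21[alt]
  n2 <- Mod(v1)^2 + Mod(v2)^2
  ok <- !degen & n2 > 0 & is.finite(n2)
  cross <- v1 * Conj(v2)
  q <- (Mod(v1)^2 - Mod(v2)^2) / n2
  u <- 2 * Re(cross) / n2
  v <- -2 * Im(cross) / n2
  if (disambiguate) {
    flip <- q < 0 | (q == 0 & u < 0) | (q == 0 & u == 0 & v < 0)
    q[flip] <- -q[flip]
    u[flip] <- -u[flip]
    v[flip] <- -v[flip]
  }
  d <- dim(local)
  dim(q) <- d; dim(u) <- d; dim(v) <- d; dim(ok) <- d
  list(q = q, u = u, v = v, valid = ok & local$valid)
}

#' Degree of optic axis uniformity (DOAU)
#'
#' For every pixel of a local Jones volume: diagonalize the local round-trip
#' matrix, take the Stokes parameters `(q, u, v)` of the phase-ordered
#' eigenvector, average the components over a centered `(axial, lateral)`
#' kernel within the B-scan, and return the Euclidean norm
#' \eqn{\sqrt{\bar q^2 + \bar u^2 + \bar v^2}}. The result lies in `[0, 1]`:
#' unity indicates a completely uniform axis orientation within the kernel and
#' zero a completely random one. Regions of nonuniform optic axis — domain
#' boundaries in particular — carry unreliable local birefringence, which is
#' why DOAU gates the volume mean.
#'
#' The eigenvector representative is selected deterministically by eigenvalue
#' phase and is *not* folded onto a hemisphere: folding would push the kernel
#' mean of completely random axes towards 0.5 instead of the random-walk
#' resultant \eqn{1/\sqrt{N}}, destroying the "zero means random" calibration.
#' Deterministic phase ordering already makes the average well defined.
#' `disambiguate = TRUE` applies the hemisphere fold anyway, for
#' antipodal-domain studies.
#'
#' Degenerate (retardance ~ 0) pixels are excluded from the kernel average; a
#' pixel whose kernel contains no usable axis is invalid.
#'
#' @param local A local `jones_volume` from [local_jones()].
#' @param kernel `(axial, lateral)` kernel in pixels, odd; default `c(5, 21)`
#'   approximates a 31 x 129 um^2 window at the default pitches.
#' @param disambiguate Fold axes onto the canonical hemisphere before
#'   averaging (default `FALSE`).
#' @return A `scalar_map` of DOAU values in `[0, 1]`.
#' @export
doau_map <- function(local, kernel = c(5L, 21L), disambiguate = FALSE) {
  stopifnot(inherits(local, "jones_volume"), length(kernel) == 2L)
  ax <- .axis_components(local, disambiguate = disambiguate)
  d <- dim(local)
  vals <- array(NA_real_, d)
  msk <- array(FALSE, d)
  for (y in seq_len(d[3L])) {
    w <- ax$valid[, , y] * 1
    qs <- .box_mean2(ifelse(ax$valid[, , y], ax$q[, , y], 0), kernel)
    us <- .box_mean2(ifelse(ax$valid[, , y], ax$u[, , y], 0), kernel)
    vs <- .box_mean2(ifelse(ax$valid[, , y], ax$v[, , y], 0), kernel)
    ws <- .box_mean2(w, kernel)
    ok <- ws > 0
    qb <- qs / ws
    ub <- us / ws
    vb <- vs / ws
    vals[, , y] <- ifelse(ok, sqrt(qb^2 + ub^2 + vb^2), NA_real_)
    msk[, , y] <- ok
  }
  vals[msk] <- pmin(vals[msk], 1)
  scalar_map(vals, mask = msk)
}

#' Volume-mean birefringence under SNR and DOAU gating
#'
#' Arithmetic mean of birefringence over the pixels that pass every filter:
#' valid birefringence, effective SNR strictly greater than
#' `config$snr_threshold_db`, and DOAU strictly greater than
#' `config$doau_threshold`. The filters commute; the count of contributing
#' pixels is returned alongside the mean.
#'
#' @param dn_map `scalar_map` of birefringence.
#' @param snr_map `scalar_map` of effective SNR (dB), co-registered.
#' @param doau `scalar_map` of DOAU, co-registered.
#' @param config A [pipeline_config()] (thresholds are read from it).
#' @return List with `mean` and `n_valid`. Zero surviving pixels is an error
#'   whose message reports the per-filter pass counts.
#' @export
mean_birefringence <- function(dn_map, snr_map, doau, config = pipeline_config()) {
  stopifnot(inherits(dn_map, "scalar_map"), inherits(snr_map, "scalar_map"),
            inherits(doau, "scalar_map"))
  stopifnot(identical(dim(dn_map$values), dim(snr_map$values)),
            identical(dim(dn_map$values), dim(doau$values)))
  pass_snr <- snr_map$mask & snr_map$values > config$snr_threshold_db
  pass_doau <- doau$mask & doau$values > config$doau_threshold
  sel <- dn_map$mask & pass_snr & pass_doau
  if (!any(sel)) {
    stop(sprintf(
      "no pixels pass the filters (valid birefringence: %d, SNR > %g dB: %d, DOAU > %g: %d)",
      sum(dn_map$mask), config$snr_threshold_db, sum(pass_snr),
      config$doau_threshold, sum(pass_doau)
    ), call. = FALSE)
  }
  list(mean = mean(dn_map$values[sel]), n_valid = sum(sel))
}
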