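#' Jones-matrix OCT volume
#'
#' Container for a volumetric set of round-trip Jones matrices, one 2x2
#' complex matrix per voxel on a `(z, x, y)` grid (axial index, lateral index,
#' frame index; depth index 1 is the tissue surface), plus the acquisition
#' metadata the processing chain needs.
#'
#' @param j Complex array of dimension `(z, x, y, 4)`; the last dimension holds
#'   the matrix elements in column-major order `J11, J21, J12, J22`.
#' @param wavelength Center wavelength in metres (default 1.31 um).
#' @param axial_pitch Axial pixel pitch in tissue, metres (default 6.125 um,
#'   i.e. 49 um per 8 pixels).
#' @param lateral_pitch Lateral pixel pitch in metres.
#' @param noise_floor Per-channel additive noise variance (linear intensity
#'   units), length 4 or scalar (recycled).
#' @param separation_pixels Axial pixel separation used to form local
#'   matrices, set by [local_jones()]; `NULL` for a cumulative volume.
#' @param valid Optional logical array `(z, x, y)` of per-pixel validity.
#' @return Object of class `jones_volume`.
#' @export
jones_volume <- function(j,
                         wavelength = 1.31e-6,
                         axial_pitch = 6.125e-6,
                         lateral_pitch = 6.125e-6,
                         noise_floor = NA_real_,
                         separation_pixels = NULL,
                         valid = NULL) {
  stopifnot(is.array(j), length(dim(j)) == 4L, dim(j)[4L] == 4L)
  stopifnot(wavelength > 0, axial_pitch > 0, lateral_pitch > 0)
  if (!is.complex(j)) storage.mode(j) <- "complex"
  noise_floor <- rep_len(as.numeric(noise_floor), 4L)
  d <- dim(j)[1:3]
  if (is.null(valid)) valid <- array(TRUE, d)
  stopifnot(identical(dim(valid), d))
  structure(
    list(
      j = j,
      wavelength = wavelength,
      axial_pitch = axial_pitch,
      lateral_pitch = lateral_pitch,
      noise_floor = noise_floor,
      separation_pixels = separation_pixels,
      valid = valid
    ),
    class = "jones_volume"
  )
}

#' @export
dim.jones_volume <- function(x) dim(x$j)[1:3]

#' @export
print.jones_volume <- function(x, ...) {
  d <- dim(x)
  kind <- if (is.null(x$separation_pixels)) "cumulative" else
    sprintf("local (separation %d px, %.1f um)",
            x$separation_pixels, 1e6 * separation_depth(x))
  cat(sprintf(
    "<jones_volume> %d x %d x %d (z,x,y), %s\n  wavelength %.3f um, axial pitch %.3f um, %d/%d pixels valid\n",
    d[1L], d[2L], d[3L], kind, 1e6 * x$wavelength, 1e6 * x$axial_pitch,
    sum(x$valid), length(x$valid)
  ))
  invisible(x)
}

#' Axial separation depth of a local Jones volume, in metres
#' @param vol A `jones_volume` produced by [local_jones()].
#' @export
separation_depth <- function(vol) {
  stopifnot(inherits(vol, "jones_volume"), !is.null(vol$separation_pixels))
  vol$separation_pixels * vol$axial_pitch
}

#' Per-pixel real-valued map on the volume grid
#'
#' @param values Numeric array (typically `(z, x, y)`).
#' @param mask Logical array of the same shape; `TRUE` marks valid pixels.
#' @return Object of class `scalar_map`.
#' @export
scalar_map <- function(values, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(values)
  stopifnot(identical(dim(values), dim(mask)))
  structure(list(values = values, mask = mask), class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<scalar_map> %s, %d/%d valid, range [%.4g, %.4g]\n",
              paste(dim(x$values), collapse = " x "),
              sum(x$mask), length(x$mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Phase-aligned moving average of Jones matrices
#'
#' Complex averaging of speckle-phase data destroys the signal unless the
#' random per-pixel global phase is referenced out first. Within each centered
#' window (per B-scan) the window-center pixel's largest-magnitude element
#' selects a reference element index; every matrix in the window is multiplied
#' by the unit phasor that aligns its phase of that same element with the
#' center's, then the four elements are averaged element-wise. Referencing one
#' fixed element per window matters: magnitudes alone can tie (for a pure
#' retarder the two diagonal elements have equal modulus and opposite phase),
#' and switching reference elements between neighbours decoheres the average.
#' Edges use window truncation. The per-channel noise floor is divided by the
#' nominal window size, since independent additive noise averages down.
#'
#' @param vol A cumulative `jones_volume`.
#' @param kernel `(axial, lateral)` window size in pixels; both odd, >= 1 and
#'   no larger than the B-scan.
#' @return A `jones_volume` of the same shape.
#' @export
moving_average_jones <- function(vol, kernel = c(3L, 3L)) {
  stopifnot(inherits(vol, "jones_volume"), length(kernel) == 2L)
  kernel <- as.integer(kernel)
  if (any(kernel < 1L) || any(kernel %% 2L == 0L)) {
    stop("kernel dimensions must be odd and >= 1", call. = FALSE)
  }
  d <- dim(vol)
  if (kernel[1L] > d[1L] || kernel[2L] > d[2L]) {
    stop("kernel larger than image", call. = FALSE)
  }
  out <- vol$j
  if (!all(kernel == 1L)) {
    for (y in seq_len(d[3L])) {
      el <- lapply(1:4, function(k) matrix(vol$j[, , y, k], d[1L], d[2L]))
      # reference element index: largest magnitude at the window center
      ref <- matrix(1L, d[1L], d[2L])
      best <- Mod(el[[1L]])
      for (k in 2:4) {
        m <- Mod(el[[k]])
        sel <- m > best
        ref[sel] <- k
        best[sel] <- m[sel]
      }
      # for each candidate reference element, filter all four channels with
      # every matrix aligned on its own phase of that element, then pick the
      # center-selected version per pixel
      for (k in 1:4) {
        use <- ref == k
        if (!any(use)) next
        phi <- Arg(el[[k]])
        al <- exp(-1i * phi)
        re <- exp(1i * phi)
        for (ch in 1:4) {
          f <- .box_mean2(el[[ch]] * al, kernel) * re
          tmp <- matrix(out[, , y, ch], d[1L], d[2L])
          tmp[use] <- f[use]
          out[, , y, ch] <- tmp
        }
      }
    }
  }
  vol$j <- out
  vol$noise_floor <- vol$noise_floor / prod(kernel)
  vol
}

#' Local round-trip Jones matrices over a fixed axial separation
#'
#' At depth `z` returns \eqn{J(z + \Delta z)\,J(z)^{-1}}, the round-trip
#' matrix of the tissue slab between the two depths; the output depth
#' dimension shrinks by `separation_pixels`. Pixels where the shallower
#' cumulative matrix is numerically singular are flagged invalid rather than
#' raising an error.
#'
#' @param vol A cumulative `jones_volume`.
#' @param separation_pixels Axial separation in pixels (default 8, i.e. 49 um
#'   at the default pitch).
#' @return A local `jones_volume` with `separation_pixels` set.
#' @export
local_jones <- function(vol, separation_pixels = 8L) {
  stopifnot(inherits(vol, "jones_volume"))
  sep <- as.integer(separation_pixels)
  d <- dim(vol)
  if (sep < 1L) stop("separation_pixels must be >= 1", call. = FALSE)
  if (d[1L] <= sep) stop("volume depth must exceed separation_pixels", call. = FALSE)
  zt <- seq_len(d[1L] - sep)          # shallow depth of each pair
  zb <- zt + sep
  a11 <- vol$j[zt, , , 1L, drop = FALSE]
  a21 <- vol$j[zt, , , 2L, drop = FALSE]
  a12 <- vol$j[zt, , , 3L, drop = FALSE]
  a22 <- vol$j[zt, , , 4L, drop = FALSE]
  b11 <- vol$j[zb, , , 1L, drop = FALSE]
  b21 <- vol$j[zb, , , 2L, drop = FALSE]
  b12 <- vol$j[zb, , , 3L, drop = FALSE]
  b22 <- vol$j[zb, , , 4L, drop = FALSE]
  det <- a11 * a22 - a12 * a21
  scale2 <- Mod(a11)^2 + Mod(a12)^2 + Mod(a21)^2 + Mod(a22)^2
  ok <- Mod(det) > 1e-12 * pmax(scale2, 1e-300)
  det[!ok] <- 1  # placeholder; pixels masked below
  # J(z+sep) %*% solve(J(z)), with solve(J) = adj(J)/det(J)
  out <- array(complex(1), c(length(zt), d[2L], d[3L], 4L))
  out[, , , 1L] <- (b11 * a22 - b12 * a21) / det
  out[, , , 2L] <- (b21 * a22 - b22 * a21) / det
  out[, , , 3L] <- (-b11 * a12 + b12 * a11) / det
  out[, , , 4L] <- (-b21 * a12 + b22 * a11) / det
  valid <- vol$valid[zt, , , drop = FALSE] & vol$valid[zb, , , drop = FALSE] &
    array(ok, c(length(zt), d[2L], d[3L]))
  jones_volume(out,
    wavelength = vol$wavelength,
    axial_pitch = vol$axial_pitch,
    lateral_pitch = vol$lateral_pitch,
    noise_floor = vol$noise_floor,
    separation_pixels = sep,
    valid = valid
  )
}

#' Effective signal-to-noise ratio map
#'
#' Per-pixel SNR in dB from the summed squared magnitude of the four Jones
#' elements relative to the summed per-channel noise floor:
#' \eqn{10 \log_{10}(\sum_{ij} |J_{ij}|^2 / \sum_{ij} \sigma^2_{ij})}.
#' All-zero pixels map to `-Inf` and are flagged invalid.
#'
#' @param vol A `jones_volume` whose `noise_floor` metadata is positive.
#' @return A `scalar_map` of SNR in dB on the volume grid.
#' @export
effective_snr <- function(vol) {
  stopifnot(inherits(vol, "jones_volume"))
  nf <- vol$noise_floor
  if (!all(is.finite(nf)) || any(nf <= 0)) {
    stop("noise_floor metadata must be positive and finite", call. = FALSE)
  }
  s <- Mod(vol$j[, , , 1L, drop = FALSE])^2 + Mod(vol$j[, , , 2L, drop = FALSE])^2 +
    Mod(vol$j[, , , 3L, drop = FALSE])^2 + Mod(vol$j[, , , 4L, drop = FALSE])^2
  dim(s) <- dim(vol)
  v <- 10 * log10(s / sum(nf))
  scalar_map(v, mask = is.finite(v) & vol$valid)
}
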