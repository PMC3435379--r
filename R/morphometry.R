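#' Cross-sectional area of a tissue strip
#'
#' Area of the manually segmented cross section, from either a simple closed
#' polygon in physical units (shoelace formula) or a boolean mask with pixel
#' pitches (pixel count times pixel area). The segmentation is assumed to be
#' in geometric coordinates already.
#'
#' @param boundary Two-column matrix/data frame of `(x_mm, z_mm)` polygon
#'   vertices (closed implicitly; a repeated final vertex is tolerated), or
#'   `NULL` when a mask is supplied.
#' @param mask Logical matrix, or `NULL` when a polygon is supplied.
#' @param pitch_mm `(row, col)` pixel pitches in mm, required with `mask`.
#' @return Area in mm^2 (positive).
#' @examples
#' rect <- cbind(c(0, 4, 4, 0), c(0, 0, 1, 1))
#' cross_section_area(rect)  # 4
#' @export
cross_section_area <- function(boundary = NULL, mask = NULL, pitch_mm = NULL) {
  if (!is.null(boundary)) {
    p <- as.matrix(boundary)
    stopifnot(ncol(p) == 2L, all(is.finite(p)))
    if (nrow(p) > 1L && all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (nrow(p) < 3L) stop("polygon needs at least 3 distinct vertices", call. = FALSE)
    if (.polygon_self_intersects(p)) {
      stop("polygon is self-intersecting", call. = FALSE)
    }
    x <- p[, 1L]
    z <- p[, 2L]
    xn <- c(x[-1L], x[1L])
    zn <- c(z[-1L], z[1L])
    area <- abs(sum(x * zn - xn * z)) / 2
  } else if (!is.null(mask)) {
    stopifnot(is.logical(mask), length(pitch_mm) == 2L, all(pitch_mm > 0))
    area <- sum(mask) * prod(pitch_mm)
  } else {
    stop("supply either a polygon boundary or a mask", call. = FALSE)
  }
  if (!(area > 0)) stop("degenerate segmentation: nonpositive area", call. = FALSE)
  area
}

# Segment-intersection test over all non-adjacent edge pairs (O(n^2), fine for
# manual segmentations).
.polygon_self_intersects <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1L), , drop = FALSE]
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      d1 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
      d2 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
      d3 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
      d4 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Laterally-averaged strip thickness
#'
#' Thickness as cross-sectional area divided by strip width.
#'
#' @param area Cross-sectional area in mm^2.
#' @param width Strip width in mm (default 4).
#' @return Thickness in mm.
#' @export
mean_thickness <- function(area, width = 4) {
  if (!(area > 0) || !(width > 0)) {
    stop("area and width must be positive", call. = FALSE)
  }
  area / width
}
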