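#' Jones matrix of an ideal linear retarder
#'
#' Builds the 2x2 complex Jones matrix
#' \eqn{R(\theta)\,\mathrm{diag}(e^{i\delta/2}, e^{-i\delta/2})\,R(-\theta)},
#' i.e. a lossless wave plate with phase retardation `retardation` whose fast
#' axis is oriented at `orientation` radians in the laboratory frame. This is
#' the forward model used throughout the phantom generators and the
#' retardance-estimator oracles.
#'
#' @param retardation Phase retardation \eqn{\delta} in radians; wrapped into
#'   `[0, 2*pi)`.
#' @param orientation Fast-axis orientation \eqn{\theta} in radians.
#' @return A 2x2 complex matrix. Unitary with unit-magnitude determinant.
#' @examples
#' make_linear_retarder(pi, 0)          # half-wave plate at 0 deg: diag(i, -i)
#' make_linear_retarder(pi / 2, pi / 4) # quarter-wave plate at 45 deg
#' @export
make_linear_retarder <- function(retardation, orientation) {
  stopifnot(is.finite(retardation), is.finite(orientation))
  d <- retardation %% (2 * pi)
  ct <- cos(orientation)
  st <- sin(orientation)
  rot <- matrix(c(ct, st, -st, ct), 2L, 2L)      # R(theta)
  roti <- matrix(c(ct, -st, st, ct), 2L, 2L)     # R(-theta)
  rot %*% diag(exp(c(1i, -1i) * d / 2)) %*% roti
}

# Stokes basis change matrix: s = A vec(E E^H) with s = (I, Q, U, V).
# Rows correspond to I = |Ex|^2+|Ey|^2, Q = |Ex|^2-|Ey|^2,
# U = 2 Re(Ex Ey*), V = -2 Im(Ex Ey*); columns follow the column-major
# vectorisation (ExEx*, EyEx*, ExEy*, EyEy*).
.stokes_A <- rbind(
  c(1,  0,   0,  1),
  c(1,  0,   0, -1),
  c(0,  1,   1,  0),
  c(0, 1i, -1i,  0)
)
.stokes_A_inv <- solve(.stokes_A)

#' Convert a Jones matrix to its Mueller matrix
#'
#' Uses the standard construction \eqn{M = A (J \otimes J^{*}) A^{-1}} in the
#' Stokes basis \eqn{(I, Q, U, V)}; the basis-change matrix `A` is documented
#' in the source. For unitary `J` the lower-right 3x3 block of the result is a
#' proper rotation.
#'
#' @param J 2x2 complex Jones matrix with finite entries.
#' @return 4x4 real Mueller matrix.
#' @export
jones_to_mueller <- function(J) {
  stopifnot(is.matrix(J), all(dim(J) == 2L), all(is.finite(Re(J))), all(is.finite(Im(J))))
  M <- .stokes_A %*% (J %x% Conj(J)) %*% .stokes_A_inv
  stopifnot(max(abs(Im(M))) < 1e-9 * max(1, max(abs(Re(M)))))
  Re(M)
}

#' Lu-Chipman polar decomposition of a Mueller matrix
#'
#' Factors a Mueller matrix as \eqn{M = M_\Delta M_R M_D} (depolarizer,
#' retarder, diattenuator) following Lu & Chipman, and reports the total
#' retardance \eqn{R = \arccos(\mathrm{tr}(M_R)/2 - 1)} with the arccos
#' argument clipped to `[-1, 1]` for numerical safety.
#'
#' @param M 4x4 real Mueller matrix derived from a nonsingular Jones matrix
#'   (or any physical Mueller matrix with `M[1,1] > 0`).
#' @return List with elements `retardance` (radians, in `[0, pi]`), `retarder`
#'   (4x4 Mueller of the retarder factor), `depolarizer`, `diattenuator`, and
#'   `diattenuation` (scalar magnitude).
#' @seealso [lu_chipman_retardance()] for the retardance-only accessor.
#' @export
lu_chipman_decompose <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == 4L), all(is.finite(M)))
  if (M[1L, 1L] <= 0) {
    stop("degenerate decomposition: M[1,1] must be positive", call. = FALSE)
  }
  Dvec <- M[1L, 2:4] / M[1L, 1L]
  d <- sqrt(sum(Dvec^2))
  if (d >= 1) {
    stop("degenerate decomposition: diattenuation magnitude >= 1", call. = FALSE)
  }
  # Diattenuator factor
  if (d > .Machine$double.eps) {
    Dhat <- Dvec / d
    mD <- sqrt(1 - d^2) * diag(3L) + (1 - sqrt(1 - d^2)) * (Dhat %o% Dhat)
  } else {
    mD <- diag(3L)
  }
  MD <- M[1L, 1L] * rbind(c(1, Dvec), cbind(Dvec, mD))
  Mp <- M %*% solve(MD)
  mp <- Mp[2:4, 2:4]
  mmT <- mp %*% t(mp)
  ev <- eigen(mmT, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  sq <- sqrt(ev)
  if (min(sq) < 1e-12 * max(1, max(sq))) {
    stop("degenerate decomposition: depolarizer factor is singular", call. = FALSE)
  }
  s <- if (det(mp) < 0) -1 else 1
  mDelta <- solve(mmT + (sq[1] * sq[2] + sq[2] * sq[3] + sq[3] * sq[1]) * diag(3L)) %*%
    ((sq[1] + sq[2] + sq[3]) * mmT + sq[1] * sq[2] * sq[3] * diag(3L)) * s
  MDelta <- rbind(c(1, 0, 0, 0), cbind(Mp[2:4, 1L], mDelta))
  mR <- solve(mDelta) %*% mp
  MR <- rbind(c(1, 0, 0, 0), cbind(c(0, 0, 0), mR))
  arg <- sum(diag(MR)) / 2 - 1
  ret <- acos(min(1, max(-1, arg)))
  list(
    retardance = ret,
    retarder = MR,
    depolarizer = MDelta,
    diattenuator = MD,
    diattenuation = d
  )
}

#' Retardance from the Lu-Chipman decomposition
#'
#' @inheritParams lu_chipman_decompose
#' @return List with `retardance` (radians in `[0, pi]`) and `retarder`
#'   (the Mueller retarder block \eqn{M_R}).
#' @examples
#' lc <- lu_chipman_retardance(jones_to_mueller(make_linear_retarder(0.3, 0.7)))
#' lc$retardance  # 0.3
#' @export
lu_chipman_retardance <- function(M) {
  dec <- lu_chipman_decompose(M)
  list(retardance = dec$retardance, retarder = dec$retarder)
}

#' Eigendecomposition of a Jones matrix with a fixed ordering convention
#'
#' Diagonalizes a 2x2 complex Jones matrix. The eigenpair whose eigenvalue has
#' the larger principal phase (in \eqn{(-\pi, \pi]}) is designated first; ties
#' are broken by larger modulus. A near-degenerate eigensystem
#' (\eqn{|\lambda_1 - \lambda_2| < 10^{-12} \max|\lambda|}) is flagged rather
#' than raised, since degenerate pixels are routinely skipped downstream.
#'
#' @param J 2x2 complex matrix.
#' @return List with `values` (complex length-2), `vectors` (2x2 complex,
#'   unit-norm columns), and `degenerate` (logical).
#' @export
diagonalize_jones <- function(J) {
  stopifnot(is.matrix(J), all(dim(J) == 2L))
  e <- eigen(J)
  degenerate <- abs(e$values[1L] - e$values[2L]) < 1e-12 * max(abs(e$values), 1e-300)
  ph <- Arg(e$values)
  ord <- order(ph, abs(e$values), decreasing = TRUE)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  vecs <- sweep(vecs, 2L, sqrt(colSums(Mod(vecs)^2)), "/")
  list(values = vals, vectors = vecs, degenerate = degenerate)
}

#' Stokes-axis representation of a polarization eigenvector
#'
#' Maps a complex field vector \eqn{(e_1, e_2)} to the unit Stokes vector
#' \eqn{q = |e_1|^2 - |e_2|^2}, \eqn{u = 2\,\mathrm{Re}(e_1 e_2^*)},
#' \eqn{v = -2\,\mathrm{Im}(e_1 e_2^*)}, each normalised by \eqn{\|e\|^2}.
#'
#' The two orthogonal eigenpolarizations of one retarder map to antipodal
#' points of the Poincaré sphere. With `disambiguate = TRUE` (default) the
#' representative is folded onto a fixed hemisphere — negate when `q < 0`, or
#' `q == 0 && u < 0`, or `q == u == 0 && v < 0` — so both eigenvectors yield
#' the same axis. Axis-uniformity imaging ([doau_map()]) deliberately keeps
#' the unfolded representative; see that help page.
#'
#' @param e Complex vector of length 2 with positive norm.
#' @param disambiguate Fold the axis onto the canonical hemisphere?
#' @return Numeric `c(q, u, v)` with unit norm.
#' @export
eigenvector_to_stokes <- function(e, disambiguate = TRUE) {
  stopifnot(length(e) == 2L)
  n2 <- sum(Mod(e)^2)
  if (!is.finite(n2) || n2 <= 0) stop("zero-norm eigenvector", call. = FALSE)
  cross <- e[1L] * Conj(e[2L])
  s <- c(Mod(e[1L])^2 - Mod(e[2L])^2, 2 * Re(cross), -2 * Im(cross)) / n2
  if (disambiguate) s <- .fold_hemisphere(s)
  s
}

# Canonical-hemisphere fold for an axis representative (lexicographic rule).
.fold_hemisphere <- function(s) {
  flip <- s[1L] < 0 ||
    (s[1L] == 0 && s[2L] < 0) ||
    (s[1L] == 0 && s[2L] == 0 && s[3L] < 0)
  if (flip) -s else s
}
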