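# Shared in-code fixtures for the test suite.

# Random unitary 2x2 Jones matrix (retarder times global phase).
random_unitary_jones <- function() {
  make_linear_retarder(runif(1, 0.1, pi - 0.1), runif(1, 0, pi)) *
    exp(2i * pi * runif(1))
}

# Random complex 2x2 with i.i.d. standard-normal parts.
random_complex_jones <- function() {
  matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2L, 2L)
}

# General elliptical retarder about a Poincare axis (unit 3-vector).
elliptical_retarder <- function(retardation, axis) {
  axis <- axis / sqrt(sum(axis^2))
  h <- retardation / 2
  matrix(c(
    complex(real = cos(h), imaginary = sin(h) * axis[1]),
    complex(real = -sin(h) * axis[3], imaginary = sin(h) * axis[2]),
    complex(real = sin(h) * axis[3], imaginary = sin(h) * axis[2]),
    complex(real = cos(h), imaginary = -sin(h) * axis[1])
  ), 2L, 2L)
}

# Build a "local" jones_volume directly from per-pixel retarders with given
# per-pixel retardation and Poincare-axis arrays (each (z, x, y)); used to
# feed DOAU with exactly controlled axis fields.
local_volume_from_axes <- function(ret, axes_q, axes_u, axes_v,
                                   separation_pixels = 1L) {
  d <- dim(ret)
  j <- array(complex(real = 0), c(d, 4L))
  h <- ret / 2
  nrm <- sqrt(axes_q^2 + axes_u^2 + axes_v^2)
  aq <- axes_q / nrm
  au <- axes_u / nrm
  av <- axes_v / nrm
  j[, , , 1L] <- complex(real = cos(h), imaginary = sin(h) * aq)
  j[, , , 2L] <- complex(real = -sin(h) * av, imaginary = sin(h) * au)
  j[, , , 3L] <- complex(real = sin(h) * av, imaginary = sin(h) * au)
  j[, , , 4L] <- complex(real = cos(h), imaginary = -sin(h) * aq)
  jones_volume(j, noise_floor = rep(1e-12, 4L),
               separation_pixels = separation_pixels)
}

# Uniform draws on the unit sphere.
runif_sphere <- function(n) {
  w <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - w^2)
  cbind(s * cos(phi), s * sin(phi), w)
}
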