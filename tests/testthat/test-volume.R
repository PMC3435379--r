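# Brute-force reference for the phase-aligned moving average: explicit loops
# over windows, same reference-element rule as the production code.
brute_force_average <- function(vol, kernel) {
  d <- dim(vol)
  hz <- (kernel[1] - 1) %/% 2
  hx <- (kernel[2] - 1) %/% 2
  out <- vol$j
  for (y in seq_len(d[3])) {
    for (z in seq_len(d[1])) {
      for (x in seq_len(d[2])) {
        Jc <- vol$j[z, x, y, ]
        ref <- which.max(Mod(Jc))
        acc <- complex(real = numeric(4))
        cnt <- 0L
        for (zz in max(1, z - hz):min(d[1], z + hz)) {
          for (xx in max(1, x - hx):min(d[2], x + hx)) {
            Jk <- vol$j[zz, xx, y, ]
            acc <- acc + Jk * exp(-1i * Arg(Jk[ref]))
            cnt <- cnt + 1L
          }
        }
        out[z, x, y, ] <- acc / cnt * exp(1i * Arg(Jc[ref]))
      }
    }
  }
  vol$j <- out
  vol
}

test_that("moving average: identity cases and kernel validation", {
  set.seed(10)
  J0 <- random_unitary_jones()
  j <- array(complex(real = 0), c(6, 6, 2, 4))
  for (k in 1:4) j[, , , k] <- J0[c(1, 2, 3, 4)][k]
  vol <- jones_volume(j, noise_floor = rep(1e-3, 4))
  # constant volume is unchanged by any kernel
  av <- moving_average_jones(vol, c(3, 3))
  expect_equal(av$j, vol$j, tolerance = 1e-12)
  # kernel (1,1) is the identity transform
  expect_equal(moving_average_jones(vol, c(1, 1))$j, vol$j)
  expect_error(moving_average_jones(vol, c(2, 3)), "odd")
  expect_error(moving_average_jones(vol, c(7, 3)), "larger than image")
  # noise floor tracks the averaging gain
  expect_equal(av$noise_floor, rep(1e-3 / 9, 4))
})

test_that("moving average of a ramp matches the brute-force windowed mean", {
  # 1D ramp in one Jones element: centered 3-point means
  j <- array(complex(real = 0), c(9, 1, 1, 4))
  j[, 1, 1, 1] <- 1:9 + 0i
  vol <- jones_volume(j, noise_floor = rep(1, 4))
  av <- moving_average_jones(vol, c(3, 1))
  direct <- c(mean(1:2), vapply(2:8, function(i) mean((i - 1):(i + 1)), 0), mean(8:9))
  expect_equal(Re(av$j[, 1, 1, 1]), direct, tolerance = 1e-12)
  # random speckle-phase volume against the loop reference
  set.seed(11)
  d <- c(7, 8, 2)
  j <- array(complex(real = rnorm(prod(d) * 4), imaginary = rnorm(prod(d) * 4)),
             c(d, 4))
  vol <- jones_volume(j, noise_floor = rep(1, 4))
  expect_equal(moving_average_jones(vol, c(3, 5))$j,
               brute_force_average(vol, c(3, 5))$j, tolerance = 1e-10)
})

test_that("local Jones matrices recover per-slab retarders", {
  # homogeneous retarder phantom: every local matrix has eigenvalue phase
  # separation rho * separation
  rho <- 0.05  # rad per pixel of round-trip retardation
  dn <- rho * 1.31e-6 / (4 * pi * 6.125e-6)
  vol <- simulate_jones_volume(phantom_spec(
    dims = c(24, 6, 2), dn = dn, snr_db = Inf, rng_seed = 3
  ))
  loc <- local_jones(vol, 8L)
  expect_equal(dim(loc)[1], 16)
  expect_equal(separation_depth(loc), 8 * 6.125e-6)
  r <- local_retardance(loc)
  expect_true(all(r$mask))
  expect_equal(unname(r$values[r$mask]), rep(rho * 8, sum(r$mask)), tolerance = 1e-9)
  # identity volume: local matrices are identity
  j <- array(complex(real = 0), c(12, 4, 1, 4))
  j[, , , 1] <- 1 + 0i
  j[, , , 4] <- 1 + 0i
  idv <- jones_volume(j, noise_floor = rep(1e-6, 4))
  li <- local_jones(idv, 4L)
  expect_equal(as.vector(li$j[, , , 1]), rep(1 + 0i, 32))
  expect_equal(max(Mod(li$j[, , , 2])), 0)
  expect_error(local_jones(idv, 12L), "depth")
})

test_that("two-layer phantom: local matrices match each layer away from the boundary", {
  dn <- 1.5e-3
  per_pix <- 4 * pi * dn * 6.125e-6 / 1.31e-6
  dims <- c(40, 4, 1)
  dnmap <- array(dn, dims)
  vol <- simulate_jones_volume(phantom_spec(
    dims = dims, dn = dnmap,
    axis = list(type = "uniform", axis = c(1, 0, 0)), snr_db = Inf, rng_seed = 4
  ))
  # second phantom with the axis rotated in the deep half
  j2 <- simulate_jones_volume(phantom_spec(
    dims = dims, dn = dnmap,
    axis = list(type = "two_domain", axis1 = c(1, 0, 0), axis2 = c(0, 1, 0),
                split_frac = 0.5),
    snr_db = Inf, rng_seed = 4
  ))
  loc <- local_jones(j2, 8L)
  r <- local_retardance(loc)
  # retardance is axis-independent here, so both domains still show the rate
  expect_equal(unname(r$values[r$mask]), rep(per_pix * 8, sum(r$mask)),
               tolerance = 1e-9)
  # axes differ between the two lateral domains
  ed1 <- diagonalize_jones(matrix(loc$j[5, 1, 1, ], 2))
  ed2 <- diagonalize_jones(matrix(loc$j[5, 4, 1, ], 2))
  s1 <- eigenvector_to_stokes(ed1$vectors[, 1])
  s2 <- eigenvector_to_stokes(ed2$vectors[, 1])
  expect_gt(sum(abs(s1 - s2)), 0.5)
})

test_that("effective SNR: zero pixels, unity ratio, generator round trip", {
  j <- array(complex(real = 0), c(4, 4, 1, 4))
  vol <- jones_volume(j, noise_floor = rep(0.25, 4))
  s <- effective_snr(vol)
  expect_true(all(s$values == -Inf))
  expect_true(all(!s$mask))
  # |J_ij|^2 = sigma_ij^2 in every channel gives 0 dB
  j[, , , ] <- 0.5 + 0i
  vol <- jones_volume(j, noise_floor = rep(0.25, 4))
  expect_equal(unname(effective_snr(vol)$values[1, 1, 1]), 0, tolerance = 1e-12)
  # phantom generated at nominal 30 dB
  v <- simulate_jones_volume(phantom_spec(dims = c(30, 30, 2), dn = 1e-3,
                                          snr_db = 30, rng_seed = 9))
  sm <- effective_snr(v)
  expect_equal(mean(sm$values), 30, tolerance = 0.5)
  expect_error(effective_snr(jones_volume(j, noise_floor = 0)), "noise_floor")
})
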