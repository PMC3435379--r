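test_that("generators are bit-reproducible given their seeds", {
  sp <- phantom_spec(dims = c(16, 8, 2), dn = 1e-3, snr_db = 25, rng_seed = 123)
  expect_identical(simulate_jones_volume(sp)$j, simulate_jones_volume(sp)$j)
  r1 <- simulate_stress_strain(0.02, 40, 3.2, noise_frac = 0.01, rng_seed = 9)
  r2 <- simulate_stress_strain(0.02, 40, 3.2, noise_frac = 0.01, rng_seed = 9)
  expect_identical(r1$data, r2$data)
  s1 <- simulate_cohort(cohort_spec(rng_seed = 5), emit = "truth")
  s2 <- simulate_cohort(cohort_spec(rng_seed = 5), emit = "truth")
  expect_identical(s1$truth, s2$truth)
  # generators do not disturb the caller's RNG stream
  set.seed(42)
  before <- runif(1)
  set.seed(42)
  invisible(simulate_jones_volume(sp))
  expect_identical(runif(1), before)
})

test_that("zero-birefringence noiseless phantom is identity up to an A-scan phasor", {
  v <- simulate_jones_volume(phantom_spec(dims = c(10, 4, 2), dn = 0,
                                          snr_db = Inf, rng_seed = 2))
  expect_lt(max(Mod(v$j[, , , 2])), 1e-12)
  expect_lt(max(Mod(v$j[, , , 3])), 1e-12)
  expect_equal(Mod(v$j[, , , 1]), array(1, c(10, 4, 2)), tolerance = 1e-12)
  expect_equal(v$j[, , , 1], v$j[, , , 4], tolerance = 1e-12)
})

test_that("uniform phantom local retardance equals the forward-model closed form", {
  dn <- 2.4e-3
  v <- simulate_jones_volume(phantom_spec(dims = c(30, 6, 1), dn = dn,
                                          snr_db = Inf, rng_seed = 3))
  r <- local_retardance(local_jones(v, 8L))
  expect_equal(unname(r$values[r$mask]),
               rep(4 * pi * dn * 8 * 6.125e-6 / 1.31e-6, sum(r$mask)),
               tolerance = 1e-9)
})

test_that("wrap guard refuses unmeasurable birefringence and reports the depth", {
  # dn above lambda / (4 sep pitch) wraps the local retardance past pi
  dn_bad <- 1.31e-6 / (4 * 8 * 6.125e-6) * 1.1
  expect_error(
    simulate_jones_volume(phantom_spec(dims = c(20, 4, 1), dn = dn_bad,
                                       snr_db = Inf, rng_seed = 1)),
    "wrap guard"
  )
  # a deep high-birefringence layer is caught too
  dnmap <- array(1e-3, c(30, 4, 1))
  dnmap[15:30, , ] <- dn_bad
  expect_error(
    simulate_jones_volume(phantom_spec(dims = c(30, 4, 1), dn = dnmap,
                                       snr_db = Inf, rng_seed = 1)),
    "depth 1[2-5]"
  )
})

test_that("two-domain phantom: DOAU near 1 inside domains, dips at the boundary", {
  v <- simulate_jones_volume(phantom_spec(
    dims = c(30, 40, 1), dn = 2e-3,
    axis = list(type = "two_domain", axis1 = c(1, 0, 0), axis2 = c(0, 1, 0),
                split_frac = 0.5),
    snr_db = Inf, rng_seed = 7
  ))
  doau <- doau_map(local_jones(v, 8L), c(5, 9))
  inside <- doau$values[8:15, c(5:14, 27:36), 1]
  boundary <- doau$values[8:15, 21, 1]
  expect_gt(min(inside), 0.999)
  expect_lt(min(boundary), 0.8)
})

test_that("stress-strain protocol constants are honoured", {
  rec <- simulate_stress_strain(0.02, 40, 3.2, noise_frac = 0, rng_seed = 1)
  eps <- rec$data$displacement_mm / rec$gauge_length_mm
  expect_equal(max(eps), 0.18)
  # preconditioning reaches exactly 6.5% strain, ten times
  peaks <- sum(abs(eps - 0.065) < 1e-9 &
                 c(diff(eps) < 0, TRUE) & c(TRUE, diff(eps) > 0))
  expect_gte(peaks, 10)
  expect_false(is.unsorted(rec$data$time_s))
  # noiseless force follows the pseudo-elastic curve exactly
  f_model <- rec$pre_load_n + rec$area_mm2 * 0.02 * expm1(40 * eps)
  expect_equal(rec$data$force_N, f_model, tolerance = 1e-12)
})

test_that("cohort latent construction hits its designed correlations", {
  # near-noiseless limit: target r -> 1 gives empirical r -> 1
  s_hi <- simulate_cohort(cohort_spec(
    target_correlation = c(A = 0.999, B = 0.999, C = 0.999, D = 0.999),
    rng_seed = 11
  ), emit = "truth")
  bb <- s_hi$truth[s_hi$truth$region == "B", ]
  expect_gt(cor(bb$mean_birefringence, bb$structural_stiffness), 0.99)
  # null targets are centred at zero over seeds
  r0 <- vapply(1:60, function(s) {
    tr <- simulate_cohort(cohort_spec(
      target_correlation = c(A = 0, B = 0, C = 0, D = 0), rng_seed = 100 + s
    ), emit = "truth")$truth
    bb <- tr[tr$region == "B", ]
    cor(bb$mean_birefringence, bb$structural_stiffness)
  }, 0)
  expect_lt(abs(mean(r0)), 0.07)  # SE ~ 1/sqrt(19 * 60) ~ 0.03
  # convergence of the construction at large n
  s_big <- simulate_cohort(cohort_spec(n_samples = 500L, rng_seed = 13),
                           emit = "truth")
  bb <- s_big$truth[s_big$truth$region == "B", ]
  expect_equal(cor(bb$mean_birefringence, bb$structural_stiffness), 0.8242,
               tolerance = 0.05)
  aa <- s_big$truth[s_big$truth$region == "A", ]
  expect_equal(cor(aa$mean_birefringence, aa$structural_stiffness), 0.5389,
               tolerance = 0.1)
  # power is negatively related to organization
  expect_lt(cor(bb$mean_birefringence, bb$power_b), -0.2)
})

test_that("calibration: mean empirical r at n = 19 is close to the 0.8 target", {
  spec <- cohort_spec(target_correlation = c(A = 0.8, B = 0.8, C = 0.8, D = 0.8))
  rs <- vapply(1:150, function(s) {
    spec$rng_seed <- 2000L + s
    tr <- simulate_cohort(spec, emit = "truth")$truth
    bb <- tr[tr$region == "B", ]
    cor(bb$mean_birefringence, bb$structural_stiffness)
  }, 0)
  # small-sample attenuation of the sample correlation is ~ r(1-r^2)/(2n) ~ 0.008
  expect_lt(abs(mean(rs) - 0.8), 0.02)
})
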