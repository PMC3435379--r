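test_that("stress and strain conversions use initial area and gauge length", {
  rec <- stress_strain_record(
    data.frame(time_s = c(0, 1), displacement_mm = c(0, 0.325),
               force_N = c(0.1, 0.1)),
    area_mm2 = 2
  )
  ss <- compute_stress_strain(rec, ramp_only = FALSE)
  expect_equal(ss$stress_mpa, c(0.05, 0.05))   # 0.1 N / 2 mm^2 = 0.05 MPa
  expect_equal(ss$strain[2], 0.065)            # 0.325 mm / 5 mm
  expect_error(stress_strain_record(rec$data, area_mm2 = 0), "area")
  expect_error(
    stress_strain_record(data.frame(time_s = c(1, 0), displacement_mm = c(0, 0),
                                    force_N = c(0, 0)), area_mm2 = 1),
    "nondecreasing"
  )
})

test_that("exponential fit recovers exact model data to machine-level accuracy", {
  eps <- seq(0, 0.065, length.out = 80)
  a <- 0.02; b <- 40
  sig <- a * expm1(b * eps)
  f <- fit_exponential(eps, sig)
  expect_equal(f$a, a, tolerance = 1e-6)
  expect_equal(f$b, b, tolerance = 1e-6)
  expect_lt(f$fit_rmse, 1e-10)
  # with a known stress datum the offset curve is fitted exactly too
  f2 <- fit_exponential(eps, 0.0125 + sig, stress_datum = 0.0125)
  expect_equal(f2$b, b, tolerance = 1e-6)
  expect_error(fit_exponential(eps[1:5], sig[1:5]), "at least 10")
})

test_that("small-b limit: fitting near-linear data recovers the product a*b", {
  k <- 0.5
  eps <- seq(0, 0.065, length.out = 60)
  f <- fit_exponential(eps, k * eps)
  expect_lt(abs(f$a * f$b - k) / k, 0.01)
})

test_that("fit is scale-equivariant: stress scale moves a, not b", {
  set.seed(60)
  eps <- seq(0, 0.065, length.out = 70)
  sig <- 0.015 * expm1(35 * eps) * (1 + 0.005 * rnorm(70))
  f1 <- fit_exponential(eps, sig)
  f3 <- fit_exponential(eps, 3 * sig)
  expect_equal(f3$a, 3 * f1$a, tolerance = 1e-6)
  expect_equal(f3$b, f1$b, tolerance = 1e-6)
  expect_equal(f3$tangent_modulus_0, 3 * f1$tangent_modulus_0, tolerance = 1e-6)
})

test_that("elastic-parameter identities hold exactly", {
  f <- fit_exponential(seq(0, 0.065, length.out = 50),
                       0.005 * expm1(50 * seq(0, 0.065, length.out = 50)))
  # tangent modulus at 0% strain is a*b (0.005 * 50 = 0.25 MPa)
  expect_equal(tangent_modulus(f, 0), f$a * f$b)
  expect_equal(tangent_modulus(f, 0), 0.25, tolerance = 1e-6)
  # ratio identity E(eps)/E(0) = exp(b eps)
  expect_equal(tangent_modulus(f, 0.03) / tangent_modulus(f, 0),
               exp(f$b * 0.03), tolerance = 1e-12)
  # structural stiffness is the exact product
  expect_equal(structural_stiffness(0.25, 0.8), 0.2)
  expect_equal(structural_stiffness(0.25, 1.6), 2 * structural_stiffness(0.25, 0.8))
  expect_error(structural_stiffness(-1, 0.8), "positive")
  # power equals the finite-difference slope of tangent modulus against stress
  eps <- seq(0, 0.065, length.out = 400)
  E <- tangent_modulus(f, eps)
  sig <- f$a * expm1(f$b * eps)
  slope <- diff(E) / diff(sig)
  expect_equal(mean(slope), exponential_power(f), tolerance = 1e-6)
  expect_equal(exponential_power(f), f$b)
})

test_that("protocol-rate noisy records recover b and E0 tightly", {
  res <- vapply(1:25, function(s) {
    rec <- simulate_stress_strain(0.02, 40, area_mm2 = 3.2, noise_frac = 0.01,
                                  rng_seed = 7000 + s)
    ss <- compute_stress_strain(rec)
    f <- fit_exponential(ss$strain, ss$stress_mpa,
                         stress_datum = rec$pre_load_n / rec$area_mm2)
    c(f$b, f$tangent_modulus_0)
  }, c(0, 0))
  expect_lt(median(abs(res[1, ] / 40 - 1)), 0.02)
  expect_lt(median(abs(res[2, ] / 0.8 - 1)), 0.05)
})

test_that("final-ramp extraction honours the loading protocol", {
  rec <- simulate_stress_strain(0.02, 40, area_mm2 = 3.2, noise_frac = 0,
                                rng_seed = 1)
  ramp <- extract_final_ramp(rec)
  # ramp spans 0 to 18% strain at 1.8 mm/min over a 5 mm gauge: 30 s
  expect_equal(max(ramp$data$displacement_mm) / rec$gauge_length_mm, 0.18)
  expect_equal(min(ramp$data$displacement_mm), 0)
  expect_equal(diff(range(ramp$data$time_s)), 30, tolerance = 0.2)
  expect_false(is.unsorted(ramp$data$displacement_mm))
})
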