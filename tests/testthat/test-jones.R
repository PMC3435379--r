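test_that("linear retarder closed forms: identity, half-wave plate, unitarity", {
  expect_equal(make_linear_retarder(0, 1.234), diag(2) + 0i, tolerance = 1e-12)
  hwp <- make_linear_retarder(pi, 0)
  expect_equal(hwp, diag(c(1i, -1i)), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    J <- make_linear_retarder(runif(1, 0, 2 * pi), runif(1, -pi, pi))
    expect_equal(Conj(t(J)) %*% J, diag(2) + 0i, tolerance = 1e-12)
    expect_equal(Mod(J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]), 1, tolerance = 1e-12)
  }
})

test_that("quarter-wave retarder eigenvalue phase separation matches construction", {
  # independent oracle: base::eigen on the constructed matrix
  J <- make_linear_retarder(pi / 2, pi / 4)
  ev <- eigen(J, only.values = TRUE)$values
  dphi <- abs(Arg(ev[1] * Conj(ev[2])))
  expect_equal(dphi, pi / 2, tolerance = 1e-9)
})

test_that("Jones-to-Mueller map: identity, quarter-wave plate, multiplicativity, rotation block", {
  expect_equal(jones_to_mueller(diag(2) + 0i), diag(4), tolerance = 1e-12)
  # tabulated Mueller matrix of a linear retarder at 0 deg: the UV block is a
  # rotation by the retardation; for a QWP the UU term vanishes and the UV
  # off-diagonal terms are +/-1 with opposite signs
  M <- jones_to_mueller(make_linear_retarder(pi / 2, 0))
  expect_equal(M[1:2, 1:2], diag(2), tolerance = 1e-9)
  expect_equal(M[3, 3], 0, tolerance = 1e-9)
  expect_equal(M[4, 4], 0, tolerance = 1e-9)
  expect_equal(abs(M[3, 4]), 1, tolerance = 1e-9)
  expect_equal(M[3, 4], -M[4, 3], tolerance = 1e-9)
  set.seed(2)
  for (i in 1:20) {
    J1 <- random_complex_jones()
    J2 <- random_complex_jones()
    expect_equal(jones_to_mueller(J1 %*% J2),
                 jones_to_mueller(J1) %*% jones_to_mueller(J2),
                 tolerance = 1e-9)
    U <- random_unitary_jones()
    blk <- jones_to_mueller(U)[2:4, 2:4]
    expect_equal(det(blk), 1, tolerance = 1e-9)
  }
})

test_that("Lu-Chipman retardance recovers the construction parameter of pure retarders", {
  set.seed(3)
  for (i in 1:25) {
    d <- runif(1, 0.01, pi - 0.01)
    th <- runif(1, 0, pi)
    lc <- lu_chipman_retardance(jones_to_mueller(make_linear_retarder(d, th)))
    expect_equal(lc$retardance, d, tolerance = 1e-9)
    # retarder block of a pure retarder reproduces the full Mueller matrix
    expect_equal(lc$retarder, jones_to_mueller(make_linear_retarder(d, th)),
                 tolerance = 1e-8)
  }
  expect_equal(lu_chipman_retardance(diag(4))$retardance, 0, tolerance = 1e-12)
})

test_that("Lu-Chipman retardance of a pure diattenuator is zero", {
  # partial polarizer: real diagonal Jones matrix, no retardation
  M <- jones_to_mueller(diag(c(1, 0.3)) + 0i)
  expect_equal(lu_chipman_retardance(M)$retardance, 0, tolerance = 1e-9)
  # rotated diattenuator
  U <- matrix(c(cos(0.4), sin(0.4), -sin(0.4), cos(0.4)), 2) + 0i
  M2 <- jones_to_mueller(U %*% diag(c(1, 0.5)) %*% t(Conj(U)))
  expect_equal(lu_chipman_retardance(M2)$retardance, 0, tolerance = 1e-9)
})

test_that("Lu-Chipman retardance is invariant under global phase of the Jones matrix", {
  set.seed(4)
  for (i in 1:10) {
    J <- random_complex_jones()
    r1 <- lu_chipman_retardance(jones_to_mueller(J))$retardance
    r2 <- lu_chipman_retardance(jones_to_mueller(J * exp(2i * pi * runif(1))))$retardance
    expect_equal(r1, r2, tolerance = 1e-9)
  }
})

test_that("degenerate decompositions are signalled", {
  # full polarizer: diattenuation magnitude 1
  expect_error(lu_chipman_decompose(jones_to_mueller(diag(c(1, 0)) + 0i)),
               "degenerate")
})

test_that("Jones diagonalization: closed forms, ordering, degeneracy flag", {
  e <- diagonalize_jones(diag(c(1i, -1i)))
  expect_false(e$degenerate)
  expect_equal(sort(Arg(e$values)), c(-pi / 2, pi / 2), tolerance = 1e-12)
  expect_equal(abs(e$vectors[, 1]), c(1, 0), tolerance = 1e-12)
  # eigenvalue phase difference equals the construction retardation
  e2 <- diagonalize_jones(make_linear_retarder(0.8, 0.5))
  expect_equal(abs(Arg(e2$values[1] * Conj(e2$values[2]))), 0.8, tolerance = 1e-9)
  # first eigenvalue has the larger phase
  expect_gte(Arg(e2$values[1]), Arg(e2$values[2]))
  expect_true(diagonalize_jones(diag(2) + 0i)$degenerate)
})

test_that("eigenvector Stokes map: cardinal states and hemisphere disambiguation", {
  expect_equal(eigenvector_to_stokes(c(1, 0)), c(1, 0, 0))
  expect_equal(eigenvector_to_stokes(c(1, 1) / sqrt(2)), c(0, 1, 0), tolerance = 1e-12)
  # (0, 1) is the antipode (-1, 0, 0); folding maps it back to (1, 0, 0)
  expect_equal(eigenvector_to_stokes(c(0, 1)), c(1, 0, 0))
  expect_equal(eigenvector_to_stokes(c(0, 1), disambiguate = FALSE), c(-1, 0, 0))
  expect_error(eigenvector_to_stokes(c(0, 0)), "zero")
  # the two eigenvectors of any nondegenerate unitary matrix give one axis
  set.seed(5)
  for (i in 1:15) {
    U <- random_unitary_jones()
    ed <- diagonalize_jones(U)
    s1 <- eigenvector_to_stokes(ed$vectors[, 1])
    s2 <- eigenvector_to_stokes(ed$vectors[, 2])
    expect_equal(s1, s2, tolerance = 1e-9)
    expect_equal(sum(s1^2), 1, tolerance = 1e-9)
  }
})
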