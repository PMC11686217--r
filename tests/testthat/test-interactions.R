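test_that("Zeeman term reproduces the geomagnetic Larmor frequency", {
  expect_equal(signif(larmor_frequency(50), 2), 1.4)
  ops <- pair_ops()
  H <- zeeman_term(field_vector(50, c(0, 0, 1)), ops)
  ev <- sort(Re(eigen(H, only.values = TRUE)$values))
  # per-electron splitting gamma_e |B|, so extreme eigenvalues at +/- omega
  omega <- 2 * pi * larmor_frequency(50)
  expect_equal(max(ev), omega, tolerance = 1e-10)
  # zero field and linearity
  expect_equal(max(abs(zeeman_term(field_vector(0, c(0, 0, 1)), ops))), 0)
  H2 <- zeeman_term(field_vector(100, c(0, 0, 1)), ops)
  expect_equal(sort(Re(eigen(H2, only.values = TRUE)$values)), 2 * ev,
               tolerance = 1e-12)
})

test_that("hyperfine term: trace, zero case, isotropic closed form", {
  ops1 <- spin_operators(spin_system(1))
  A <- diag(c(-2.6, -2.6, 49.2))
  expect_equal(sum(diag(A)), 44.0, tolerance = 1e-12)
  H <- hyperfine_term(list(A), ops1)
  expect_lt(max(abs(H - Conj(t(H)))), 1e-10)
  expect_equal(max(abs(hyperfine_term(list(matrix(0, 3, 3)), ops1))), 0)
  expect_error(hyperfine_term(list(A, A), ops1), "tensors")
  # isotropic A, I = 1/2: eigenvalues A/4 (x3) and -3A/4 per second electron
  opsh <- spin_operators(spin_system(1 / 2))
  a <- 10
  Hi <- hyperfine_term(list(diag(a, 3)), opsh)
  ev <- sort(unique(round(Re(eigen(Hi, only.values = TRUE)$values) /
                            (2 * pi), 9)))
  expect_equal(ev, c(-3 * a / 4, a / 4), tolerance = 1e-9)
})

test_that("point-dipole tensor: span, trace, r^-3 law", {
  D <- point_dipole_tensor(c(4.5, 0, 0))
  pv <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values)
  span_ghz <- (max(pv) - min(pv)) / 1e3
  expect_equal(signif(span_ghz, 2), 1.7)   # 3d at contact distance
  expect_lt(abs(sum(diag(D))), 1e-9 * norm(D, "F"))
  # principal values {-2d, d, d} with the unique axis along the displacement
  d <- dipolar_coupling(4.5, "MHz")
  expect_equal(pv, c(-2 * d, d, d), tolerance = 1e-9)
  D2 <- point_dipole_tensor(c(9, 0, 0))
  expect_equal(D2, D / 8, tolerance = 1e-12)
  expect_error(point_dipole_tensor(c(0, 0, 0)), "zero-length")
})

test_that("distributed dipole tensor matches the brute-force weighted sum", {
  # single site per radical collapses to the point-dipole tensor
  s1 <- tibble::tibble(x = 0, y = 0, z = 0, population = 1)
  s2 <- tibble::tibble(x = 4.56, y = 0, z = 0, population = 1)
  expect_equal(distributed_dipole_tensor(s1, s2),
               point_dipole_tensor(c(4.56, 0, 0)), tolerance = 1e-12)
  # two sites each vs hand-computed sum
  d1 <- tibble::tibble(x = c(0, 1), y = c(0, 0.5), z = 0,
                       population = c(0.7, 0.3))
  d2 <- tibble::tibble(x = c(4, 5), y = c(0.2, -0.4), z = c(0.3, 0),
                       population = c(0.4, 0.6))
  Dref <- matrix(0, 3, 3)
  for (i in 1:2) for (j in 1:2) {
    dr <- c(d2$x[j] - d1$x[i], d2$y[j] - d1$y[i], d2$z[j] - d1$z[i])
    Dref <- Dref + d1$population[i] * d2$population[j] *
      point_dipole_tensor(dr)
  }
  expect_equal(distributed_dipole_tensor(d1, d2), Dref, tolerance = 1e-12)
  # non-normalized populations rejected
  bad <- tibble::tibble(x = c(0, 1), y = 0, z = 0, population = c(0.6, 0.5))
  expect_error(distributed_dipole_tensor(bad, s2), "sum to 1")
  # coincident cross-radical sites rejected
  expect_error(distributed_dipole_tensor(s1, s1), "coincident")
})

test_that("dipolar term commutes with the singlet projector", {
  ops <- pair_ops()
  pr <- electronic_projectors(ops)
  D <- point_dipole_tensor(c(4.56, 0, 0))
  H <- dipolar_term(D, ops)
  expect_lt(max(abs(H %*% pr$PS - pr$PS %*% H)), 1e-10)
  expect_equal(max(abs(dipolar_term(matrix(0, 3, 3), ops))), 0)
  expect_error(dipolar_term(diag(c(1, 1, 1)), ops), "traceless")
  # triplet-manifold eigenvalues from a direct 4x4 diagonalization
  evH <- sort(Re(eigen(H, only.values = TRUE)$values))
  d <- 2 * pi * dipolar_coupling(4.56, "MHz")
  # H = sum_ij D_ij S1_i S2_j with D = d*diag(-2,1,1): triplet levels
  # {-d/4 ... } -- compare against direct contraction eigenvalues
  expect_lt(max(abs(sort(evH) -
                      sort(Re(eigen(dipolar_term(D, ops),
                                    only.values = TRUE)$values)))), 1e-12)
  # singlet eigenvalue is 0 (EED acts only within the triplet manifold)
  psv <- eigen(pr$PS, symmetric = TRUE)
  vs <- psv$vectors[, which.max(Re(psv$values))]
  expect_lt(abs(Conj(vs) %*% H %*% vs), 1e-10)
})

test_that("exchange term: splitting and commutation", {
  ops <- pair_ops()
  pr <- electronic_projectors(ops)
  J <- 7
  H <- exchange_term(J, ops)
  ev <- sort(unique(round(Re(eigen(H, only.values = TRUE)$values) /
                            (2 * pi), 9)))
  expect_equal(ev, c(-J / 2, 3 * J / 2), tolerance = 1e-9)
  expect_lt(max(abs(H %*% pr$PS - pr$PS %*% H)), 1e-10)
  expect_equal(max(abs(exchange_term(0, ops))), 0)
})

test_that("yields are invariant under a global frame rotation", {
  cfg <- toy_cfg()
  R3 <- rot_about(c(1, 2, 0.5), 1.1)
  cfg_rot <- rotate_config(cfg, R3)
  dirs <- as.matrix(fibonacci_sphere(12)[, c("x", "y", "z")])
  y0 <- zenospin:::.yield_batch(cfg, dirs)$phi_s
  y1 <- zenospin:::.yield_batch(cfg_rot, dirs %*% t(R3))$phi_s
  expect_equal(y1, y0, tolerance = 1e-8)
})

test_that("large separations converge to the hyperfine-only limit", {
  dirs <- as.matrix(fibonacci_sphere(6)[, c("x", "y", "z")])
  cfg_far <- toy_cfg(r = 400)
  cfg_hf <- toy_cfg(); cfg_hf$displacement <- NULL   # no EED at all
  y_far <- zenospin:::.yield_batch(cfg_far, dirs)$phi_s
  y_hf <- zenospin:::.yield_batch(cfg_hf, dirs)$phi_s
  expect_equal(y_far, y_hf, tolerance = 1e-3)
  # and the dipolar norm itself vanishes as r^-3
  expect_lt(norm(point_dipole_tensor(c(400, 0, 0)), "F"), 1e-2)
})
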