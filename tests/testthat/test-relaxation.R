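test_that("spectral density: analytic Lorentzian against quadrature", {
  expect_equal(spectral_density(0, covariance = 3, tau_c_ns = 2),
               3 * 2e-3 + 0i)
  expect_lt(Mod(spectral_density(1e9, covariance = 1, tau_c_ns = 1)), 1e-5)
  # complex omega from a reactive eigenvalue pair vs numerical quadrature
  omega <- 40 - 15i   # decaying difference (Im < 0)
  tau_c <- 1e-3
  nq <- 200000
  ts <- seq(0, 0.15, length.out = nq + 1)
  g <- exp(-ts / tau_c) * exp(1i * omega * ts)
  w <- c(1, rep(c(4, 2), nq / 2 - 1), 4, 1)
  quad <- sum(w * g) * diff(ts)[1] / 3
  expect_equal(spectral_density(omega, 1, 1), quad, tolerance = 1e-8)
  expect_error(spectral_density(-2000i, 1, 1), "divergent")
})

test_that("random-field channels have the stated structure", {
  ops <- pair_ops()
  ch <- rfr_channels(ops, gamma = 1, tau_c_ns = 1)
  expect_length(ch$ops, 6)
  expect_equal(diag(ch$cov), rep(1000, 6))     # gamma / tau_c
  expect_equal(ch$cov - diag(diag(ch$cov)), matrix(0, 6, 6))  # uncorrelated
  expect_length(rfr_channels(ops, gamma = 0)$ops, 0)
})

test_that("zero-variance channels contribute nothing", {
  cfg <- toy_cfg()
  ops <- spin_operators(cfg$system)
  pr <- electronic_projectors(ops)
  gen <- reactive_liouvillian(spin_hamiltonian(cfg, ops),
                              haberkorn_operator(cfg$rates, pr))
  R <- nz_superoperator(rfr_channels(ops, gamma = 0), gen)
  expect_equal(max(abs(R$R)), 0)
  R2 <- nz_superoperator(scalar_fluctuation_channel(
    ops, "eed_amplitude", variance = 0, axis = c(1, 0, 0)), gen)
  expect_equal(max(abs(R2$R)), 0)
})

test_that("NZ superoperator matches the quadrature oracle", {
  # small reactive system: electron pair, Zeeman + dipolar, modest rates
  ops <- pair_ops()
  pr <- electronic_projectors(ops)
  H <- zeeman_term(field_vector(500, c(0, 0, 1)), ops) +
    dipolar_term(point_dipole_tensor(c(15, 0, 0)), ops)
  K <- haberkorn_operator(reaction_rates(20, 2), pr)
  gen <- reactive_liouvillian(H, K)
  ch <- rfr_channels(ops, gamma = 0.5, tau_c_ns = 1)
  R <- nz_superoperator(ch, gen)$R
  Rq <- nz_quadrature_oracle(ch$ops, ch$cov, ch$tau_c, gen$L)
  expect_lt(max(abs(R - Rq)) / max(abs(R)), 1e-6)
})

test_that("K = 0 limit reproduces the Redfield tensor", {
  # with no recombination the memory integral uses the coherent propagator:
  # quadrature of the textbook (non-secular, Schroedinger-picture) Redfield
  # construction must agree entrywise
  ops <- pair_ops()
  H <- zeeman_term(field_vector(300, c(0, 1, 1)), ops) +
    dipolar_term(point_dipole_tensor(c(12, 0, 0)), ops)
  gen <- reactive_liouvillian(H, matrix(0i, 4, 4))
  ch <- rfr_channels(ops, gamma = 0.3, tau_c_ns = 1)
  R <- nz_superoperator(ch, gen)$R
  Rq <- nz_quadrature_oracle(ch$ops, ch$cov, ch$tau_c, gen$L)
  expect_lt(max(abs(R - Rq)), 1e-8 * max(abs(R)))
  # relaxation alone must not create or destroy population
  vid <- as.vector(diag(4) + 0i)
  expect_lt(max(abs(Conj(vid) %*% R)), 1e-8 * max(abs(R)))
})

test_that("random fields relax a bare pair to the analytic Bloch limit", {
  # H = 0, K = 0: each electron depolarizes independently; the singlet
  # probability relaxes from p0 to 1/4 at rate 4 gamma
  ops <- pair_ops()
  gamma <- 0.8
  ch <- rfr_channels(ops, gamma = gamma, tau_c_ns = 1)
  gen <- reactive_liouvillian(matrix(0i, 4, 4), matrix(0i, 4, 4))
  R <- nz_superoperator(ch, gen)
  rho0 <- initial_state(ops, "triplet")
  ts <- seq(0, 1.2, by = 0.2)
  out <- propagate(rho0, gen, ts, relaxation = R, kS = 0)
  ref <- 1 / 4 - (1 / 4) * exp(-4 * gamma * ts)
  expect_equal(out$p_singlet, ref, tolerance = 1e-6)
  expect_lt(max(abs(out$trace - 1)), 1e-8)
  expect_lt(max(out$herm_resid), 1e-9)
})

test_that("singlet-triplet dephasing decays the S/T0 coherence at gamma", {
  ops <- pair_ops()
  gamma <- 2.5
  ch <- scalar_fluctuation_channel(ops, "st_dephasing", gamma = gamma,
                                   tau_c_ns = 1)
  gen <- reactive_liouvillian(matrix(0i, 4, 4), matrix(0i, 4, 4))
  R <- nz_superoperator(ch, gen)$R
  s <- c(0, 1, -1, 0) / sqrt(2); t0 <- c(0, 1, 1, 0) / sqrt(2)
  coh <- outer(s, Conj(t0))   # |S><T0|
  ts <- c(0.1, 0.4, 1)
  for (t in ts) {
    E <- expm_taylor((gen$L + R) * t)
    ct <- matrix(E %*% as.vector(coh), 4, 4)
    amp <- sum(Conj(s) * (ct %*% t0))
    expect_equal(Mod(amp), exp(-gamma * t), tolerance = 1e-6)
  }
})

test_that("tensor channels: modes, equivalence with the scalar channel", {
  cfg <- toy_cfg()
  ops <- spin_operators(cfg$system)
  pr <- electronic_projectors(ops)
  gen <- reactive_liouvillian(spin_hamiltonian(cfg, ops),
                              haberkorn_operator(cfg$rates, pr))
  # diagonal covariance: "auto" and "auto+cross" identical
  cv <- diag(c(1, 0.5, 0.2, 0.1, 0.05))
  Ra <- nz_superoperator(tensor_fluctuation_channels(ops, cv, mode = "auto"),
                         gen)$R
  Rb <- nz_superoperator(tensor_fluctuation_channels(ops, cv,
                                                     mode = "auto+cross"),
                         gen)$R
  expect_equal(Ra, Rb, tolerance = 1e-12)
  # rank-1 covariance along the point-dipole direction reproduces the
  # scalar eed_amplitude channel
  var_d_rad <- 5000   # rad^2 us^-2
  v <- tensor_components(-(3 * outer(c(1, 0, 0), c(1, 0, 0)) - diag(3)))
  cv1 <- (var_d_rad / (2 * pi)^2) * outer(v, v)   # MHz^2 component covariance
  R1 <- nz_superoperator(tensor_fluctuation_channels(ops, cv1,
                                                     mode = "auto+cross"),
                         gen)$R
  R2 <- nz_superoperator(scalar_fluctuation_channel(
    ops, "eed_amplitude", variance = var_d_rad, axis = c(1, 0, 0)), gen)$R
  expect_lt(max(abs(R1 - R2)), 1e-10 * max(abs(R2)))
  # covariance must be PSD
  bad <- diag(5); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(tensor_fluctuation_channels(ops, bad, mode = "auto+cross"),
               "positive-semidefinite")
})

test_that("relaxation preserves Hermiticity under propagation", {
  cfg <- toy_cfg(kS = 10, kT = 0.1)
  ops <- spin_operators(cfg$system)
  pr <- electronic_projectors(ops)
  gen <- reactive_liouvillian(spin_hamiltonian(cfg, ops),
                              haberkorn_operator(cfg$rates, pr))
  R <- nz_superoperator(rfr_channels(ops, gamma = 1), gen)
  out <- propagate(initial_state(ops, "triplet"), gen, c(0, 0.05, 0.2, 0.5),
                   relaxation = R, kS = 10)
  expect_lt(max(out$herm_resid), 1e-9)
})

test_that("anisotropy is monotonically degraded by random-field noise", {
  cfg <- toy_cfg()   # peak rates (3.74, 1e-3)
  ops <- spin_operators(cfg$system)
  dirs <- fibonacci_sphere(30)[, c("x", "y", "z")]
  s_of <- function(gamma) {
    ch <- if (gamma > 0) rfr_channels(ops, gamma = gamma) else NULL
    ys <- zenospin:::.yield_batch(cfg, dirs, channels = ch, engine = "cpp")
    anisotropy_metrics(ys$phi_s)$s_pct
  }
  s_vals <- vapply(c(0, 0.1, 1, 10), s_of, numeric(1))
  expect_true(all(diff(s_vals) < 0))
})

test_that("weak-coupling validity guard warns when strained", {
  cfg <- toy_cfg()
  ops <- spin_operators(cfg$system)
  pr <- electronic_projectors(ops)
  gen <- reactive_liouvillian(spin_hamiltonian(cfg, ops),
                              haberkorn_operator(cfg$rates, pr))
  ch <- rfr_channels(ops, gamma = 500, tau_c_ns = 30)
  expect_warning(nz_superoperator(ch, gen), "second-order")
})
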