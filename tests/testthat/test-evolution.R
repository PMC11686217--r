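test_that("reaction rates encode the reoxidation scheme", {
  r <- reaction_rates(3.74, 1e-3)
  expect_equal(r$kf, r$kT)
  expect_equal(r$kr, r$kS - r$kT)
  expect_error(reaction_rates(-1, 1), "non-negative")
  expect_warning(reaction_rates(1e7, 1), "supported range")
})

test_that("Haberkorn operator has eigenvalues kS/2 and kT/2", {
  pr <- electronic_projectors(spin_system())
  K <- haberkorn_operator(reaction_rates(2000, 1), pr)
  ev <- sort(unique(round(Re(eigen(K, symmetric = TRUE,
                                   only.values = TRUE)$values), 9)))
  expect_equal(ev, c(0.5, 1000))
  expect_lt(max(abs(K - Conj(t(K)))), 1e-12)
  # kS = kT gives (k/2) identity; always PSD
  K2 <- haberkorn_operator(reaction_rates(3, 3), pr)
  expect_equal(K2, 1.5 * diag(4) + 0i, tolerance = 1e-12)
  for (r in list(c(0.01, 5), c(100, 100), c(1e5, 1e-3))) {
    Kr <- haberkorn_operator(reaction_rates(r[1], r[2]), pr)
    expect_gte(min(Re(eigen(Kr, symmetric = TRUE, only.values = TRUE)$values)),
               0)
  }
})

test_that("Liouvillian spectrum matches the eigenvalue-pair formula", {
  ops <- spin_operators(spin_system(1 / 2))
  pr <- electronic_projectors(ops)
  cfgH <- zeeman_term(field_vector(50, c(0, 0, 1)), ops) +
    hyperfine_term(list(diag(c(1, 2, 10))), ops)
  K <- haberkorn_operator(reaction_rates(5, 0.2), pr)
  gen <- reactive_liouvillian(cfgH, K)
  evL <- eigen(gen$L, only.values = TRUE)$values
  evH <- eigen(gen$Heff, only.values = TRUE)$values
  ref <- as.vector(outer(-1i * evH, 1i * Conj(evH), "+"))
  # compare as multisets
  key <- function(z) sort(paste(round(Re(z), 6), round(Im(z), 6)))
  expect_equal(key(evL), key(ref))
  expect_error(reactive_liouvillian(cfgH, diag(2) + 0i), "dimensions")
})

test_that("trace decays at the rate prescribed by the reaction operator", {
  ops <- pair_ops()
  pr <- electronic_projectors(ops)
  # singlet-manifold state with H = 0: d Tr/dt = -kS Tr
  gen <- reactive_liouvillian(matrix(0i, 4, 4),
                              haberkorn_operator(reaction_rates(2, 0.5), pr))
  rho0 <- initial_state(ops, "singlet")
  out <- propagate(rho0, gen, seq(0, 2, by = 0.25), kS = 2)
  expect_equal(out$trace, exp(-2 * out$time), tolerance = 1e-8)
  expect_equal(out$trace[1], 1, tolerance = 1e-12)
  # triplet-born with H = 0: pure triplet decay, no singlet ever
  gen2 <- reactive_liouvillian(matrix(0i, 4, 4),
                               haberkorn_operator(reaction_rates(2, 0.5), pr))
  outT <- propagate(initial_state(ops, "triplet"), gen2, seq(0, 2, by = 0.5),
                    kS = 2)
  expect_equal(outT$p_triplet, exp(-0.5 * outT$time), tolerance = 1e-8)
  expect_lt(max(abs(outT$p_singlet)), 1e-10)
  # K = 0 conserves the trace
  H <- zeeman_term(field_vector(50, c(0, 1, 0)), ops)
  gen0 <- reactive_liouvillian(H, matrix(0i, 4, 4))
  out0 <- propagate(initial_state(ops, "triplet"), gen0, seq(0, 1, by = 0.2),
                    kS = 0)
  expect_lt(max(abs(out0$trace - 1)), 1e-10)
  expect_lt(max(out0$herm_resid), 1e-10)
})

test_that("initial states are normalized and spin-pure", {
  ops <- spin_operators(spin_system(1))
  rho_t <- initial_state(ops, "triplet")
  pr <- electronic_projectors(ops)
  expect_equal(Re(sum(diag(rho_t))), 1, tolerance = 1e-12)
  expect_lt(abs(sum(diag(pr$PS %*% rho_t))), 1e-12)
  # singlet-born, no nuclei: pure |S><S|
  ops0 <- pair_ops()
  rho_s <- initial_state(ops0, "singlet")
  expect_equal(Re(sum(diag(rho_s %*% rho_s))), 1, tolerance = 1e-12)
  expect_error(initial_state(ops, "doublet"))
})

test_that("Laplace-domain yield agrees with time-domain integration", {
  # moderate dipolar coupling keeps the oscillatory integration cheap
  cfg <- toy_cfg(r = 30, kS = 2, kT = 0.4)
  ops <- spin_operators(cfg$system)
  pr <- electronic_projectors(ops)
  H <- spin_hamiltonian(cfg, ops)
  gen <- reactive_liouvillian(H, haberkorn_operator(cfg$rates, pr))
  rho0 <- initial_state(ops, "triplet")
  y <- singlet_yield(rho0, gen, cfg$rates, projectors = pr)
  out <- propagate(rho0, gen, c(0, 2^(0:6) * 0.5), kS = cfg$rates$kS)
  expect_equal(tail(out$yield_s_cum, 1), y$phi_s, tolerance = 1e-6)
  expect_equal(y$phi_s + y$phi_t, 1, tolerance = 1e-8)
})

test_that("yield solver handles the degenerate rate cases", {
  cfg <- toy_cfg()
  ops <- spin_operators(cfg$system)
  pr <- electronic_projectors(ops)
  H <- spin_hamiltonian(cfg, ops)
  rho0 <- initial_state(ops, "triplet")
  # kS = 0: yield vanishes through its prefactor
  r0 <- reaction_rates(0, 1)
  gen0 <- reactive_liouvillian(H, haberkorn_operator(r0, pr))
  expect_equal(singlet_yield(rho0, gen0, r0, projectors = pr)$phi_s, 0)
  # kT = 0 without relaxation: refused with a named non-decaying subspace
  rT <- reaction_rates(1, 0)
  genT <- reactive_liouvillian(H, haberkorn_operator(rT, pr))
  expect_error(singlet_yield(rho0, genT, rT, projectors = pr),
               "non-decaying")
})

test_that("no singlet-triplet coupling means zero triplet-born yield", {
  # pure EED + exchange, B = 0, no hyperfine: PS commutes with H
  sys <- spin_system()
  cfg <- rp_config(sys, hyperfine = list(), displacement = c(4.56, 0, 0),
                   exchange_J = 5, field = field_vector(0, c(0, 0, 1)),
                   rates = reaction_rates(3.74, 1e-3))
  ops <- spin_operators(sys)
  pr <- electronic_projectors(ops)
  gen <- reactive_liouvillian(spin_hamiltonian(cfg, ops),
                              haberkorn_operator(cfg$rates, pr))
  y <- singlet_yield(initial_state(ops, "triplet"), gen, cfg$rates,
                     projectors = pr)
  expect_lt(abs(y$phi_s), 1e-12)
})

test_that("symmetric recombination factorizes into coherent dynamics", {
  # kS = kT = k: Phi_S = k int e^{-kt} Tr(PS rho_coh(t)) dt
  cfg <- toy_cfg(kS = 1, kT = 1)
  ops <- spin_operators(cfg$system)
  pr <- electronic_projectors(ops)
  H <- spin_hamiltonian(cfg, ops)
  rho0 <- initial_state(ops, "triplet")
  gen <- reactive_liouvillian(H, haberkorn_operator(cfg$rates, pr))
  y <- singlet_yield(rho0, gen, cfg$rates, projectors = pr)
  # coherent-only dynamics via Hermitian eigen-decomposition
  ee <- eigen(H)
  rho_t <- function(t) {
    U <- ee$vectors %*% diag(exp(-1i * ee$values * t)) %*% Conj(t(ee$vectors))
    U %*% rho0 %*% Conj(t(U))
  }
  ts <- seq(0, 25, by = 0.01)
  ps <- vapply(ts, function(t) Re(sum(diag(pr$PS %*% rho_t(t)))), numeric(1))
  ref <- sum(exp(-ts) * ps) * 0.01   # k = 1
  expect_equal(y$phi_s, ref, tolerance = 2e-3)
})

test_that("Laplace and time domain agree on a two-nucleus system", {
  sys <- spin_system(c(1 / 2, 1 / 2))
  cfg <- rp_config(sys,
                   hyperfine = list(diag(c(2, 2, 12)), diag(c(-1, 3, 5))),
                   displacement = c(15, 3, 0),
                   rates = reaction_rates(5, 0.5))
  ops <- spin_operators(sys)
  pr <- electronic_projectors(ops)
  gen <- reactive_liouvillian(spin_hamiltonian(cfg, ops),
                              haberkorn_operator(cfg$rates, pr))
  rho0 <- initial_state(ops, "triplet")
  y <- singlet_yield(rho0, gen, cfg$rates, projectors = pr)
  out <- propagate(rho0, gen, c(0, 5, 10, 20, 40), kS = 5)
  expect_equal(tail(out$yield_s_cum, 1), y$phi_s, tolerance = 1e-6)
})
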