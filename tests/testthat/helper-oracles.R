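# Shared fixtures and independent oracle implementations used across tests.
# Oracles deliberately avoid the package's computational paths: matrix
# exponentials via scaling-and-squaring Taylor series, memory integrals via
# numerical quadrature, eigen-decompositions only through base eigen() on
# independently assembled matrices.

toy_cfg <- function(...) toy_n5_config(...)

# bare electron pair with a simple anisotropic Hamiltonian, for small oracles
pair_ops <- function() spin_operators(spin_system())

# complex matrix exponential by scaling and squaring of the Taylor series
expm_taylor <- function(M, nterm = 30) {
  nrm <- max(abs(M))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 2L)
  A <- M / 2^s
  E <- diag(nrow(M)) + 0i
  term <- E
  for (k in seq_len(nterm)) {
    term <- term %*% A / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

# commutation superoperator (column stacking), coded independently
comm_super <- function(A) {
  n <- nrow(A)
  kronecker(diag(n) + 0i, A) - kronecker(t(A), diag(n) + 0i)
}

# Quadrature oracle for the relaxation superoperator:
# R = -sum_jk cov_jk int_0^T exp(-t/tauc) Adj(A_j) e^{Lt} A_k dt,
# composite Simpson rule on incremental matrix exponentials. To keep the
# cost down the kernel integral F(T) = int exp(-t/tauc) e^{Lt} dt is
# accumulated once and the channel double sum applied at the end.
nz_quadrature_oracle <- function(ops_list, cov, tau_c, L, tmax = NULL,
                                 nstep = 8000) {
  if (is.null(tmax)) tmax <- 45 * tau_c
  if (nstep %% 2 == 1) nstep <- nstep + 1
  dt <- tmax / nstep
  n2 <- nrow(L)
  Estep <- expm_taylor(L * dt)
  Fk <- matrix(0i, n2, n2)
  E <- diag(n2) + 0i
  for (s in 0:nstep) {
    w <- if (s == 0 || s == nstep) 1 else if (s %% 2 == 1) 4 else 2
    Fk <- Fk + (w * dt / 3) * exp(-s * dt / tau_c) * E
    E <- E %*% Estep
  }
  As <- lapply(ops_list, comm_super)
  R <- matrix(0i, n2, n2)
  for (j in seq_along(As)) for (k in seq_along(As)) {
    if (cov[j, k] == 0) next
    R <- R - cov[j, k] * (Conj(t(As[[j]])) %*% Fk %*% As[[k]])
  }
  R
}

# rotation matrix about a unit axis (Rodrigues), used for invariance checks
rot_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# rotate an rp_config's frame-fixed quantities by R3
rotate_config <- function(cfg, R3) {
  cfg$hyperfine <- lapply(cfg$hyperfine, function(A) R3 %*% A %*% t(R3))
  if (!is.null(cfg$displacement))
    cfg$displacement <- as.numeric(R3 %*% cfg$displacement)
  if (!is.null(cfg$eed_tensor))
    cfg$eed_tensor <- R3 %*% cfg$eed_tensor %*% t(R3)
  cfg
}
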