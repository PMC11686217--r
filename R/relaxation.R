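# Noise channels: a group of coupling operators A_i (rad us^-1 scaling) with a
# covariance matrix over the fluctuating amplitudes X_i and one exponential
# correlation time tau_c. The relaxation superoperator is second order in the
# system-bath coupling, with the reactive propagator (not the bare coherent
# one) inside the memory integral, so it remains accurate under fast
# spin-selective recombination where Redfield theory fails.

.noise_channels <- function(ops_list, cov, tau_c_us, labels, kind) {
  cov <- as.matrix(cov)
  stopifnot(length(ops_list) == nrow(cov), nrow(cov) == ncol(cov))
  if (nrow(cov) > 0) {
    if (max(abs(cov - t(cov))) > 1e-10 * max(1, max(abs(cov))))
      stop("channel covariance must be symmetric", call. = FALSE)
    ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(1, max(abs(ev))))
      stop("channel covariance must be positive-semidefinite", call. = FALSE)
  }
  if (tau_c_us <= 0) stop("tau_c must be positive", call. = FALSE)
  structure(list(ops = ops_list, cov = cov, tau_c = tau_c_us,
                 labels = labels, kind = kind),
            class = "noise_channels")
}

#' @export
print.noise_channels <- function(x, ...) {
  cat("<noise_channels> kind:", x$kind, "|", length(x$ops),
      "channel(s), tau_c =", x$tau_c * 1e3, "ns\n")
  invisible(x)
}

#' Lorentzian spectral density of an exponentially correlated fluctuation
#'
#' One-sided Fourier transform `j(omega) = integral_0^inf g(t) e^{i omega t} dt`
#' of `g(t) = cov * exp(-t / tau_c)`, evaluated analytically:
#' `j(omega) = cov / (1/tau_c - i omega)`. `omega` may be complex (eigenvalue
#' differences of a decaying effective Hamiltonian); the integral converges
#' when `Re(1/tau_c - i omega) > 0`.
#'
#' @param omega Angular frequency (rad us^-1), possibly complex.
#' @param covariance Variance/covariance of the fluctuating amplitude.
#' @param tau_c_ns Correlation time in ns (default 1).
#' @return Complex spectral density. `j(0) = covariance * tau_c`.
#' @export
spectral_density <- function(omega, covariance = 1, tau_c_ns = 1) {
  tau_c <- tau_c_ns * 1e-3
  den <- 1 / tau_c - 1i * omega
  if (any(Re(den) <= 0))
    stop("divergent spectral density: growing mode (Re(1/tau_c - i omega) <= 0)",
         call. = FALSE)
  covariance / den
}

#' Random-field relaxation channels
#'
#' Uncorrelated magnetic-field noise of equal amplitude along the three
#' Cartesian directions of each electron: six channels with operators
#' `S_{i,j}` and per-channel variance `<dB_i^2> = gamma / tau_c` (angular
#' frequency units), a widely used stand-in for spin-rotational and similar
#' decoherence mechanisms of the superoxide radical.
#'
#' @param ops [spin_operators()].
#' @param gamma Effective relaxation rate `<dB_i^2> tau_c` in us^-1
#'   (alternatively give `variance` directly).
#' @param variance Per-channel variance in rad^2 us^-2 (overrides `gamma`).
#' @param tau_c_ns Correlation time in ns (default 1).
#' @return A `noise_channels` group (empty when the rate is 0).
#' @export
#' @examples
#' ch <- rfr_channels(spin_operators(spin_system()), gamma = 1)
#' ch$cov[1, 1]   # 1000 rad^2 us^-2 at tau_c = 1 ns
rfr_channels <- function(ops, gamma = NULL, variance = NULL, tau_c_ns = 1) {
  tau_c <- tau_c_ns * 1e-3
  if (is.null(variance)) {
    stopifnot(!is.null(gamma), gamma >= 0)
    variance <- gamma / tau_c
  }
  if (variance == 0)
    return(.noise_channels(list(), matrix(0, 0, 0), tau_c, character(), "rfr"))
  axes <- c("x", "y", "z")
  ops_list <- c(lapply(axes, function(a) ops$S1[[a]]),
                lapply(axes, function(a) ops$S2[[a]]))
  labels <- c(paste0("b1", axes), paste0("b2", axes))
  .noise_channels(ops_list, diag(variance, 6), tau_c, labels, "rfr")
}

#' Scalar fluctuation channels: dipolar amplitude, exchange, S/T dephasing
#'
#' Single-operator noise channels driven by one fluctuating scalar:
#' * `"eed_amplitude"`: fluctuation of the dipolar coupling parameter `d`
#'   along a fixed inter-radical axis, operator
#'   `3 (S1.n)(S2.n) - S1.S2`, variance `Var(d)` (rad^2 us^-2) with effective
#'   rate `gamma = Var(d) tau_c`;
#' * `"exchange"`: fluctuating exchange coupling, operator `-2 S1.S2`;
#' * `"st_dephasing"`: singlet-triplet dephasing, operator `(P_S - P_T)/2`,
#'   which decays singlet-triplet coherences at rate `gamma`.
#'
#' @param ops [spin_operators()].
#' @param kind One of `"eed_amplitude"`, `"exchange"`, `"st_dephasing"`.
#' @param gamma Effective rate `variance * tau_c` in us^-1 (or give
#'   `variance`).
#' @param variance Variance of the fluctuating amplitude in rad^2 us^-2.
#' @param tau_c_ns Correlation time in ns.
#' @param axis Dipolar axis (required for `"eed_amplitude"`).
#' @return A `noise_channels` group.
#' @export
scalar_fluctuation_channel <- function(ops,
                                       kind = c("eed_amplitude", "exchange",
                                                "st_dephasing"),
                                       gamma = NULL, variance = NULL,
                                       tau_c_ns = 1, axis = NULL) {
  kind <- match.arg(kind)
  tau_c <- tau_c_ns * 1e-3
  if (is.null(variance)) {
    stopifnot(!is.null(gamma), gamma >= 0)
    variance <- gamma / tau_c
  }
  if (variance < 0) stop("variance must be non-negative", call. = FALSE)
  A <- switch(kind,
    eed_amplitude = {
      if (is.null(axis))
        stop("eed_amplitude requires the dipolar `axis`", call. = FALSE)
      n <- axis / sqrt(sum(axis^2))
      Sn1 <- n[1] * ops$S1$x + n[2] * ops$S1$y + n[3] * ops$S1$z
      Sn2 <- n[1] * ops$S2$x + n[2] * ops$S2$y + n[3] * ops$S2$z
      3 * Sn1 %*% Sn2 - .dot_ss(ops$S1, ops$S2)
    },
    exchange = -2 * .dot_ss(ops$S1, ops$S2),
    st_dephasing = {
      pr <- electronic_projectors(ops)
      (pr$PS - pr$PT) / 2
    })
  if (variance == 0)
    return(.noise_channels(list(), matrix(0, 0, 0), tau_c, character(), kind))
  .noise_channels(list(A), matrix(variance, 1, 1), tau_c, kind, kind)
}

# Basis for traceless symmetric 3x3 tensors matching the component order
# {(Dxx - Dyy)/2, Dzz, Dxy, Dxz, Dyz}: D = sum_i c_i B_i for any such D.
.tensor_basis <- function() {
  list(diag(c(1, -1, 0)),
       diag(c(-1 / 2, -1 / 2, 1)),
       matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3),
       matrix(c(0, 0, 1, 0, 0, 0, 1, 0, 0), 3, 3),
       matrix(c(0, 0, 0, 0, 0, 1, 0, 1, 0), 3, 3))
}

#' Components of a traceless symmetric tensor
#'
#' Coordinates in the fixed five-component basis
#' `{(Dxx - Dyy)/2, Dzz, Dxy, Dxz, Dyz}` used by the dipolar-tensor
#' fluctuation channels.
#'
#' @param D 3x3 symmetric traceless tensor.
#' @return Named numeric vector of length 5.
#' @export
tensor_components <- function(D) {
  .check_tensor3(D)
  c(E = (D[1, 1] - D[2, 2]) / 2, zz = D[3, 3],
    xy = D[1, 2], xz = D[1, 3], yz = D[2, 3])
}

#' Dipolar-tensor fluctuation channels (auto / auto+cross)
#'
#' Five noise channels, one per independent component of the traceless
#' symmetric dipolar tensor, with operators `S1 . B_i . S2` (the component
#' basis contracted with the electron spins) and the covariance of the
#' component fluctuations as sampled from a trajectory or a synthetic
#' displacement model. `mode = "auto"` keeps only the diagonal of the
#' covariance (auto-correlations); `"auto+cross"` keeps the full matrix.
#'
#' @param ops [spin_operators()].
#' @param stats A [tensor_statistics()] result (needs `cov`, in MHz^2), or a
#'   bare 5x5 covariance matrix in MHz^2.
#' @param tau_c_ns Correlation time in ns.
#' @param mode `"auto"` or `"auto+cross"`.
#' @return A `noise_channels` group (5 channels; empty if covariance is 0).
#' @export
tensor_fluctuation_channels <- function(ops, stats, tau_c_ns = 1,
                                        mode = c("auto", "auto+cross")) {
  mode <- match.arg(mode)
  tau_c <- tau_c_ns * 1e-3
  cov_mhz2 <- if (inherits(stats, "tensor_stats")) stats$cov else as.matrix(stats)
  stopifnot(all(dim(cov_mhz2) == c(5, 5)))
  if (mode == "auto") cov_mhz2 <- diag(diag(cov_mhz2), 5)
  cov_rad <- cov_mhz2 * (2 * pi)^2   # operators carry the 2*pi MHz scaling
  if (max(abs(cov_rad)) == 0)
    return(.noise_channels(list(), matrix(0, 0, 0), tau_c, character(),
                           "eed_tensor"))
  ax <- c("x", "y", "z")
  ops_list <- lapply(.tensor_basis(), function(B) {
    H <- matrix(0i, ops$dim, ops$dim)
    for (i in 1:3) for (j in 1:3)
      if (B[i, j] != 0) H <- H + B[i, j] * ops$S1[[ax[i]]] %*% ops$S2[[ax[j]]]
    H
  })
  .noise_channels(ops_list, cov_rad, tau_c,
                  c("E", "zz", "xy", "xz", "yz"), "eed_tensor")
}

#' Nakajima-Zwanzig relaxation superoperator
#'
#' Builds `R = -sum_{j,k} integral_0^inf g_jk(tau) A_j^+ e^{L tau} A_k dtau`
#' where `A_i = [A_i, .]` is the commutation superoperator of channel `i` and
#' `L` the *reactive* Liouvillian. With `H_eff = H - iK` diagonalized as
#' `V Lam V^-1`, the memory integral is evaluated analytically: the propagator
#' is diagonal in the non-Hermitian eigenbasis with eigenvalues
#' `-i (Lam_a - conj(Lam_b))`, and the exponential correlation functions give
#' Lorentzian spectral densities at those complex eigenvalue differences.
#' With `K = 0` this reduces to the (non-secular) Redfield tensor.
#'
#' @param channels A `noise_channels` group, or a list of groups (summed).
#' @param generator A [reactive_liouvillian()] result.
#' @return Object of class `relaxation_superop`: `R` (Liouville-space matrix),
#'   `cond` (condition number of the eigenvector matrix), `kinds`.
#' @export
nz_superoperator <- function(channels, generator) {
  stopifnot(inherits(generator, "reactive_generator"))
  if (inherits(channels, "noise_channels")) channels <- list(channels)
  n <- generator$dim
  R <- matrix(0i, n^2, n^2)
  if (!length(channels) || all(vapply(channels, function(g) length(g$ops) == 0,
                                      logical(1))))
    return(structure(list(R = R, cond = 1,
                          kinds = character()), class = "relaxation_superop"))
  ee <- eigen(generator$Heff)
  V <- ee$vectors; lam <- ee$values
  Vi <- tryCatch(solve(V), error = function(e)
    stop("H_eff not diagonalizable within working precision: ",
         conditionMessage(e), call. = FALSE))
  cnd <- norm(V, "2") * norm(Vi, "2")
  if (cnd > 1e8)
    warning("eigenvector matrix of H_eff is ill-conditioned (kappa = ",
            signif(cnd, 3), "); relaxation superoperator may be inaccurate")
  W <- kronecker(Conj(V), V)
  Wi <- kronecker(Conj(Vi), Vi)
  lamL <- as.vector(outer(-1i * lam, 1i * Conj(lam), "+")) # -i(lam_a - lam_b*)
  kinds <- character()
  for (grp in channels) {
    if (!length(grp$ops)) next
    kinds <- c(kinds, grp$kind)
    if (max(diag(grp$cov)) * grp$tau_c^2 > 0.1)
      warning("channel group '", grp$kind, "': variance * tau_c^2 = ",
              signif(max(diag(grp$cov)) * grp$tau_c^2, 3),
              " > 0.1; second-order (weak-coupling) treatment is strained")
    g <- 1 / (1 / grp$tau_c - lamL)
    G <- W %*% (g * Wi)   # integral of g(tau)/cov * e^{L tau}
    As <- lapply(grp$ops, function(A) {
      kronecker(diag(n) + 0i, A) - kronecker(t(A), diag(n) + 0i)
    })
    for (j in seq_along(As)) for (k in seq_along(As)) {
      cjk <- grp$cov[j, k]
      if (cjk == 0) next
      R <- R - cjk * (Conj(t(As[[j]])) %*% G %*% As[[k]])
    }
  }
  structure(list(R = R, cond = cnd, kinds = kinds),
            class = "relaxation_superop")
}

#' @export
print.relaxation_superop <- function(x, ...) {
  cat("<relaxation_superop>", nrow(x$R), "x", ncol(x$R),
      "| kinds:", paste(unique(x$kinds), collapse = ", "),
      "| kappa(V) =", signif(x$cond, 3), "\n")
  invisible(x)
}

# Materialize the declarative `noise` section of an rp_config into channel
# groups on the given operator set.
.build_noise <- function(config, ops) {
  if (is.null(config$noise)) return(NULL)
  lapply(config$noise, function(sp) {
    kind <- sp$kind
    tau <- sp$tau_c_ns %||% 1
    if (kind == "rfr") {
      rfr_channels(ops, gamma = sp$gamma, variance = sp$variance, tau_c_ns = tau)
    } else if (kind %in% c("eed_amplitude", "exchange", "st_dephasing")) {
      axis <- sp$axis %||% config$displacement
      scalar_fluctuation_channel(ops, kind, gamma = sp$gamma,
                                 variance = sp$variance, tau_c_ns = tau,
                                 axis = axis)
    } else if (kind == "tensor") {
      tensor_fluctuation_channels(ops, sp$stats, tau_c_ns = tau,
                                  mode = sp$mode %||% "auto+cross")
    } else stop("unknown noise kind: ", kind, call. = FALSE)
  })
}
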