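#' Spin-selective recombination rate constants
#'
#' First-order rate constants of the singlet and triplet reaction channels.
#' In the reoxidation scheme the triplet channel is the slow "escape/forward"
#' path and the singlet channel adds the fast recombination on top:
#' `k_S = k_r + k_f`, `k_T = k_f`, so `k_f = k_T` and `k_r = k_S - k_T`.
#'
#' @param kS,kT Rates in us^-1, non-negative. Values outside `[1e-3, 1e6]`
#'   are accepted with a warning (the supported study range).
#' @return Object of class `reaction_rates` with fields `kS`, `kT`, `kf`, `kr`.
#' @export
#' @examples
#' reaction_rates(3.74, 1e-3)
reaction_rates <- function(kS, kT) {
  stopifnot(is.numeric(kS), is.numeric(kT), length(kS) == 1, length(kT) == 1)
  if (kS < 0 || kT < 0) stop("rates must be non-negative", call. = FALSE)
  rng <- c(kS, kT)[c(kS, kT) > 0]
  if (length(rng) && (min(rng) < 1e-3 || max(rng) > 1e6))
    warning("rate outside the supported range [1e-3, 1e6] us^-1")
  structure(list(kS = kS, kT = kT, kf = kT, kr = kS - kT),
            class = "reaction_rates")
}

#' Haberkorn recombination operator
#'
#' `K = (kS/2) P_S + (kT/2) P_T`: a positive-semidefinite Hermitian operator
#' whose anticommutator with the density matrix removes singlet and triplet
#' populations at `kS` and `kT`.
#'
#' @param rates A [reaction_rates()] (or list with `kS`, `kT`).
#' @param projectors List with `PS`, `PT` from [electronic_projectors()].
#' @return Hermitian PSD matrix `K` in us^-1.
#' @export
haberkorn_operator <- function(rates, projectors) {
  if (rates$kS < 0 || rates$kT < 0)
    stop("rates must be non-negative", call. = FALSE)
  rates$kS / 2 * projectors$PS + rates$kT / 2 * projectors$PT
}

#' Reactive Liouvillian
#'
#' Assembles the generator of `d rho/dt = -i[H, rho] - {K, rho}` as a matrix
#' acting on the column-stacked density matrix:
#' `L = -i (I (x) H_eff - conj(H_eff) (x) I)` with `H_eff = H - i K`.
#' The eigenvalues of `L` are `-i (lambda_a - conj(lambda_b))` over pairs of
#' eigenvalues of `H_eff`, so the spectral abscissa is non-positive whenever
#' both rates are positive.
#'
#' @param H Hermitian Hamiltonian (rad us^-1).
#' @param K Haberkorn operator (us^-1), PSD, same dimension.
#' @return Object of class `reactive_generator`: `H`, `K`, `Heff`, `L`
#'   (Liouville-space matrix, column-stacking convention), `dim`.
#' @export
reactive_liouvillian <- function(H, K) {
  if (!all(dim(H) == dim(K)))
    stop("H and K dimensions differ", call. = FALSE)
  n <- nrow(H)
  if (n^2 > 20000)
    warning("Liouville dimension ", n^2,
            " exceeds the dense-solve comfort zone (~20000); ",
            "prefer time-domain propagation")
  Heff <- H - 1i * K
  Id <- diag(n) + 0i
  L <- -1i * (kronecker(Id, Heff) - kronecker(Conj(Heff), Id))
  structure(list(H = H, K = K, Heff = Heff, L = L, dim = n),
            class = "reactive_generator")
}

#' Initial density matrix of the radical pair
#'
#' The nascent flavin-superoxide pair inherits the triplet multiplicity of
#' ground-state molecular oxygen: `rho_0 = P_T / Tr(P_T)`, i.e. a maximally
#' mixed electronic triplet with maximally mixed nuclei (the community
#' standard for the unspecified nuclear state). `"singlet"` gives
#' `P_S / Tr(P_S)`.
#'
#' @param ops [spin_operators()] (or a [spin_system()]).
#' @param multiplicity `"triplet"` (default) or `"singlet"`.
#' @return Hermitian PSD matrix with unit trace.
#' @export
initial_state <- function(ops, multiplicity = c("triplet", "singlet")) {
  multiplicity <- match.arg(multiplicity)
  pr <- electronic_projectors(ops)
  P <- if (multiplicity == "triplet") pr$PT else pr$PS
  P / Re(sum(diag(P)))
}

#' Propagate the density matrix in time
#'
#' Integrates the reactive master equation (optionally with a relaxation
#' superoperator added) with the stiff complex ODE solver `deSolve::zvode`,
#' and tracks the trace, singlet and triplet probabilities, and the running
#' singlet-yield integral `kS * integral Tr(P_S rho) dt`.
#'
#' @param rho0 Initial density matrix.
#' @param generator A [reactive_liouvillian()] result.
#' @param times Non-negative, increasing time grid in us.
#' @param relaxation Optional [nz_superoperator()] result (or bare matrix)
#'   added to the Liouvillian.
#' @param kS Singlet rate used for the running yield column; recovered from
#'   `K` as `2 Tr(K P_S)/Tr(P_S)` when omitted.
#' @param atol,rtol Solver tolerances.
#' @return Tibble with columns `time`, `trace`, `p_singlet`, `p_triplet`,
#'   `yield_s_cum`, `herm_resid` (max anti-Hermitian residual) and
#'   `min_eig` (smallest eigenvalue of rho, for positivity monitoring).
#' @export
propagate <- function(rho0, generator, times, relaxation = NULL, kS = NULL,
                      atol = 1e-12, rtol = 1e-10) {
  stopifnot(inherits(generator, "reactive_generator"))
  if (any(diff(times) <= 0) || any(times < 0))
    stop("`times` must be non-negative and increasing", call. = FALSE)
  n <- generator$dim
  M <- generator$L
  if (!is.null(relaxation)) M <- M + .relax_matrix(relaxation)
  PS <- .recover_ps(generator)
  PT <- diag(n) - PS
  if (is.null(kS))
    kS <- Re(2 * sum(diag(generator$K %*% PS)) / sum(diag(PS)))
  vps <- as.vector(t(PS))  # Tr(PS rho) = vec(t(PS)) . vec(rho)
  vpt <- as.vector(t(PT))
  vid <- as.vector(diag(n) + 0i)
  deriv <- function(t, y, parms) {
    rho <- y[seq_len(n * n)]
    list(c(parms$M %*% rho, parms$kS * sum(parms$vps * rho)))
  }
  y0 <- c(as.vector(rho0) + 0i, 0i)
  sol <- deSolve::zvode(y = y0, times = times, func = deriv,
                        parms = list(M = M, kS = kS, vps = vps),
                        atol = atol, rtol = rtol, maxsteps = 500000)
  if (attr(sol, "istate")[1] < 0)
    stop("zvode integration failed; istate = ", attr(sol, "istate")[1],
         " at step count ", attr(sol, "istate")[13], call. = FALSE)
  ys <- sol[, -1, drop = FALSE]
  res <- purrr::map_dfr(seq_len(nrow(ys)), function(i) {
    v <- ys[i, seq_len(n * n)]
    rho <- matrix(v, n, n)
    herm <- max(abs(rho - Conj(t(rho))))
    ev <- suppressWarnings(min(Re(eigen((rho + Conj(t(rho))) / 2,
                                        symmetric = TRUE,
                                        only.values = TRUE)$values)))
    tibble::tibble(time = times[i],
                   trace = Re(sum(v * vid)),
                   p_singlet = Re(sum(v * vps)),
                   p_triplet = Re(sum(v * vpt)),
                   yield_s_cum = Re(unname(ys[i, n * n + 1])),
                   herm_resid = herm, min_eig = ev)
  })
  if (any(res$min_eig < -1e-8))
    stop("density matrix lost positivity beyond tolerance (min eigenvalue ",
         signif(min(res$min_eig), 3), ")", call. = FALSE)
  res
}

.relax_matrix <- function(relaxation) {
  if (inherits(relaxation, "relaxation_superop")) relaxation$R else relaxation
}

# PS from K is ambiguous when kS == kT; recover from the operator structure
.recover_ps <- function(generator) {
  n <- generator$dim
  # K = kS/2 PS + kT/2 PT; PS = I/4 - S1.S2 is idempotent with trace n/4
  # use the projector identity: PS = (K - kT/2 I) / ((kS - kT)/2) unless equal
  ev <- eigen(generator$K, symmetric = TRUE)
  vals <- unique(round(Re(ev$values), 12))
  if (length(vals) == 1) {
    # kS == kT: K carries no singlet/triplet distinction; rebuild from trace
    # structure is unavailable -- fall back to the canonical projector
    m <- n / 4
    # electronic projector on e1 (x) e2 (x) nuclei ordering
    ss <- .dot_ss(list(x = .op_at(c(2, 2, m), 1, .single_spin_matrices(1/2)$x),
                       y = .op_at(c(2, 2, m), 1, .single_spin_matrices(1/2)$y),
                       z = .op_at(c(2, 2, m), 1, .single_spin_matrices(1/2)$z)),
                  list(x = .op_at(c(2, 2, m), 2, .single_spin_matrices(1/2)$x),
                       y = .op_at(c(2, 2, m), 2, .single_spin_matrices(1/2)$y),
                       z = .op_at(c(2, 2, m), 2, .single_spin_matrices(1/2)$z)))
    return(diag(n) / 4 - ss)
  }
  kS2 <- max(Re(ev$values)); kT2 <- min(Re(ev$values))
  P <- ev$vectors %*% diag(as.numeric(abs(Re(ev$values) - kS2) < 1e-12)) %*%
    Conj(t(ev$vectors))
  # K's larger eigenvalue belongs to the singlet only when kS > kT; the
  # singlet subspace has dimension n/4
  if (abs(Re(sum(diag(P))) - n / 4) < 1e-6) P else diag(n) - P
}

#' Singlet recombination yield by Laplace-domain solve
#'
#' Solves the linear system obtained by Laplace-transforming the master
#' equation at `s = 0`: `(-L - R) X = rho_0`, then
#' `Phi_S = kS Tr(P_S X)`. With both rates positive (or relaxation ensuring
#' decay) the solution exists and `Phi_S + Phi_T = 1`.
#'
#' @param rho0 Initial density matrix (unit trace).
#' @param generator A [reactive_liouvillian()] result.
#' @param rates A [reaction_rates()]; needed for the yield prefactors.
#' @param relaxation Optional [nz_superoperator()] result (or bare Liouville
#'   matrix) added to the generator.
#' @param projectors Optional list `PS`/`PT` (recovered from `K` if omitted).
#' @return Object of class `yield_value`: list with `phi_s`, `phi_t`.
#' @export
singlet_yield <- function(rho0, generator, rates, relaxation = NULL,
                          projectors = NULL) {
  stopifnot(inherits(generator, "reactive_generator"))
  kS <- rates$kS; kT <- rates$kT
  if (kS == 0)
    return(structure(list(phi_s = 0, phi_t = NA_real_), class = "yield_value"))
  if (kT == 0 && is.null(relaxation))
    stop("kT = 0 leaves the triplet subspace non-decaying: the s = 0 Laplace ",
         "system is singular. Use kT >= 1e-3 us^-1 or add relaxation.",
         call. = FALSE)
  if (is.null(projectors)) {
    PS <- .recover_ps(generator); PT <- diag(generator$dim) - PS
  } else { PS <- projectors$PS; PT <- projectors$PT }
  M <- generator$L
  if (!is.null(relaxation)) M <- M + .relax_matrix(relaxation)
  x <- tryCatch(solve(-M, as.vector(rho0)),
                error = function(e)
                  stop("Laplace system singular or ill-conditioned (",
                       conditionMessage(e),
                       "); a non-decaying subspace is likely", call. = FALSE))
  X <- matrix(x, generator$dim, generator$dim)
  phi_s <- kS * Re(sum(diag(PS %*% X)))
  phi_t <- kT * Re(sum(diag(PT %*% X)))
  structure(list(phi_s = phi_s, phi_t = phi_t), class = "yield_value")
}

#' @export
print.yield_value <- function(x, ...) {
  cat(sprintf("<yield> Phi_S = %.6f  Phi_T = %.6f  (sum %.2e from 1)\n",
              x$phi_s, x$phi_t, x$phi_s + x$phi_t - 1))
  invisible(x)
}
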