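#' Magnetic field vector
#'
#' @param magnitude Field strength in microtesla (default 50, geomagnetic).
#' @param direction Cartesian direction (normalized internally), or use
#'   `theta`/`phi` (radians, physics convention: `theta` from +z).
#' @param theta,phi Spherical angles, used when `direction` is `NULL`.
#' @return Object of class `field_vector`: `vec` (uT), `magnitude`,
#'   `direction` (unit), `theta`, `phi`.
#' @export
#' @examples
#' field_vector(50, c(0, 0, 1))
field_vector <- function(magnitude = 50, direction = NULL,
                         theta = 0, phi = 0) {
  stopifnot(is.numeric(magnitude), length(magnitude) == 1, magnitude >= 0)
  if (is.null(direction))
    direction <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  stopifnot(length(direction) == 3)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("field direction must be non-zero", call. = FALSE)
  direction <- direction / nrm
  structure(list(vec = magnitude * direction, magnitude = magnitude,
                 direction = direction,
                 theta = acos(pmin(1, pmax(-1, direction[3]))),
                 phi = atan2(direction[2], direction[1])),
            class = "field_vector")
}

.as_field <- function(field) {
  if (inherits(field, "field_vector")) return(field)
  if (is.numeric(field) && length(field) == 3)
    return(field_vector(sqrt(sum(field^2)),
                        if (all(field == 0)) c(0, 0, 1) else field))
  stop("`field` must be a field_vector or a length-3 numeric", call. = FALSE)
}

#' Electron Zeeman Hamiltonian
#'
#' Both electrons share the free-electron gyromagnetic ratio (no g-anisotropy);
#' the term is implemented with a positive precession frequency
#' `omega = gamma_e |B|`, which leaves all reaction yields unchanged relative
#' to the opposite overall sign.
#'
#' @param field A [field_vector()] (uT) or length-3 numeric field in uT.
#' @param ops [spin_operators()].
#' @return Hermitian Hamiltonian matrix in rad us^-1.
#' @export
zeeman_term <- function(field, ops) {
  field <- .as_field(field)
  b <- .gamma_e * field$vec  # rad us^-1 components
  S <- lapply(c("x", "y", "z"), function(a) ops$S1[[a]] + ops$S2[[a]])
  b[1] * S[[1]] + b[2] * S[[2]] + b[3] * S[[3]]
}

.check_tensor3 <- function(A, what = "tensor") {
  if (!is.matrix(A) || !all(dim(A) == c(3, 3)) || !is.numeric(A))
    stop(what, " must be a real 3x3 matrix", call. = FALSE)
  invisible(A)
}

#' Hyperfine Hamiltonian
#'
#' `sum_k I_k . A_k . S_e` for the nuclei of the system. By default the tensors
#' attach to electron 1, matching a flavin-superoxide pair in which only the
#' flavin radical has hyperfine couplings.
#'
#' @param tensors List of 3x3 hyperfine tensors in MHz (nu-values), one per
#'   nucleus in declaration order. A single matrix is accepted for a
#'   one-nucleus system. Symmetry is not required.
#' @param ops [spin_operators()].
#' @param electron Which electron the tensors couple to (default 1).
#' @return Hermitian Hamiltonian matrix in rad us^-1.
#' @export
hyperfine_term <- function(tensors, ops, electron = 1) {
  if (is.matrix(tensors)) tensors <- list(tensors)
  if (length(tensors) != length(ops$nuc))
    stop("got ", length(tensors), " tensors for ", length(ops$nuc),
         " declared nuclei", call. = FALSE)
  S <- if (electron == 1) ops$S1 else ops$S2
  H <- matrix(0i, ops$dim, ops$dim)
  ax <- c("x", "y", "z")
  for (k in seq_along(tensors)) {
    A <- .mhz(.check_tensor3(tensors[[k]], "hyperfine tensor"))
    Ik <- ops$nuc[[k]]
    for (i in 1:3) for (j in 1:3)
      if (A[i, j] != 0) H <- H + A[i, j] * Ik[[ax[i]]] %*% S[[ax[j]]]
  }
  H
}

#' Point-dipole electron-electron dipolar tensor
#'
#' For a displacement `r` between the two point electron spins, the dipolar
#' Hamiltonian `-d(r) (3 (S1.n)(S2.n) - S1.S2)` corresponds to the symmetric
#' traceless tensor with principal values `{-2d, d, d}` (unique axis along the
#' displacement), `d(r) = mu0 ge^2 muB^2 / (4 pi r^3)`. At contact distance
#' (4.5 A) the extreme span `3d` reaches 1.7 GHz.
#'
#' @param displacement Length-3 displacement vector in Angstrom.
#' @return 3x3 symmetric traceless tensor in MHz.
#' @export
#' @examples
#' D <- point_dipole_tensor(c(4.56, 0, 0))
#' sum(diag(D))   # 0
point_dipole_tensor <- function(displacement) {
  stopifnot(is.numeric(displacement), length(displacement) == 3)
  displacement <- unname(as.numeric(displacement))
  r <- sqrt(sum(displacement^2))
  if (r == 0) stop("zero-length displacement", call. = FALSE)
  n <- displacement / r
  d <- dipolar_coupling(r, "MHz")
  -d * (3 * outer(n, n) - diag(3))
}

.as_sites <- function(sites, what) {
  if (is.data.frame(sites)) {
    stopifnot(all(c("x", "y", "z", "population") %in% names(sites)))
    pos <- as.matrix(sites[, c("x", "y", "z")])
    pop <- sites$population
  } else if (is.list(sites)) {
    pos <- sites$positions
    pop <- sites$populations
  } else stop(what, ": supply a data frame with x, y, z, population",
              call. = FALSE)
  if (abs(sum(pop) - 1) > 1e-6)
    stop(what, ": populations must sum to 1 (got ", signif(sum(pop), 6), ")",
         call. = FALSE)
  list(pos = pos, pop = pop)
}

#' Dipolar tensor for distributed spin densities
#'
#' Population-weighted double sum of point-dipole tensors over all pairs of
#' spin-density sites on the two radicals, accounting for the spread of the
#' spin densities (e.g. over the isoalloxazine ring and the two superoxide
#' oxygens) instead of collapsing each radical to a point.
#'
#' @param density_1,density_2 Data frames with columns `x`, `y`, `z`
#'   (Angstrom) and `population` (summing to 1 on each radical), e.g. from
#'   [synthetic_spin_density()] or [sites_from_pdb()].
#' @return 3x3 symmetric traceless tensor in MHz.
#' @export
distributed_dipole_tensor <- function(density_1, density_2) {
  s1 <- .as_sites(density_1, "density_1")
  s2 <- .as_sites(density_2, "density_2")
  D <- matrix(0, 3, 3)
  for (i in seq_along(s1$pop)) for (j in seq_along(s2$pop)) {
    dr <- s2$pos[j, ] - s1$pos[i, ]
    if (sum(dr^2) < 1e-12)
      stop("coincident spin-density sites across radicals (singular r^-3)",
           call. = FALSE)
    D <- D + s1$pop[i] * s2$pop[j] * point_dipole_tensor(dr)
  }
  D
}

#' Electron-electron dipolar Hamiltonian
#'
#' Contracts a symmetric traceless coupling tensor with the two electron spins:
#' `H = sum_ij D_ij S1_i S2_j`. Its eigenstates within the electronic space are
#' the singlet and triplet states, so it commutes with the singlet projector.
#'
#' @param tensor 3x3 symmetric traceless tensor in MHz, e.g. from
#'   [point_dipole_tensor()].
#' @param ops [spin_operators()].
#' @return Hermitian Hamiltonian matrix in rad us^-1.
#' @export
dipolar_term <- function(tensor, ops) {
  .check_tensor3(tensor, "dipolar tensor")
  if (abs(sum(diag(tensor))) > 1e-9 * max(1e-300, norm(tensor, "F")))
    stop("dipolar tensor must be traceless", call. = FALSE)
  if (max(abs(tensor - t(tensor))) > 1e-9 * max(1e-300, norm(tensor, "F")))
    stop("dipolar tensor must be symmetric", call. = FALSE)
  A <- .mhz(tensor)
  ax <- c("x", "y", "z")
  H <- matrix(0i, ops$dim, ops$dim)
  for (i in 1:3) for (j in 1:3)
    if (A[i, j] != 0) H <- H + A[i, j] * ops$S1[[ax[i]]] %*% ops$S2[[ax[j]]]
  H
}

#' Exchange Hamiltonian
#'
#' `H = -2 J S1 . S2`: the singlet is shifted by `+3J/2` and each triplet by
#' `-J/2` (angular frequency), a singlet-triplet splitting of `2J`.
#'
#' @param J Exchange coupling in MHz.
#' @param ops [spin_operators()].
#' @return Hermitian Hamiltonian matrix in rad us^-1.
#' @export
exchange_term <- function(J, ops) {
  stopifnot(is.numeric(J), length(J) == 1, is.finite(J))
  -2 * .mhz(J) * .dot_ss(ops$S1, ops$S2)
}
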