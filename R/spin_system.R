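#' Define a two-electron radical-pair spin system
#'
#' A radical pair always carries two electron spins (S = 1/2 each); any number
#' of nuclear spins can be attached to either radical. In the flavin-superoxide
#' models only radical 1 (the flavin semiquinone) carries nuclei -- the oxygens
#' of superoxide are spinless -- but nuclei on radical 2 are permitted.
#'
#' @param nuclei A data frame (or tibble) with one row per nucleus and columns
#'   `spin` (spin quantum number, a non-negative half-integer such as 1/2 or 1),
#'   `radical` (1 or 2) and optionally `label`. `NULL` (default) declares a bare
#'   electron pair. A bare numeric vector is taken as spins on radical 1.
#' @return An object of class `spin_system` with fields `nuclei` (tibble),
#'   `dims` (tensor-factor dimensions, electrons first) and `dim` (total
#'   Hilbert-space dimension `4 * prod(2 I_k + 1)`).
#' @export
#' @examples
#' spin_system()                      # bare electron pair, dimension 4
#' spin_system(1)                     # one I = 1 nitrogen on radical 1, dim 12
#' spin_system(tibble::tibble(spin = c(1, 1/2), radical = c(1, 1),
#'                            label = c("N5", "H5")))
spin_system <- function(nuclei = NULL) {
  if (is.null(nuclei)) {
    nuclei <- tibble::tibble(spin = numeric(), radical = integer(),
                             label = character())
  } else if (is.numeric(nuclei)) {
    nuclei <- tibble::tibble(spin = as.numeric(nuclei), radical = 1L,
                             label = paste0("I", seq_along(nuclei)))
  } else {
    nuclei <- tibble::as_tibble(nuclei)
    if (!all(c("spin", "radical") %in% names(nuclei)))
      stop("`nuclei` needs columns `spin` and `radical`", call. = FALSE)
    if (!"label" %in% names(nuclei))
      nuclei$label <- paste0("I", seq_len(nrow(nuclei)))
  }
  bad <- nuclei$spin < 0 | abs(2 * nuclei$spin - round(2 * nuclei$spin)) > 1e-9
  if (any(bad))
    stop("invalid nuclear spin quantum number(s): ",
         paste(nuclei$spin[bad], collapse = ", "),
         " (must be non-negative half-integers)", call. = FALSE)
  if (!all(nuclei$radical %in% c(1, 2)))
    stop("`radical` must be 1 or 2", call. = FALSE)
  nuclei$radical <- as.integer(nuclei$radical)
  dims <- c(2L, 2L, as.integer(round(2 * nuclei$spin + 1)))
  structure(list(nuclei = nuclei, dims = dims, dim = prod(dims)),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat("<spin_system> two electrons + ", nrow(x$nuclei), " nuclei, dimension ",
      x$dim, "\n", sep = "")
  if (nrow(x$nuclei)) print(x$nuclei)
  invisible(x)
}

# Cartesian spin matrices for a single spin quantum number I (2I+1 x 2I+1)
.single_spin_matrices <- function(I) {
  m <- seq(I, -I, by = -1)
  n <- length(m)
  sp <- matrix(0i, n, n)
  for (k in seq_len(max(n - 1, 0)))
    sp[k, k + 1] <- sqrt(I * (I + 1) - m[k + 1] * (m[k + 1] + 1))
  sm <- Conj(t(sp))
  list(x = (sp + sm) / 2, y = (sp - sm) / 2i, z = diag(m, n) + 0i)
}

.op_at <- function(dims, pos, M) {
  mats <- lapply(dims, function(d) diag(d) + 0i)
  mats[[pos]] <- M
  Reduce(kronecker, mats)
}

#' Build composite-space spin operators
#'
#' Constructs the Cartesian spin operators of both electrons and all nuclei on
#' the full tensor-product space. Basis ordering is fixed as
#' electron 1 (x) electron 2 (x) nuclei in declaration order, so serialized
#' operators are reproducible.
#'
#' @param system A [spin_system()].
#' @return An object of class `spin_operators`: lists `S1`, `S2` and `nuc`
#'   (per-nucleus) each holding `x`, `y`, `z` complex matrices, plus `id`,
#'   `dim` and the originating `system`. All operators are Hermitian and
#'   satisfy the angular-momentum algebra `[Sx, Sy] = i Sz` (cyclic).
#' @export
#' @examples
#' ops <- spin_operators(spin_system(1))
#' dim(ops$S1$x)   # 12 x 12
spin_operators <- function(system) {
  stopifnot(inherits(system, "spin_system"))
  dims <- system$dims
  if (system$dim > 1024)
    warning("Hilbert dimension ", system$dim,
            " > 1024; dense Liouville-space solves will be impractical")
  e <- .single_spin_matrices(1 / 2)
  S1 <- lapply(e, function(M) .op_at(dims, 1L, M))
  S2 <- lapply(e, function(M) .op_at(dims, 2L, M))
  nuc <- lapply(seq_len(nrow(system$nuclei)), function(k) {
    s <- .single_spin_matrices(system$nuclei$spin[k])
    lapply(s, function(M) .op_at(dims, 2L + k, M))
  })
  names(nuc) <- system$nuclei$label
  structure(list(S1 = S1, S2 = S2, nuc = nuc,
                 id = diag(system$dim) + 0i, dim = system$dim,
                 system = system),
            class = "spin_operators")
}

# S_a . S_b for two xyz operator triples
.dot_ss <- function(a, b) a$x %*% b$x + a$y %*% b$y + a$z %*% b$z

#' Electronic singlet and triplet projectors
#'
#' The singlet projector on the composite space is
#' `P_S = I/4 - S1 . S2`; the triplet projector is its complement.
#' Their traces are 1x and 3x the nuclear-space dimension respectively, and
#' both commute with every nuclear operator.
#'
#' @param ops A [spin_operators()] object (or a [spin_system()], in which case
#'   operators are built internally).
#' @return List with Hermitian idempotent matrices `PS` and `PT`.
#' @export
#' @examples
#' pr <- electronic_projectors(spin_system())
#' sum(diag(pr$PS))   # 1
electronic_projectors <- function(ops) {
  if (inherits(ops, "spin_system")) ops <- spin_operators(ops)
  stopifnot(inherits(ops, "spin_operators"))
  PS <- ops$id / 4 - .dot_ss(ops$S1, ops$S2)
  list(PS = PS, PT = ops$id - PS)
}
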