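#' Declarative run configuration for a radical-pair model
#'
#' Bundles everything needed to assemble the spin Hamiltonian and the reaction
#' scheme: the spin system, hyperfine tensors, the inter-radical geometry (a
#' displacement vector, from which a point-dipole tensor is built, or an
#' explicit dipolar tensor), exchange coupling, the magnetic field, the
#' recombination rates, the initial spin multiplicity, and optional noise
#' channel declarations for the relaxation superoperator.
#'
#' @param system A [spin_system()].
#' @param hyperfine List of 3x3 tensors in MHz (one per nucleus); a single
#'   matrix is accepted for one nucleus.
#' @param displacement Inter-radical displacement vector in Angstrom, or
#'   `NULL` if `eed_tensor` is given (or no dipolar coupling is wanted).
#' @param eed_tensor Optional explicit 3x3 symmetric traceless tensor (MHz);
#'   overrides `displacement`.
#' @param exchange_J Exchange coupling J in MHz (default 0).
#' @param field A [field_vector()]; the magnitude is used by orientation scans,
#'   the direction as the default single-run direction.
#' @param rates A [reaction_rates()].
#' @param initial `"triplet"` (default; ground-state oxygen makes the nascent
#'   pair triplet-born) or `"singlet"`.
#' @param noise Optional list of noise declarations, each a list with `kind`
#'   (`"rfr"`, `"eed_amplitude"`, `"exchange"`, `"st_dephasing"`, `"tensor"`),
#'   `gamma` or `variance`, `tau_c_ns`, and kind-specific fields (`axis`,
#'   `stats`, `mode`). See [rfr_channels()] and friends.
#' @return Object of class `rp_config`.
#' @seealso [toy_n5_config()] for the canonical one-nitrogen model.
#' @export
rp_config <- function(system, hyperfine = list(), displacement = NULL,
                      eed_tensor = NULL, exchange_J = 0,
                      field = field_vector(50), rates = reaction_rates(1, 1),
                      initial = c("triplet", "singlet"), noise = NULL) {
  stopifnot(inherits(system, "spin_system"))
  initial <- match.arg(initial)
  if (is.matrix(hyperfine)) hyperfine <- list(hyperfine)
  if (length(hyperfine) != nrow(system$nuclei))
    stop("need one hyperfine tensor per nucleus", call. = FALSE)
  if (!is.null(displacement)) stopifnot(length(displacement) == 3)
  structure(list(system = system, hyperfine = hyperfine,
                 displacement = displacement, eed_tensor = eed_tensor,
                 exchange_J = exchange_J, field = .as_field(field),
                 rates = rates, initial = initial, noise = noise),
            class = "rp_config")
}

#' @export
print.rp_config <- function(x, ...) {
  cat("<rp_config> dim", x$system$dim,
      "| kS =", x$rates$kS, "kT =", x$rates$kT, "us^-1",
      "| |B| =", x$field$magnitude, "uT",
      "|", x$initial, "born\n")
  if (!is.null(x$displacement))
    cat("  displacement:", paste(signif(x$displacement, 4), collapse = ", "),
        "A  (d =", signif(dipolar_coupling(sqrt(sum(x$displacement^2))), 4),
        "MHz)\n")
  if (!is.null(x$noise)) cat(" ", length(x$noise), "noise channel group(s)\n")
  invisible(x)
}

#' Canonical one-nitrogen toy model
#'
#' The minimal flavin-superoxide model: two electrons plus the dominant
#' flavin N5 nucleus (I = 1) with an idealized axial hyperfine tensor
#' (A_perp = -2.6 MHz, A_par = 49.2 MHz, unique axis z), superoxide displaced
#' at contact distance along x (perpendicular to the hyperfine axis -- the
#' geometry that maximizes the directional effect), a geomagnetic-strength
#' field, and strongly asymmetric recombination at the peak-sensitivity rates.
#'
#' @param r Inter-radical distance in Angstrom (default 4.56, the mean
#'   separation seen in binding-pocket molecular-dynamics simulations).
#' @param axis Displacement direction (unit vector; default x).
#' @param a_perp,a_par Axial hyperfine principal values in MHz.
#' @param b_ut Field magnitude in uT.
#' @param kS,kT Recombination rate constants in us^-1.
#' @param noise Optional noise declarations, as in [rp_config()].
#' @param idealized If `TRUE`, set A_perp = 0 (the reduced model used for the
#'   effective-Hamiltonian spectral analysis).
#' @return An [rp_config()].
#' @export
#' @examples
#' cfg <- toy_n5_config()
toy_n5_config <- function(r = 4.56, axis = c(1, 0, 0),
                          a_perp = -2.6, a_par = 49.2, b_ut = 50,
                          kS = 3.74, kT = 1e-3, noise = NULL,
                          idealized = FALSE) {
  if (idealized) a_perp <- 0
  sys <- spin_system(tibble::tibble(spin = 1, radical = 1, label = "N5"))
  rp_config(system = sys,
            hyperfine = list(diag(c(a_perp, a_perp, a_par))),
            displacement = r * axis / sqrt(sum(axis^2)),
            field = field_vector(b_ut),
            rates = reaction_rates(kS, kT),
            initial = "triplet", noise = noise)
}

#' Assemble the coherent spin Hamiltonian of a configuration
#'
#' Sums Zeeman, hyperfine, electron-electron dipolar and exchange terms.
#'
#' @param config An [rp_config()].
#' @param ops [spin_operators()] for `config$system` (built if omitted).
#' @param field_direction Optional override of the field direction (length-3);
#'   the configured magnitude is retained. Used by orientation scans.
#' @return Hermitian Hamiltonian matrix in rad us^-1.
#' @export
spin_hamiltonian <- function(config, ops = NULL, field_direction = NULL) {
  stopifnot(inherits(config, "rp_config"))
  if (is.null(ops)) ops <- spin_operators(config$system)
  fld <- if (is.null(field_direction)) config$field else
    field_vector(config$field$magnitude, field_direction)
  H <- zeeman_term(fld, ops)
  if (length(config$hyperfine)) H <- H + hyperfine_term(config$hyperfine, ops)
  D <- .eed_tensor_of(config)
  if (!is.null(D)) H <- H + dipolar_term(D, ops)
  if (config$exchange_J != 0) H <- H + exchange_term(config$exchange_J, ops)
  H
}

.eed_tensor_of <- function(config) {
  if (!is.null(config$eed_tensor)) config$eed_tensor
  else if (!is.null(config$displacement)) point_dipole_tensor(config$displacement)
  else NULL
}

#' Write / read a run configuration as JSON
#'
#' Serializes the `system`, tensors, geometry, field, rates and noise sections
#' so runs are reproducible across machines.
#'
#' @param config An [rp_config()].
#' @param path File path.
#' @return `write_rp_config()` returns `path` invisibly; `read_rp_config()`
#'   returns an [rp_config()].
#' @export
write_rp_config <- function(config, path) {
  stopifnot(inherits(config, "rp_config"))
  x <- list(
    system = list(nuclei = as.data.frame(config$system$nuclei)),
    hyperfine = lapply(config$hyperfine, unclass),
    displacement = config$displacement,
    eed_tensor = config$eed_tensor,
    exchange_J = config$exchange_J,
    field = list(magnitude = config$field$magnitude,
                 direction = config$field$direction),
    rates = list(kS = config$rates$kS, kT = config$rates$kT),
    initial = config$initial,
    noise = config$noise
  )
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_rp_config
#' @export
#' @examples
#' cfg <- read_rp_config(system.file("extdata", "toy_n5.json",
#'                                   package = "zenospin"))
#' cfg
read_rp_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sys <- if (length(x$system$nuclei)) spin_system(x$system$nuclei)
         else spin_system()
  raw <- x$hyperfine
  hf <- if (is.null(raw) || (is.list(raw) && !length(raw))) list()
  else if (is.array(raw) && length(dim(raw)) == 3)
    lapply(seq_len(dim(raw)[1]), function(i) {
      A <- raw[i, , ]; storage.mode(A) <- "double"; A
    })
  else if (is.matrix(raw)) {
    storage.mode(raw) <- "double"; list(raw)
  } else lapply(raw, function(A) {
    A <- as.matrix(A); storage.mode(A) <- "double"; A
  })
  noise <- x$noise
  if (!is.null(noise) && is.data.frame(noise))
    noise <- lapply(seq_len(nrow(noise)), function(i) as.list(noise[i, ]))
  rp_config(system = sys, hyperfine = hf,
            displacement = x$displacement,
            eed_tensor = if (!is.null(x$eed_tensor)) as.matrix(x$eed_tensor),
            exchange_J = x$exchange_J %||% 0,
            field = field_vector(x$field$magnitude, unlist(x$field$direction)),
            rates = reaction_rates(x$rates$kS, x$rates$kT),
            initial = x$initial, noise = noise)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spin-density sites from a PDB structure
#'
#' Reads atom coordinates from a PDB file and returns them as a spin-density
#' site table (equal populations by default) for
#' [distributed_dipole_tensor()]. Requires the `bio3d` package.
#'
#' @param path PDB file path.
#' @param chain,resno,elety Optional atom selectors (chain id, residue
#'   number(s), atom name(s)) passed to `bio3d::atom.select()`.
#' @return Tibble with columns `x`, `y`, `z` (Angstrom), `population`, `label`.
#' @export
sites_from_pdb <- function(path, chain = NULL, resno = NULL, elety = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("sites_from_pdb() needs the bio3d package", call. = FALSE)
  pdb <- bio3d::read.pdb(path)
  args <- list(pdb)
  if (!is.null(chain)) args$chain <- chain
  if (!is.null(resno)) args$resno <- resno
  if (!is.null(elety)) args$elety <- elety
  sel <- do.call(bio3d::atom.select, args)
  at <- pdb$atom[sel$atom, , drop = FALSE]
  if (!nrow(at)) stop("no atoms matched the selection", call. = FALSE)
  tibble::tibble(x = at$x, y = at$y, z = at$z,
                 population = 1 / nrow(at), label = at$elety)
}
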