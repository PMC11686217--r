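# Spectral analysis of the effective non-Hermitian Hamiltonian
# H_eff = H - iK. Under strongly asymmetric recombination the imaginary
# parts of its slow eigenvalues shrink as 1/k_S -- the quantum Zeno
# signature -- and the number of slowly depopulating states differs between
# field directions parallel and perpendicular to the dipolar axis, which is
# the origin of the large directional magnetic field effect.

# electronic label states in the e1 (x) e2 basis {aa, ab, ba, bb}
.electronic_label_states <- function(basis = c("lambda", "t0")) {
  basis <- match.arg(basis)
  s  <- c(0, 1, -1, 0) / sqrt(2)
  t0 <- c(0, 1, 1, 0) / sqrt(2)
  tp <- c(1, 0, 0, 0)
  tm <- c(0, 0, 0, 1)
  tsig <- (tp + tm) / sqrt(2)   # symmetric T+/T- combination
  tdel <- (tp - tm) / sqrt(2)
  if (basis == "t0")
    list(S = s, T0 = t0, T_Sigma = tsig, T_Delta = tdel)
  else
    list(S = s,
         T_Lambda = (tsig + t0) / sqrt(2),
         T_Gamma  = (tsig - t0) / sqrt(2),
         T_Delta  = tdel)
}

#' Spectrum of the effective non-Hermitian Hamiltonian
#'
#' Diagonalizes `H_eff = H - iK` for a given field direction and labels each
#' eigenstate by its dominant electronic character (squared overlap of the
#' nuclear-traced eigenvector density with a labeled electronic basis).
#' Imaginary parts lie in `[-kS/2, 0]` and their sum equals `-Tr K`. The slow
#' triplet recombination can be disregarded for this analysis (`kT = 0` by
#' default), which isolates the Zeno-suppressed depopulation rates.
#'
#' @param config An [rp_config()] (a one-nucleus toy configuration is the
#'   intended use; see [toy_n5_config()]).
#' @param field_direction `"x"`, `"y"`, `"z"` or a length-3 vector.
#' @param kS,kT Recombination rates in us^-1 (defaults: config kS, and 0).
#' @param label_basis `"lambda"` (S, T_Lambda, T_Gamma, T_Delta, the basis of
#'   the x-field discussion, with `T_Lambda/Gamma = (T_Sigma +/- T0)/sqrt(2)`)
#'   or `"t0"` (S, T0, T_Sigma, T_Delta).
#' @return Tibble of class `heff_spectrum`, sorted by `|Im|`: columns
#'   `eigenvalue` (complex), `re`, `im`, `abs_im`, `label`, `overlap`,
#'   `ambiguous` (top-two label overlaps within 1%), `cluster`
#'   (`"zero"`, `"slow"`, `"fast"`).
#' @export
heff_spectrum <- function(config, field_direction = "x", kS = NULL, kT = 0,
                          label_basis = c("lambda", "t0")) {
  stopifnot(inherits(config, "rp_config"))
  label_basis <- match.arg(label_basis)
  dir <- .named_direction(field_direction)
  if (is.null(kS)) kS <- config$rates$kS
  ops <- spin_operators(config$system)
  pr <- electronic_projectors(ops)
  H <- spin_hamiltonian(config, ops, field_direction = dir)
  Heff <- H - 1i * (kS / 2 * pr$PS + kT / 2 * pr$PT)
  ee <- eigen(Heff)
  lam <- ee$values
  n <- length(lam)
  dn <- n / 4   # nuclear dimension
  labs <- .electronic_label_states(label_basis)
  lab_out <- character(n); ovl_out <- numeric(n); amb <- logical(n)
  for (i in seq_len(n)) {
    v <- ee$vectors[, i]
    v <- v / sqrt(sum(Mod(v)^2))
    # partial trace over the (fastest-varying) nuclear factor
    vm <- matrix(v, nrow = dn)          # dn x 4, electronic index as column
    red <- t(vm) %*% Conj(vm)           # red[e,e'] = sum_nu v[nu,e] conj(v[nu,e'])
    ovl <- vapply(labs, function(u) Re(Conj(u) %*% red %*% u)[1], numeric(1))
    o <- order(ovl, decreasing = TRUE)
    lab_out[i] <- names(labs)[o[1]]
    ovl_out[i] <- ovl[o[1]]
    amb[i] <- (ovl[o[1]] - ovl[o[2]]) < 0.01
  }
  out <- tibble::tibble(eigenvalue = lam, re = Re(lam), im = Im(lam),
                        abs_im = abs(Im(lam)), label = lab_out,
                        overlap = ovl_out, ambiguous = amb)
  out <- dplyr::arrange(out, .data$abs_im)
  out$cluster <- .im_clusters(out$abs_im)
  attr(out, "kS") <- kS; attr(out, "kT") <- kT
  attr(out, "field_direction") <- dir
  class(out) <- c("heff_spectrum", class(out))
  out
}

.named_direction <- function(d) {
  if (is.character(d))
    switch(d, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
           stop("unknown direction ", d, call. = FALSE))
  else { stopifnot(length(d) == 3); d / sqrt(sum(d^2)) }
}

# Classify |Im lambda| into numerical-zero / slow / fast clusters.
# Zeros: below an absolute floor tied to eigensolver precision. Among the
# non-zeros, the largest gap in log10|Im| separates the Zeno-suppressed slow
# cluster from the directly recombining fast cluster.
.im_clusters <- function(abs_im) {
  n <- length(abs_im)
  cl <- rep("slow", n)
  floor_ <- 1e4 * .Machine$double.eps * max(abs_im, 1e-300)
  zero <- abs_im <= floor_
  cl[zero] <- "zero"
  nz <- which(!zero)
  if (length(nz) >= 2) {
    lg <- log10(abs_im[nz])
    o <- order(lg)
    gaps <- diff(lg[o])
    cut <- which.max(gaps)
    if (max(gaps) > 0.5) {   # require a visible cluster separation
      fast <- nz[o][(cut + 1):length(nz)]
      cl[fast] <- "fast"
    } else cl[nz] <- "fast"  # no separation: single reactive cluster
  } else if (length(nz)) cl[nz] <- "fast"
  cl
}

#' Count slowly decaying eigenstates
#'
#' Number of eigenstates in the slow (Zeno-suppressed) cluster of a
#' [heff_spectrum()]. With `distinct = TRUE` (default) degenerate decay
#' rates are counted once -- for the one-nitrogen toy the nuclear `m = +/-1`
#' symmetry doubles every slow rate, and the physically meaningful count is
#' per distinct rate: for the idealized toy (`A_perp = 0`) a field along the
#' dipolar axis x leaves two slow states, a field along z only one.
#'
#' @param spectrum A [heff_spectrum()] result.
#' @param distinct Collapse (near-)degenerate rates before counting.
#' @param tol Relative tolerance for rate degeneracy (default 1e-6).
#' @return Integer count.
#' @export
slow_state_count <- function(spectrum, distinct = TRUE, tol = 1e-6) {
  v <- spectrum$abs_im[spectrum$cluster == "slow"]
  if (!length(v)) return(0L)
  if (!distinct) return(length(v))
  v <- sort(v)
  length(v) - sum(diff(v) / v[-1] < tol)
}

#' Quantum Zeno scaling of the slow depopulation rates
#'
#' Fits the log-log slope of the slowest non-zero `|Im lambda|` of `H_eff`
#' (triplet recombination removed) against `k_S`. In the Zeno regime -- `k_S`
#' well above every internal frequency scale, including the dominant
#' electron-electron dipolar coupling -- the slow imaginary parts scale as
#' `1/k_S` (slope -1): faster singlet recombination *protects* the remaining
#' states, the hallmark of the quantum Zeno effect. The default window
#' `[1e4, 1e6]` us^-1 lies above the crossover `k_S ~ 2 d` (about 7e3 us^-1
#' at 4.56 A); below it the slow rates still grow with `k_S` and the fit is
#' refused as non-monotone.
#'
#' @param config An [rp_config()] (one-nucleus toy intended).
#' @param ks_values Rates to scan, spanning at least two decades (default
#'   nine log-spaced points over `[1e4, 1e6]`).
#' @param field_direction As in [heff_spectrum()] (default `"x"`).
#' @param check_monotone Error if the slow rates are not decreasing in `k_S`
#'   (indicates the window reaches below the Zeno regime). Default `TRUE`.
#' @return Object of class `zeno_fit`: list with `slope`, `se`, `data`
#'   (tibble `ks`, `slow_im`), `field_direction`.
#' @export
zeno_scaling <- function(config, ks_values = 10^seq(4, 6, length.out = 9),
                         field_direction = "x", check_monotone = TRUE) {
  stopifnot(length(ks_values) >= 3)
  slow <- vapply(ks_values, function(k) {
    sp <- heff_spectrum(config, field_direction, kS = k, kT = 0)
    v <- sp$abs_im[sp$cluster == "slow"]
    if (!length(v))
      stop("no slow cluster at kS = ", k, call. = FALSE)
    min(v)
  }, numeric(1))
  if (check_monotone && any(diff(slow) >= 0))
    stop("slow depopulation rates are not monotonically decreasing over the ",
         "requested kS values; the window extends below the Zeno regime ",
         "(crossover near kS ~ 2d)", call. = FALSE)
  fit <- lm(log(slow) ~ log(ks_values))
  structure(list(slope = unname(coef(fit)[2]),
                 se = unname(sqrt(diag(vcov(fit)))[2]),
                 data = tibble::tibble(ks = ks_values, slow_im = slow),
                 field_direction = field_direction),
            class = "zeno_fit")
}

#' @export
print.zeno_fit <- function(x, ...) {
  cat(sprintf("<zeno_fit> slope = %.3f (se %.3f) over kS in [%.3g, %.3g] us^-1\n",
              x$slope, x$se, min(x$data$ks), max(x$data$ks)))
  invisible(x)
}
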