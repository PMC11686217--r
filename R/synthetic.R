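# Synthetic stand-ins for trajectory-derived inputs: the displacement of the
# superoxide about its binding-pocket mean position is modelled as a
# stationary Gaussian with exponential temporal autocorrelation. Because the
# second-order relaxation theory needs only the covariance of the fluctuating
# couplings and the correlation time, samples are drawn independently and
# tau_c enters the noise channels as a separate parameter.

#' Gaussian displacement model for the inter-radical vector
#'
#' @param mean Mean displacement vector in Angstrom (default 4.56 A along x:
#'   the contact distance seen in binding-pocket simulations, along the
#'   direction perpendicular to the main hyperfine axis that maximizes the
#'   directional effect).
#' @param sd Per-axis standard deviations in Angstrom (default 0.25 A,
#'   a typical thermal RMS excursion of a small ligand in a pocket).
#' @param tau_c_ns Correlation time in ns (default 1).
#' @param seed Optional integer seed stored with the model.
#' @return Object of class `displacement_model`.
#' @export
displacement_model <- function(mean = c(4.56, 0, 0), sd = rep(0.25, 3),
                               tau_c_ns = 1, seed = NULL) {
  stopifnot(length(mean) == 3)
  if (length(sd) == 1) sd <- rep(sd, 3)
  stopifnot(length(sd) == 3)
  if (any(sd < 0)) stop("sd must be non-negative", call. = FALSE)
  if (sqrt(sum(mean^2)) == 0) stop("mean displacement must be non-zero",
                                   call. = FALSE)
  structure(list(mean = mean, sd = sd, tau_c_ns = tau_c_ns, seed = seed),
            class = "displacement_model")
}

#' "Trajectory-2-like" displacement model
#'
#' A non-ideal geometry fixture: the mean inter-radical vector is tilted 30
#' degrees below the ring plane (towards -z), qualitatively emulating a
#' trajectory in which the superoxide slides below the flavin ring plane.
#' It exercises the suboptimal-geometry pathway; no claim is made of
#' matching any particular trajectory's statistics.
#'
#' @param r Mean distance in Angstrom.
#' @param sd,tau_c_ns,seed As in [displacement_model()].
#' @return A `displacement_model`.
#' @export
traj2_displacement_model <- function(r = 4.56, sd = rep(0.25, 3),
                                     tau_c_ns = 1, seed = NULL) {
  displacement_model(mean = r * c(cos(pi / 6), 0, -sin(pi / 6)),
                     sd = sd, tau_c_ns = tau_c_ns, seed = seed)
}

#' Sample displacement vectors
#'
#' Independent Gaussian draws about the model mean (temporal correlation
#' enters the relaxation theory only through `tau_c`).
#'
#' @param model A [displacement_model()].
#' @param n Number of samples.
#' @param seed Integer seed (falls back to `model$seed`); the draw is
#'   reproducible whenever a seed is given.
#' @return Tibble with columns `x`, `y`, `z` (Angstrom).
#' @export
sample_displacements <- function(model, n, seed = model$seed) {
  stopifnot(inherits(model, "displacement_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(x = rnorm(n, model$mean[1], model$sd[1]),
                 y = rnorm(n, model$mean[2], model$sd[2]),
                 z = rnorm(n, model$mean[3], model$sd[3]))
}

#' Dipolar-tensor statistics of displacement samples
#'
#' Maps every sampled displacement to its point-dipole tensor and summarizes:
#' the mean tensor, the 5x5 covariance of the traceless-symmetric components
#' (basis `{(Dxx-Dyy)/2, Dzz, Dxy, Dxz, Dyz}`), and the variance of the
#' scalar coupling parameter `d(|r|)` from which the effective
#' dipolar-relaxation rate `gamma = Var(d) tau_c` follows.
#'
#' @param samples Tibble/data frame with columns `x`, `y`, `z` (Angstrom), or
#'   an n x 3 matrix.
#' @return Object of class `tensor_stats`: `mean_tensor` (MHz),
#'   `cov` (MHz^2, 5x5), `var_d_mhz2`, `n`.
#' @export
tensor_statistics <- function(samples) {
  if (is.data.frame(samples)) samples <- as.matrix(samples[, c("x", "y", "z")])
  if (nrow(samples) < 2)
    stop("need at least 2 samples", call. = FALSE)
  tens <- lapply(seq_len(nrow(samples)),
                 function(i) point_dipole_tensor(samples[i, ]))
  comps <- t(vapply(tens, tensor_components, numeric(5)))
  dvals <- dipolar_coupling(sqrt(rowSums(samples^2)), "MHz")
  structure(list(mean_tensor = Reduce(`+`, tens) / length(tens),
                 cov = cov(comps),
                 var_d_mhz2 = var(dvals),
                 n = nrow(samples)),
            class = "tensor_stats")
}

#' @export
print.tensor_stats <- function(x, ...) {
  cat("<tensor_stats> n =", x$n,
      "| Var(d) =", signif(x$var_d_mhz2, 4), "MHz^2",
      "(gamma at 1 ns:", signif(effective_gamma(x, 1), 4), "us^-1)\n")
  invisible(x)
}

#' Effective dipolar relaxation rate gamma = Var(d) tau_c
#'
#' Converts the sampled variance of the scalar dipolar coupling to the
#' effective relaxation rate in us^-1 (variance in angular-frequency units
#' times the correlation time).
#'
#' @param stats A [tensor_statistics()] result (or variance in MHz^2).
#' @param tau_c_ns Correlation time in ns.
#' @return Rate in us^-1.
#' @export
effective_gamma <- function(stats, tau_c_ns = 1) {
  v <- if (inherits(stats, "tensor_stats")) stats$var_d_mhz2 else stats
  v * (2 * pi)^2 * tau_c_ns * 1e-3
}

#' Synthetic spin-density site distributions
#'
#' Generates plausible spin-density site sets for distributed-dipole
#' calculations: `"ring"` places sites on a planar polygon mimicking the
#' spread over an isoalloxazine ring system (radius ~1.4 A in the xy plane),
#' `"diatomic"` two sites along z split by the 1.33 A superoxide bond, and
#' `"point"` a single site. Populations are mildly uneven (log-normal,
#' normalized) for ring sites when a seed is given, equal otherwise.
#'
#' @param template `"ring"`, `"diatomic"` or `"point"`.
#' @param n_sites Number of sites (ring only; >= 1).
#' @param center Center position (Angstrom).
#' @param radius Ring radius in Angstrom.
#' @param seed Optional seed for the population draw.
#' @return Tibble with columns `x`, `y`, `z`, `population` (summing to 1).
#' @export
synthetic_spin_density <- function(template = c("ring", "diatomic", "point"),
                                   n_sites = 8, center = c(0, 0, 0),
                                   radius = 1.4, seed = NULL) {
  template <- match.arg(template)
  stopifnot(n_sites >= 1)
  if (template == "point" || (template == "ring" && n_sites == 1)) {
    pos <- matrix(center, 1, 3)
    pop <- 1
  } else if (template == "diatomic") {
    pos <- rbind(center + c(0, 0, 1.33 / 2), center - c(0, 0, 1.33 / 2))
    pop <- c(0.5, 0.5)
  } else {
    ang <- 2 * pi * (seq_len(n_sites) - 1) / n_sites
    pos <- cbind(center[1] + radius * cos(ang),
                 center[2] + radius * sin(ang),
                 center[3] + 0)
    if (!is.null(seed)) {
      set.seed(seed)
      w <- exp(rnorm(n_sites, 0, 0.5))
    } else w <- rep(1, n_sites)
    pop <- w / sum(w)
  }
  tibble::tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3], population = pop)
}

#' Tilted / rhombic hyperfine tensor
#'
#' Builds `R diag(A_xx, A_yy, A_par) R^T` with `A_xx = a_perp + rhombicity`,
#' `A_yy = a_perp - rhombicity` (rhombicity `E = (A_xx - A_yy)/2`) and `R`
#' the ZYZ Euler rotation of the principal axes relative to the molecular
#' frame. The principal values are invariant under the tilt.
#'
#' @param a_perp,a_par Axial principal values in MHz (defaults: the flavin N5
#'   values -2.6 and 49.2).
#' @param rhombicity `E` in MHz (default 0).
#' @param tilt ZYZ Euler angles in degrees, length 3.
#' @return 3x3 symmetric tensor in MHz.
#' @export
#' @examples
#' tilted_hyperfine()                     # diag(-2.6, -2.6, 49.2)
#' tilted_hyperfine(tilt = c(0, 90, 0))   # unique axis rotated z -> x
tilted_hyperfine <- function(a_perp = -2.6, a_par = 49.2, rhombicity = 0,
                             tilt = c(0, 0, 0)) {
  stopifnot(length(tilt) == 3)
  R <- .rot_z(tilt[1]) %*% .rot_y(tilt[2]) %*% .rot_z(tilt[3])
  R %*% diag(c(a_perp + rhombicity, a_perp - rhombicity, a_par)) %*% t(R)
}

.rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
.rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
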