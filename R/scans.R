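#' Quasi-uniform orientations on the sphere (Fibonacci lattice)
#'
#' Deterministic golden-angle spiral: `z_i = 1 - 2 (i + 1/2) / N`,
#' `phi_i = 2 pi i (2 - phi_golden)`, `i = 0 .. N-1`. Fixed so that scan
#' results are bit-reproducible.
#'
#' @param n Number of orientations (>= 1).
#' @return Tibble with columns `index`, `x`, `y`, `z`, `theta`, `phi`
#'   (unit vectors; physics convention for the angles).
#' @export
#' @examples
#' fibonacci_sphere(300)
fibonacci_sphere <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  phi <- 2 * pi * i * (2 - (1 + sqrt(5)) / 2)
  rho <- sqrt(pmax(0, 1 - z^2))
  tibble::tibble(index = i + 1L,
                 x = rho * cos(phi), y = rho * sin(phi), z = z,
                 theta = acos(z), phi = atan2(sin(phi), cos(phi)))
}

#' Anisotropy metrics of a set of singlet yields
#'
#' Directional magnetic-field-effect measures over a set of field
#' orientations: the absolute anisotropy `Delta Phi_S = max - min` and the
#' relative anisotropy `S = Delta Phi_S / mean(Phi_S)` (quoted as a
#' percentage in `s_pct`).
#'
#' @param yields Numeric vector of singlet yields (>= 2 values), or an
#'   orientation-scan tibble with a `phi_s` column.
#' @return One-row tibble of class `anisotropy_metrics`: `n`, `phi_bar`,
#'   `phi_max`, `phi_min`, `delta_phi`, `s`, `s_pct`.
#' @export
anisotropy_metrics <- function(yields) {
  if (is.data.frame(yields)) yields <- yields$phi_s
  if (length(yields) < 2)
    stop("need at least 2 yields to quantify anisotropy", call. = FALSE)
  m <- mean(yields)
  out <- tibble::tibble(n = length(yields), phi_bar = m,
                        phi_max = max(yields), phi_min = min(yields),
                        delta_phi = max(yields) - min(yields))
  out$s <- out$delta_phi / out$phi_bar
  out$s_pct <- 100 * out$s
  class(out) <- c("anisotropy_metrics", class(out))
  out
}

#' Singlet-yield anisotropy over field orientations
#'
#' Computes the singlet recombination yield for every orientation of the
#' magnetic field (molecular frame fixed, field direction scanned --
#' equivalent to reorienting a rigid pair), then summarizes the directional
#' magnetic field effect. When noise channels are declared, the relaxation
#' superoperator is rebuilt for every orientation since it depends on
#' `H_eff`.
#'
#' @param config An [rp_config()].
#' @param orientations Integer (Fibonacci-sphere size, default 300) or a
#'   matrix/tibble of unit vectors (columns `x`, `y`, `z`).
#' @param rates Optional [reaction_rates()] override.
#' @param noise Optional noise channel group(s) (overrides `config$noise`);
#'   see [rfr_channels()], [scalar_fluctuation_channel()],
#'   [tensor_fluctuation_channels()].
#' @param engine `"cpp"` (compiled eigenbasis kernel, default) or `"r"`
#'   (pure-R reference path).
#' @return Tibble of class `anisotropy_scan` with one row per orientation
#'   (`x`, `y`, `z`, `theta`, `phi`, `phi_s`, `phi_t`); the metrics row is
#'   attached as attribute `"metrics"` and via [glance()].
#' @export
#' @examples
#' \donttest{
#' scan <- orientation_scan(toy_n5_config(), orientations = 50)
#' glance(scan)
#' }
orientation_scan <- function(config, orientations = 300, rates = NULL,
                             noise = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "rp_config"))
  dirs <- if (is.numeric(orientations) && length(orientations) == 1)
    fibonacci_sphere(orientations) else tibble::as_tibble(orientations)
  ops <- spin_operators(config$system)
  channels <- if (!is.null(noise)) noise else .build_noise(config, ops)
  ys <- .yield_batch(config, dirs[, c("x", "y", "z")], rates = rates,
                     ops = ops, channels = channels, engine = engine)
  out <- dplyr::bind_cols(dirs, ys)
  if (!"theta" %in% names(out)) {
    out$theta <- acos(pmin(1, pmax(-1, out$z)))
    out$phi <- atan2(out$y, out$x)
  }
  attr(out, "metrics") <- anisotropy_metrics(ys$phi_s)
  attr(out, "rates") <- if (is.null(rates)) config$rates else rates
  attr(out, "b_ut") <- config$field$magnitude
  class(out) <- c("anisotropy_scan", class(out))
  out
}

#' Relative anisotropy over a grid of recombination rates
#'
#' Repeats the orientation scan at every node of a logarithmic
#' `(k_S, k_T)` grid and records the anisotropy metrics, producing the
#' rate-space sensitivity heatmap whose asymmetric branch (`k_S >> k_T`)
#' carries the quantum-Zeno-boosted magnetic field effects.
#'
#' @param config An [rp_config()].
#' @param ks,kt Rate grids in us^-1 (vectors, possibly length 1); `NULL`
#'   (default) uses `n_grid` log-spaced points over `[1e-3, 1e6]`.
#' @param n_grid Size of the default log-spaced grids (default 16).
#' @param orientations As in [orientation_scan()] (default 100 for grids).
#' @param noise Optional noise channel group(s).
#' @param engine `"cpp"` or `"r"`.
#' @return Tibble of class `rate_grid` with columns `ks`, `kt`, `phi_bar`,
#'   `delta_phi`, `s_pct` (plus `failed` flag); attributes `s_max`, `argmax`.
#' @export
rate_grid_scan <- function(config, ks = NULL, kt = NULL, n_grid = 16,
                           orientations = 100, noise = NULL,
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.null(ks)) ks <- 10^seq(-3, 6, length.out = n_grid)
  if (is.null(kt)) kt <- 10^seq(-3, 6, length.out = n_grid)
  stopifnot(all(ks > 0), all(kt > 0))
  dirs <- if (is.numeric(orientations) && length(orientations) == 1)
    fibonacci_sphere(orientations) else tibble::as_tibble(orientations)
  ops <- spin_operators(config$system)
  channels <- if (!is.null(noise)) noise else .build_noise(config, ops)
  grid <- tidyr::expand_grid(ks = ks, kt = kt)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    r <- reaction_rates(grid$ks[i], grid$kt[i])
    m <- tryCatch({
      ys <- .yield_batch(config, dirs[, c("x", "y", "z")], rates = r,
                         ops = ops, channels = channels, engine = engine)
      anisotropy_metrics(ys$phi_s)
    }, error = function(e) NULL)
    if (is.null(m))
      tibble::tibble(ks = r$kS, kt = r$kT, phi_bar = NA_real_,
                     delta_phi = NA_real_, s_pct = NA_real_, failed = TRUE)
    else
      tibble::tibble(ks = r$kS, kt = r$kT, phi_bar = m$phi_bar,
                     delta_phi = m$delta_phi, s_pct = m$s_pct, failed = FALSE)
  })
  nfail <- sum(res$failed)
  if (nfail > 0)
    warning(nfail, " grid node(s) failed; see the `failed` column")
  best <- dplyr::slice_max(dplyr::filter(res, !.data$failed), .data$s_pct,
                           n = 1, with_ties = FALSE)
  attr(res, "s_max") <- best$s_pct
  attr(res, "argmax") <- c(ks = best$ks, kt = best$kt)
  attr(res, "orientations") <- nrow(dirs)
  class(res) <- c("rate_grid", class(res))
  res
}

#' Anisotropy as a function of field magnitude
#'
#' Runs the orientation scan at a series of field strengths at fixed rates;
#' for the contact-distance toy pair the directional effect persists and
#' grows from the geomagnetic 50 uT up to tens of mT.
#'
#' @param config An [rp_config()].
#' @param magnitudes Field magnitudes in uT (> 0).
#' @param orientations,noise,engine As in [orientation_scan()].
#' @return Tibble of class `field_scan` with `b_ut`, `phi_bar`, `delta_phi`,
#'   `s_pct`.
#' @export
field_scan <- function(config, magnitudes, orientations = 100, noise = NULL,
                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(all(magnitudes > 0))
  res <- purrr::map_dfr(magnitudes, function(b) {
    cfg <- config
    cfg$field <- field_vector(b, config$field$direction)
    sc <- orientation_scan(cfg, orientations = orientations, noise = noise,
                           engine = engine)
    m <- attr(sc, "metrics")
    tibble::tibble(b_ut = b, phi_bar = m$phi_bar, delta_phi = m$delta_phi,
                   s_pct = m$s_pct)
  })
  class(res) <- c("field_scan", class(res))
  res
}
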