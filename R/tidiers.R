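# broom-style accessors and ggplot2 autoplot methods for the result types.

#' @export
tidy.anisotropy_scan <- function(x, ...) {
  tibble::as_tibble(unclass(x))[, c("theta", "phi", "x", "y", "z",
                                    "phi_s", "phi_t")]
}

#' @export
glance.anisotropy_scan <- function(x, ...) {
  m <- attr(x, "metrics")
  r <- attr(x, "rates")
  dplyr::mutate(m, ks = r$kS, kt = r$kT, b_ut = attr(x, "b_ut"))
}

#' @export
tidy.rate_grid <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.rate_grid <- function(x, ...) {
  am <- attr(x, "argmax")
  tibble::tibble(s_max_pct = attr(x, "s_max"),
                 ks_opt = am[["ks"]], kt_opt = am[["kt"]],
                 n_nodes = nrow(x), n_failed = sum(x$failed),
                 orientations = attr(x, "orientations"))
}

#' @export
tidy.heff_spectrum <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
tidy.zeno_fit <- function(x, ...) {
  tibble::tibble(term = "log(kS)", estimate = x$slope, std.error = x$se)
}

#' @export
glance.zeno_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, se = x$se, n = nrow(x$data),
                 ks_min = min(x$data$ks), ks_max = max(x$data$ks),
                 field_direction = paste(x$field_direction, collapse = ","))
}

#' @export
tidy.yield_value <- function(x, ...) {
  tibble::tibble(phi_s = x$phi_s, phi_t = x$phi_t)
}

#' Plot methods
#'
#' `autoplot()` methods: orientation scans map the yield over the sphere
#' (theta-phi plane), rate grids render the log-log sensitivity heatmap with
#' the argmax marked, field scans and Zeno fits give the corresponding
#' curves.
#'
#' @param object A result object from [orientation_scan()],
#'   [rate_grid_scan()], [field_scan()] or [zeno_scaling()].
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-zenospin
NULL

#' @rdname autoplot-zenospin
#' @export
autoplot.anisotropy_scan <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$phi, y = .data$theta,
                               colour = .data$phi_s)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(name = expression(Phi[S])) +
    ggplot2::labs(x = expression(phi ~ "(rad)"),
                  y = expression(theta ~ "(rad)"),
                  title = "Singlet yield over field orientations") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-zenospin
#' @export
autoplot.rate_grid <- function(object, ...) {
  am <- attr(object, "argmax")
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$ks, y = .data$kt,
                               fill = .data$s_pct)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = tibble::tibble(ks = am[["ks"]],
                                              kt = am[["kt"]]),
                        ggplot2::aes(x = .data$ks, y = .data$kt),
                        inherit.aes = FALSE, shape = 4, colour = "white") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey80") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "S (%)") +
    ggplot2::labs(x = expression(k[S] ~ (mu * s^-1)),
                  y = expression(k[T] ~ (mu * s^-1)),
                  title = "Relative anisotropy over recombination rates") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-zenospin
#' @export
autoplot.field_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$b_ut, y = .data$s_pct)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "|B| (uT)", y = "S (%)",
                  title = "Anisotropy vs field magnitude") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-zenospin
#' @export
autoplot.zeno_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ks, y = .data$slow_im)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(k[S] ~ (mu * s^-1)),
                  y = expression("slowest" ~ "|Im" ~ lambda * "|" ~
                                   (mu * s^-1)),
                  title = sprintf("Quantum Zeno scaling (slope %.2f)",
                                  object$slope)) +
    ggplot2::theme_minimal()
}
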