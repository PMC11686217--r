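# Internal dispatcher computing (Phi_S, Phi_T) for a batch of field
# directions. engine = "cpp" uses the compiled eigenbasis kernel; engine = "r"
# runs the full pure-R reference path (dense Liouville-space assembly +
# nz_superoperator + singlet_yield), which is slower but serves as the
# independent route in the test suite.
.yield_batch <- function(config, dirs, rates = NULL, ops = NULL,
                         channels = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.null(ops)) ops <- spin_operators(config$system)
  if (is.null(rates)) rates <- config$rates
  if (is.null(channels)) channels <- .build_noise(config, ops)
  pr <- electronic_projectors(ops)
  rho0 <- initial_state(ops, config$initial)
  H0 <- spin_hamiltonian(.zero_field(config), ops)   # field-independent part
  omega <- .gamma_e * config$field$magnitude
  SX <- ops$S1$x + ops$S2$x
  SY <- ops$S1$y + ops$S2$y
  SZ <- ops$S1$z + ops$S2$z
  dirs <- as.matrix(dirs)
  stopifnot(ncol(dirs) == 3)

  grp <- .flatten_channels(channels)
  if (engine == "cpp") {
    out <- yield_batch_cpp(H0, SX, SY, SZ, dirs, omega, pr$PS, pr$PT,
                           rates$kS, rates$kT, rho0,
                           grp$ops, grp$cov, grp$tau_c,
                           length(grp$ops) > 0)
    return(tibble::tibble(phi_s = out[, 1], phi_t = out[, 2]))
  }
  res <- purrr::map_dfr(seq_len(nrow(dirs)), function(q) {
    H <- H0 + omega * (dirs[q, 1] * SX + dirs[q, 2] * SY + dirs[q, 3] * SZ)
    gen <- reactive_liouvillian(H, haberkorn_operator(rates, pr))
    rel <- if (length(grp$ops)) nz_superoperator(channels, gen) else NULL
    y <- singlet_yield(rho0, gen, rates, relaxation = rel, projectors = pr)
    tibble::tibble(phi_s = y$phi_s, phi_t = y$phi_t)
  })
  res
}

.zero_field <- function(config) {
  config$field <- field_vector(0, c(0, 0, 1))
  config
}

# Merge channel groups into a single operator list + block covariance.
# Groups must share tau_c (cross-kind covariances are zero by design).
.flatten_channels <- function(channels) {
  if (is.null(channels))
    return(list(ops = list(), cov = matrix(0, 0, 0), tau_c = 1e-3))
  if (inherits(channels, "noise_channels")) channels <- list(channels)
  channels <- Filter(function(g) length(g$ops) > 0, channels)
  if (!length(channels))
    return(list(ops = list(), cov = matrix(0, 0, 0), tau_c = 1e-3))
  taus <- vapply(channels, function(g) g$tau_c, numeric(1))
  if (length(unique(taus)) > 1)
    stop("all channel groups must share tau_c in a single scan",
         call. = FALSE)
  ops <- do.call(c, lapply(channels, function(g) g$ops))
  m <- length(ops)
  cov <- matrix(0, m, m)
  at <- 0
  for (g in channels) {
    idx <- at + seq_along(g$ops)
    cov[idx, idx] <- g$cov
    at <- at + length(g$ops)
  }
  list(ops = ops, cov = cov, tau_c = taus[1])
}
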