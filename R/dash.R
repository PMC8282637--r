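#' DASH algorithm configuration
#'
#' @param f power fraction in `(0, 1)` sent into the modulated probe
#'   beam; the remaining `1 - f` stays in the corrected reference beam.
#'   0.3 is robust across samples and signal levels.
#' @param P number of phase steps per mode measurement; the phase offset
#'   `phi_p = p * 2*pi/P`, `p = 0 ... P-1`, is cycled and the two-photon
#'   signal recorded at each step. Three steps are the minimum that
#'   determines amplitude and phase; 5 matches the experimental protocol.
#' @param iterations number of passes through the mode basis.
#' @param skip_zero_mode_first_iteration if `TRUE` the zero-frequency
#'   mode is not measured during the first iteration (it is then
#'   indistinguishable from the flat reference); it is measured in later
#'   iterations.
#' @param use_sqrt if `TRUE` (default) the phase-stepping estimator works
#'   on the square root of the recorded two-photon signal, which is
#'   linear in the interfering field amplitude.
#' @return An object of class `"dash_config"`.
#' @examples
#' dash_config(P = 3, iterations = 20)
#' @export
dash_config <- function(f = 0.3, P = 5L, iterations = 1L,
                        skip_zero_mode_first_iteration = TRUE,
                        use_sqrt = TRUE) {
  if (!is.numeric(f) || f <= 0 || f >= 1)
    stop("f must lie strictly between 0 and 1", call. = FALSE)
  P <- as.integer(P)
  if (P < 3L) stop("P must be >= 3 (phase stepping is underdetermined ",
                   "below three steps)", call. = FALSE)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  structure(list(f = f, P = P, iterations = as.integer(iterations),
                 skip_zero_mode_first_iteration =
                   isTRUE(skip_zero_mode_first_iteration),
                 use_sqrt = isTRUE(use_sqrt)),
            class = "dash_config")
}

#' @export
print.dash_config <- function(x, ...) {
  cat(sprintf(paste0("<dash_config> f = %g, P = %d, iterations = %d, ",
                     "skip zero mode in iter 1: %s, sqrt estimator: %s\n"),
              x$f, x$P, x$iterations, x$skip_zero_mode_first_iteration,
              x$use_sqrt))
  invisible(x)
}

#' Compose the SLM phase mask for one phase step
#'
#' The SLM splits the beam holographically: the displayed phase is the
#' argument of the weighted sum of the normalised reference field
#' `C/|C|` (weight `sqrt(1-f)`) and the probe grating `exp(1i*(M +
#' phi_p))` (weight `sqrt(f)`), with `phi_p = p * 2*pi/P`. Pixels where
#' the sum vanishes exactly take phase 0 by convention; pixels where
#' `|C| = 0` use a unit reference of phase 0 (with a warning).
#'
#' @param C complex reference field on the SLM grid (a matrix, or a list
#'   with element `C`).
#' @param mode a mode from [build_grating_basis()], or a phase matrix.
#' @param p phase-step index in `0 ... P-1`.
#' @param config a [dash_config()].
#' @return Real phase matrix with values in `(-pi, pi]`.
#' @export
compose_slm_phase <- function(C, mode, p, config) {
  if (is.list(C) && !is.null(C$C)) C <- C$C
  M <- if (is.list(mode)) mode$pattern else mode
  if (p < 0 || p >= config$P) stop("p must be in 0 ... P-1", call. = FALSE)
  modC <- Mod(C)
  if (any(modC == 0)) {
    warning("reference field has zero-modulus pixels; using phase 0 there")
    C[modC == 0] <- 1 + 0i
    modC[modC == 0] <- 1
  }
  phi_p <- p * 2 * pi / config$P
  s <- sqrt(1 - config$f) * (C / modC) +
    sqrt(config$f) * exp(1i * (M + phi_p))
  out <- Arg(s)
  # pixels where the two phasors cancel have no defined phase: 0 by
  # convention (with a numerical tolerance; both weights are O(1))
  out[Mod(s) < 1e-9] <- 0
  out
}

#' Phase-stepping interferometric estimator
#'
#' Given the `P` detected signals recorded while the probe's phase offset
#' `phi_p = p * 2*pi/P` was cycled, extracts the interference term's
#' amplitude and phase as the first discrete Fourier coefficient of the
#' sequence `s_p` (`s_p = sqrt(counts_p)` when `use_sqrt`, making `s_p`
#' linear in field amplitude for a point-like signal):
#' `F1 = (2/P) * sum(s_p * exp(-1i * phi_p))`, `a = |F1|`,
#' `phi = Arg(F1)`. For a noiseless two-beam signal the estimate is exact
#' for any `P >= 3`.
#'
#' @param counts numeric vector of `P` non-negative signals.
#' @param P number of phase steps (defaults to `length(counts)`).
#' @param use_sqrt take the square root of the signal first.
#' @return List with elements `a` (>= 0) and `phi` in `(-pi, pi]`;
#'   `a = 0` forces `phi = 0`.
#' @examples
#' # pure two-beam interference, exact recovery
#' phis <- (0:4) * 2 * pi / 5
#' s <- (1 + 0.25 + 2 * 0.5 * cos(phis - 1))^2
#' phase_step_estimate(s, use_sqrt = TRUE)
#' @export
phase_step_estimate <- function(counts, P = length(counts),
                                use_sqrt = TRUE) {
  if (P < 3L) stop("phase stepping needs P >= 3 (underdetermined)",
                   call. = FALSE)
  if (length(counts) != P) stop("expected ", P, " counts", call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  s <- if (use_sqrt) sqrt(counts) else counts
  phi_p <- (seq_len(P) - 1) * 2 * pi / P
  f1 <- (2 / P) * sum(s * exp(-1i * phi_p))
  a <- Mod(f1)
  # an unmodulated sequence has no first harmonic: clamp numerical
  # residue so the (a = 0 -> phi = 0) convention holds in floating point
  if (a < 1e-12 * (sum(s) / P)) a <- 0
  list(a = a, phi = if (a == 0) 0 else Arg(f1))
}

#' Holographic correction update
#'
#' Adds the newly measured mode, at its fitted amplitude and with its
#' phase error pre-compensated, to the complex reference field:
#' `C <- C + a * exp(1i * (M - phi))`. The phase of `C` is the new
#' correction; because contributions are added rather than replaced, the
#' field averages all measurements of a mode across iterations.
#'
#' @param C complex reference field matrix.
#' @param mode a mode from [build_grating_basis()] or a phase matrix.
#' @param a non-negative amplitude weight.
#' @param phi measured phase offset.
#' @return The updated complex field matrix.
#' @export
dash_update <- function(C, mode, a, phi) {
  M <- if (is.list(mode)) mode$pattern else mode
  C + a * exp(1i * (M - phi))
}

# expected-count scale: mean expected signal over the P phase steps of
# the first measured mode with the flat reference equals I0
calibrate_interferometric <- function(fm, basis, dcfg, first_mode) {
  C0 <- matrix(1 + 0i, fm$config$n_slm, fm$config$n_slm)
  sig <- vapply(0:(dcfg$P - 1L), function(p)
    focal_signal(fm, compose_slm_phase(C0, basis$modes[[first_mode]],
                                       p, dcfg)), numeric(1))
  fm$config$i0 / mean(sig)
}

#' Run the DASH algorithm
#'
#' For each iteration and each mode, cycles the `P` phase steps of the
#' composed hologram, records Poisson photon counts, estimates the
#' mode's amplitude and phase by phase-stepping interferometry, and
#' immediately folds the result into the reference field at its raw
#' first-harmonic amplitude, so each mode enters the hologram weighted
#' by its measured interference strength (the correction phase Arg(C)
#' is invariant to the overall scale of C, so no further normalisation
#' is needed; the unit-modulus initial reference then carries
#' negligible inertia compared to the measured modes).
#' The final reference field of an iteration seeds the next one. The
#' enhancement trace is evaluated noise-free from the pure correction
#' phase `Arg(C)` after every mode update.
#'
#' @param scatterer a [generate_scatterer()] mask.
#' @param basis a [build_grating_basis()] basis.
#' @param sim_config a [sim_config()].
#' @param config a [dash_config()].
#' @param seed integer seed for the photon-noise stream.
#' @return List of class `"wavefront_run"` with elements `C` (final
#'   complex reference field), `correction` (its phase), `trace` (a
#'   [convergence_trace()]) and `measurements` (data frame with one row
#'   per mode measurement: `i`, `n`, `kx`, `ky`, `m_start`, `a`, `phi`,
#'   and the photon counts `count_1 ... count_P`).
#' @examples
#' cfg <- sim_config(n_slm = 8, n_scat = 16, i0 = 1000)
#' sc <- generate_scatterer(cfg, seed = 2)
#' b <- build_grating_basis(8, 8)
#' r <- run_dash(sc, b, cfg, dash_config(P = 3), seed = 1)
#' r$trace
#' @export
run_dash <- function(scatterer, basis, sim_config, config = dash_config(),
                     seed = 1L) {
  fm <- forward_model(scatterer, sim_config)
  sched <- iteration_schedule(basis$n_modes, config$P, config$iterations,
                              config$skip_zero_mode_first_iteration)
  scale <- calibrate_interferometric(
    fm, basis, config,
    first_measured_mode(basis, config$skip_zero_mode_first_iteration))
  det <- detector_model(scale, sim_config$noiseless)
  n_slm <- sim_config$n_slm
  # flat initial reference: phase zero, unit modulus. Only the phase
  # enters the displayed hologram; the modulus is a prior weight that
  # measured modes (raw first-harmonic amplitudes, of order
  # sqrt(I0) >> 1) quickly dominate, which is what lets the correction
  # form within the first pass through the basis
  C <- matrix(1 + 0i, n_slm, n_slm)
  tb <- trace_builder(sched$total)
  rows <- vector("list", config$iterations * basis$n_modes)
  nrow_used <- 0L
  with_seed(seed, {
    for (it in seq_len(config$iterations)) {
      for (nm in seq_len(basis$n_modes)) {
        mode <- basis$modes[[nm]]
        if (it == 1L && config$skip_zero_mode_first_iteration &&
            mode$kx == 0L && mode$ky == 0L) next
        counts <- numeric(config$P)
        for (p in 0:(config$P - 1L)) {
          ph <- compose_slm_phase(C, mode, p, config)
          counts[p + 1L] <- record_photons(focal_signal(fm, ph), det)
        }
        est <- phase_step_estimate(counts, config$P, config$use_sqrt)
        C <- dash_update(C, mode, est$a, est$phi)
        eta <- mask_enhancement(fm, Arg(C))
        trace_push(tb, counts, eta)
        nrow_used <- nrow_used + 1L
        rows[[nrow_used]] <- c(i = it - 1L, n = mode$n, kx = mode$kx,
                               ky = mode$ky,
                               m_start = tb$pos - config$P + 1L,
                               a = est$a, phi = est$phi, counts)
      }
    }
  })
  meas <- as.data.frame(do.call(rbind, rows[seq_len(nrow_used)]))
  names(meas) <- c("i", "n", "kx", "ky", "m_start", "a", "phi",
                   paste0("count_", seq_len(config$P)))
  structure(list(C = C, correction = Arg(C),
                 trace = convergence_trace(tb$eta, tb$photons,
                                           sched$boundaries, "dash", seed),
                 measurements = meas, detector = det,
                 config = config, sim_config = sim_config),
            class = "wavefront_run")
}

first_measured_mode <- function(basis, skip_zero) {
  for (i in seq_along(basis$modes)) {
    m <- basis$modes[[i]]
    if (!skip_zero || m$kx != 0L || m$ky != 0L) return(i)
  }
  stop("basis has no measurable mode", call. = FALSE)
}

#' @export
print.wavefront_run <- function(x, ...) {
  cat(sprintf("<wavefront_run> %s: final eta = %.3g after %d measurements\n",
              x$trace$algorithm, x$trace$eta[length(x$trace$eta)],
              length(x$trace$m)))
  invisible(x)
}
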