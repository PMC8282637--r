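#' Run the F-SHARP algorithm
#'
#' F-SHARP probes the scattered field with an external scanning
#' interferometer: the SLM-corrected beam (power `1 - f`) acts as the
#' static probe while a weak scanned beam -- a tilted plane wave, one
#' tilt per grating mode (power `f`) -- is superposed on it in the focal
#' plane with a stepped global phase. Because the scan arm modulates the
#' full complex field, the superposition is exact (no phase-only
#' hologram approximation, unlike DASH's common-path composition). Each
#' mode's amplitude and phase come from the same phase-stepping
#' estimator as DASH, but the correction is only REPLACED at the end of
#' the iteration: `C <- sum_n a_n * exp(1i * (M_n - phi_n))`. The
#' enhancement trace is therefore piecewise constant, stepping at
#' iteration boundaries; the recorded boundary value is the enhancement
#' the displayed mask achieved during the iteration, i.e. immediately
#' before the end-of-iteration update takes effect.
#'
#' @inheritParams run_dash
#' @return A `"wavefront_run"`, as [run_dash()].
#' @export
run_fsharp <- function(scatterer, basis, sim_config,
                       config = dash_config(), seed = 1L) {
  fm <- forward_model(scatterer, sim_config)
  sched <- iteration_schedule(basis$n_modes, config$P, config$iterations,
                              config$skip_zero_mode_first_iteration)
  n_slm <- sim_config$n_slm
  flat <- matrix(0, n_slm, n_slm)
  wr <- sqrt(1 - config$f)
  ws <- sqrt(config$f)
  steps <- exp(1i * (0:(config$P - 1L)) * 2 * pi / config$P)
  # calibration: flat probe + first scanned mode, averaged over the
  # P phase steps, produces I0 expected photons per measurement
  e_flat <- focal_field(fm, flat)
  e_m1 <- focal_field(
    fm, basis$modes[[first_measured_mode(
      basis, config$skip_zero_mode_first_iteration)]]$pattern)
  sig0 <- vapply(steps, function(st)
    field_signal(fm, wr * e_flat + ws * st * e_m1), numeric(1))
  det <- detector_model(sim_config$i0 / mean(sig0), sim_config$noiseless)
  C <- matrix(1 + 0i, n_slm, n_slm)
  tb <- trace_builder(sched$total)
  rows <- vector("list", config$iterations * basis$n_modes)
  nrow_used <- 0L
  with_seed(seed, {
    for (it in seq_len(config$iterations)) {
      eta_displayed <- mask_enhancement(fm, Arg(C))
      e_probe <- focal_field(fm, Arg(C))
      C_new <- matrix(0 + 0i, n_slm, n_slm)
      for (nm in seq_len(basis$n_modes)) {
        mode <- basis$modes[[nm]]
        if (it == 1L && config$skip_zero_mode_first_iteration &&
            mode$kx == 0L && mode$ky == 0L) next
        e_scan <- focal_field(fm, mode$pattern)
        counts <- numeric(config$P)
        for (p in seq_len(config$P)) {
          e <- wr * e_probe + ws * steps[p] * e_scan
          counts[p] <- record_photons(field_signal(fm, e), det)
        }
        est <- phase_step_estimate(counts, config$P, config$use_sqrt)
        C_new <- dash_update(C_new, mode, est$a, est$phi)
        trace_push(tb, counts, eta_displayed)
        nrow_used <- nrow_used + 1L
        rows[[nrow_used]] <- c(i = it - 1L, n = mode$n, kx = mode$kx,
                               ky = mode$ky,
                               m_start = tb$pos - config$P + 1L,
                               a = est$a, phi = est$phi, counts)
      }
      if (any(Mod(C_new) > 0)) C <- C_new  # end-of-iteration replacement
    }
  })
  meas <- as.data.frame(do.call(rbind, rows[seq_len(nrow_used)]))
  names(meas) <- c("i", "n", "kx", "ky", "m_start", "a", "phi",
                   paste0("count_", seq_len(config$P)))
  structure(list(C = C, correction = Arg(C),
                 trace = convergence_trace(tb$eta, tb$photons,
                                           sched$boundaries, "fsharp",
                                           seed),
                 measurements = meas, detector = det,
                 config = config, sim_config = sim_config),
            class = "wavefront_run")
}

#' IMPACT tag frequencies
#'
#' One distinct integer modulation frequency per modulated pixel, chosen
#' just above `T/3` of a length-`T` window with `T = 6 * (n_px + 1)`.
#' For a two-photon (`|E|^4`) signal the spectrum of the recorded trace
#' contains, besides the first-order interference lines at the tag
#' frequencies, second-order beats at pairwise sums and differences of
#' tags; with this plan the differences fall in `(0, T/6]`, the sums
#' fold onto `[2, T/3]`, and the conjugate band occupies `(T/2, 2T/3]`,
#' so all of them stay clear of the signal band.
#'
#' @param n_px number of modulated pixels.
#' @return List with `freqs` (integer vector) and `T` (window length).
#' @export
impact_tag_frequencies <- function(n_px) {
  T <- 6L * (n_px + 1L)
  freqs <- (T %/% 3L) + seq_len(n_px)
  # constructive check: band edges clear of fold-backs and conjugates
  lo <- min(freqs); hi <- max(freqs)
  if (hi >= T %/% 2L || (T - 2L * lo) >= lo || (hi - lo) >= lo)
    stop("tag frequency bands collide", call. = FALSE)
  list(freqs = freqs, T = T)
}

#' Extract modulated-pixel phases from an IMPACT time series
#'
#' Takes the DFT of the square root of the recorded two-photon signal
#' and reads the complex amplitude at each pixel's tag frequency.
#'
#' @param counts length-`T` vector of recorded signals.
#' @param freqs integer tag frequencies (one per modulated pixel).
#' @param use_sqrt demodulate `sqrt(counts)` (default) or raw counts.
#' @return List with `harmonics` (complex, one per pixel) and `phases`
#'   (`Arg` of the harmonics, 0 where the amplitude is 0).
#' @export
impact_extract_phases <- function(counts, freqs, use_sqrt = TRUE) {
  s <- if (use_sqrt) sqrt(counts) else counts
  spec <- stats::fft(s)
  h <- spec[freqs + 1L] / length(s)
  ph <- ifelse(Mod(h) == 0, 0, Arg(h))
  list(harmonics = h, phases = ph)
}

#' Run the IMPACT algorithm
#'
#' IMPACT is the common-path sibling of F-SHARP: the SLM pixels are
#' split into two checkerboard halves, the static half displays the
#' current correction and acts as the reference wave, and the other
#' half is modulated so that every modulated pixel carries a unique
#' modulation; the demodulated interference phases replace the
#' modulated half's correction, and the halves swap roles.
#'
#' Two multiplexing schemes are provided. The default, `"time"`,
#' probes the modulated half mode by mode with the restricted grating
#' set (on a checkerboard half, gratings `k` and `k + (n/2, n/2)`
#' coincide, so exactly `n_slm^2 / 2` distinct restricted gratings
#' exist -- one unique spatial frequency per modulated pixel), stepping
#' each grating through `P` global phase offsets and reconstructing the
#' half's correction from the amplitude-weighted mode sum. This is the
#' time-multiplexed realisation of the pixel-tagging idea and shares
#' F-SHARP's interference contrast, so it remains usable at low photon
#' counts. The `"frequency"` scheme ramps every modulated pixel
#' simultaneously at its own tag frequency over a window of `T` time
#' samples (random start phases, demodulated out) and reads each
#' pixel's phase from the DFT of the square root of the recorded
#' signal; with the probe power spread over all modulated pixels at
#' once, its per-pixel interference contrast is a factor `~sqrt(N/2)`
#' smaller, and in the photon-starved benchmark regimes it stalls --
#' which is why it is not the default.
#'
#' @param scatterer a [generate_scatterer()] mask.
#' @param sim_config a [sim_config()].
#' @param total_m total number of measurements to spend (the run covers
#'   it with whole half-updates).
#' @param boundaries iteration-boundary measurement indices for the
#'   trace (from the shared benchmark schedule).
#' @param P phase steps per mode (time multiplexing).
#' @param seed seed for the photon-noise and dither-phase streams.
#' @param multiplex `"time"` (default) or `"frequency"`.
#' @param use_sqrt demodulate the square root of the signal.
#' @return A `"wavefront_run"` (no per-mode measurement table; the
#'   correction lives on pixel phases directly).
#' @export
run_impact <- function(scatterer, sim_config, total_m, boundaries,
                       P = 5L, seed = 1L,
                       multiplex = c("time", "frequency"),
                       use_sqrt = TRUE) {
  multiplex <- match.arg(multiplex)
  fm <- forward_model(scatterer, sim_config)
  n_slm <- sim_config$n_slm
  theta <- matrix(0, n_slm, n_slm)
  cb <- outer(seq_len(n_slm), seq_len(n_slm), "+") %% 2L == 0L
  halves <- list(which(cb), which(!cb))
  n_px <- length(halves[[1L]])
  tb <- trace_builder(total_m)
  if (multiplex == "time") {
    hmodes <- half_grating_modes(n_slm)
    offs <- (0:(P - 1L)) * 2 * pi / P
    # calibration: flat correction, first restricted grating, averaged
    # over the P phase steps
    sig0 <- vapply(offs, function(o) {
      ph <- theta
      ph[halves[[1L]]] <- hmodes[[1L]]$pattern[halves[[1L]]] + o
      focal_signal(fm, ph)
    }, numeric(1))
    det <- detector_model(sim_config$i0 / mean(sig0),
                          sim_config$noiseless)
    n_updates <- ceiling(total_m / (length(hmodes) * P))
    with_seed(seed, {
      for (u in seq_len(n_updates)) {
        mod_px <- halves[[(u - 1L) %% 2L + 1L]]
        eta_displayed <- mask_enhancement(fm, theta)
        C_half <- numeric(length(mod_px)) + 0i
        for (mode in hmodes) {
          counts <- numeric(P)
          for (p in seq_len(P)) {
            ph <- theta
            ph[mod_px] <- mode$pattern[mod_px] + offs[p]
            counts[p] <- record_photons(focal_signal(fm, ph), det)
          }
          est <- phase_step_estimate(counts, P, use_sqrt)
          C_half <- C_half +
            est$a * exp(1i * (mode$pattern[mod_px] - est$phi))
          trace_push(tb, counts, eta_displayed)
        }
        # the modulated half probes absolutely (tags displayed without
        # the current correction), so each half-update replaces the
        # half's phases with the fresh amplitude-weighted estimate --
        # anchoring the truth component every cycle instead of letting
        # estimate noise accumulate
        if (any(Mod(C_half) > 0))
          theta[mod_px] <- Arg(C_half)
      }
    })
    cfg_out <- list(multiplex = "time", P = P,
                    modes_per_half = length(hmodes))
  } else {
    tags <- impact_tag_frequencies(n_px)
    T <- tags$T
    ramp <- outer(tags$freqs, 0:(T - 1L)) * 2 * pi / T  # n_px x T
    sig0 <- vapply(seq_len(T), function(t) {
      ph <- theta; ph[halves[[1L]]] <- ph[halves[[1L]]] + ramp[, t]
      focal_signal(fm, ph)
    }, numeric(1))
    det <- detector_model(sim_config$i0 / mean(sig0),
                          sim_config$noiseless)
    n_updates <- ceiling(total_m / T)
    with_seed(seed, {
      for (u in seq_len(n_updates)) {
        mod_px <- halves[[(u - 1L) %% 2L + 1L]]
        beta <- stats::runif(n_px, 0, 2 * pi)
        counts <- numeric(T)
        for (t in seq_len(T)) {
          ph <- theta
          ph[mod_px] <- ph[mod_px] + ramp[, t] + beta
          counts[t] <- record_photons(focal_signal(fm, ph), det)
        }
        ex <- impact_extract_phases(counts, tags$freqs,
                                    use_sqrt = use_sqrt)
        phs <- ifelse(Mod(ex$harmonics) == 0, 0,
                      Arg(ex$harmonics * exp(-1i * beta)))
        theta[mod_px] <- (theta[mod_px] - phs) %% (2 * pi)
        trace_push(tb, counts, mask_enhancement(fm, theta))
      }
    })
    cfg_out <- list(multiplex = "frequency", T = T)
  }
  structure(list(C = exp(1i * theta), correction = theta,
                 trace = convergence_trace(tb$eta, tb$photons, boundaries,
                                           "impact", seed),
                 measurements = NULL, detector = det,
                 config = cfg_out, sim_config = sim_config),
            class = "wavefront_run")
}

# The 128 grating modes that remain distinct when restricted to one
# checkerboard half of an n_slm x n_slm SLM: k and k + (n/2, n/2)
# render identical patterns there (exp(1i*pi*(x+y)) is constant on a
# checkerboard), so of each such pair the lower-|k| member is kept,
# in spiral order.
half_grating_modes <- function(n_slm) {
  full <- build_grating_basis(n_slm, n_slm)$modes
  h <- n_slm %/% 2L
  seen <- character(0)
  keep <- list()
  for (m in full) {
    key1 <- paste(m$kx %% n_slm, m$ky %% n_slm)
    key2 <- paste((m$kx + h) %% n_slm, (m$ky + h) %% n_slm)
    if (key1 %in% seen || key2 %in% seen) next
    seen <- c(seen, key1)
    keep[[length(keep) + 1L]] <- m
  }
  keep
}

# shared calibration for full-power pixel algorithms: flat mask -> I0
calibrate_flat <- function(fm)
  detector_model(fm$config$i0 / fm$flat_signal, fm$config$noiseless)

#' Run the continuous sequential algorithm (CSA)
#'
#' Visits the SLM pixels cyclically in a fixed raster order; for each
#' pixel its phase is stepped through `P` offsets, the recorded signals
#' are fitted by their first harmonic, and the fitted optimum offset is
#' applied immediately before moving on.
#'
#' @param scatterer a [generate_scatterer()] mask.
#' @param sim_config a [sim_config()].
#' @param P phase steps per pixel visit (>= 3).
#' @param total_m total measurement budget.
#' @param boundaries iteration boundaries for the trace.
#' @param seed photon-noise seed.
#' @return A `"wavefront_run"`.
#' @export
run_csa <- function(scatterer, sim_config, P = 3L, total_m, boundaries,
                    seed = 1L) {
  fm <- forward_model(scatterer, sim_config)
  det <- calibrate_flat(fm)
  n_slm <- sim_config$n_slm
  theta <- matrix(0, n_slm, n_slm)
  offs <- (0:(P - 1L)) * 2 * pi / P
  tb <- trace_builder(total_m)
  n_visits <- ceiling(total_m / P)
  with_seed(seed, {
    px <- 0L
    for (v in seq_len(n_visits)) {
      px <- px %% (n_slm^2) + 1L
      counts <- numeric(P)
      base <- theta[px]
      for (p in seq_len(P)) {
        theta[px] <- base + offs[p]
        counts[p] <- record_photons(focal_signal(fm, theta), det)
      }
      est <- phase_step_estimate(counts, P, use_sqrt = FALSE)
      # fitted signal c0 + a*cos(offset + phi) peaks at offset = -phi
      theta[px] <- (base - est$phi) %% (2 * pi)
      trace_push(tb, counts, mask_enhancement(fm, theta))
    }
  })
  structure(list(C = exp(1i * theta), correction = theta,
                 trace = convergence_trace(tb$eta, tb$photons, boundaries,
                                           "csa", seed),
                 measurements = NULL, detector = det,
                 config = list(P = P), sim_config = sim_config),
            class = "wavefront_run")
}

#' Run the partitioning algorithm (PA)
#'
#' Each step draws a fresh random half of all SLM pixels, steps a common
#' phase offset on that half through `P` values, and immediately applies
#' the offset whose measured signal was largest. Because the zero offset
#' is among the tested values, a noiseless run never decreases the
#' signal.
#'
#' @inheritParams run_csa
#' @return A `"wavefront_run"`.
#' @export
run_pa <- function(scatterer, sim_config, P = 3L, total_m, boundaries,
                   seed = 1L) {
  fm <- forward_model(scatterer, sim_config)
  det <- calibrate_flat(fm)
  n_slm <- sim_config$n_slm
  n_px <- n_slm^2
  theta <- matrix(0, n_slm, n_slm)
  offs <- (0:(P - 1L)) * 2 * pi / P
  tb <- trace_builder(total_m)
  n_steps <- ceiling(total_m / P)
  with_seed(seed, {
    for (v in seq_len(n_steps)) {
      half <- sample.int(n_px, n_px %/% 2L)
      counts <- numeric(P)
      base <- theta[half]
      for (p in seq_len(P)) {
        theta[half] <- base + offs[p]
        counts[p] <- record_photons(focal_signal(fm, theta), det)
      }
      theta[half] <- (base + offs[which.max(counts)]) %% (2 * pi)
      trace_push(tb, counts, mask_enhancement(fm, theta))
    }
  })
  structure(list(C = exp(1i * theta), correction = theta,
                 trace = convergence_trace(tb$eta, tb$photons, boundaries,
                                           "pa", seed),
                 measurements = NULL, detector = det,
                 config = list(P = P), sim_config = sim_config),
            class = "wavefront_run")
}

#' Genetic-algorithm configuration
#'
#' Hyperparameters follow common wavefront-shaping GA practice: a
#' population of phase masks ranked by one noisy fitness measurement
#' each, rank-proportional parent selection, pixelwise random-mask
#' crossover, and a pixelwise mutation rate decaying exponentially with
#' the measurement count, `r(m) = r_final + (r_initial - r_final) *
#' exp(-m / decay)`.
#'
#' @param population number of masks (>= 4).
#' @param elite_fraction fraction of top-ranked masks copied unchanged
#'   into the next generation.
#' @param mutation_rate_initial,mutation_rate_final mutation rates in
#'   `(0, 1)`.
#' @param decay decay constant in measurements.
#' @param phase_levels optional integer: restrict mask phases to this
#'   many equally spaced levels (continuous phases when `NULL`).
#' @return An object of class `"ga_config"`.
#' @export
ga_config <- function(population = 30L, elite_fraction = 0.25,
                      mutation_rate_initial = 0.1,
                      mutation_rate_final = 0.013, decay = 650,
                      phase_levels = NULL) {
  if (population < 4L) stop("population must be >= 4", call. = FALSE)
  if (elite_fraction <= 0 || elite_fraction >= 1)
    stop("elite_fraction must lie in (0, 1)", call. = FALSE)
  for (r in c(mutation_rate_initial, mutation_rate_final))
    if (r < 0 || r >= 1) stop("mutation rates must lie in [0, 1)",
                              call. = FALSE)
  structure(list(population = as.integer(population),
                 elite_fraction = elite_fraction,
                 mutation_rate_initial = mutation_rate_initial,
                 mutation_rate_final = mutation_rate_final,
                 decay = decay, phase_levels = phase_levels),
            class = "ga_config")
}

#' Run the genetic algorithm
#'
#' Maintains a population of phase masks ranked by measured fitness.
#' Each mask's fitness is measured ONCE, when the mask is created (one
#' noisy photon count, one measurement `m`); elite masks carry their
#' stored fitness forward unchanged. Every generation the non-elite
#' masks are replaced by mutated crossovers of rank-selected parents
#' and only those new masks are measured. At low photon counts this
#' single-shot fitness is exactly what makes genetic search fragile: a
#' lucky upward noise fluctuation sticks to a mediocre mask
#' indefinitely (winner's curse), so the elite stalls. The enhancement
#' trace follows the best mask by measured fitness, evaluated
#' noise-free.
#'
#' @param scatterer a [generate_scatterer()] mask.
#' @param sim_config a [sim_config()].
#' @param config a [ga_config()].
#' @param total_m total measurement budget.
#' @param boundaries iteration boundaries for the trace.
#' @param seed seed for mask initialisation, GA randomness and photon
#'   noise.
#' @return A `"wavefront_run"`.
#' @export
run_ga <- function(scatterer, sim_config, config = ga_config(), total_m,
                   boundaries, seed = 1L) {
  fm <- forward_model(scatterer, sim_config)
  det <- calibrate_flat(fm)
  n_slm <- sim_config$n_slm
  n_px <- n_slm^2
  G <- config$population
  rand_phase <- function(k) {
    if (is.null(config$phase_levels)) stats::runif(k, 0, 2 * pi)
    else (sample.int(config$phase_levels, k, replace = TRUE) - 1L) *
      2 * pi / config$phase_levels
  }
  tb <- trace_builder(total_m)
  with_seed(seed, {
    pop <- lapply(seq_len(G), function(i) matrix(rand_phase(n_px), n_slm))
    fit <- vapply(pop, function(mask)
      record_photons(focal_signal(fm, mask), det), numeric(1))
    trace_push(tb, fit, mask_enhancement(fm, pop[[which.max(fit)]]))
    ord <- order(fit, decreasing = TRUE)
    pop <- pop[ord]; fit <- fit[ord]
    n_elite <- max(1L, ceiling(config$elite_fraction * G))
    n_child <- G - n_elite
    rank_prob <- (G:1) / sum(G:1)
    m_used <- G
    while (tb$pos < total_m) {
      rate <- config$mutation_rate_final +
        (config$mutation_rate_initial - config$mutation_rate_final) *
        exp(-m_used / config$decay)
      offspring <- lapply(seq_len(n_child), function(k) {
        par <- sample.int(G, 2L, prob = rank_prob)
        pick <- stats::runif(n_px) < 0.5
        child <- pop[[par[1L]]]
        child[pick] <- pop[[par[2L]]][pick]
        mut <- stats::runif(n_px) < rate
        if (any(mut)) child[mut] <- rand_phase(sum(mut))
        child
      })
      child_fit <- vapply(offspring, function(mask)
        record_photons(focal_signal(fm, mask), det), numeric(1))
      pop <- c(pop[seq_len(n_elite)], offspring)
      fit <- c(fit[seq_len(n_elite)], child_fit)
      ord <- order(fit, decreasing = TRUE)
      pop <- pop[ord]; fit <- fit[ord]
      m_used <- m_used + n_child
      trace_push(tb, child_fit, mask_enhancement(fm, pop[[1L]]))
    }
  })
  structure(list(C = exp(1i * pop[[1L]]), correction = pop[[1L]],
                 trace = convergence_trace(tb$eta, tb$photons, boundaries,
                                           "ga", seed),
                 measurements = NULL, detector = det,
                 config = config, sim_config = sim_config),
            class = "wavefront_run")
}
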