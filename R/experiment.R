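#' Signal enhancement
#'
#' The enhancement `eta` is the ratio of the corrected to the uncorrected
#' two-photon signal.
#'
#' @param corrected_signal corrected signal (>= 0).
#' @param uncorrected_signal uncorrected signal (> 0).
#' @return Dimensionless ratio.
#' @export
enhancement <- function(corrected_signal, uncorrected_signal) {
  if (any(uncorrected_signal <= 0))
    stop("uncorrected signal must be > 0", call. = FALSE)
  corrected_signal / uncorrected_signal
}

#' Measurement-count bookkeeping
#'
#' Two counting conventions are in use for interferometric mode
#' protocols. Under `"phase_steps"` every detector exposure counts: one
#' iteration over `n_modes` modes with `P` phase steps each spends
#' `n_modes * P` measurements, and skipping the zero mode in the first
#' iteration gives `(n_modes - 1) * P + (iterations - 1) * n_modes * P`
#' in total (e.g. 1120 after one and 10,120 after nine iterations of the
#' 225-mode, 5-step protocol). Under `"modes"` each measured mode counts
#' once regardless of `P` and the zero mode is included (225 modes over
#' nine iterations give 2025 mode-measurements).
#'
#' @param n_modes number of modes per iteration.
#' @param P phase steps per mode.
#' @param iterations number of iterations.
#' @param skip_zero_first whether the zero mode is skipped in the first
#'   iteration (`"phase_steps"` convention only).
#' @param convention `"phase_steps"` or `"modes"`.
#' @return Integer measurement count.
#' @examples
#' measurement_count(225, 5, 1)                        # 1120
#' measurement_count(225, 5, 9)                        # 10120
#' measurement_count(225, 5, 9, convention = "modes")  # 2025
#' @export
measurement_count <- function(n_modes, P, iterations,
                              skip_zero_first = TRUE,
                              convention = c("phase_steps", "modes")) {
  convention <- match.arg(convention)
  stopifnot(n_modes >= 1, P >= 1, iterations >= 1)
  if (convention == "modes") return(as.integer(iterations * n_modes))
  if (skip_zero_first)
    as.integer((n_modes - 1) * P + (iterations - 1) * n_modes * P)
  else as.integer(iterations * n_modes * P)
}

#' Detect the convergence iteration of a trace
#'
#' Convergence is declared at the first iteration boundary where the
#' enhancement reaches `threshold` times the final plateau, the plateau
#' being the mean of the boundary enhancements of the last two
#' iterations (averaging two damps shot-noise wobble). Returns `-1` if
#' no boundary reaches the plateau ("does not converge").
#'
#' @param trace a [convergence_trace()] spanning at least 2 iterations.
#' @param threshold plateau fraction, default 0.9.
#' @return 1-based iteration index, or -1.
#' @export
detect_convergence <- function(trace, threshold = 0.9) {
  be <- boundary_eta(trace)
  if (length(be) < 2L) stop("trace must span >= 2 iterations",
                            call. = FALSE)
  eta_final <- mean(be[(length(be) - 1L):length(be)])
  hit <- which(be >= threshold * eta_final)
  if (length(hit) == 0L) -1L else hit[1L]
}

#' Measurements and photons needed to reach a threshold enhancement
#'
#' Scans the trace for the first measurement at which `eta >=
#' threshold_eta` and reports the measurement index and the cumulative
#' number of detected photons spent up to and including it. The
#' pre-measurement state (`m = 0`, `eta = 1`) satisfies any threshold
#' `<= 1` at zero cost.
#'
#' @param trace a [convergence_trace()].
#' @param threshold_eta enhancement threshold.
#' @return List with `m` and `photons`; both `-1` if the threshold is
#'   never reached.
#' @export
photons_to_threshold <- function(trace, threshold_eta) {
  if (threshold_eta <= 1) return(list(m = 0L, photons = 0))
  hit <- which(trace$eta >= threshold_eta)
  if (length(hit) == 0L) return(list(m = -1L, photons = -1))
  list(m = trace$m[hit[1L]], photons = trace$cum_photons[hit[1L]])
}

#' Run the convergence benchmark
#'
#' Runs each requested algorithm on the same set of seeded white-noise
#' scatterers (one scatterer per trial, shared across algorithms;
#' photon-noise streams independent per algorithm) and aggregates the
#' enhancement at every iteration boundary into mean and standard error
#' of the mean (SEM = sd / sqrt(trials)) over trials.
#'
#' @param algorithms character vector from `c("dash", "fsharp",
#'   "impact", "csa", "pa", "ga")`.
#' @param sim_config a [sim_config()].
#' @param dash_config a [dash_config()]; its `P`, `iterations` and
#'   zero-mode policy also set the shared measurement schedule that
#'   aligns all algorithms on one m-axis.
#' @param basis a [build_grating_basis()] basis (default: `S = n_slm`
#'   so the mode count equals the correctable pixel count).
#' @param trials number of scatterer realisations (>= 2).
#' @param seed master seed; all per-trial seeds derive from it.
#' @param ga a [ga_config()] for the genetic algorithm.
#' @return An object of class `"benchmark_result"`: list with `summary`
#'   (data frame: algorithm, iteration, m, mean_eta, sem), `traces`
#'   (list of per-algorithm lists of [convergence_trace()]s),
#'   `scatterer_seeds`, `scatterer_hashes`, and the configurations.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_slm = 8, n_scat = 16, i0 = 1000)
#' bm <- run_benchmark(c("dash", "fsharp"), cfg,
#'                     dash_config(P = 3, iterations = 3), trials = 2)
#' bm
#' }
#' @export
run_benchmark <- function(algorithms, sim_config,
                          dash_config = dashsim::dash_config(P = 5L),
                          basis = NULL, trials = 10L, seed = 1L,
                          ga = ga_config()) {
  known <- c("dash", "fsharp", "impact", "csa", "pa", "ga")
  algorithms <- match.arg(algorithms, known, several.ok = TRUE)
  if (trials < 2L) stop("trials must be >= 2", call. = FALSE)
  if (is.null(basis))
    basis <- build_grating_basis(sim_config$n_slm, sim_config$n_slm)
  if (basis$n_slm != sim_config$n_slm)
    stop("basis and sim_config disagree on the SLM grid", call. = FALSE)
  sched <- iteration_schedule(basis$n_modes, dash_config$P,
                              dash_config$iterations,
                              dash_config$skip_zero_mode_first_iteration)
  scat_seeds <- vapply(seq_len(trials), function(tr)
    derive_seed(seed, "scatterer", tr), integer(1))
  traces <- stats::setNames(
    lapply(algorithms, function(a) vector("list", trials)), algorithms)
  hashes <- character(trials)
  for (tr in seq_len(trials)) {
    scat <- generate_scatterer(sim_config, scat_seeds[tr])
    hashes[tr] <- scatterer_hash(scat)
    for (alg in algorithms) {
      s <- derive_seed(seed, alg, tr)
      run <- switch(alg,
        dash = run_dash(scat, basis, sim_config, dash_config, seed = s),
        fsharp = run_fsharp(scat, basis, sim_config, dash_config,
                            seed = s),
        impact = run_impact(scat, sim_config, sched$total,
                            sched$boundaries, P = dash_config$P,
                            seed = s),
        csa = run_csa(scat, sim_config, dash_config$P, sched$total,
                      sched$boundaries, seed = s),
        pa = run_pa(scat, sim_config, dash_config$P, sched$total,
                    sched$boundaries, seed = s),
        ga = run_ga(scat, sim_config, ga, sched$total, sched$boundaries,
                    seed = s))
      traces[[alg]][[tr]] <- run$trace
    }
  }
  summ <- do.call(rbind, lapply(algorithms, function(alg) {
    be <- sapply(traces[[alg]], boundary_eta)  # iterations x trials
    if (is.null(dim(be))) be <- matrix(be, nrow = 1L)
    data.frame(algorithm = alg,
               iteration = seq_len(nrow(be)),
               m = sched$boundaries,
               mean_eta = rowMeans(be),
               sem = apply(be, 1, stats::sd) / sqrt(trials))
  }))
  structure(list(summary = summ, traces = traces,
                 scatterer_seeds = scat_seeds,
                 scatterer_hashes = hashes, trials = trials,
                 seed = as.integer(seed), sim_config = sim_config,
                 dash_config = dash_config, schedule = sched),
            class = "benchmark_result")
}

# stable fingerprint of a scatterer used for cross-algorithm fairness
scatterer_hash <- function(scatterer) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(as.numeric(scatterer$phase), f, endian = "little")
  unname(tools::md5sum(f))
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d trials, seed %d, I0 = %g\n",
              x$trials, x$seed, x$sim_config$i0))
  last <- x$summary[x$summary$iteration == max(x$summary$iteration), ]
  for (i in seq_len(nrow(last)))
    cat(sprintf("  %-7s final eta = %7.2f +/- %.2f (SEM)\n",
                last$algorithm[i], last$mean_eta[i], last$sem[i]))
  invisible(x)
}

#' @export
summary.benchmark_result <- function(object, ...) object$summary

#' @export
plot.benchmark_result <- function(x, log = "y", ...) {
  s <- x$summary
  algs <- unique(s$algorithm)
  cols <- grDevices::hcl.colors(max(3L, length(algs)), "Dark 3")
  graphics::matplot(matrix(s$m, ncol = length(algs)),
                    matrix(s$mean_eta, ncol = length(algs)),
                    type = "l", lty = 1, col = cols[seq_along(algs)],
                    log = log, xlab = "measurement number m",
                    ylab = "mean enhancement eta", ...)
  for (k in seq_along(algs)) {
    sk <- s[s$algorithm == algs[k], ]
    graphics::arrows(sk$m, pmax(sk$mean_eta - sk$sem, .Machine$double.eps),
                     sk$m, sk$mean_eta + sk$sem, length = 0.02,
                     angle = 90, code = 3, col = cols[k])
  }
  graphics::legend("bottomright", legend = algs, col = cols[seq_along(algs)],
                   lty = 1, bty = "n")
  invisible(x)
}
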