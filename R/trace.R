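#' Convergence trace
#'
#' The common currency of the benchmark: enhancement `eta` as a function
#' of the measurement number `m`, where every detector exposure (one
#' phase step, or one time sample for IMPACT) increments `m` by exactly
#' one. `eta[m]` is the noise-free enhancement of the correction mask in
#' effect after measurement `m`; before any measurement the mask is flat
#' and `eta = 1` by construction. `cum_photons[m]` is the running total
#' of detected photons, so measurement- and photon-budget comparisons
#' share one object.
#'
#' @param eta numeric vector of enhancements, one per measurement.
#' @param cum_photons cumulative detected photon counts, same length.
#' @param boundaries measurement indices at iteration ends.
#' @param algorithm label, e.g. `"dash"`.
#' @param seed the trial's master seed.
#' @return An object of class `"convergence_trace"`.
#' @export
convergence_trace <- function(eta, cum_photons, boundaries, algorithm,
                              seed = NA_integer_) {
  stopifnot(length(eta) == length(cum_photons), all(eta > 0))
  structure(list(m = seq_along(eta), eta = as.numeric(eta),
                 cum_photons = as.numeric(cum_photons),
                 boundaries = as.integer(boundaries),
                 algorithm = as.character(algorithm),
                 seed = as.integer(seed)),
            class = "convergence_trace")
}

#' @export
print.convergence_trace <- function(x, ...) {
  cat(sprintf(paste0("<convergence_trace> %s, %d measurements, ",
                     "%d iterations, final eta = %.3g\n"),
              x$algorithm, length(x$m), length(x$boundaries),
              x$eta[length(x$eta)]))
  invisible(x)
}

#' @export
as.data.frame.convergence_trace <- function(x, ...) {
  it <- findInterval(x$m - 1L, x$boundaries) + 1L
  data.frame(algorithm = x$algorithm, seed = x$seed, m = x$m,
             iteration = it, eta = x$eta, cum_photons = x$cum_photons)
}

#' @export
plot.convergence_trace <- function(x, log = "y", ...) {
  graphics::plot(x$m, x$eta, type = "l", log = log,
                 xlab = "measurement number m", ylab = "enhancement eta",
                 main = x$algorithm, ...)
  graphics::abline(v = x$boundaries, col = "grey80", lty = 3)
  invisible(x)
}

#' Enhancement at iteration boundaries
#'
#' @param trace a [convergence_trace()].
#' @return Numeric vector, `eta` at each iteration boundary.
#' @export
boundary_eta <- function(trace) trace$eta[trace$boundaries]

# Measurement schedule shared by all algorithms: iteration k (1-based)
# spans `per_iter[k]` measurements; with the zero mode skipped the first
# iteration has (n_modes - 1) * P steps, all later ones n_modes * P.
iteration_schedule <- function(n_modes, P, iterations, skip_zero_first) {
  per_iter <- rep(n_modes * P, iterations)
  if (skip_zero_first) per_iter[1L] <- (n_modes - 1L) * P
  list(per_iter = per_iter, boundaries = cumsum(per_iter),
       total = sum(per_iter))
}

# trace accumulator: fills eta/photon slots for blocks of measurements
trace_builder <- function(total) {
  env <- new.env(parent = emptyenv())
  env$eta <- numeric(total)
  env$photons <- numeric(total)
  env$pos <- 0L
  env$cum <- 0
  env
}

# record `k` measurements that detected `counts` photons (length k) and
# left the correction at enhancement `eta`
trace_push <- function(tb, counts, eta) {
  k <- length(counts)
  idx <- tb$pos + seq_len(k)
  keep <- idx <= length(tb$eta)
  tb$eta[idx[keep]] <- eta
  tb$photons[idx[keep]] <- cumsum(counts)[keep] + tb$cum
  tb$cum <- tb$cum + sum(counts)
  tb$pos <- tb$pos + k
  invisible(tb)
}
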