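#' Simulation configuration
#'
#' Defines the numerical optics testbed: an SLM with `n_slm^2` correctable
#' pixels conjugate to the pupil (Fourier) plane, a phase-only scatterer on
#' a finer `n_scat^2` grid in the same plane, and a fluorescent sample in
#' the focal plane. Each SLM pixel controls an integer block of
#' `(n_scat/n_slm)^2` scatterer pixels.
#'
#' @param n_slm side length of the SLM pixel grid; the number of
#'   correctable pixels is `n_slm^2`.
#' @param n_scat side length of the scatterer grid; must be an integer
#'   multiple of `n_slm`.
#' @param pad_factor zero-padding factor (>= 1) applied before propagation
#'   to the focal plane, controlling focal-plane sampling density.
#' @param sample_model `"layer"` for a homogeneous two-dimensional
#'   fluorescent layer filling the focal plane, or `"point"` for a single
#'   point-like emitter.
#' @param i0 expected number of detected photons per measurement in the
#'   uncorrected state (the initial signal level).
#' @param seed default integer seed for scatterer generation.
#' @param noiseless if `TRUE`, all detectors built from this
#'   configuration report expected counts without Poisson shot noise.
#' @param eta_metric how the enhancement eta of a correction mask is
#'   scored: `"peak"` (default) is the ratio of the maximum two-photon
#'   signal over the focal plane to the uncorrected maximum, matching
#'   the usual definition of signal enhancement on images; `"total"`
#'   is the ratio of the layer-integrated signal (the quantity the
#'   detector actually records).
#' @param point_index for `sample_model = "point"`, the `(row, col)` focal
#'   pixel of the emitter (1-based, on the padded grid); defaults to the
#'   zero-frequency pixel `(1, 1)`.
#' @return An object of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_slm = 16, n_scat = 32, i0 = 1000)
#' cfg
#' @export
sim_config <- function(n_slm = 16L, n_scat = 32L, pad_factor = 2L,
                       sample_model = c("layer", "point"), i0 = 1000,
                       seed = 1L, point_index = NULL, noiseless = FALSE,
                       eta_metric = c("peak", "total")) {
  sample_model <- match.arg(sample_model)
  eta_metric <- match.arg(eta_metric)
  n_slm <- as.integer(n_slm); n_scat <- as.integer(n_scat)
  pad_factor <- as.integer(pad_factor)
  if (n_slm < 1L || n_scat < 1L)
    stop("grid sides must be positive integers", call. = FALSE)
  if (n_scat %% n_slm != 0L)
    stop("n_scat (", n_scat, ") must be an integer multiple of n_slm (",
         n_slm, ")", call. = FALSE)
  if (pad_factor < 1L) stop("pad_factor must be >= 1", call. = FALSE)
  if (!is.numeric(i0) || i0 <= 0) stop("i0 must be > 0", call. = FALSE)
  if (is.null(point_index)) point_index <- c(1L, 1L)
  structure(list(n_slm = n_slm, n_scat = n_scat, pad_factor = pad_factor,
                 sample_model = sample_model, i0 = i0,
                 seed = as.integer(seed),
                 point_index = as.integer(point_index),
                 noiseless = isTRUE(noiseless),
                 eta_metric = eta_metric),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Scattering simulation configuration\n")
  cat(sprintf("  SLM grid      : %d x %d  (N = %d correctable pixels)\n",
              x$n_slm, x$n_slm, x$n_slm^2))
  cat(sprintf("  scatterer grid: %d x %d  (N_scat = %d pixels)\n",
              x$n_scat, x$n_scat, x$n_scat^2))
  cat(sprintf("  pad factor    : %d   sample: %s   I0: %g photons/meas.\n",
              x$pad_factor, x$sample_model, x$i0))
  invisible(x)
}

#' Two-dimensional complex field
#'
#' A square grid of complex amplitudes tagged with the optical plane it
#' lives in. Phase-only elements (SLM, scatterer) act multiplicatively and
#' conserve the total power `sum(|E|^2)`.
#'
#' @param grid square complex matrix.
#' @param plane `"pupil"` or `"focal"`.
#' @return An object of class `"complex_field"`.
#' @export
complex_field <- function(grid, plane = c("pupil", "focal")) {
  plane <- match.arg(plane)
  if (!is.matrix(grid) || nrow(grid) != ncol(grid))
    stop("grid must be a square matrix", call. = FALSE)
  storage.mode(grid) <- "complex"
  structure(list(grid = grid, plane = plane, side = nrow(grid)),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d, %s plane, power = %.6g\n",
              x$side, x$side, x$plane, total_power(x)))
  invisible(x)
}

#' Total optical power of a field
#'
#' @param field a [complex_field()].
#' @return `sum(|E|^2)` over the grid.
#' @export
total_power <- function(field) {
  g <- if (inherits(field, "complex_field")) field$grid else field
  sum(Re(g)^2 + Im(g)^2)
}

#' Generate a white-noise phase scatterer
#'
#' Draws an independent uniform phase in `[0, 2*pi)` for every pixel of
#' the `n_scat` grid. The scatterer sits in the pupil (Fourier) plane and
#' is phase-only, so it scrambles the focal field into fully developed
#' speckle without absorbing power.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the same seed always regenerates the
#'   identical mask.
#' @return An object of class `"scatterer_mask"` with elements `phase`
#'   (matrix in `[0, 2*pi)`), `seed` and `n_scat`.
#' @examples
#' sc <- generate_scatterer(sim_config(n_slm = 8, n_scat = 16), seed = 7)
#' range(sc$phase)
#' @export
generate_scatterer <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_scat
  ph <- with_seed(seed, matrix(stats::runif(n * n, 0, 2 * pi), n, n))
  structure(list(phase = ph, seed = as.integer(seed), n_scat = n),
            class = "scatterer_mask")
}

#' @export
print.scatterer_mask <- function(x, ...) {
  cat(sprintf("<scatterer_mask> %d x %d white-noise phases, seed %d\n",
              x$n_scat, x$n_scat, x$seed))
  invisible(x)
}

# column-major index map taking the n_scat grid onto SLM pixels
# (nearest-neighbour block upsampling)
upsample_index <- function(n_slm, n_scat) {
  b <- n_scat %/% n_slm
  up <- rep(seq_len(n_slm), each = b)
  # idx[i, j] = column-major index of SLM pixel (up[i], up[j])
  matrix(outer(up, (up - 1L) * n_slm, "+"), n_scat, n_scat)
}

#' Map an SLM phase pattern to the pupil field
#'
#' Each SLM pixel imposes its phase on a block of `(n_scat/n_slm)^2`
#' scatterer-grid pixels (nearest-neighbour upsampling); the emerging
#' pupil field has unit modulus everywhere, hence total power `n_scat^2`.
#'
#' @param slm_phase real `n_slm x n_slm` matrix of phases (radians).
#' @param config a [sim_config()].
#' @return A pupil-plane [complex_field()] on the `n_scat` grid.
#' @export
slm_to_pupil <- function(slm_phase, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.matrix(slm_phase) || any(dim(slm_phase) != config$n_slm))
    stop("slm_phase must be ", config$n_slm, " x ", config$n_slm,
         call. = FALSE)
  idx <- upsample_index(config$n_slm, config$n_scat)
  complex_field(matrix(exp(1i * slm_phase)[idx], config$n_scat),
                plane = "pupil")
}

# cache of truncated unitary DFT factor matrices, keyed by (side, n_in):
# E = (W %*% X %*% t(W)) / side equals the unitary FFT of X zero-padded
# to side x side. Matrix products beat fft() here because the pupil
# occupies only the top-left n_in x n_in corner of the padded grid.
.dft_cache <- new.env(parent = emptyenv())
dft_factor <- function(side, n_in) {
  key <- paste(side, n_in)
  w <- .dft_cache[[key]]
  if (is.null(w)) {
    w <- exp(-2i * pi * outer(0:(side - 1L), 0:(n_in - 1L)) / side)
    .dft_cache[[key]] <- w
  }
  w
}

#' Propagate a pupil field to the focal plane
#'
#' Applies the phase scatterer and the unitary discrete Fourier transform
#' (with zero padding by `pad_factor`), modelling the lens relation
#' between the pupil and the focal plane. The unitary normalisation makes
#' power bookkeeping exact: total power is conserved to machine
#' precision.
#'
#' @param pupil pupil-plane [complex_field()] on the `n_scat` grid.
#' @param scatterer a [scatterer_mask()] (or `NULL` for no aberration).
#' @param config a [sim_config()].
#' @return A focal-plane [complex_field()] on the padded grid.
#' @export
propagate_to_focus <- function(pupil, scatterer, config) {
  stopifnot(inherits(config, "sim_config"))
  g <- if (inherits(pupil, "complex_field")) pupil$grid else pupil
  n <- config$n_scat
  if (!is.matrix(g) || any(dim(g) != n))
    stop("pupil must be on the ", n, " x ", n, " scatterer grid",
         call. = FALSE)
  if (!is.null(scatterer)) g <- g * exp(1i * scatterer$phase)
  side <- n * config$pad_factor
  w <- dft_factor(side, n)
  complex_field((w %*% g %*% t(w)) / side, plane = "focal")
}

#' Two-photon excited fluorescence signal
#'
#' The TPEF response scales with the square of the intensity, i.e.
#' `|E|^4`. For the layer sample the signal integrates `|E|^4` over the
#' whole focal grid; for the point sample it reads `|E|^4` at the
#' designated emitter pixel.
#'
#' @param focal focal-plane [complex_field()].
#' @param sample_model `"layer"` or `"point"`.
#' @param point_index `(row, col)` of the point emitter (1-based).
#' @return Non-negative scalar signal (arbitrary units).
#' @export
tpef_signal <- function(focal, sample_model = c("layer", "point"),
                        point_index = c(1L, 1L)) {
  sample_model <- match.arg(sample_model)
  g <- if (inherits(focal, "complex_field")) focal$grid else focal
  i2 <- Re(g)^2 + Im(g)^2
  if (sample_model == "layer") sum(i2 * i2)
  else i2[point_index[1L], point_index[2L]]^2
}

#' Ideal photon-counting detector
#'
#' Converts the raw two-photon signal to an expected photon count by an
#' exactly linear scale; quantum efficiency is 1 and readout noise 0, so
#' the only noise is Poisson shot noise.
#'
#' @param scale positive conversion factor from signal to expected count.
#' @param noiseless if `TRUE`, [record_photons()] returns the expected
#'   count itself instead of a Poisson draw (useful for noise-free
#'   algorithm analysis).
#' @return An object of class `"detector_model"`.
#' @export
detector_model <- function(scale = 1, noiseless = FALSE) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0",
                                             call. = FALSE)
  structure(list(scale = scale, quantum_efficiency = 1, readout_noise = 0,
                 noiseless = isTRUE(noiseless)),
            class = "detector_model")
}

#' Record a photon count
#'
#' Draws a Poisson count with mean `scale * signal` from the current RNG
#' stream (or returns the mean itself for a noiseless detector).
#'
#' @param signal non-negative raw signal.
#' @param detector a [detector_model()].
#' @return Photon count (integer unless the detector is noiseless).
#' @export
record_photons <- function(signal, detector) {
  if (any(signal < 0)) stop("signal must be >= 0", call. = FALSE)
  if (detector$noiseless) return(detector$scale * signal)
  stats::rpois(length(signal), detector$scale * signal)
}

#' Compiled forward model for one scatterer
#'
#' Precomputes everything needed to evaluate the photon-producing chain
#' SLM phase -> pupil field -> scatterer -> focal field -> TPEF signal,
#' so the per-exposure cost inside the optimisation loops is a pair of
#' small complex matrix products.
#'
#' @param scatterer a [scatterer_mask()].
#' @param config a [sim_config()].
#' @return An object of class `"forward_model"`; use [focal_signal()] and
#'   [mask_enhancement()] on it.
#' @export
forward_model <- function(scatterer, config) {
  stopifnot(inherits(config, "sim_config"),
            inherits(scatterer, "scatterer_mask"),
            scatterer$n_scat == config$n_scat)
  n <- config$n_scat
  side <- n * config$pad_factor
  fm <- list(
    config = config,
    scatterer = scatterer,
    scat_field = exp(1i * scatterer$phase),
    up_idx = upsample_index(config$n_slm, n),
    w = dft_factor(side, n),
    side = side,
    norm4 = as.numeric(side)^4
  )
  class(fm) <- "forward_model"
  flat <- matrix(0, config$n_slm, config$n_slm)
  fm$flat_signal <- focal_signal(fm, flat)
  fm$flat_peak <- peak_signal(fm, flat)
  fm
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf(paste0("<forward_model> scatterer seed %d, %d->%d grid,",
                     " flat-mask signal %.6g\n"),
              x$scatterer$seed, x$config$n_slm, x$config$n_scat,
              x$flat_signal))
  invisible(x)
}

#' Fast TPEF signal for an SLM phase mask
#'
#' @param fm a [forward_model()].
#' @param slm_phase real `n_slm x n_slm` phase matrix.
#' @return The raw TPEF signal for the configured sample model.
#' @export
focal_signal <- function(fm, slm_phase) {
  f <- fm$scat_field * exp(1i * slm_phase)[fm$up_idx]
  e <- fm$w %*% f %*% t(fm$w)
  i2 <- Re(e)^2 + Im(e)^2
  if (fm$config$sample_model == "layer") sum(i2 * i2) / fm$norm4
  else i2[fm$config$point_index[1L], fm$config$point_index[2L]]^2 / fm$norm4
}

#' Focal-plane complex field for an SLM phase mask
#'
#' Unitary propagation of the unit-amplitude SLM field through the
#' scatterer; the building block for interferometer-style algorithms
#' that superpose two independently propagated beams in the focal
#' plane.
#'
#' @param fm a [forward_model()].
#' @param slm_phase real `n_slm x n_slm` phase matrix.
#' @return Complex matrix on the padded focal grid.
#' @export
focal_field <- function(fm, slm_phase) {
  f <- fm$scat_field * exp(1i * slm_phase)[fm$up_idx]
  (fm$w %*% f %*% t(fm$w)) / fm$side
}

# TPEF signal of a precomputed focal field
field_signal <- function(fm, e) {
  i2 <- Re(e)^2 + Im(e)^2
  if (fm$config$sample_model == "layer") sum(i2 * i2)
  else i2[fm$config$point_index[1L], fm$config$point_index[2L]]^2
}

# maximum pixelwise TPEF signal over the focal plane
peak_signal <- function(fm, slm_phase) {
  f <- fm$scat_field * exp(1i * slm_phase)[fm$up_idx]
  e <- fm$w %*% f %*% t(fm$w)
  i2 <- Re(e)^2 + Im(e)^2
  max(i2)^2 / fm$norm4
}

#' Noise-free enhancement of a phase mask
#'
#' The enhancement eta of a correction mask relative to the flat
#' (uncorrected) mask, evaluated noise-free at full power. Under the
#' default `"peak"` metric it is the ratio of the maximum pixelwise
#' two-photon signal over the focal plane -- the simulation analogue of
#' the enhancement read off an image maximum; under `"total"` it is the
#' ratio of the layer-integrated signal the detector records.
#'
#' @param fm a [forward_model()].
#' @param slm_phase real `n_slm x n_slm` phase matrix.
#' @return Dimensionless enhancement; 1 for the flat mask.
#' @export
mask_enhancement <- function(fm, slm_phase) {
  if (fm$config$sample_model == "point" ||
      fm$config$eta_metric == "total")
    focal_signal(fm, slm_phase) / fm$flat_signal
  else peak_signal(fm, slm_phase) / fm$flat_peak
}

#' Ideal phase-conjugation mask
#'
#' Block-averages the scatterer phase onto the SLM grid (circular mean
#' per block) and negates it: the best correction available at SLM
#' resolution, used as the reference ceiling for enhancement.
#'
#' @param scatterer a [scatterer_mask()].
#' @param config a [sim_config()].
#' @return An `n_slm x n_slm` phase matrix.
#' @export
conjugate_mask <- function(scatterer, config) {
  b <- config$n_scat %/% config$n_slm
  z <- exp(-1i * scatterer$phase)
  acc <- matrix(0 + 0i, config$n_slm, config$n_slm)
  for (r in seq_len(b)) for (cc in seq_len(b)) {
    acc <- acc + z[seq(r, config$n_scat, by = b),
                   seq(cc, config$n_scat, by = b)]
  }
  Arg(acc)
}
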