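# Small builders shared across test files. All fixtures are generated
# in code; grids are kept small (8x8 SLM over 16x16 scatterer) so the
# unit suite stays fast.

small_cfg <- function(i0 = 1000, noiseless = FALSE, ...) {
  sim_config(n_slm = 8L, n_scat = 16L, i0 = i0, noiseless = noiseless,
             ...)
}

# a scatterer with externally supplied phases (e.g. constant, or a
# block-resolved grating) wearing the regular class
manual_scatterer <- function(phase, seed = 0L) {
  structure(list(phase = phase, seed = as.integer(seed),
                 n_scat = nrow(phase)),
            class = "scatterer_mask")
}

flat_scatterer <- function(cfg, value = 0) {
  manual_scatterer(matrix(value, cfg$n_scat, cfg$n_scat))
}

# scatterer equal to minus a block-upsampled SLM grating: exactly
# correctable at SLM resolution, so one mode carries all aberration
grating_scatterer <- function(cfg, kx, ky) {
  b <- cfg$n_scat %/% cfg$n_slm
  m <- render_mode(kx, ky, cfg$n_slm)
  up <- m[rep(seq_len(cfg$n_slm), each = b), rep(seq_len(cfg$n_slm),
                                                 each = b)]
  manual_scatterer((-up) %% (2 * pi))
}

# independent least-squares oracle for the phase-stepping estimator:
# fit s_p = c0 + A * cos(phi_p + delta) by linear regression on
# cos/sin regressors
ls_phase_fit <- function(s, P = length(s)) {
  phi_p <- (seq_len(P) - 1) * 2 * pi / P
  fit <- stats::lm(s ~ cos(phi_p) + sin(phi_p))
  cc <- stats::coef(fit)
  # c0 + b1 cos + b2 sin = c0 + A cos(phi + delta) with
  # A = sqrt(b1^2 + b2^2), delta = atan2(-b2, b1)
  list(a = sqrt(cc[2]^2 + cc[3]^2), delta = atan2(-cc[3], cc[2]))
}

# noiseless two-beam phase-stepping sequence: reference r, mode b,
# relative phase `delta` (mode field b * exp(1i*(phi_p - delta)))
two_beam_counts <- function(r, b, delta, P) {
  phi_p <- (seq_len(P) - 1) * 2 * pi / P
  (r^2 + b^2 + 2 * r * b * cos(phi_p - delta))^2
}
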