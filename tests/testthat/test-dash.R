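test_that("hologram composition has the right limits and conventions", {
  C <- matrix(1 + 0i, 4, 4)
  M <- matrix(pi / 2, 4, 4)
  # f -> 1: pure mode term, wrapped
  expect_equal(compose_slm_phase(C, M, 0, list(f = 1, P = 4)),
               matrix(pi / 2, 4, 4))
  # f -> 0: pure reference phase
  Cr <- matrix(exp(1i * 0.7), 4, 4)
  expect_equal(compose_slm_phase(Cr, M, 0, list(f = 0, P = 4)),
               matrix(0.7, 4, 4), tolerance = 1e-12)
  # f = 0.5, equal-weight phasors at 0 and pi/2 bisect to pi/4
  expect_equal(compose_slm_phase(C, M, 0, list(f = 0.5, P = 4))[1, 1],
               pi / 4, tolerance = 1e-12)
  # exact cancellation at f = 0.5 and opposed phases: phase 0 by
  # convention
  Mo <- matrix(pi, 4, 4)
  expect_equal(compose_slm_phase(C, Mo, 0, list(f = 0.5, P = 4)),
               matrix(0, 4, 4), tolerance = 1e-12)
  # zero-modulus reference pixels fall back to phase 0, with a warning
  Cz <- C; Cz[2, 2] <- 0 + 0i
  expect_warning(ph <- compose_slm_phase(Cz, M, 0, list(f = 0.3, P = 4)),
                 "zero-modulus")
  expect_equal(ph[2, 2], ph[1, 1])
  # output is always a valid wrapped phase
  expect_true(all(ph > -pi & ph <= pi))
})

test_that("phase-stepping estimator matches a least-squares oracle", {
  # no modulation, no first harmonic
  flat <- phase_step_estimate(rep(42, 5))
  expect_equal(flat$a, 0, tolerance = 1e-12)
  expect_equal(flat$phi, 0)
  expect_equal(phase_step_estimate(rep(0, 4)), list(a = 0, phi = 0))
  expect_error(phase_step_estimate(c(1, 2), P = 2), "P >= 3")

  for (delta in c(0.3, pi / 3, -2.0)) {
    for (P in c(3, 5, 64)) {
      cnt <- two_beam_counts(r = 1, b = 0.5, delta = delta, P = P)
      est <- phase_step_estimate(cnt, P, use_sqrt = TRUE)
      ora <- ls_phase_fit(sqrt(cnt), P)
      expect_equal(est$a, unname(ora$a), tolerance = 1e-9)
      # the estimator's phi equals the oracle's delta; for the mode
      # field b*exp(1i*(phi_p - delta)) that is -delta
      expect_equal(est$phi, unname(ora$delta), tolerance = 1e-9)
      expect_equal(est$phi, -delta, tolerance = 1e-9)
    }
    # exact trigonometric interpolation: P = 3 equals P = 64
    e3 <- phase_step_estimate(two_beam_counts(1, 0.5, delta, 3), 3)
    e64 <- phase_step_estimate(two_beam_counts(1, 0.5, delta, 64), 64)
    expect_equal(e3$a, e64$a, tolerance = 1e-9)
    expect_equal(e3$phi, e64$phi, tolerance = 1e-9)
  }
})

test_that("the holographic update adds the measured mode", {
  C <- matrix(1 + 0i, 4, 4)
  M <- matrix(0, 4, 4)
  expect_identical(dash_update(C, M, 0, 1.3), C)
  expect_equal(dash_update(C, M, 1, 0), matrix(2 + 0i, 4, 4))
  # destructive sum at pixels where the mode is pi out of phase
  g <- render_mode(1, 0, 4)
  C2 <- dash_update(C, g, 1, 0)
  expect_equal(Mod(C2[3, 1]), 0, tolerance = 1e-12)  # g[3, 1] = pi
})

test_that("a corrected system yields vanishing modulation depths", {
  # modes rendered on the full scatterer grid at P = 7: no diffraction
  # order of the two-beam hologram collides with the demodulation bin,
  # so probing a perfectly corrected system returns essentially no
  # first harmonic, while the same modes probed through a speckle
  # state modulate strongly
  cfg <- sim_config(16, 16, pad_factor = 1, noiseless = TRUE)
  b <- build_grating_basis(8, 16)
  dcfg <- dash_config(P = 7)
  C0 <- matrix(1 + 0i, 16, 16)
  depth_for <- function(scatterer) {
    fm <- forward_model(scatterer, cfg)
    vapply(b$modes[2:10], function(m) {
      sig <- vapply(0:6, function(p)
        focal_signal(fm, compose_slm_phase(C0, m, p, dcfg)), numeric(1))
      est <- phase_step_estimate(sig, 7)
      est$a / mean(sqrt(sig))
    }, numeric(1))
  }
  d_flat <- depth_for(flat_scatterer(cfg, 1.2))
  d_speckle <- depth_for(generate_scatterer(cfg, seed = 4))
  expect_lt(max(d_flat), 0.02)
  expect_gt(median(d_speckle), 10 * median(d_flat))
})

test_that("noiseless DASH enhancement grows across iterations to a stable plateau", {
  cfg <- small_cfg(noiseless = TRUE, eta_metric = "total")
  sc <- generate_scatterer(cfg, seed = 3)
  b <- build_grating_basis(8, 8)
  run <- run_dash(sc, b, cfg, dash_config(P = 3, iterations = 6),
                  seed = 1)
  be <- boundary_eta(run$trace)
  # iteration-level monotone rise ...
  expect_true(all(diff(be[1:4]) > 0))
  # ... to a plateau that stays put (holographic averaging)
  expect_lt(diff(range(be[4:6])) / be[6], 0.05)
  expect_gt(be[6], be[1])
})

test_that("re-measuring a mode right after its update shrinks its phase", {
  cfg <- small_cfg(noiseless = TRUE)
  sc <- generate_scatterer(cfg, seed = 8)
  fm <- forward_model(sc, cfg)
  b <- build_grating_basis(8, 8)
  dcfg <- dash_config(P = 5)
  det <- detector_model(1, noiseless = TRUE)
  C <- matrix(1 + 0i, 8, 8)
  measure <- function(C, mode) {
    cnt <- vapply(0:4, function(p)
      record_photons(focal_signal(fm, compose_slm_phase(C, mode, p,
                                                        dcfg)), det),
      numeric(1))
    phase_step_estimate(cnt, 5)
  }
  before <- after <- amp <- numeric(0)
  for (nm in 2:20) {
    mode <- b$modes[[nm]]
    est <- measure(C, mode)
    C <- dash_update(C, mode, est$a, est$phi)
    est2 <- measure(C, mode)
    before <- c(before, abs(est$phi)); after <- c(after, abs(est2$phi))
    amp <- c(amp, est$a)
  }
  keep <- amp > 0.01 * max(amp)
  expect_lt(mean(after[keep]), mean(before[keep]))
})

test_that("noiseless DASH converges to the conjugation reference level", {
  # the block-averaged conjugation mask is the natural reference; under
  # the integrated |E|^4 objective DASH often ends ABOVE it (the
  # reference is not the optimum of this objective), and on no
  # scatterer should it fall far below
  cfg <- small_cfg(noiseless = TRUE, eta_metric = "total")
  b <- build_grating_basis(8, 8)
  frac <- vapply(1:10, function(sd) {
    sc <- generate_scatterer(cfg, seed = sd)
    fm <- forward_model(sc, cfg)
    eta_perfect <- mask_enhancement(fm, conjugate_mask(sc, cfg))
    run <- run_dash(sc, b, cfg, dash_config(P = 5, iterations = 3),
                    seed = sd)
    run$trace$eta[length(run$trace$eta)] / eta_perfect
  }, numeric(1))
  expect_gt(min(frac), 0.7)
  expect_gt(median(frac), 0.9)
})

test_that("DASH bookkeeping: schedule, counts and reproducibility", {
  cfg <- small_cfg(i0 = 200)
  sc <- generate_scatterer(cfg, seed = 4)
  b <- build_grating_basis(8, 8)
  dcfg <- dash_config(P = 3, iterations = 2)
  r1 <- run_dash(sc, b, cfg, dcfg, seed = 9)
  r2 <- run_dash(sc, b, cfg, dcfg, seed = 9)
  expect_identical(r1$trace$eta, r2$trace$eta)
  expect_identical(r1$measurements, r2$measurements)
  # zero mode skipped in iteration 0 only
  expect_equal(nrow(r1$measurements), (64 - 1) + 64)
  expect_equal(length(r1$trace$m), (64 - 1) * 3 + 64 * 3)
  expect_equal(r1$trace$boundaries, c(189L, 381L))
  expect_false(any(r1$measurements$kx == 0 & r1$measurements$ky == 0 &
                     r1$measurements$i == 0))
  expect_true(any(r1$measurements$kx == 0 & r1$measurements$ky == 0 &
                    r1$measurements$i == 1))
})
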