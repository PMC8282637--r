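test_that("F-SHARP updates only at iteration boundaries", {
  cfg <- small_cfg(i0 = 500)
  sc <- generate_scatterer(cfg, seed = 2)
  b <- build_grating_basis(8, 8)
  run <- run_fsharp(sc, b, cfg, dash_config(P = 3, iterations = 3),
                    seed = 1)
  tr <- run$trace
  starts <- c(1L, tr$boundaries[-length(tr$boundaries)] + 1L)
  for (k in seq_along(starts)) {
    seg <- tr$eta[starts[k]:tr$boundaries[k]]
    expect_equal(length(unique(seg)), 1L)  # flat within the iteration
  }
  expect_equal(tr$eta[1], 1)  # flat mask displayed during iteration 1
})

test_that("F-SHARP matches direct conjugation on a point-like target", {
  # with a point sample the interferometric estimate of every mode is
  # exact (sqrt of the signal is the probe-scan cross term), so one
  # noiseless F-SHARP iteration reproduces the conjugation mask
  cfg <- small_cfg(noiseless = TRUE, sample_model = "point")
  sc <- generate_scatterer(cfg, seed = 5)
  fm <- forward_model(sc, cfg)
  eta_perfect <- mask_enhancement(fm, conjugate_mask(sc, cfg))
  b <- build_grating_basis(8, 8)
  rf <- run_fsharp(sc, b, cfg, dash_config(P = 5, iterations = 2),
                   seed = 1)
  expect_gt(boundary_eta(rf$trace)[2], 0.95 * eta_perfect)
})
test_that("IMPACT tag frequency plan keeps all mixing products out of band", {
  for (n_px in c(4, 32, 128)) {
    tg <- impact_tag_frequencies(n_px)
    lo <- min(tg$freqs); hi <- max(tg$freqs)
    expect_equal(length(unique(tg$freqs)), n_px)
    expect_lt(hi, tg$T / 2)                      # below Nyquist
    expect_lt(max(tg$freqs) - min(tg$freqs), lo) # differences below band
    # sum frequencies fold back below the band
    sums <- outer(tg$freqs, tg$freqs, "+")
    expect_lt(max(tg$T - sums), lo)
    # conjugate band above
    expect_gt(min(tg$T - tg$freqs), hi)
  }
})

test_that("IMPACT extraction recovers phases from a synthetic record", {
  tg <- impact_tag_frequencies(4)
  set.seed(5)
  delta <- stats::runif(4, -pi, pi)
  t <- 0:(tg$T - 1)
  # weak modulators: |A + sum b e^{i...}| is linear in b to first
  # order, so in-band leakage from the modulus nonlinearity stays
  # third-order (~b^3/A^2)
  field <- 10 + Reduce(`+`, lapply(1:4, function(j)
    0.01 * exp(1i * (tg$freqs[j] * t * 2 * pi / tg$T + delta[j]))))
  ex <- impact_extract_phases(Mod(field)^2, tg$freqs)
  err <- Arg(exp(1i * (ex$phases - delta)))
  expect_lt(max(abs(err)), 1e-6)
})

test_that("frequency-multiplexed IMPACT is a no-op on a flat scatterer", {
  # point sample: sqrt of the signal is exactly |E|^2, so the band plan
  # is exact and no spurious correction can appear
  cfg <- small_cfg(noiseless = TRUE, sample_model = "point")
  sc <- flat_scatterer(cfg)
  run <- run_impact(sc, cfg, total_m = 2 * 6 * 33, boundaries = c(6 * 33,
                    2 * 6 * 33), seed = 1, multiplex = "frequency")
  # no aberration: extracted corrections leave the mask flat
  ph <- run$correction
  ph <- Arg(exp(1i * (ph - ph[1, 1])))  # common piston removed
  expect_lt(max(abs(ph)), 1e-6)
  expect_equal(boundary_eta(run$trace), c(1, 1), tolerance = 1e-9)
})

test_that("time-multiplexed IMPACT converges on noiseless systems", {
  # bootstraps slowly from the diffuse state (like F-SHARP), then
  # settles near the conjugation reference
  cfg <- sim_config(16, 32, noiseless = TRUE, eta_metric = "total")
  sc <- generate_scatterer(cfg, seed = 7)
  fm <- forward_model(sc, cfg)
  eta_perfect <- mask_enhancement(fm, conjugate_mask(sc, cfg))
  tot <- 16L * 128L * 5L
  run <- run_impact(sc, cfg, tot, seq(640L, tot, 640L), P = 5, seed = 1)
  be <- boundary_eta(run$trace)
  expect_gt(be[16], 0.6 * eta_perfect)
  expect_gt(be[16], 4 * be[1])
})
test_that("the restricted half-basis has one mode per modulated pixel", {
  hm <- dashsim:::half_grating_modes(8)
  expect_equal(length(hm), 32)  # 8^2 / 2
  # restricted patterns are pairwise distinct on the checkerboard half
  cb <- outer(1:8, 1:8, "+") %% 2 == 0
  px <- which(cb)
  pat <- vapply(hm, function(m) paste(round(m$pattern[px], 9),
                                      collapse = ","), character(1))
  expect_equal(length(unique(pat)), 32)
})

test_that("CSA corrects a single aberrated pixel in one visit", {
  cfg <- small_cfg(noiseless = TRUE)
  aberr <- 2.1
  ph <- matrix(0, 16, 16); ph[5:6, 9:10] <- aberr  # SLM pixel (3, 5)
  sc <- manual_scatterer(ph)
  P <- 8L
  run <- run_csa(sc, cfg, P = P, total_m = 64L * P,
                 boundaries = 64L * P, seed = 1)
  got <- run$correction[3, 5]
  err <- Arg(exp(1i * (got + aberr)))
  expect_lt(abs(err), pi / P)
  # other pixels move only through weak |E|^4 sidelobe cross-talk
  others <- Arg(exp(1i * run$correction[-(3 + 4 * 8)]))
  expect_lt(max(abs(others)), 0.1)
})

test_that("CSA is a no-op on a flat scatterer", {
  cfg <- small_cfg(noiseless = TRUE)
  sc <- flat_scatterer(cfg)
  run <- run_csa(sc, cfg, P = 4, total_m = 64L * 4L,
                 boundaries = 64L * 4L, seed = 1)
  expect_lt(max(abs(Arg(exp(1i * run$correction)))), 1e-6)
})

test_that("PA accepts only measured improvements and reproduces by seed", {
  cfg <- small_cfg(noiseless = TRUE, eta_metric = "total")
  set.seed(31)
  bin <- matrix(sample(c(0, pi), 256, replace = TRUE), 16)
  sc <- manual_scatterer(bin)
  r1 <- run_pa(sc, cfg, P = 4, total_m = 400, boundaries = c(200, 400),
               seed = 6)
  r2 <- run_pa(sc, cfg, P = 4, total_m = 400, boundaries = c(200, 400),
               seed = 6)
  expect_identical(r1$correction, r2$correction)
  # noiseless: the applied offset is the best measured one and offset 0
  # is among the candidates, so eta never decreases at update points
  eta_upd <- r1$trace$eta[seq(4, 400, by = 4)]
  expect_true(all(diff(eta_upd) > -1e-9))
})

test_that("GA with zero mutation keeps an identical population fixed", {
  cfg <- small_cfg(i0 = 100)
  sc <- generate_scatterer(cfg, seed = 3)
  # one quantisation level forces every mask (initial and offspring) to
  # the same flat pattern; with mutation off the population can never
  # change, so the best mask stays the flat mask forever
  gcfg <- ga_config(population = 6, phase_levels = 1,
                    mutation_rate_initial = 0,
                    mutation_rate_final = 0)
  run <- run_ga(sc, cfg, gcfg, total_m = 120, boundaries = c(60, 120),
                seed = 2)
  expect_true(all(run$trace$eta == run$trace$eta[1]))
  expect_equal(run$correction, matrix(0, 8, 8))
})

test_that("GA finds the brute-force optimum of a tiny quantised problem", {
  cfg <- sim_config(n_slm = 2, n_scat = 4, i0 = 1000, noiseless = TRUE)
  sc <- generate_scatterer(cfg, seed = 12)
  fm <- forward_model(sc, cfg)
  L <- 8L
  # brute force over all 8^4 quantised masks
  lv <- (0:(L - 1)) * 2 * pi / L
  best <- 0
  for (a in lv) for (b in lv) for (cc in lv) for (d in lv)
    best <- max(best, focal_signal(fm, matrix(c(a, b, cc, d), 2)))
  gcfg <- ga_config(population = 8, phase_levels = L,
                    mutation_rate_initial = 0.2,
                    mutation_rate_final = 0.05, decay = 500)
  run <- run_ga(sc, cfg, gcfg, total_m = 200 * 8,
                boundaries = c(800, 1600), seed = 5)
  got <- focal_signal(fm, run$correction)
  expect_gt(got, best * (1 - 1e-9))
})

test_that("all algorithms leave total pupil power unchanged", {
  cfg <- small_cfg(i0 = 300)
  sc <- generate_scatterer(cfg, seed = 1)
  b <- build_grating_basis(8, 8)
  dcfg <- dash_config(P = 3, iterations = 1)
  runs <- list(
    run_dash(sc, b, cfg, dcfg, seed = 1),
    run_fsharp(sc, b, cfg, dcfg, seed = 1),
    run_csa(sc, cfg, 3, 189L, 189L, seed = 1))
  for (r in runs) {
    pup <- slm_to_pupil(r$correction, cfg)
    expect_equal(total_power(pup), cfg$n_scat^2, tolerance = 1e-10)
  }
})
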