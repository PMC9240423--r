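# The synthetic forward model: FID series, multi-echo stacks, force traces
# and cohort draws, each validated against simple independent oracles.

test_that("a flat protocol (no depletion, no noise) yields identical FIDs", {
  p <- smallProtocol(n_points = 256L)
  truth <- kineticsGroundTruth(depletion_frac = 0, noise_sd = 0,
                               ph_end_exercise = 7.25)
  s <- generateFidSeries(p, truth)
  m <- fidMatrix(s)
  for (i in 2:nrow(m)) expect_identical(m[i, ], m[1, ])
})

test_that("FID generation is reproducible under a fixed seed", {
  p <- smallProtocol(n_points = 128L)
  truth <- kineticsGroundTruth(noise_sd = 0.5, seed = 11L)
  s1 <- generateFidSeries(p, truth)
  s2 <- generateFidSeries(p, truth)
  expect_identical(fidMatrix(s1), fidMatrix(s2))
  truth2 <- kineticsGroundTruth(noise_sd = 0.5, seed = 12L)
  expect_false(identical(fidMatrix(s1),
                         fidMatrix(generateFidSeries(p, truth2))))
})

test_that("DFT peak areas are proportional to configured amplitudes", {
  # high-resolution condition where region integration is itself accurate:
  # narrow equal dampings (1 Hz) and a long acquisition so adjacent-peak
  # tail cross-talk is far below the 0.1 % assertion
  d <- 1
  db <- c(0.5, 300)
  priors <- list(
    peakPrior("PCr", 0, c(-0.5, 0.5), damping_init = d, damping_bounds = db),
    peakPrior("Pi", 4.8, c(3.271, 5.689), damping_init = d, damping_bounds = db),
    peakPrior("gammaATP", -2.5, c(-3.2, -1.8), n_lines = 2L, j_hz = 16.5,
              ratios = c(1, 1), damping_init = d, damping_bounds = db),
    peakPrior("alphaATP", -7.5, c(-8.2, -6.8), n_lines = 2L, j_hz = 16.5,
              ratios = c(1, 1), damping_init = d, damping_bounds = db),
    peakPrior("betaATP", -16.2, c(-17, -15.4), n_lines = 3L, j_hz = 16.5,
              ratios = c(1, 2, 1), damping_init = d, damping_bounds = db)
  )
  p <- acquisitionProtocol(n_rest = 1L, n_exercise = 1L, n_recovery = 1L,
                           block_exercise = 1L, block_recovery = 1L,
                           n_points = 65536L)
  truth <- kineticsGroundTruth(pcr_rest_mM = 16, pi_rest_mM = 12, atp_mM = 8,
                               depletion_frac = 0, ph_end_exercise = 7.25)
  fid <- fidMatrix(generateFidSeries(p, truth, priors))[1, ]
  centres <- c(0, shiftFromPh(7.25), -2.5, -7.5, -16.2) * p@f0_mhz
  amps <- c(16, 12, 8, 8, 8)
  areas <- integrateSpectrumVoronoi(fid, p@sweep_hz, centres)
  ratios <- (areas / areas[1]) / (amps / amps[1])
  expect_true(all(abs(ratios - 1) < 1e-3))
})

test_that("PCr + Pi is conserved in every generated FID", {
  # conservation holds per FID by construction; quantify single-FID blocks
  # so the assertion is not confounded by line smear across summed blocks
  p <- acquisitionProtocol(n_rest = 2L, n_exercise = 20L, n_recovery = 20L,
                           block_exercise = 1L, block_recovery = 1L,
                           n_points = 512L)
  s <- generateFidSeries(p, kineticsGroundTruth(tau_stim_min = 0.3,
                                                tau_rec_min = 0.4))
  q <- quantifySeries(s)
  pcr <- q$amplitude[q$name == "PCr"]
  pi_amp <- q$amplitude[q$name == "Pi"]
  tot <- pcr + pi_amp
  expect_true(all(abs(tot / tot[1] - 1) < 0.005))
  # and the exercise bins really do exchange amplitude between the pools
  expect_lt(min(pcr) / max(pcr), 0.7)
})

test_that("multi-echo stack follows S0*exp(-TE/T2), with Inf as no-decay flag", {
  te <- defaultEchoTimes()
  st <- generateMultiechoStack(c(4, 4), te, Inf, s0_map = 500)
  expect_true(all(apply(st@data[, , , 1], c(1, 2), function(v)
    all(v == 500))))
  # two-pixel truth map recovered by an independent log-linear regression
  t2map <- matrix(c(25, 31), 1, 2)
  st2 <- generateMultiechoStack(c(1, 2), te, t2map, s0_map = 1000)
  for (j in 1:2) {
    sig <- st2@data[1, j, , 1]
    slope <- unname(coef(lm(log(sig) ~ te))[2])
    expect_equal(-1 / slope, t2map[1, j], tolerance = 1e-10)
  }
  expect_error(generateMultiechoStack(c(2, 2), te, -5), "positive")
  expect_error(generateMultiechoStack(c(2, 2), rev(te), 30), "increasing")
})

test_that("multi-echo noise is Rician and seed-stable", {
  te <- defaultEchoTimes()
  a <- generateMultiechoStack(c(8, 8), te, 30, noise_sd = 20, seed = 3L)
  b <- generateMultiechoStack(c(8, 8), te, 30, noise_sd = 20, seed = 3L)
  expect_identical(a@data, b@data)
  expect_true(all(a@data >= 0))  # magnitude data
})

test_that("force trace has one twitch per pulse and a faithful envelope", {
  p <- acquisitionProtocol()
  tr <- generateForceTrace(p)
  expect_length(tr@stim_times_s, 360L)
  tw <- detectTwitches(tr)
  expect_identical(nrow(asTable(tw)), 360L)
  # detected peaks match generator ground truth
  expect_true(all(abs(asTable(tw)$peak_mN - tr@truth_peaks_mN) /
                    tr@truth_peaks_mN < 0.005))
  # envelope-sum oracle: summed detected peaks vs summed envelope
  expect_equal(sum(asTable(tw)$peak_mN), sum(tr@truth_peaks_mN),
               tolerance = 0.005)
  # biphasic: peak near 90 s, lower at both ends
  pk <- asTable(tw)$peak_mN
  expect_gt(pk[91], pk[1])
  expect_gt(pk[91], pk[360])
})

test_that("constant envelope gives constant detected peaks", {
  p <- acquisitionProtocol(exercise_duration_s = 30)
  tr <- generateForceTrace(p, list(shape = "constant", peak_mN = 150))
  pk <- asTable(detectTwitches(tr))$peak_mN
  expect_equal(pk, rep(150, 30), tolerance = 1e-6)
})

test_that("cohort draws match their generating distribution and are seeded", {
  expect_error(generateCohort(n_per_group = 0L), ">= 1")
  bad <- list(CON = list(muscle_volume_mm3 = c(150, -1)))
  expect_error(generateCohort(bad, 3L), "negative SD")
  spec <- list(CON = list(muscle_volume_mm3 = c(154.76, 15.82)))
  co <- generateCohort(spec, 1000L, seed = 5L)
  se <- 15.82 / sqrt(1000)
  expect_lt(abs(mean(co$muscle_volume_mm3) - 154.76), 2 * se)
  expect_identical(co, generateCohort(spec, 1000L, seed = 5L))
})
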