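# Binning and constrained time-domain fitting.

test_that("default protocol bins into 1 rest + 30 exercise + 7 recovery", {
  p <- acquisitionProtocol()
  expect_identical(unname(nBins(p)), c(1L, 30L, 7L))
  s <- generateFidSeries(smallProtocol(128L), kineticsGroundTruth())
  blocks <- binFids(s)
  expect_length(blocks, 1L + 6L + 4L)
  expect_identical(vapply(blocks, `[[`, "", "phase"),
                   rep(c("rest", "exercise", "recovery"), c(1L, 6L, 4L)))
  # midpoint of the rest block spans acquisitions 1..10 at TR 1.875
  expect_equal(blocks[[1]]$mid_time_s, 10 * 1.875 / 2)
  # block sums are plain complex sums (linearity): total energy check
  total <- Reduce(`+`, lapply(blocks, `[[`, "fid"))
  expect_equal(total, colSums(fidMatrix(s)), tolerance = 1e-12)
})

test_that("indivisible counts are rejected naming the phase", {
  expect_error(acquisitionProtocol(n_exercise = 451L), "divisible")
})

test_that("all-zero FIDs produce all-zero, flagged blocks", {
  p <- smallProtocol(64L)
  n <- p@n_rest + p@n_exercise + p@n_recovery
  s <- new("FIDSeries", fids = matrix(complex(real = 0), n, 64L),
           protocol = p,
           phase = rep(c("rest", "exercise", "recovery"),
                       c(p@n_rest, p@n_exercise, p@n_recovery)),
           truth = NULL)
  blocks <- binFids(s)
  expect_true(all(vapply(blocks, function(b) all(b$fid == 0), TRUE)))
  res <- fitBlock(blocks[[1]], defaultPriors(), p)
  expect_true(all(res$amplitude == 0))
  expect_false(any(res$converged))
})

test_that("a single noiseless PCr peak is recovered exactly", {
  p <- acquisitionProtocol(n_points = 1024L)
  t <- (0:1023) / p@sweep_hz
  prior <- list(peakPrior("PCr", 0, c(-0.5, 0.5), damping_init = 25))
  fid <- 100 * exp(complex(real = -30 * t, imaginary = 2 * pi * 0 * t))
  res <- fitBlock(fid, prior, p)
  expect_true(res$converged)
  expect_equal(res$amplitude, 100, tolerance = 1e-5)
  expect_equal(res$shift_ppm, 0, tolerance = 1e-6)
  expect_equal(res$damping_hz, 30, tolerance = 1e-4)
})

test_that("amplitude ratios and ATP multiplet totals are recovered", {
  p <- acquisitionProtocol(n_rest = 1L, n_exercise = 1L, n_recovery = 1L,
                           block_exercise = 1L, block_recovery = 1L)
  truth <- kineticsGroundTruth(pcr_rest_mM = 10, pi_rest_mM = 2, atp_mM = 5,
                               depletion_frac = 0, ph_end_exercise = 7.25)
  s <- generateFidSeries(p, truth)
  res <- fitBlock(fidMatrix(s)[1, ], defaultPriors(), p)
  expect_true(all(res$converged))
  amp <- setNames(res$amplitude, res$name)
  expect_equal(amp[["Pi"]] / amp[["PCr"]], 0.2, tolerance = 1e-3)
  expect_equal(amp[["betaATP"]] / amp[["PCr"]], 0.5, tolerance = 1e-3)
  # the 1:2:1 beta-ATP triplet's total equals the generated total
  expect_equal(amp[["betaATP"]], 5, tolerance = 0.005)
})

test_that("fit scales linearly with global FID amplitude, shifts unchanged", {
  p <- acquisitionProtocol(n_rest = 1L, n_exercise = 1L, n_recovery = 1L,
                           block_exercise = 1L, block_recovery = 1L,
                           n_points = 1024L)
  truth <- kineticsGroundTruth(depletion_frac = 0, ph_end_exercise = 7.25)
  fid <- fidMatrix(generateFidSeries(p, truth))[1, ]
  r1 <- fitBlock(fid, defaultPriors(), p)
  r2 <- fitBlock(7.5 * fid, defaultPriors(), p)
  expect_equal(r2$amplitude, 7.5 * r1$amplitude, tolerance = 1e-6)
  expect_equal(r2$shift_ppm, r1$shift_ppm, tolerance = 1e-8)
})

test_that("time-domain fit agrees with frequency-domain integration", {
  # well-separated noiseless singlets (PCr and beta-ATP positions, ~2 kHz
  # apart) with equal dampings and symmetric integration windows
  priors <- list(peakPrior("PCr", 0, c(-1, 1), damping_init = 30),
                 peakPrior("betaATP", -16.2, c(-17, -15.4), damping_init = 30))
  p <- acquisitionProtocol(n_points = 4096L)
  t <- (0:4095) / p@sweep_hz
  f_b <- -16.2 * p@f0_mhz
  fid <- 12 * exp(complex(real = -30 * t)) +
    3 * exp(complex(real = -30 * t, imaginary = 2 * pi * f_b * t))
  res <- fitBlock(fid, priors, p)
  a_fit <- setNames(res$amplitude, res$name)
  area_pcr <- integrateSpectrum(fid, p@sweep_hz, 0, 500)
  area_b <- integrateSpectrum(fid, p@sweep_hz, f_b, 500)
  expect_equal(a_fit[["betaATP"]] / a_fit[["PCr"]], area_b / area_pcr,
               tolerance = 0.01)
})

test_that("quantified series tracks the generator ground truth per bin", {
  p <- smallProtocol(512L)
  # constant series: flat amplitudes across bins
  flat <- generateFidSeries(p, kineticsGroundTruth(depletion_frac = 0,
                                                   ph_end_exercise = 7.25))
  qf <- quantifySeries(flat)
  pcr <- qf$amplitude[qf$name == "PCr"]
  expect_true(all(abs(pcr / pcr[1] - 1) < 1e-6))
  # -50 % depletion with a fast time constant so the exercise plateau is
  # reached well before the last bin of the reduced protocol
  dep <- generateFidSeries(p, kineticsGroundTruth(depletion_frac = -0.5,
                                                  tau_stim_min = 0.2))
  qd <- quantifySeries(dep)
  pcr_d <- qd[qd$name == "PCr", ]
  last_ex <- max(which(pcr_d$phase == "exercise"))
  expect_equal(pcr_d$amplitude[last_ex] / pcr_d$amplitude[1], 0.5,
               tolerance = 0.005)
})

test_that("out-of-order phase labels are rejected at construction", {
  p <- smallProtocol(64L)
  n <- p@n_rest + p@n_exercise + p@n_recovery
  expect_error(
    new("FIDSeries", fids = matrix(complex(real = 1), n, 64L), protocol = p,
        phase = rev(rep(c("rest", "exercise", "recovery"),
                        c(p@n_rest, p@n_exercise, p@n_recovery))),
        truth = NULL),
    "time-ordered")
})

test_that("amplitude estimates are unbiased under noise (Monte Carlo)", {
  p <- acquisitionProtocol(n_rest = 1L, n_exercise = 1L, n_recovery = 1L,
                           block_exercise = 1L, block_recovery = 1L,
                           n_points = 512L)
  n_rep <- 200L
  est <- vapply(seq_len(n_rep), function(i) {
    truth <- kineticsGroundTruth(depletion_frac = 0, ph_end_exercise = 7.25,
                                 noise_sd = 0.5, seed = 1000L + i)
    res <- fitBlock(fidMatrix(generateFidSeries(p, truth))[1, ],
                    defaultPriors(), p)
    res$amplitude[res$name == "PCr"]
  }, 0)
  se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - 16) / se, 4)  # within Monte-Carlo error
})
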