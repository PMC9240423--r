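# Mono-exponential PCr kinetics and the derived energetic indices.

test_that("noiseless depletion and recovery fits recover their tau exactly", {
  # recovery: 7 bins at 56.25 s, the protocol's recovery resolution
  t_rec <- (seq_len(7) - 0.5) * 56.25 / 60
  y_rec <- 7 + 9 * (1 - exp(-t_rec / 2.19))
  fr <- fitRecovery(t_rec, y_rec)
  expect_true(fr$converged)
  expect_equal(fr$tau_min, 2.19, tolerance = 1e-6)
  expect_equal(fr$amplitude, 9, tolerance = 1e-6)
  # depletion: 28.125 s bins over the exercise phase
  t_dep <- (seq_len(30) - 0.5) * 28.125 / 60
  y_dep <- 7 + 9 * exp(-t_dep / 1.57)
  fd <- fitDepletion(t_dep, y_dep)
  expect_true(fd$converged)
  expect_equal(fd$tau_min, 1.57, tolerance = 1e-6)
  expect_equal(fd$plateau, 7, tolerance = 1e-6)
})

test_that("degenerate inputs are flagged, not silently fitted", {
  t <- seq(0.25, 6, by = 0.25)
  fc <- fitDepletion(t, rep(10, length(t)))
  expect_false(fc$converged)
  expect_equal(fc$amplitude, 0)
  fr <- fitRecovery(t, rep(5, length(t)))
  expect_false(fr$converged)
  expect_error(fitDepletion(1:3, c(1, 2, 3)), "at least 4")
})

test_that("nonlinear fits agree with the brute-force grid oracle", {
  set.seed(42)
  taus <- seq(0.5, 5, by = 0.002)
  for (rep in 1:5) {
    t <- (seq_len(20) - 0.5) * 0.3
    tau_true <- runif(1, 1, 3)
    y <- 6 + 8 * exp(-t / tau_true) + rnorm(20, sd = 0.3)
    fit <- fitDepletion(t, y)
    oracle <- gridTau(t, y, taus, "depletion")
    expect_lt(abs(fit$tau_min - oracle), 0.002 + 1e-9)
  }
  for (rep in 1:5) {
    t <- (seq_len(20) - 0.5) * 0.3
    tau_true <- runif(1, 1, 3)
    y <- 6 + 8 * (1 - exp(-t / tau_true)) + rnorm(20, sd = 0.3)
    fit <- fitRecovery(t, y)
    oracle <- gridTau(t, y, taus, "recovery")
    expect_lt(abs(fit$tau_min - oracle), 0.002 + 1e-9)
  }
})

test_that("tau estimates are robust at the default noise level", {
  set.seed(7)
  n_rep <- 200L
  errs <- vapply(seq_len(n_rep), function(i) {
    t <- (seq_len(30) - 0.5) * 28.125 / 60
    y <- 7 + 9 * exp(-t / 1.57) + rnorm(30, sd = 0.25)
    abs(fitDepletion(t, y)$tau_min - 1.57) / 1.57
  }, 0)
  expect_lt(median(errs), 0.10)
})

test_that("rate and cost arithmetic behaves as defined", {
  expect_equal(vPcr(0, 2.19), 0)
  expect_equal(vPcr(6.745, 2.19), 3.08, tolerance = 1e-3)
  expect_equal(vPcr(2 * 6.745, 2.19), 2 * vPcr(6.745, 2.19))
  expect_error(vPcr(5, 0), "positive")
  expect_equal(pcrCost(5, 10), 0.5)
  expect_equal(pcrCost(5, 10, scale = 1000), 500)
  expect_error(pcrCost(5, 0), "positive")
  # cost vanishes as force grows without bound
  expect_lt(pcrCost(5, 1e12), 1e-11)
})

test_that("ADP-corrected Vmax matches its closed form and bounds", {
  expect_equal(vMax(3.08, 48.94), 4.968, tolerance = 1e-3)
  expect_equal(vMax(3.69, 55.17), 5.697, tolerance = 1e-3)
  expect_error(vMax(3, 0), "positive")
  # Km = 0 collapses to the uncorrected rate
  expect_equal(vMax(3.08, 48.94, physioConstants(km_adp_uM = 0)), 3.08)
  # v_max >= v_pcr_rec whenever Km, ADP > 0
  for (adp in c(5, 30, 80, 500))
    expect_gte(vMax(3.08, adp), 3.08)
})

test_that("fits are invariant to declared time-unit changes", {
  t_min <- (seq_len(12) - 0.5) * 0.5
  y <- 6 + 9 * exp(-t_min / 1.8)
  f_min <- fitDepletion(t_min, y)
  f_sec <- fitDepletion(t_min * 60, y)
  expect_equal(f_sec$tau_min / 60, f_min$tau_min, tolerance = 1e-8)
  expect_equal(f_sec$amplitude, f_min$amplitude, tolerance = 1e-8)
})

test_that("summarizeKinetics requires all phases and propagates fits", {
  run <- defaultNoiselessRun()
  k <- run$kinetics
  expect_equal(k@tau_stim_min, 1.57, tolerance = 1e-3)
  expect_equal(k@tau_rec_min, 2.19, tolerance = 2e-3)
  expect_equal(k@delta_pcr_pct, -56.45, tolerance = 0.05)
  expect_gte(k@v_max_mM_per_min, k@v_pcr_rec_mM_per_min)
  # series lacking a recovery phase is rejected
  truncated <- run$metab
  truncated@data <- truncated@data[truncated@data$phase != "recovery", ]
  expect_error(summarizeKinetics(truncated), "recovery")
})
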