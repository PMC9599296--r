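test_that("identical config and seed give bit-identical pairs and cohorts", {
  cp <- coupling_spec(1, 2, "theta", "theta", "amplitude", delay_ms = 45)
  p1 <- make_coupled_pair(fix_fs, 10, cp, seed = 3)
  p2 <- make_coupled_pair(fix_fs, 10, cp, seed = 3)
  expect_identical(p1$x, p2$x)
  expect_identical(p1$y, p2$y)

  cfg <- cohort_config(n_subjects = 2, n_roi = 4, n_posterior = 2,
                       fs = fix_fs, duration = 16, n_couplings = 3, seed = 11)
  c1 <- make_cohort(cfg)
  c2 <- make_cohort(cfg)
  expect_identical(c1$subjects[[1]]$recording, c2$subjects[[1]]$recording)
  expect_identical(c1$truth, c2$truth)
})

test_that("zero-strength pairs are independent at the envelope level", {
  cp <- coupling_spec(1, 2, "delta", "delta", "amplitude",
                      delay_ms = 80, strength = 0)
  pr <- make_coupled_pair(fix_fs, 30, cp, seed = 5)
  ex <- docmflow:::envelope(docmflow:::bandpass(pr$x, 1, 4, fix_fs))
  ey <- docmflow:::envelope(docmflow:::bandpass(pr$y, 1, 4, fix_fs))
  cc <- stats::ccf(ey, ex, lag.max = 30, plot = FALSE)
  # smooth delta envelopes have few effective degrees of freedom; the noise
  # floor is set by the envelope autocorrelation time (~1/bandwidth)
  n_eff <- length(ex) / (fix_fs / 3)
  expect_lt(max(abs(cc$acf)), 4 / sqrt(n_eff))
})

test_that("amplitude plants put the envelope cross-correlation peak at the delay", {
  hits <- vapply(1:4, function(sd) {
    z <- make_pair_envelopes("delta", "delta", "amplitude", 80, 1.5, 40, sd)
    cc <- stats::ccf(z$env_y, z$env_x, lag.max = 30, plot = FALSE)
    abs(cc$lag[which.max(cc$acf)] - z$delay_samples) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})

test_that("cross-band phase plants modulate the target phase increment", {
  # Rayleigh-style statistic of the delta-phase-binned mean theta increment,
  # against its own permutation quantile (the stated oracle)
  z <- make_pair_envelopes("delta", "theta", "phase", 80, 2, 30, 9)
  d <- z$delay_samples
  phx <- docmflow:::lag_series(z$phase_x, d)
  dphy <- diff(z$phase_y)
  dphy <- atan2(sin(dphy), cos(dphy))
  rayleigh <- function(ph, inc) {
    bins <- cut(ph, breaks = seq(-pi, pi, length.out = 9), include.lowest = TRUE)
    stats::sd(tapply(inc, bins, mean))  # spread of phase-binned mean increments
  }
  obs <- rayleigh(phx[-1], dphy)
  set.seed(42)
  null <- replicate(199, rayleigh(sample(phx[-1]), dphy))
  expect_gt(obs, stats::quantile(null, 0.95))
})

test_that("cohort structure follows the configuration", {
  cfg <- cohort_config(n_subjects = 4, n_roi = 6, n_posterior = 3,
                       fs = fix_fs, duration = 16, n_couplings = 4,
                       gradient_bands = "alpha1", seed = 2)
  coh <- make_cohort(cfg)
  ages <- vapply(coh$subjects, `[[`, 0, "age")
  expect_equal(range(ages), cfg$age_range)
  expect_equal(dim(coh$subjects[[1]]$recording), c(6, 16 * fix_fs))
  # gradient invariant: every planted alpha1 coupling runs posterior -> anterior
  a1 <- docmflow:::band_index("alpha1")
  grad_rows <- coh$truth[coh$truth$source_band == a1 | coh$truth$target_band == a1, ]
  expect_gt(nrow(grad_rows), 0)
  expect_true(all(grad_rows$source_roi %in% coh$partition$posterior))
  expect_true(all(grad_rows$target_roi %in% coh$partition$anterior))
})

test_that("the cross/within mixture peaks for the subject nearest the profile peak", {
  cfg <- cohort_config(n_subjects = 9, n_roi = 6, n_posterior = 3,
                       fs = fix_fs, duration = 16, n_couplings = 10, seed = 4)
  coh <- make_cohort(cfg)
  ratio <- vapply(seq_len(9), function(s) {
    tr <- coh$truth[coh$truth$subject == s, ]
    mean(tr$source_band != tr$target_band)
  }, numeric(1))
  ages <- vapply(coh$subjects, `[[`, 0, "age")
  nearest <- which.min(abs(ages - cfg$bai_profile$peak))
  expect_equal(ratio[nearest], max(ratio))  # ties possible from rounding
})

test_that("generator input validation rejects unusable settings", {
  cp <- coupling_spec(1, 2, "delta", "delta", "amplitude", delay_ms = 6000)
  expect_error(make_coupled_pair(fix_fs, 10, cp), "delay")
  expect_error(coupling_spec(1, 2, "nosuch", "delta"), "unknown band")
  expect_error(coupling_spec(1, 2, "beta", "delta"), "slower band")
  expect_error(make_coupled_pair(60, 10,
    coupling_spec(1, 2, "delta", "delta")), "fs")
  expect_error(cohort_config(age_range = c(50, 20)), "age_range")
  expect_error(make_cohort(cohort_config(n_subjects = 1)), "n_subjects")
})

test_that("cohorts round-trip through the text store", {
  cfg <- cohort_config(n_subjects = 2, n_roi = 3, n_posterior = 1,
                       fs = fix_fs, duration = 10, n_couplings = 2, seed = 8)
  coh <- make_cohort(cfg)
  dir <- tempfile()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$subjects[[2]]$age, coh$subjects[[2]]$age)
  expect_equal(back$subjects[[1]]$recording, coh$subjects[[1]]$recording,
               tolerance = 1e-12)
  expect_equal(back$truth$delay_ms, coh$truth$delay_ms)
  unlink(dir, recursive = TRUE)
})

test_that("null pairs leave directionality indices centred on zero", {
  # directionality of dPTE over independent pairs, 50 replicates
  vals <- vapply(1:50, function(sd) {
    cp <- coupling_spec(1, 2, "alpha1", "alpha1", "phase", strength = 0)
    pr <- make_coupled_pair(fix_fs, 10, cp, seed = sd + 500)
    phx <- docmflow:::instantaneous_phase(docmflow:::bandpass(pr$x, 8, 10, fix_fs))
    phy <- docmflow:::instantaneous_phase(docmflow:::bandpass(pr$y, 8, 10, fix_fs))
    dpte(pte(phx, phy, delta = 7), pte(phy, phx, delta = 7)) - 0.5
  }, numeric(1))
  expect_lt(abs(mean(vals)), 2 * stats::sd(vals) / sqrt(length(vals)))
})
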