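test_that("coupling-mode bookkeeping follows the shape law", {
  mt <- mode_table()
  expect_equal(nrow(mt), 6 + choose(6, 2))
  expect_true(all(mt$band_from <= mt$band_to))
  cross <- mt[!mt$within, ]
  expect_true(all(cross$band_from < cross$band_to))   # slower band modulates
  expect_equal(cross$name[1], "delta-theta")
  expect_equal(cross$name[15], "beta-gamma")
  expect_equal(modulated_set("beta"), 6L)             # beta modulates only gamma
  expect_error(modulated_set("gamma"), "no modulated")
})

test_that("the lag scan localizes a planted 80 ms amplitude delay", {
  z <- make_pair_envelopes("delta", "delta", "amplitude", 80, 1.5, 90, 1)
  ls <- lag_scan(z$env_x, z$env_y, fix_fs, "dste", lag_grid = seq(-30, 30),
                 n_surr = 100, seed = 1, m = 3, tau = 1, k_grid = 12)
  expect_lte(abs(ls$best_lag_samples - z$delay_samples), 2)
  expect_lt(ls$p, 0.01)
  expect_true(is.finite(ls$z))
  # swapping the inputs flips the sign of the recovered lag
  ls_sw <- lag_scan(z$env_y, z$env_x, fix_fs, "dste", lag_grid = seq(-30, 30),
                    n_surr = 100, seed = 2, m = 3, tau = 1, k_grid = 12)
  expect_lte(abs(ls_sw$best_lag_samples + z$delay_samples), 2)
})

test_that("uncoupled pairs rarely reach lag significance", {
  ps <- vapply(1:8, function(sd) {
    z <- make_pair_envelopes("delta", "delta", "amplitude", 80, 0, 40, sd + 70)
    lag_scan(z$env_x, z$env_y, fix_fs, "dste", lag_grid = seq(-25, 25),
             n_surr = 100, seed = sd, m = 3, tau = 1, k_grid = 12)$p
  }, numeric(1))
  expect_gte(mean(ps >= 0.01), 7 / 8)
})

test_that("a degenerate (constant) pair cannot produce a lag estimate", {
  expect_error(lag_scan(rep(1, 200), rep(1, 200), fix_fs, "dste",
                        lag_grid = 0:3, k_grid = 2), "degenerate")
})

test_that("a planted mode mixture is recovered in the comodulogram", {
  modes <- mode_table()
  cfgA <- pipeline_config(n_surr = 400L, estimate_lags = FALSE,
                          env_decim = 4L, tau = 1L)
  # 70% beta-beta, 30% delta-theta over ten region pairs
  pm <- vapply(1:10, function(i) {
    mid <- if (i <= 7) 5L else 7L
    tm <- modes[mid, ]
    cp <- coupling_spec(1, 2, tm$band_from, tm$band_to, "amplitude",
                        delay_ms = band_delay_ms[tm$band_from], strength = 3)
    pr <- make_coupled_pair(256, 120, cp, noise_sd = 0.1, seed = 200 + i)
    be <- band_epoch(rbind(pr$x, pr$y), 256, epoch_length = 4)
    st <- pair_mode_statistics(be, 1, 2, "amplitude", cfgA, fs = 256, seed = i)
    docm_pool(st$z)$mode_id
  }, integer(1))
  cm <- comodulogram(array(pm))
  expect_lt(abs(cm["beta", "beta"] - 0.7), 0.1)
  expect_lt(abs(cm["delta", "theta"] - 0.3), 0.1)
})

test_that("dominant-mode assignment handles the three scenarios and ties", {
  p <- rep(1, 21); s <- stats::runif(21)
  # scenario C: no survivor
  expect_equal(docm_assign(p, s)$mode_id, 0L)
  expect_equal(docm_assign(p, s)$strength, 0)
  # scenario A: single survivor
  p1 <- p; p1[7] <- 1e-5
  expect_equal(docm_assign(p1, s, lags = 1:21)$mode_id, 7L)
  expect_equal(docm_assign(p1, s, lags = 1:21)$lag, 7)
  # scenario B: strongest of several survivors
  p2 <- p; p2[c(1, 7)] <- 1e-5; s2 <- s; s2[1] <- 0.2; s2[7] <- 0.9
  expect_equal(docm_assign(p2, s2)$mode_id, 7L)
  # strength ties break to the lowest mode id
  s3 <- s2; s3[1] <- 0.9
  expect_equal(docm_assign(p2, s3)$mode_id, 1L)
  expect_error(docm_assign(p[1:5], s[1:5], n_modes = 21), "21")
})

test_that("pooled pair-level detection is calibrated and powerful", {
  set.seed(15)
  # null z: no mode passes
  z0 <- matrix(stats::rnorm(21 * 20), 21)
  expect_equal(docm_pool(z0)$mode_id, 0L)
  # one strong mode
  z1 <- z0; z1[9, ] <- z1[9, ] + 1.5
  expect_equal(docm_pool(z1)$mode_id, 9L)
})

test_that("network FDR zeroes unsupported assignments and keeps shape", {
  E <- 3; R <- 5
  mode_id <- array(0L, c(E, R, R)); strength <- array(0, c(E, R, R))
  lag <- array(NA_real_, c(E, R, R)); p <- array(NA_real_, c(E, R, R))
  # all assigned pairs have p = 1 -> empty network
  mode_id[1, 1, 2] <- 3L; strength[1, 1, 2] <- 1; p[1, 1, 2] <- 1
  tz <- docm_network(mode_id, strength, lag, p)
  expect_equal(sum(tz$mode_id > 0), 0)
  expect_equal(dim(tz$strength), c(21, E, R, R))
  # a strongly supported edge survives
  p[1, 1, 2] <- 1e-9
  t2 <- docm_network(mode_id, strength, lag, p)
  expect_equal(t2$mode_id[3, 1, 1, 2], 3L)
  expect_equal(t2$strength[3, 1, 1, 2], 1)
})

test_that("one planted edge among nulls survives the epoch-wise FDR", {
  set.seed(16)
  fp_frac <- replicate(50, {
    E <- 2; R <- 6
    mode_id <- array(0L, c(E, R, R)); strength <- array(0, c(E, R, R))
    lag <- array(NA_real_, c(E, R, R)); p <- array(NA_real_, c(E, R, R))
    off <- which(row(diag(R)) != col(diag(R)), arr.ind = TRUE)
    for (e in 1:E) for (r in seq_len(nrow(off))) {
      mode_id[e, off[r, 1], off[r, 2]] <- sample(1:21, 1)
      strength[e, off[r, 1], off[r, 2]] <- stats::runif(1)
      p[e, off[r, 1], off[r, 2]] <- stats::runif(1)
    }
    p[1, 1, 2] <- 1e-10
    tz <- docm_network(mode_id, strength, lag, p, q = 0.01)
    stopifnot(tz$mode_id[mode_id[1, 1, 2], 1, 1, 2] > 0)
    (sum(tz$mode_id > 0) - 1) / (E * R * (R - 1) - 1)
  })
  expect_lte(mean(fp_frac), 0.011)
})

test_that("comodulograms are probability distributions over mode counts", {
  # every significant pair delta-delta
  ids <- matrix(0L, 4, 4); ids[1, 2] <- 1L; ids[3, 4] <- 1L
  cm <- comodulogram(ids)
  expect_equal(cm[1, 1], 1)
  expect_equal(sum(cm), 1)
  # arbitrary tensor: sums to one, entries times total count are integers
  set.seed(17)
  ids2 <- matrix(sample(0:21, 100, replace = TRUE), 10)
  cm2 <- comodulogram(ids2)
  expect_equal(sum(cm2), 1, tolerance = 1e-12)
  counts <- attr(cm2, "counts")
  expect_true(all(abs(as.numeric(cm2[cbind(mode_table()$band_from,
                                           mode_table()$band_to)]) *
                        sum(counts) - counts) < 1e-9))
  expect_error(comodulogram(matrix(0L, 3, 3)), "undefined")
})
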