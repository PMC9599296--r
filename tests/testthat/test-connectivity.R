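test_that("dSTE vanishes for constant sources and matches the chain-rule case", {
  set.seed(8)
  s_a <- sample(1:4, 300, replace = TRUE)
  pair_const <- list(s_a = s_a, s_b = rep(2L, 300), k = 4)
  expect_equal(dste(pair_const, d = 1), 0)

  # target copies the source with unit delay: dSTE equals the conditional
  # entropy H(A_{t+1} | A_t) of the target chain (binary symbols), computed
  # by brute-force enumeration
  src <- sample(1:2, 400, replace = TRUE)
  tgt <- c(1L, src[-400])            # A_{t+1} = B_t
  pair_copy <- list(s_a = tgt, s_b = src, k = 2)
  got <- dste(pair_copy, d = 1)
  # brute-force H(A_{t+1} | A_t) over the same triplet support
  t_idx <- seq_len(399)
  af <- tgt[t_idx + 1]; an <- tgt[t_idx]
  h <- 0
  for (a1 in 1:2) for (a0 in 1:2) {
    n2 <- sum(af == a1 & an == a0)
    if (n2 == 0) next
    h <- h - n2 / 399 * log2(n2 / sum(an == a0))
  }
  expect_equal(got, h, tolerance = 1e-12)
})

test_that("dSTE equals the brute-force triple-loop plug-in oracle", {
  set.seed(9)
  for (k in c(3, 5)) for (d in c(1, 3)) {
    s_a <- sample(seq_len(k), 300, replace = TRUE)
    s_b <- sample(seq_len(k), 300, replace = TRUE)
    pair <- list(s_a = s_a, s_b = s_b, k = k)
    expect_equal(dste(pair, d = d), te_bruteforce(s_a, s_b, d = d),
                 tolerance = 1e-12)
  }
})

test_that("independent long symbol sequences give near-zero dSTE", {
  set.seed(10)
  s_a <- sample(1:3, 1e4, replace = TRUE)
  s_b <- sample(1:3, 1e4, replace = TRUE)
  obs <- dste(list(s_a = s_a, s_b = s_b, k = 3), d = 1)
  # shuffled-source reference distribution bounds the plug-in bias
  ref <- vapply(1:20, function(i) dste(list(s_a = s_a, s_b = sample(s_b), k = 3)),
                numeric(1))
  expect_lt(obs, mean(ref) + 4 * stats::sd(ref))
  expect_lt(obs, 0.01)
})

test_that("direction index normalization and antisymmetry", {
  expect_equal(direction_index(0.3, 0), 1)
  expect_equal(direction_index(0.2, 0.2), 0)
  expect_equal(direction_index(0.3, 0.1), 0.5)
  for (i in 1:10) {
    f <- stats::runif(2)
    expect_equal(direction_index(f[1], f[2]), -direction_index(f[2], f[1]))
    expect_lte(abs(direction_index(f[1], f[2])), 1)
  }
  expect_error(direction_index(0, 0), "zero")
  expect_error(direction_index(-1, 2), "nonnegative")
})

test_that("phase TE detects delayed phase copies and respects the bin rule", {
  # bin rule at Ns = 1000, delta = 1: round(exp(0.626 + 0.4 log 998)) = 30
  expect_equal(pte_bins(1000, 1), 30L)
  expect_error(pte_bins(3, 2), "few")

  set.seed(11)
  base <- docmflow:::instantaneous_phase(docmflow:::bandpass(stats::rnorm(3000),
                                                             8, 10, fix_fs))
  lagged <- docmflow:::lag_series(base, 5)  # lagged copies base 5 samples later
  expect_gt(pte(base, lagged, delta = 5), pte(lagged, base, delta = 5))

  # independence: observed within the shuffled-source bias envelope
  other <- docmflow:::instantaneous_phase(docmflow:::bandpass(stats::rnorm(3000),
                                                              8, 10, fix_fs))
  obs <- pte(base, other, delta = 5)
  ref <- vapply(1:20, function(i) {
    sh <- sample.int(2998, 1)
    pte(c(base[(sh + 1):3000], base[1:sh]), other, delta = 5)
  }, numeric(1))
  expect_lt(abs(obs - mean(ref)), 5 * stats::sd(ref))
})

test_that("dPTE normalization identities", {
  expect_equal(dpte(0.2, 0.2), 0.5)
  expect_equal(dpte(0.7, 0), 1)
  expect_equal(dpte(0.2, 0.1), 2 / 3, tolerance = 1e-12)
  expect_error(dpte(0, 0), "undefined")
})

test_that("surrogate p-values follow the smoothed convention at the extremes", {
  set.seed(12)
  # strong coupling: observed above every surrogate -> p = 1/(1+N)
  src <- sample(1:3, 500, replace = TRUE)
  tgt <- c(1L, src[-500])
  pair <- list(s_a = tgt, s_b = src, k = 3)
  r <- surrogate_p_dste(pair, d = 1, n_surr = 100, seed = 1)
  expect_equal(r$p, 1 / 101)
  # proportion convention can reach zero
  r0 <- surrogate_p_dste(pair, d = 1, n_surr = 100, seed = 1,
                         convention = "proportion")
  expect_equal(r0$p, 0)
  # a constant source can never beat its surrogates: p ~ 1
  pc <- list(s_a = sample(1:3, 500, replace = TRUE), s_b = rep(1L, 500), k = 3)
  expect_gt(surrogate_p_dste(pc, n_surr = 100, seed = 2)$p, 0.5)
  expect_error(surrogate_p_dste(pair, n_surr = 10), "n_surr")
})

test_that("epoch-shuffle admissible pairings and small-epoch behaviour", {
  # 3 epochs -> 3^2 - 3 = 6 mismatched pairings, all used
  expect_equal(nrow(docmflow:::mismatched_pairings(3)), 6)
  set.seed(13)
  px <- matrix(stats::rnorm(3 * 256), 3)
  py <- matrix(stats::rnorm(3 * 256), 3)
  r <- surrogate_p_dpte(px, py, n_surr = 6, seed = 1)
  expect_length(r$surrogates, 6)
  expect_length(r$p_epoch, 3)
  expect_error(surrogate_p_dpte(px[1, , drop = FALSE], py[1, , drop = FALSE]),
               "two epochs")
})

test_that("planted phase coupling is detected by the epoch-shuffle test", {
  ps <- vapply(1:5, function(sd) {
    z <- make_phase_epochs("alpha1", "alpha1", strength = 3, delay_ms = 28,
                           duration = 80, seed = sd + 700)
    surrogate_p_dpte(z$px, z$py, delta = 14, n_surr = 3000, seed = sd)$p
  }, numeric(1))
  expect_gte(mean(ps < 0.01), 0.8)
})

test_that("BH filtering matches the hand-ordered reference", {
  set.seed(14)
  # one tiny p-value among uniform noise survives alone at q = 0.01
  p <- matrix(0.5 + stats::runif(100, 0, 0.4), 10, 10)
  p[2, 7] <- 1e-6
  diag(p) <- NA
  mask <- fdr_filter(p, q = 0.01)
  expect_true(mask[2, 7])
  expect_equal(sum(mask), 1)

  # all p = 1: nothing survives
  expect_equal(sum(fdr_filter(matrix(1, 5, 5), 0.01)), 0)

  # random matrices agree with the explicit BH ordering rule
  for (i in 1:5) {
    pm <- matrix(stats::runif(64)^2, 8, 8)
    off <- row(pm) != col(pm)
    expect_equal(fdr_filter(pm, 0.05)[off], bh_reference(pm[off], 0.05))
  }

  # uniform null: expected false-positive fraction at most q
  fp <- vapply(1:200, function(i) {
    pm <- matrix(stats::runif(100), 10, 10)
    mean(fdr_filter(pm, 0.01)[row(pm) != col(pm)])
  }, numeric(1))
  expect_lte(mean(fp), 0.01)
})
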