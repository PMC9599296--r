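part <- list(posterior = 1:4, anterior = 5:8)

test_that("posterior-anterior index arithmetic and error contracts", {
  v <- c(rep(0.2, 4), rep(0.2, 4))
  expect_equal(pai(v, part), 0)
  expect_equal(pai(c(rep(0.2, 4), rep(0.1, 4)), part), 50)
  # matrix input: rows averaged off-diagonal first
  M <- matrix(0.1, 8, 8); M[1:4, ] <- 0.2; diag(M) <- 99
  expect_equal(pai(M, part), 50)
  expect_error(pai(c(rep(0, 4), rep(0.1, 4)), part), "undefined")
  expect_error(pai(v, list(posterior = 1:4, anterior = 4:8)), "disjoint")
  # swapping the sets negates the numerator (denominator changes)
  a <- c(0.3, 0.25, 0.2, 0.35, 0.1, 0.12, 0.08, 0.11)
  swapped <- list(posterior = part$anterior, anterior = part$posterior)
  mp <- mean(a[1:4]); ma <- mean(a[5:8])
  expect_equal(pai(a, part) * mp / 100, -(pai(a, swapped) * ma / 100),
               tolerance = 1e-12)
})

test_that("PAI randomization test separates gradients from exchangeable means", {
  set.seed(18)
  flat <- stats::rnorm(8, 0.2, 0.001)
  expect_gt(pai_significance(flat, part, n_perm = 500, seed = 1)$p, 0.2)
  grad <- c(stats::rnorm(4, 0.5, 0.01), stats::rnorm(4, 0.05, 0.01))
  expect_lt(pai_significance(grad, part, n_perm = 500, seed = 1)$p, 0.01)
  # numerator permutation distribution is symmetric about zero under
  # exchangeability: full enumeration over a 6-region partition
  v6 <- c(0.1, 0.3, 0.2, 0.15, 0.25, 0.05)
  combs <- utils::combn(6, 3)
  diffs <- apply(combs, 2, function(ix) mean(v6[ix]) - mean(v6[-ix]))
  expect_equal(mean(diffs), 0, tolerance = 1e-12)
  expect_equal(sort(diffs), sort(-diffs), tolerance = 1e-12)
})

test_that("age-group delay aggregation follows the modulator convention", {
  mt <- mode_table()
  # single subject with a single delta-delta lag of 80 ms everywhere
  lags <- matrix(NA_real_, 2, 21)
  lags[, 1] <- 80
  tab <- agegroup_delays(lags, ages = c(20, 25), groups = c(18, 27),
                         mode_scope = "within")
  expect_equal(unname(tab[1, "delta"]), 80)
  # beta modulates only gamma: the beta column equals the beta-gamma lag
  lags2 <- matrix(stats::runif(21 * 4, 10, 90), 4, 21)
  bg <- mt$mode_id[mt$name == "beta-gamma"]
  g2 <- c(18, 40, 60)
  ages2 <- rep(c(20, 55), 2)
  tab2 <- agegroup_delays(lags2, ages = ages2, groups = g2, mode_scope = "cross")
  expect_equal(unname(tab2[, "beta"]),
               as.numeric(tapply(lags2[, bg],
                                 cut(ages2, g2, include.lowest = TRUE), mean)))
  # planted lags decreasing with band frequency are recovered in order
  lags3 <- matrix(rep(c(80, 45, 28, 24, 18, 15, rep(NA, 15)), each = 4), 4)
  tab3 <- agegroup_delays(lags3, ages = c(20, 30, 45, 55))
  expect_true(all(diff(colMeans(tab3, na.rm = TRUE)) < 0))
  expect_error(agegroup_delays(lags3, ages = c(20, 30, 45, 99)), "outside")
})

test_that("group comparisons use rank sums with Bonferroni control", {
  set.seed(19)
  same <- replicate(4, stats::rnorm(10, 50, 5), simplify = FALSE)
  r <- compare_groups(same)
  expect_equal(nrow(r), 6)              # 4 groups -> 6 pairwise comparisons
  expect_false(any(r$significant))
  shifted <- same
  shifted[[4]] <- shifted[[4]] + 25     # 5 SD shift
  r2 <- compare_groups(shifted)
  expect_true(all(r2$significant[r2$group1 == "4" | r2$group2 == "4"]))
  expect_equal(attr(r2, "threshold"), 0.01 / 6)
  expect_warning(compare_groups(list(a = rep(1, 5), b = stats::rnorm(5))),
                 "degenerate")
  expect_error(compare_groups(list(a = 1:5)), "groups")
})

test_that("frequency-dependent brain age index ratios", {
  pd <- matrix(0, 6, 6)
  pd[1, 1] <- 0.10
  pd[1, 2:6] <- 0.05
  pd[2, 2] <- 0.65
  pd <- pd / sum(pd)
  expect_equal(fbai(pd, "delta"), 2, tolerance = 1e-12)
  expect_equal(fbai(pd, "delta", invert = TRUE), 0.5, tolerance = 1e-12)
  # equal within and mean-cross probabilities give 1
  pd2 <- matrix(1 / 36, 6, 6)
  expect_equal(fbai(pd2, "theta"), 1)
  # scale invariance before renormalization
  expect_equal(fbai(pd * 3, "delta"), fbai(pd, "delta"))
  expect_error(fbai(pd, "gamma"), "modulator")
  pd3 <- pd; pd3[3, 4:6] <- 0
  expect_error(fbai(pd3, "alpha1"), "zero")
})

test_that("two-segment fits recover exact Gaussian curves", {
  x <- seq(18, 60, by = 1)
  a <- 1.45; s1 <- 15.8; xo <- 28.5
  y <- a * exp(-(x - xo)^2 / (2 * s1^2))
  f <- fit_bai_curve(x, y)
  cf <- coef(f)
  expect_equal(unname(cf["below", ]), c(a, s1, xo), tolerance = 1e-6)
  expect_equal(unname(cf["above", ]), c(a, s1, xo), tolerance = 1e-6)
  # peak identity: predict at xo equals a
  expect_equal(unname(predict(f, xo)), a, tolerance = 1e-6)
  expect_equal(length(residuals(f)), length(x))
  expect_lt(max(abs(residuals(f))), 1e-8)
  expect_output(print(f), "Gaussian")
  expect_error(fit_bai_curve(x[1:10], y[1:10]), "4 points")
})
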