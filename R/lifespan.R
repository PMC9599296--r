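#' Posterior-anterior index
#'
#' Percentage contrast between the average direction index over the posterior
#' region set and over the anterior set:
#' `100 * (mean_posterior - mean_anterior) / mean_posterior`. Positive values
#' indicate preferential posterior-to-anterior information flow.
#'
#' @param roi_values Per-region average direction values (e.g. each region's
#'   mean outgoing direction index), or a square direction matrix whose rows
#'   are averaged (off-diagonal) to per-region values first.
#' @param partition List with disjoint integer index sets `posterior` and
#'   `anterior`.
#' @param normalize If `TRUE`, per-region values are divided by the maximum
#'   absolute observed value before the contrast (off by default).
#' @param tol Posterior means smaller than this in magnitude make the index
#'   undefined.
#' @return PAI in percent.
#' @export
pai <- function(roi_values, partition, normalize = FALSE, tol = 1e-12) {
  v <- roi_direction_values(roi_values)
  check_partition(partition, length(v))
  if (normalize) v <- v / max(abs(v))
  mp <- mean(v[partition$posterior])
  ma <- mean(v[partition$anterior])
  if (abs(mp) < tol) stop("PAI undefined: posterior mean is (near) zero")
  100 * (mp - ma) / mp
}

roi_direction_values <- function(x) {
  if (is.matrix(x)) {
    diag(x) <- NA
    rowMeans(x, na.rm = TRUE)
  } else as.numeric(x)
}

check_partition <- function(partition, n_roi) {
  p <- partition$posterior; a <- partition$anterior
  if (!length(p) || !length(a)) stop("both region sets must be non-empty")
  if (length(intersect(p, a))) stop("posterior and anterior sets must be disjoint")
  if (any(c(p, a) < 1 | c(p, a) > n_roi)) stop("region index out of range")
  invisible(TRUE)
}

#' Randomization significance of the posterior-anterior index
#'
#' Permutes the per-region average values across regions, recomputes the PAI
#' for each permutation, and returns the one-sided permutation p-value of the
#' observed index in the direction of its sign (the ratio-normalized index
#' has heavy two-sided tails under permutation because the posterior-mean
#' denominator can come arbitrarily close to zero).
#'
#' @inheritParams pai
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `p`, `observed` and the permutation `surrogates`.
#' @export
pai_significance <- function(roi_values, partition, n_perm = 1000, seed = 1,
                             normalize = FALSE) {
  v <- roi_direction_values(roi_values)
  check_partition(partition, length(v))
  if (length(partition$posterior) < 2 || length(partition$anterior) < 2)
    stop("need at least two regions per set")
  obs <- pai(v, partition, normalize = normalize)
  set.seed(seed)
  surr <- vapply(seq_len(n_perm), function(r)
    tryCatch(pai(sample(v), partition, normalize = normalize),
             error = function(e) NA_real_), numeric(1))
  surr <- surr[is.finite(surr)]
  p <- if (obs >= 0) (1 + sum(surr >= obs)) / (1 + length(surr))
       else (1 + sum(surr <= obs)) / (1 + length(surr))
  list(p = p, observed = obs, surrogates = surr)
}

#' Default age-group edges
#'
#' Age groups 18-27, 28-40, 41-50 and 51-60 years.
#' @return Numeric vector of interval edges for [cut()].
#' @export
default_age_groups <- function() c(18, 27, 40, 50, 60)

#' Per-subject mean lags per coupling mode
#'
#' Averages the time lags of a subject's dominant-coupling-mode tensor first
#' across epochs, then across region pairs, yielding one lag per mode.
#'
#' @param tensor A `docm_tensor`.
#' @return Numeric vector of length `n_modes` (NA for modes never assigned).
#' @export
subject_mode_lags <- function(tensor) {
  vapply(seq_len(tensor$n_modes), function(m) {
    lg <- tensor$lag[m, , , , drop = FALSE]
    if (all(is.na(lg))) return(NA_real_)
    # epochs first, then pairs
    per_pair <- apply(lg[1, , , , drop = TRUE], c(2, 3), function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    mean(per_pair, na.rm = TRUE)
  }, numeric(1))
}

#' Age-group aggregation of time delays
#'
#' Aggregates per-subject, per-mode mean time delays into an age-group by
#' band table. For `mode_scope = "within"` the six within-band lags are used
#' directly; for `"cross"` each modulating band's lag is the average over its
#' modulated set (e.g. the delta row averages delta-theta ... delta-gamma;
#' beta modulates only gamma).
#'
#' @param subject_lags Subjects x modes matrix of mean lags (columns ordered
#'   as [mode_table()]).
#' @param ages Per-subject ages (years).
#' @param groups Age-group edges (default [default_age_groups()]).
#' @param mode_scope `"within"` or `"cross"`.
#' @param bands Band definition data frame.
#' @return Matrix groups x bands of group-mean lags (cross scope: modulating
#'   bands only).
#' @export
agegroup_delays <- function(subject_lags, ages, groups = default_age_groups(),
                            mode_scope = c("within", "cross"),
                            bands = default_bands()) {
  mode_scope <- match.arg(mode_scope)
  subject_lags <- as.matrix(subject_lags)
  modes <- mode_table(bands)
  nb <- nrow(bands)
  grp <- cut(ages, groups, include.lowest = TRUE)
  if (any(is.na(grp))) stop("ages outside the group edges")
  if (any(table(grp) == 0)) stop("empty age group")
  if (mode_scope == "within") {
    per_subj <- subject_lags[, seq_len(nb), drop = FALSE]
    colnames(per_subj) <- bands$name
  } else {
    mod_bands <- seq_len(nb - 1L)
    per_subj <- sapply(mod_bands, function(k) {
      cols <- modes$mode_id[!modes$within & modes$band_from == k]
      rowMeans(subject_lags[, cols, drop = FALSE], na.rm = TRUE)
    })
    per_subj <- matrix(per_subj, nrow = nrow(subject_lags))
    colnames(per_subj) <- bands$name[mod_bands]
  }
  out <- apply(per_subj, 2, function(v) tapply(v, grp, mean, na.rm = TRUE))
  matrix(out, nrow = nlevels(grp), dimnames = list(levels(grp), colnames(per_subj)))
}

#' Pairwise rank-sum comparisons between age groups
#'
#' Wilcoxon rank sum tests between every pair of groups with a Bonferroni
#' threshold `alpha / n_comparisons`.
#'
#' @param values_by_group Named list of numeric vectors (>= 2 groups with
#'   >= 2 values each).
#' @param alpha Uncorrected level (default 0.01).
#' @param n_comparisons Bonferroni divisor (default: number of group pairs).
#' @return Data frame with columns `group1`, `group2`, `p`, `significant`
#'   (after Bonferroni), plus attributes `alpha` and `threshold`.
#' @export
compare_groups <- function(values_by_group, alpha = 0.01,
                           n_comparisons = choose(length(values_by_group), 2)) {
  g <- length(values_by_group)
  if (g < 2 || any(lengths(values_by_group) < 2))
    stop("need >= 2 groups with >= 2 subjects each")
  for (v in values_by_group)
    if (stats::sd(v, na.rm = TRUE) == 0)
      warning("degenerate (constant) group sample")
  prs <- utils::combn(g, 2)
  nm <- names(values_by_group) %||% as.character(seq_len(g))
  res <- data.frame(
    group1 = nm[prs[1, ]], group2 = nm[prs[2, ]],
    p = apply(prs, 2, function(ij)
      suppressWarnings(stats::wilcox.test(values_by_group[[ij[1]]],
                                          values_by_group[[ij[2]]])$p.value))
  )
  res$significant <- res$p < alpha / n_comparisons
  attr(res, "alpha") <- alpha
  attr(res, "threshold") <- alpha / n_comparisons
  res
}

#' Frequency-dependent brain age index
#'
#' For a modulating band k, the ratio of the within-band dominant-coupling
#' probability `PD(k, k)` to the mean cross-band probability over k's
#' modulated set. With `invert = TRUE` the reciprocal is returned (the
#' cross-over-within orientation).
#'
#' @param pd A `comodulogram` (6 x 6 probability matrix, rows modulate
#'   columns).
#' @param k Modulating band (name or index; gamma is excluded).
#' @param invert Return the reciprocal ratio.
#' @param bands Band definition data frame.
#' @return Dimensionless index.
#' @export
fbai <- function(pd, k, invert = FALSE, bands = default_bands()) {
  i <- band_index(k, bands)
  if (i >= nrow(bands)) stop("the highest band is not a modulator")
  cross <- mean(pd[i, modulated_set(i, bands)])
  within <- pd[i, i]
  num <- if (invert) cross else within
  den <- if (invert) within else cross
  if (den == 0) stop("fBAI undefined: zero denominator")
  num / den
}
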