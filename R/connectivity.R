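# Plug-in transfer entropy over integer-coded sequences.
# Triplets are (target_{t+delta}, target_t, source_{t+delta-d}); probabilities
# are relative frequencies of observed triplets; log base is `base`.
te_plugin <- function(target, source, k_t, k_s, d = 1, delta = 1, base = 2) {
  n <- length(target)
  if (length(source) != n) stop("sequences must be aligned")
  if (abs(d) >= n / 2) stop("delay must be below half the sequence length")
  t0 <- max(1L, 1L + as.integer(d) - as.integer(delta))
  t_hi <- n - delta + min(0L, as.integer(d))
  t_idx <- seq.int(t0, t_hi)
  if (t0 > t_hi) stop("sequences too short for (d, delta)")
  a_fut <- target[t_idx + delta]
  a_now <- target[t_idx]
  b_del <- source[t_idx + delta - d]
  # joint and marginal counts via mixed-radix codes over the data
  code3 <- (a_fut - 1) + k_t * (a_now - 1) + k_t * k_t * (b_del - 1)
  n3 <- tabulate(code3 + 1L, k_t * k_t * k_s)
  n_ab <- tabulate((a_now - 1) + k_t * (b_del - 1) + 1L, k_t * k_s)
  n2 <- tabulate((a_fut - 1) + k_t * (a_now - 1) + 1L, k_t * k_t)
  n1 <- tabulate(a_now, k_t)
  keep <- which(n3 > 0)
  af <- (keep - 1) %% k_t
  an <- ((keep - 1) %/% k_t) %% k_t
  bd <- (keep - 1) %/% (k_t * k_t)
  N <- length(t_idx)
  p3 <- n3[keep] / N
  sum(p3 * (log(n3[keep] / n_ab[an + k_t * bd + 1L]) -
              log(n2[af + k_t * an + 1L] / n1[an + 1L])) / log(base))
}

#' Delay symbolic transfer entropy
#'
#' Transfer entropy from the source to the target symbol sequence with an
#' explicit source-target delay `d` (samples): the gain in predicting the
#' target's next symbol from the source's symbol `d` steps back, beyond the
#' target's own past. Estimated by plug-in probabilities over observed symbol
#' triplets, log base 2 (bits). Zero when the source adds nothing (e.g. a
#' constant source).
#'
#' @param pair A `symbolic_pair` from [symbolize()], or a list with integer
#'   sequences `s_a`, `s_b` and alphabet size `k`.
#' @param d Delay in samples between driver and driven system.
#' @param delta Prediction step (default 1 sample).
#' @param direction `"ba"` for source B driving target A (default, the
#'   B -> A flow), `"ab"` for the reverse.
#' @return Transfer entropy in bits (>= 0 up to plug-in bias).
#' @export
dste <- function(pair, d = 1, delta = 1, direction = c("ba", "ab")) {
  direction <- match.arg(direction)
  k <- pair$k %||% max(pair$s_a, pair$s_b)
  if (direction == "ba")
    te_plugin(pair$s_a, pair$s_b, k, k, d = d, delta = delta, base = 2)
  else
    te_plugin(pair$s_b, pair$s_a, k, k, d = d, delta = delta, base = 2)
}

#' Normalized direction index
#'
#' Common normalization of directed coupling estimates:
#' `(f_ij - f_ji) / (f_ij + f_ji)`, in [-1, 1]; +1 for exclusive i -> j flow,
#' 0 for balanced flow.
#'
#' @param f_ij,f_ji Nonnegative directed estimates (not both zero).
#' @return The direction index.
#' @export
direction_index <- function(f_ij, f_ji) {
  if (any(c(f_ij, f_ji) < 0)) stop("inputs must be nonnegative")
  if (f_ij + f_ji == 0) stop("direction undefined: both estimates are zero")
  (f_ij - f_ji) / (f_ij + f_ji)
}

#' Histogram bin count for phase transfer entropy
#'
#' `round(exp(0.626 + 0.4 * log(Ns - delta - 1)))` bins for `Ns` phase samples
#' and prediction step `delta`.
#'
#' @param n_samples Number of phase samples.
#' @param delta Prediction step (samples).
#' @return Integer bin count.
#' @export
pte_bins <- function(n_samples, delta = 1) {
  if (n_samples - delta - 1 < 1) stop("too few samples for the bin rule")
  as.integer(round(exp(0.626 + 0.4 * log(n_samples - delta - 1))))
}

#' Phase transfer entropy
#'
#' Transfer entropy between two instantaneous-phase series, estimated from
#' histograms of single, paired and triplet phase occurrences with the bin
#' count of [pte_bins()]. Dimensionless (natural log).
#'
#' @param phase_x Source phase series (radians).
#' @param phase_y Target phase series (radians), same length.
#' @param delta Prediction step in samples (default 1).
#' @param bins Optional bin-count override.
#' @param d Source delay in samples (defaults to `delta`; used by the
#'   time-lag scan).
#' @return PTE from x to y.
#' @export
pte <- function(phase_x, phase_y, delta = 1, bins = NULL, d = delta) {
  n <- length(phase_x)
  if (length(phase_y) != n) stop("phase series must have equal length")
  if (delta >= n) stop("delta must be below the series length")
  B <- bins %||% pte_bins(n, delta)
  bx <- pmin(pmax(ceiling((phase_x + pi) / (2 * pi) * B), 1L), B)
  by <- pmin(pmax(ceiling((phase_y + pi) / (2 * pi) * B), 1L), B)
  te_plugin(by, bx, B, B, d = d, delta = delta, base = exp(1))
}

#' Directed phase-transfer-entropy normalization
#'
#' `pte_xy / (pte_xy + pte_yx)`, in [0, 1]: 0.5 means no preferred direction,
#' values above 0.5 mean preferential x -> y flow.
#'
#' @param pte_xy,pte_yx Nonnegative PTE values (not both zero).
#' @return The normalized value.
#' @export
dpte <- function(pte_xy, pte_yx) {
  if (any(c(pte_xy, pte_yx) < 0)) stop("inputs must be nonnegative")
  if (pte_xy + pte_yx == 0) stop("dPTE undefined: both PTE values are zero")
  pte_xy / (pte_xy + pte_yx)
}

surrogate_p <- function(observed, surrogates, convention = c("smoothed", "proportion")) {
  convention <- match.arg(convention)
  c_ge <- sum(surrogates >= observed)
  if (convention == "smoothed") (1 + c_ge) / (1 + length(surrogates))
  else c_ge / length(surrogates)
}

#' Surrogate significance of dSTE
#'
#' Builds the null distribution by randomizing the source symbol sequence and
#' recomputing dSTE; one-sided p-value for the observed value. The default
#' randomization (`method = "shift"`) rotates the source by a random circular
#' time shift, which breaks the source-target alignment while preserving the
#' source's own temporal structure and is calibrated for autocorrelated
#' symbol sequences; `method = "permute"` shuffles the source elements
#' (destroying its autocorrelation, anti-conservative on smooth envelopes).
#'
#' @param pair A `symbolic_pair`.
#' @param d,delta Delay and prediction step, as in [dste()].
#' @param n_surr Number of surrogates (>= 100).
#' @param seed Integer seed (deterministic results).
#' @param direction Flow direction tested, as in [dste()].
#' @param method Source randomization: `"shift"` (default) or `"permute"`.
#' @param convention `"smoothed"` for p = (1 + c)/(1 + N) (default, never
#'   exactly zero) or `"proportion"` for the plain exceedance proportion c/N.
#' @return List with `p`, `observed` and the `surrogates` vector.
#' @export
surrogate_p_dste <- function(pair, d = 1, delta = 1, n_surr = 1000, seed = 1,
                             direction = "ba", method = c("shift", "permute"),
                             convention = c("smoothed", "proportion")) {
  convention <- match.arg(convention)
  method <- match.arg(method)
  if (n_surr < 100) stop("n_surr must be >= 100")
  obs <- dste(pair, d = d, delta = delta, direction = direction)
  src <- if (direction == "ba") pair$s_b else pair$s_a
  tgt <- if (direction == "ba") pair$s_a else pair$s_b
  k <- pair$k %||% max(pair$s_a, pair$s_b)
  n <- length(src)
  set.seed(seed)
  surr <- vapply(seq_len(n_surr), function(i) {
    src_r <- if (method == "permute") sample(src) else {
      sh <- sample.int(n - 2, 1)
      c(src[(sh + 1):n], src[1:sh])
    }
    te_plugin(tgt, src_r, k, k, d = d, delta = delta, base = 2)
  }, numeric(1))
  list(p = surrogate_p(obs, surr, convention), observed = obs, surrogates = surr)
}

mismatched_pairings <- function(n_ep) {
  g <- expand.grid(i = seq_len(n_ep), j = seq_len(n_ep))
  g[g$i != g$j, , drop = FALSE]
}

#' Epoch-shuffle significance of dPTE
#'
#' Null distribution for the directed phase flow of a region pair from
#' mismatched-epoch pairings: dPTE computed between epoch i of the source and
#' epoch j != i of the target. With `E` epochs there are `E^2 - E` admissible
#' pairings; up to `n_surr` are sampled without replacement (all are used if
#' fewer exist). Observed values are the matched-epoch dPTEs, each compared
#' one-sidedly against the shared surrogate distribution.
#'
#' @param phase_x,phase_y Epochs x samples phase matrices for the two regions
#'   (>= 2 epochs).
#' @param delta Prediction step in samples.
#' @param n_surr Target number of surrogates (default 1000). Mismatched
#'   pairings are sampled with replacement when more than `E^2 - E` are
#'   requested, otherwise without.
#' @param seed Integer seed.
#' @param convention p-value convention, see [surrogate_p_dste()].
#' @return List with `p` (epoch-mean observed dPTE against means of
#'   epoch-sized surrogate groups, so the null matches the averaging of the
#'   observed statistic), `p_epoch` (per-epoch dPTE against the raw surrogate
#'   values), `observed`, `observed_epoch`, `surrogates`.
#' @export
surrogate_p_dpte <- function(phase_x, phase_y, delta = 1, n_surr = 1000,
                             seed = 1, convention = c("smoothed", "proportion")) {
  convention <- match.arg(convention)
  phase_x <- as.matrix(phase_x); phase_y <- as.matrix(phase_y)
  n_ep <- nrow(phase_x)
  if (n_ep < 2) stop("need at least two epochs")
  obs_e <- vapply(seq_len(n_ep), function(e)
    dpte(pte(phase_x[e, ], phase_y[e, ], delta),
         pte(phase_y[e, ], phase_x[e, ], delta)), numeric(1))
  pairs <- mismatched_pairings(n_ep)
  set.seed(seed)
  if (nrow(pairs) > n_surr) {
    pairs <- pairs[sample.int(nrow(pairs), n_surr), ]
  } else if (n_surr > nrow(pairs)) {
    pairs <- pairs[sample.int(nrow(pairs), n_surr, replace = TRUE), ]
  }
  surr <- vapply(seq_len(nrow(pairs)), function(r) {
    xs <- phase_x[pairs$i[r], ]; ys <- phase_y[pairs$j[r], ]
    dpte(pte(xs, ys, delta), pte(ys, xs, delta))
  }, numeric(1))
  n_grp <- floor(length(surr) / n_ep)
  grp_means <- if (n_grp >= 2)
    colMeans(matrix(surr[seq_len(n_grp * n_ep)], n_ep, n_grp)) else surr
  list(p = surrogate_p(mean(obs_e), grp_means, convention),
       p_epoch = vapply(obs_e, surrogate_p, numeric(1),
                        surrogates = surr, convention = convention),
       observed = mean(obs_e), observed_epoch = obs_e, surrogates = surr)
}

#' Benjamini-Hochberg survivor mask for a p-value matrix
#'
#' Applies BH false-discovery-rate control at level `q` over all off-diagonal
#' entries of a square p-value matrix.
#'
#' @param p_matrix Square matrix of p-values in [0, 1] (diagonal ignored).
#' @param q FDR level (default 0.01).
#' @return Logical matrix of survivors (diagonal `FALSE`).
#' @export
fdr_filter <- function(p_matrix, q = 0.01) {
  p_matrix <- as.matrix(p_matrix)
  if (nrow(p_matrix) != ncol(p_matrix)) stop("p_matrix must be square")
  off <- row(p_matrix) != col(p_matrix)
  pv <- p_matrix[off]
  if (any(pv < 0 | pv > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  mask <- matrix(FALSE, nrow(p_matrix), ncol(p_matrix))
  adj <- stats::p.adjust(pv, method = "BH")
  mask[off] <- !is.na(adj) & adj <= q
  mask
}
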