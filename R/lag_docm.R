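# Plug-in mutual information (bits) between integer sequences at a relative
# lag L >= 0: pairs (x_t, y_{t+L}); L < 0 pairs (x_{t-L}, y_t).
symbol_mi <- function(x, y, k, L) {
  n <- length(x)
  if (abs(L) >= n - 2) stop("lag too large for the series")
  if (L >= 0) { xs <- x[seq_len(n - L)]; ys <- y[seq_len(n - L) + L] }
  else { xs <- x[seq_len(n + L) - L]; ys <- y[seq_len(n + L)] }
  N <- length(xs)
  n2 <- tabulate((xs - 1) + k * (ys - 1) + 1L, k * k)
  nx <- tabulate(xs, k); ny <- tabulate(ys, k)
  keep <- which(n2 > 0)
  xi <- (keep - 1) %% k; yi <- (keep - 1) %/% k
  sum(n2[keep] / N * log2(n2[keep] * N / (nx[xi + 1] * ny[yi + 1])))
}

#' Time-lag scan for a pair of series
#'
#' Locates the coupling delay by maximising the delayed mutual information
#' between the two symbol sequences (amplitude domain: Neural-Gas symbols of
#' the envelopes; phase domain: histogram-binned phases) over a grid of
#' signed lags spanning up to half an epoch in each direction. Mutual
#' information is symmetric in time, so its peak sits at the centre of the
#' lagged dependence even when zero-phase filtering smears it; the directed
#' transfer-entropy estimators evaluated at the best lag supply the direction
#' index. Positive best lags mean a drives b; negative mean b drives a at
#' `|lag|`. The profile maximum is z-scored against the profile mean and
#' standard deviation, and a surrogate p-value is attached in which each
#' surrogate (random circular time shift of the source) is scanned over a
#' strided version of the same lag grid and its maximum retained
#' (max-statistics, so the selection step is part of the null).
#'
#' @param a,b Input series: amplitude envelopes for `"dste"`, instantaneous
#'   phases for `"dpte"`.
#' @param fs Sampling rate (Hz).
#' @param estimator `"dste"` or `"dpte"`.
#' @param lag_grid Integer delays in samples (default: every sample in
#'   +/- `max_lag`).
#' @param max_lag Half-width of the default grid in samples.
#' @param n_surr Surrogates for the best-lag p-value.
#' @param seed Integer seed.
#' @param m,tau,k_grid Embedding and codebook settings (dSTE only).
#' @param convention Surrogate p-value convention, see [surrogate_p_dste()].
#' @return List with `best_lag` (ms; sign gives direction), `best_lag_samples`,
#'   `best_value` (mutual information at the best lag, bits),
#'   `best_value_norm` (bounded direction index of the directed estimator at
#'   the best lag, signed by direction), `z`, `p`, and the full `profile`
#'   over `lags`.
#' @export
lag_scan <- function(a, b, fs, estimator = c("dste", "dpte"),
                     lag_grid = NULL, max_lag = round(length(a) / 4),
                     n_surr = 200, seed = 1, m = 3, tau = 1, k_grid = 2:20,
                     convention = "smoothed") {
  estimator <- match.arg(estimator)
  lags <- lag_grid %||% seq.int(-max_lag, max_lag)
  if (estimator == "dste") {
    sp <- symbolize_pair(a, b, m = m, tau = tau, k_grid = k_grid,
                         seed = seed, on_fail = "best")
    src <- sp$s_a; tgt <- sp$s_b; k <- sp$k
  } else {
    k <- pte_bins(length(a), 1)
    src <- pmin(pmax(ceiling((a + pi) / (2 * pi) * k), 1L), k)
    tgt <- pmin(pmax(ceiling((b + pi) / (2 * pi) * k), 1L), k)
  }
  profile <- vapply(lags, function(L) symbol_mi(src, tgt, k, L), numeric(1))
  s <- stats::sd(profile)
  if (!is.finite(s) || s == 0) stop("constant lag profile: z undefined, lag rejected")
  i_best <- which.max(profile)
  z <- (profile[i_best] - mean(profile)) / s
  L <- lags[i_best]
  surr_lags <- lags[unique(round(seq(1, length(lags),
                                     length.out = min(length(lags), 16))))]
  set.seed(child_seed(seed, 1))
  surr <- vapply(seq_len(n_surr), function(r) {
    n <- length(src); sh <- sample.int(n - 2, 1)
    src_r <- c(src[(sh + 1):n], src[1:sh])  # rotation keeps source dynamics
    max(vapply(surr_lags, function(Ls) symbol_mi(src_r, tgt, k, Ls),
               numeric(1)))
  }, numeric(1))
  # direction index from the two directed estimators, each maximised over
  # the (strided) delay grid
  fwd <- max(vapply(surr_lags, function(Ls) te_plugin(tgt, src, k, k, d = Ls),
                    numeric(1)))
  bwd <- max(vapply(surr_lags, function(Ls) te_plugin(src, tgt, k, k, d = Ls),
                    numeric(1)))
  norm <- if (fwd + bwd > 0) direction_index(fwd, bwd) else 0
  list(best_lag = L / fs * 1000, best_lag_samples = L,
       best_value = profile[i_best],
       best_value_norm = norm,
       z = z, p = surrogate_p(profile[i_best], surr, convention),
       profile = profile, lags = lags, fs = fs, estimator = estimator)
}

#' Assign the dominant coupling mode for one region pair and epoch
#'
#' Three-scenario rule over the 21 candidate coupling modes, each with a
#' surrogate p-value and a strength: (A) a single mode passes the
#' Bonferroni-corrected threshold `p < alpha / n_modes` and is the dominant
#' coupling mode; (B) several pass and the strongest wins (strength ties
#' broken toward the lowest mode id); (C) none passes and mode 0 with zero
#' strength is assigned.
#'
#' @param p_values Numeric vector of per-mode p-values (length 21 for six
#'   bands).
#' @param strengths Per-mode coupling strengths (same length).
#' @param lags Per-mode time lags in ms (same length; optional).
#' @param alpha Family-wise level before Bonferroni division (default 0.01).
#' @param n_modes Number of candidate modes (default `length(p_values)`;
#'   must equal 6 within- plus 15 cross-band modes for the default bands).
#' @return List with `mode_id` (0 if none), `strength` (0 if none), `lag`
#'   (NA if none) and `p` (the winning mode's p-value, NA if none).
#' @export
docm_assign <- function(p_values, strengths, lags = rep(NA_real_, length(p_values)),
                        alpha = 0.01, n_modes = length(p_values)) {
  if (length(p_values) != n_modes || length(strengths) != n_modes)
    stop("expected exactly ", n_modes, " candidate modes")
  surv <- which(p_values < alpha / n_modes)
  if (!length(surv))
    return(list(mode_id = 0L, strength = 0, lag = NA_real_, p = NA_real_))
  win <- surv[order(-strengths[surv], surv)[1]]
  list(mode_id = as.integer(win), strength = strengths[win],
       lag = lags[win], p = p_values[win])
}

#' Pair-level dominant coupling mode from pooled epoch evidence
#'
#' Aggregates per-epoch surrogate-normalized strengths across epochs: under
#' the null each mode's per-epoch z is approximately standard normal, so the
#' pooled statistic `mean(z) * sqrt(E)` is compared to the normal upper tail
#' with the same Bonferroni correction across modes as [docm_assign()]. This
#' pair-level decision is more powerful than any single 4-second epoch and is
#' used for comodulograms built from pair counts.
#'
#' @param z Modes x epochs matrix of surrogate-normalized strengths.
#' @param alpha Family level before Bonferroni division (default 0.01).
#' @param n_modes Bonferroni divisor (default: number of rows).
#' @return List with `mode_id` (0 if no mode passes), `strength` (pooled z of
#'   the winning mode), `p` (its pooled normal p-value) and `p_pooled` (all
#'   modes).
#' @export
docm_pool <- function(z, alpha = 0.01, n_modes = nrow(z)) {
  z <- as.matrix(z)
  E <- ncol(z)
  z_pool <- rowMeans(z) * sqrt(E)
  p_pool <- stats::pnorm(z_pool, lower.tail = FALSE)
  surv <- which(p_pool < alpha / n_modes)
  if (!length(surv))
    return(list(mode_id = 0L, strength = 0, p = NA_real_, p_pooled = p_pool))
  win <- surv[order(-z_pool[surv], surv)[1]]
  list(mode_id = as.integer(win), strength = z_pool[win], p = p_pool[win],
       p_pooled = p_pool)
}

#' Network-level FDR filtering of assigned coupling modes
#'
#' Applies Benjamini-Hochberg control across all region pairs within each
#' epoch to the p-values of the assigned dominant coupling modes; pairs that
#' do not survive are reset to mode 0, and the per-mode 4D tensors
#' (strength, mode identity, lag of shape `[n_modes, epochs, R, R]`) are
#' assembled.
#'
#' @param mode_id,strength,lag,p Arrays of shape `[epochs, R, R]` from
#'   per-pair [docm_assign()] results (entries for unassigned pairs: 0 / 0 /
#'   NA / NA).
#' @param q FDR level within each epoch's network (default 0.01).
#' @param n_modes Total number of candidate modes (default 21).
#' @return A `docm_tensor`: list of arrays `strength`, `mode_id`, `lag` of
#'   shape `[n_modes, epochs, R, R]` plus `n_modes`.
#' @export
docm_network <- function(mode_id, strength, lag, p, q = 0.01,
                         n_modes = nrow(mode_table())) {
  dm <- dim(mode_id)
  E <- dm[1]; R <- dm[2]
  for (e in seq_len(E)) {
    pm <- matrix(p[e, , ], R, R)
    pm[is.na(pm)] <- 1
    keep <- fdr_filter(pm, q)
    drop <- !keep & matrix(mode_id[e, , ] > 0, R, R)
    if (any(drop)) {
      me <- matrix(mode_id[e, , ], R, R); me[drop] <- 0L
      se <- matrix(strength[e, , ], R, R); se[drop] <- 0
      le <- matrix(lag[e, , ], R, R); le[drop] <- NA_real_
      mode_id[e, , ] <- me; strength[e, , ] <- se; lag[e, , ] <- le
    }
  }
  ts_ <- array(0, c(n_modes, E, R, R))
  tm <- array(0L, c(n_modes, E, R, R))
  tl <- array(NA_real_, c(n_modes, E, R, R))
  for (m in seq_len(n_modes)) {
    sel <- mode_id == m
    ts_[m, , , ][sel] <- strength[sel]
    tm[m, , , ][sel] <- m
    tl[m, , , ][sel] <- lag[sel]
  }
  structure(list(strength = ts_, mode_id = tm, lag = tl, n_modes = n_modes),
            class = "docm_tensor")
}

#' Comodulogram of dominant-coupling-mode probabilities
#'
#' Counts dominant-coupling-mode occurrences over epochs and region pairs and
#' normalises by the total count, yielding a 6 x 6 probability matrix:
#' within-band modes on the diagonal, cross-band modes above it (row =
#' modulating band, column = modulated band). The entries sum to one.
#'
#' @param tensor A `docm_tensor` from [docm_network()], or an integer array /
#'   matrix of assigned mode ids (0 = none).
#' @param bands Band definition data frame.
#' @return A `comodulogram`: the 6 x 6 matrix `pd` with attribute `counts`
#'   (per-mode counts, length 21).
#' @export
comodulogram <- function(tensor, bands = default_bands()) {
  modes <- mode_table(bands)
  ids <- if (inherits(tensor, "docm_tensor")) tensor$mode_id else tensor
  ids <- ids[ids > 0]
  if (!length(ids)) stop("all-zero tensor: probability distribution undefined")
  counts <- tabulate(ids, nrow(modes))
  pd_modes <- counts / sum(counts)
  nb <- nrow(bands)
  pd <- matrix(0, nb, nb, dimnames = list(bands$name, bands$name))
  for (m in seq_len(nrow(modes)))
    pd[modes$band_from[m], modes$band_to[m]] <- pd_modes[m]
  structure(pd, counts = counts, class = c("comodulogram", "matrix"))
}

#' @export
print.comodulogram <- function(x, digits = 3, ...) {
  cat("Comodulogram (rows modulate columns); sum =", format(sum(x)), "\n")
  print(round(unclass(x), digits))
  invisible(x)
}

# Per-mode probabilities as a named vector (inverse of the matrix layout).
comodulogram_modes <- function(pd, bands = default_bands()) {
  modes <- mode_table(bands)
  stats::setNames(pd[cbind(modes$band_from, modes$band_to)], modes$name)
}
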