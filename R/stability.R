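graph_laplacian <- function(W) {
  Ws <- (W + t(W)) / 2   # heat kernels use the symmetrized weights
  diag(Ws) <- 0
  diag(rowSums(Ws)) - Ws
}

#' Graph diffusion distance between two weighted networks
#'
#' Maximises, over diffusion time t, the Frobenius distance between the heat
#' kernels `exp(-t L_a)` and `exp(-t L_b)` of the two graphs' Laplacians
#' (computed on the symmetrized weights). Zero for identical networks.
#'
#' @param net_a,net_b Nonnegative weighted adjacency matrices of equal shape.
#' @param t_grid Diffusion times scanned (default 20 log-spaced values in
#'   [1e-2, 1e1]); the grid maximum is refined locally.
#' @return The distance (nonnegative scalar) with attribute `t_max`.
#' @export
gdd <- function(net_a, net_b,
                t_grid = exp(seq(log(1e-2), log(1e1), length.out = 20))) {
  net_a <- as.matrix(net_a); net_b <- as.matrix(net_b)
  if (!all(dim(net_a) == dim(net_b))) stop("networks must have the same shape")
  if (any(net_a < 0) || any(net_b < 0)) stop("weights must be nonnegative")
  ea <- eigen(graph_laplacian(net_a), symmetric = TRUE)
  eb <- eigen(graph_laplacian(net_b), symmetric = TRUE)
  kernel <- function(e, t) e$vectors %*% (exp(-t * pmax(e$values, 0)) * t(e$vectors))
  xi <- function(t) {
    d <- kernel(ea, t) - kernel(eb, t)
    sum(d * d)
  }
  vals <- vapply(t_grid, xi, numeric(1))
  i <- which.max(vals)
  lo <- t_grid[max(i - 1, 1)]; hi <- t_grid[min(i + 1, length(t_grid))]
  opt <- stats::optimize(xi, c(lo, hi), maximum = TRUE)
  best <- if (opt$objective > vals[i]) opt else list(maximum = t_grid[i], objective = vals[i])
  structure(sqrt(best$objective), t_max = best$maximum)
}

# Directed degree-preserving edge swaps: (a->b, c->d) becomes (a->d, c->b)
# when neither replacement edge nor a self-loop would be created. Weights
# travel with the rewired edges.
rewire_directed <- function(W, n_swaps = 10 * sum(W != 0)) {
  A <- W
  n <- nrow(A)
  for (s in seq_len(n_swaps)) {
    edges <- which(A != 0, arr.ind = TRUE)
    if (nrow(edges) < 2) break
    ij <- edges[sample.int(nrow(edges), 2), , drop = FALSE]
    a <- ij[1, 1]; b <- ij[1, 2]; c_ <- ij[2, 1]; d <- ij[2, 2]
    if (a == d || c_ == b) next
    if (A[a, d] != 0 || A[c_, b] != 0) next
    w1 <- A[a, b]; w2 <- A[c_, d]
    A[a, b] <- 0; A[c_, d] <- 0
    A[a, d] <- w1; A[c_, b] <- w2
  }
  A
}

# Multiplicative row/column repair toward the original out-/in-strengths,
# preserving the zero pattern (so degrees stay exact).
strength_repair <- function(A, out_target, in_target, tol = 0.01, max_iter = 200) {
  for (it in seq_len(max_iter)) {
    ro <- rowSums(A)
    sc <- ifelse(ro > 0, out_target / ro, 1)
    A <- A * sc
    ci <- colSums(A)
    sc <- ifelse(ci > 0, in_target / ci, 1)
    A <- sweep(A, 2, sc, `*`)
    dev <- max(abs(rowSums(A) - out_target) / pmax(out_target, 1e-12),
               abs(colSums(A) - in_target) / pmax(in_target, 1e-12))
    if (dev < tol) break
  }
  A
}

#' Degree- and strength-preserving network null distribution for GDD
#'
#' Creates randomized directed networks by shuffling the directed connections
#' while preserving each node's in- and out-degree exactly (edge swaps) and
#' its in- and out-strength within a relative tolerance (multiplicative
#' repair), then computes the graph diffusion distance between the original
#' network and each surrogate.
#'
#' @param net Nonnegative weighted directed adjacency matrix (>= 4 nodes).
#' @param n_rand Number of surrogate networks (default 1000).
#' @param seed Integer seed.
#' @param strength_tol Relative strength tolerance (default 1%).
#' @return List with the `gdd` null distribution, the list of `surrogates`
#'   (only if `keep_surrogates`), and a function `p_value(observed)` giving
#'   the one-sided probability that a null GDD is at most the observed one
#'   (small observed GDD = networks more similar than the null).
#' @param keep_surrogates Retain the surrogate matrices (default FALSE).
#' @export
gdd_null <- function(net, n_rand = 1000, seed = 1, strength_tol = 0.01,
                     keep_surrogates = FALSE) {
  net <- as.matrix(net)
  if (nrow(net) < 4) stop("need at least 4 nodes")
  out_s <- rowSums(net); in_s <- colSums(net)
  set.seed(seed)
  surr <- vector("list", n_rand)
  dist_null <- numeric(n_rand)
  for (r in seq_len(n_rand)) {
    A <- rewire_directed(net)
    A <- strength_repair(A, out_s, in_s, tol = strength_tol)
    dist_null[r] <- gdd(net, A)
    if (keep_surrogates) surr[[r]] <- A
  }
  list(gdd = dist_null,
       surrogates = if (keep_surrogates) surr,
       p_value = function(observed)
         (1 + sum(dist_null <= observed)) / (1 + length(dist_null)))
}

#' Delay-stability index of a region pair
#'
#' Mean over standard deviation of a pair's time delays across epochs; high
#' values indicate a consistent latency. A zero standard deviation (perfectly
#' stable delay) yields `Inf`.
#'
#' @param lags Vector of per-epoch time delays.
#' @return The stability index.
#' @export
stability_cv <- function(lags) {
  lags <- lags[is.finite(lags)]
  if (length(lags) < 2) return(NA_real_)
  s <- stats::sd(lags)
  if (s == 0) return(Inf)
  mean(lags) / s
}

cv_criterion_pass <- function(lags, cv_thresh = 10, alpha = 0.01) {
  lags <- lags[is.finite(lags)]
  if (length(lags) < 3) return(NA)
  s <- stats::sd(lags)
  if (s == 0) return(TRUE)  # perfectly stable
  cv <- mean(lags) / s
  if (cv <= cv_thresh) return(FALSE)
  stats::t.test(lags, alternative = "greater")$p.value < alpha
}

#' Reject unstable epochs by network- and delay-stability criteria
#'
#' An epoch fails the whole-brain criterion when more than half of its
#' pairwise graph-diffusion distances are joint z > `z_thresh` outliers
#' (z-scored over all epoch pairs). A region pair fails the delay criterion
#' when its stability index (mean/SD of delays across epochs) is not above
#' `cv_thresh` with a significant one-tailed t-test; such failures are
#' attributed to the epochs whose delay deviates more than 2 SD from the pair
#' mean. Epochs failing both criteria -- a network outlier and attributed in
#' more than `pair_frac` of the region pairs with defined delays -- are
#' rejected.
#'
#' @param gdd_matrix Symmetric epochs x epochs distance matrix (zero
#'   diagonal).
#' @param lag_array Region-pairs x epochs matrix of per-epoch delays (NA
#'   where undefined).
#' @param z_thresh GDD outlier threshold (default 2).
#' @param cv_thresh Stability-index threshold (default 10).
#' @param pair_frac Fraction of pairs above which an epoch is rejected
#'   (default 0.10).
#' @param alpha Level of the one-tailed t-test (default 0.01).
#' @return A `stability_report`: list with `rejected` (epoch indices),
#'   `gdd_outlier`, `cv_fail_frac`, `cv_pass` (per pair), `gdd_matrix`, `pass`.
#' @export
reject_epochs <- function(gdd_matrix, lag_array, z_thresh = 2, cv_thresh = 10,
                          pair_frac = 0.10, alpha = 0.01) {
  G <- as.matrix(gdd_matrix)
  E <- nrow(G)
  if (E < 3) stop("need at least 3 epochs")
  if (max(abs(G - t(G))) > 1e-8) stop("gdd_matrix must be symmetric")
  ut <- upper.tri(G)
  vals <- G[ut]
  s <- stats::sd(vals)
  zmat <- matrix(FALSE, E, E)
  if (is.finite(s) && s > 0) {
    zv <- (G - mean(vals)) / s
    zmat <- zv > z_thresh
    diag(zmat) <- FALSE
  }
  gdd_outlier <- vapply(seq_len(E), function(e)
    mean(zmat[e, -e] | zmat[-e, e]) > 0.5, logical(1))
  lag_array <- as.matrix(lag_array)
  cv_pass <- apply(lag_array, 1, cv_criterion_pass,
                   cv_thresh = cv_thresh, alpha = alpha)
  cv_attrib <- matrix(FALSE, nrow(lag_array), E)
  for (pr in seq_len(nrow(lag_array))) {
    if (isTRUE(cv_pass[pr]) || is.na(cv_pass[pr])) next
    v <- lag_array[pr, ]
    mu <- mean(v, na.rm = TRUE); sv <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(sv) || sv == 0) next
    cv_attrib[pr, ] <- is.finite(v) & abs(v - mu) > 2 * sv
  }
  n_defined <- max(sum(!is.na(cv_pass)), 1)
  cv_fail_frac <- colSums(cv_attrib) / n_defined
  rejected <- which(gdd_outlier & cv_fail_frac > pair_frac)
  structure(list(rejected = rejected, gdd_outlier = gdd_outlier,
                 cv_fail_frac = cv_fail_frac, cv_pass = cv_pass,
                 gdd_matrix = G, pass = length(rejected) == 0),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability report:", nrow(x$gdd_matrix), "epochs;",
      length(x$rejected), "rejected",
      if (length(x$rejected)) paste0("(", paste(x$rejected, collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' Test-retest comparison of two scan sessions
#'
#' Wilcoxon rank-sum comparisons of the two sessions' GDD and delay-stability
#' values (a significant difference flags instability), and the brain-age
#' index retention rule: a subject's BAI is session-averaged only when both
#' sessions' BAI lie within `distance_thresh` (Euclidean distance) of the
#' reference fitted curve at the subject's age; otherwise the subject is
#' excluded from the BAI charts.
#'
#' @param gdd1,gdd2 Session GDD value vectors.
#' @param cv1,cv2 Session delay-stability value vectors (optional).
#' @param bai1,bai2 Per-subject BAI values for the two sessions (optional).
#' @param ages Subject ages matching `bai1`/`bai2`.
#' @param reference A `bai_fit` (or a function of age) giving the reference
#'   curve.
#' @param alpha Significance level (default 0.01).
#' @param distance_thresh BAI distance threshold (default 0.02).
#' @return List with `gdd_p`, `cv_p`, `stable` (no significant session
#'   difference), and per-subject `bai` (session average or NA), `bai_retained`.
#' @export
retest_compare <- function(gdd1, gdd2, cv1 = NULL, cv2 = NULL,
                           bai1 = NULL, bai2 = NULL, ages = NULL,
                           reference = NULL, alpha = 0.01,
                           distance_thresh = 0.02) {
  if (is.null(gdd1) || is.null(gdd2)) stop("both sessions are required")
  gdd_p <- suppressWarnings(stats::wilcox.test(gdd1, gdd2)$p.value)
  cv_p <- if (!is.null(cv1) && !is.null(cv2))
    suppressWarnings(stats::wilcox.test(cv1, cv2)$p.value) else NA_real_
  out <- list(gdd_p = gdd_p, cv_p = cv_p,
              stable = gdd_p >= alpha && (is.na(cv_p) || cv_p >= alpha))
  if (!is.null(bai1) && !is.null(bai2)) {
    if (is.null(ages) || is.null(reference))
      stop("ages and a reference curve are required for the BAI rule")
    ref_fun <- if (inherits(reference, "bai_fit"))
      function(a) predict(reference, a) else reference
    ref <- ref_fun(ages)
    keep <- abs(bai1 - ref) < distance_thresh & abs(bai2 - ref) < distance_thresh
    out$bai_retained <- keep
    out$bai <- ifelse(keep, (bai1 + bai2) / 2, NA_real_)
  }
  out
}
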