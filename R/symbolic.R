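#' Time-delay embedding
#'
#' Stacks delay vectors `x_t = (x_t, x_{t+tau}, ..., x_{t+(m-1)tau})` as rows.
#'
#' @param x Numeric vector.
#' @param m Embedding dimension.
#' @param tau Embedding delay in samples.
#' @return Matrix with `length(x) - (m-1)*tau` rows and `m` columns.
#' @export
delay_embed <- function(x, m, tau) {
  n <- length(x)
  t_max <- n - (m - 1) * tau
  if (t_max < 1) stop("series too short for embedding (m=", m, ", tau=", tau, ")")
  idx <- outer(seq_len(t_max), (0:(m - 1)) * tau, `+`)
  matrix(x[idx], t_max, m)
}

# Squared Euclidean cross-distances between row sets.
cross_dist2 <- function(Q, E) {
  d2 <- matrix(rowSums(Q^2), nrow(Q), nrow(E)) +
    matrix(rowSums(E^2), nrow(Q), nrow(E), byrow = TRUE) -
    2 * tcrossprod(Q, E)
  pmax(d2, 0)
}

#' Embedding selection by minimal one-step prediction error
#'
#' Scans a grid of (m, tau) embeddings and returns the pair minimising the
#' mean squared one-step prediction error of a local-constant predictor: the
#' future of each embedded point is predicted by the mean future of its
#' nearest neighbours. Ties are broken toward the smallest (m, tau), scanning
#' m then tau in ascending order.
#'
#' @param x Numeric vector.
#' @param m_grid,tau_grid Candidate embedding dimensions and delays.
#' @param n_neighbors Number of nearest neighbours for the predictor.
#' @param horizon Prediction horizon in samples.
#' @param max_points Cap on the number of query points (evenly subsampled) to
#'   bound the quadratic neighbour search.
#' @return List with `m`, `tau` and the full `mse` grid (m x tau matrix).
#' @export
ragwitz_embed <- function(x, m_grid = 1:10, tau_grid = 1:9, n_neighbors = 5,
                          horizon = 1, max_points = 300) {
  if (!length(m_grid) || !length(tau_grid)) stop("empty search grid")
  n <- length(x)
  if (n <= max(m_grid) * max(tau_grid) + horizon)
    stop("series too short for the largest embedding on the grid")
  mse <- matrix(NA_real_, length(m_grid), length(tau_grid),
                dimnames = list(m_grid, tau_grid))
  best <- NULL
  for (mi in seq_along(m_grid)) {
    for (ti in seq_along(tau_grid)) {
      m <- m_grid[mi]; tau <- tau_grid[ti]
      span <- (m - 1) * tau
      t_max <- n - span - horizon
      if (t_max < n_neighbors + 2) next
      E <- delay_embed(x[seq_len(n - horizon)], m, tau)[seq_len(t_max), , drop = FALSE]
      fut <- x[seq_len(t_max) + span + horizon]
      qi <- if (t_max > max_points)
        unique(round(seq(1, t_max, length.out = max_points))) else seq_len(t_max)
      d2 <- cross_dist2(E[qi, , drop = FALSE], E)
      d2[cbind(seq_along(qi), qi)] <- Inf  # exclude self-matches
      k <- min(n_neighbors, t_max - 1)
      pred <- apply(d2, 1, function(row) mean(fut[order(row)[seq_len(k)]]))
      err <- mean((fut[qi] - pred)^2)
      mse[mi, ti] <- err
      if (is.null(best) || err < best$err)
        best <- list(m = m, tau = tau, err = err)
    }
  }
  if (is.null(best)) stop("no admissible (m, tau) on the grid")
  list(m = best$m, tau = best$tau, mse = mse)
}

# One Neural-Gas run: rank-based soft-max competitive learning with
# exponentially annealed neighbourhood width and learning rate.
neural_gas_run <- function(X, k, steps, lambda0, lambda_f, lr0, lr_f) {
  N <- nrow(X)
  codes <- X[sample.int(N, k, replace = k > N), , drop = FALSE]
  frac <- (seq_len(steps) - 1) / max(steps - 1, 1)
  lambdas <- lambda0 * (lambda_f / lambda0)^frac
  lrs <- lr0 * (lr_f / lr0)^frac
  pick <- sample.int(N, steps, replace = TRUE)
  for (s in seq_len(steps)) {
    xi <- X[pick[s], ]
    diff <- sweep(codes, 2, xi, `-`)
    ranks <- rank(rowSums(diff * diff), ties.method = "first") - 1
    codes <- codes - (lrs[s] * exp(-ranks / lambdas[s])) * diff
  }
  codes
}

codebook_distortion <- function(X, codes) {
  d2 <- cross_dist2(X, codes)
  assign <- max.col(-d2, ties.method = "first")
  num <- sum(d2[cbind(seq_len(nrow(X)), assign)])
  den <- sum(sweep(X, 2, colMeans(X), `-`)^2)
  list(n_distortion = num / den, assign = assign, numerator = num)
}

#' Fit a shared Neural-Gas codebook under a distortion criterion
#'
#' Runs the Neural-Gas vector quantizer for each codebook size `k` on an
#' ascending grid and returns the first (smallest) `k` whose normalised
#' distortion -- total quantization error divided by the total dispersion of
#' the input vectors -- falls below `max_distortion`.
#'
#' @param X Matrix of embedded vectors (typically the two trajectories of a
#'   pair stacked row-wise).
#' @param k_grid Ascending candidate codebook sizes (default 2..40).
#' @param max_distortion Acceptance threshold on the normalised distortion
#'   (default 0.05).
#' @param steps_per_k Adaptation steps per code vector (default 100).
#' @param seed Integer seed; identical data and seed give identical codebooks.
#' @param on_fail `"error"` (default) to signal when no `k` on the grid meets
#'   the criterion, or `"best"` to return the best codebook found.
#' @return A `codebook`: list with `vectors` (k_o x m), `k_o`, `n_distortion`,
#'   `m` and `converged`.
#' @export
fit_codebook <- function(X, k_grid = 2:40, max_distortion = 0.05,
                         steps_per_k = 100, seed = 1,
                         on_fail = c("error", "best")) {
  on_fail <- match.arg(on_fail)
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least two vectors")
  if (is.unsorted(k_grid, strictly = TRUE)) stop("k_grid must be ascending")
  if (sum(sweep(X, 2, colMeans(X), `-`)^2) == 0)
    stop("degenerate input: zero dispersion")
  best <- NULL
  for (k in k_grid) {
    set.seed(child_seed(seed, k))
    codes <- neural_gas_run(X, k, steps = steps_per_k * k,
                            lambda0 = k / 2, lambda_f = 0.01,
                            lr0 = 0.5, lr_f = 0.005)
    dd <- codebook_distortion(X, codes)
    if (is.null(best) || dd$n_distortion < best$n_distortion)
      best <- list(vectors = codes, k_o = as.integer(k),
                   n_distortion = dd$n_distortion, m = ncol(X))
    if (dd$n_distortion < max_distortion) {
      return(structure(c(best, converged = TRUE), class = "codebook"))
    }
  }
  if (on_fail == "error")
    stop(sprintf("no k on the grid meets nDistortion < %.3f (best: %.4f at k = %d)",
                 max_distortion, best$n_distortion, best$k_o))
  structure(c(best, converged = FALSE), class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat("Neural-Gas codebook: k_o =", x$k_o, ", m =", x$m,
      sprintf(", nDistortion = %.4f", x$n_distortion),
      if (!x$converged) "(criterion not met)" else "", "\n")
  invisible(x)
}

#' Symbolize a pair of embedded trajectories with a shared codebook
#'
#' Assigns every embedded vector to its nearest code vector (Euclidean
#' distance; ties broken toward the lowest code index), mapping the pair to
#' two integer symbol sequences over the common vocabulary.
#'
#' @param traj_a,traj_b Embedded trajectories (rows are delay vectors) of
#'   equal row count and dimension `codebook$m`.
#' @param codebook A [fit_codebook()] result.
#' @return A `symbolic_pair`: list with integer sequences `s_a`, `s_b`
#'   (values in 1..k_o) and the `codebook`.
#' @export
symbolize <- function(traj_a, traj_b, codebook) {
  traj_a <- as.matrix(traj_a); traj_b <- as.matrix(traj_b)
  if (ncol(traj_a) != codebook$m || ncol(traj_b) != codebook$m)
    stop("embedding dimension does not match the codebook")
  if (nrow(traj_a) != nrow(traj_b)) stop("trajectories must have equal length")
  assign_near <- function(Tr)
    max.col(-cross_dist2(Tr, codebook$vectors), ties.method = "first")
  structure(list(s_a = assign_near(traj_a), s_b = assign_near(traj_b),
                 k = codebook$k_o, codebook = codebook),
            class = "symbolic_pair")
}

# Convenience: embed, fit and symbolize two raw series with shared settings.
symbolize_pair <- function(x, y, m, tau, k_grid = 2:40, seed = 1,
                           on_fail = "best", steps_per_k = 100) {
  ea <- delay_embed(x, m, tau)
  eb <- delay_embed(y, m, tau)
  cb <- fit_codebook(rbind(ea, eb), k_grid = k_grid, seed = seed,
                     on_fail = on_fail, steps_per_k = steps_per_k)
  symbolize(ea, eb, cb)
}
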