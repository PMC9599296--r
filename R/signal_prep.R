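#' Flag an artefactual independent component
#'
#' A component series is deemed artefactual when, after normalisation to zero
#' mean and unit variance, more than 20% of its values fall outside (-2, +2).
#'
#' @param component Numeric vector (length >= 2, nonzero variance).
#' @param z_limit Absolute z-score bound (default 2).
#' @param frac Exceedance fraction that must be strictly exceeded (default 0.2).
#' @return `TRUE` iff the fraction of |z| > `z_limit` values exceeds `frac`.
#' @export
flag_artifact_component <- function(component, z_limit = 2, frac = 0.2) {
  if (length(component) < 2) stop("component too short")
  s <- stats::sd(component)
  if (!is.finite(s) || s == 0) stop("degenerate component: zero variance")
  z <- (component - mean(component)) / s
  mean(abs(z) > z_limit) > frac
}

#' Representative time series of a region from its voxel block
#'
#' Functional interpolation of the voxels within a region: the absolute
#' Pearson correlation between every voxel pair defines a within-region
#' connectivity matrix; each voxel's strength is its row sum (diagonal
#' excluded); strengths normalised to unit sum give voxel weights; the
#' representative series is the weight-averaged voxel series.
#'
#' @param block Voxels x samples numeric matrix (>= 1 voxel, finite values).
#' @return List with `series` (the representative samples vector) and
#'   `weights` (per-voxel weights summing to one).
#' @export
roi_representative <- function(block) {
  block <- as.matrix(block)
  if (!all(is.finite(block))) stop("voxel block contains non-finite values")
  v <- nrow(block)
  if (v < 1) stop("empty voxel block")
  if (v == 1) return(list(series = as.numeric(block[1, ]), weights = 1))
  C <- abs(stats::cor(t(block)))
  diag(C) <- 0
  ss <- rowSums(C)
  tot <- sum(ss)
  if (!is.finite(tot) || tot == 0) stop("degenerate voxel block: all correlations zero")
  w <- unname(ss / tot)
  list(series = as.numeric(crossprod(block, w)), weights = w)
}

#' Band-pass, Hilbert-transform and epoch a multichannel recording
#'
#' Each region's series is zero-phase band-pass filtered per band; the Hilbert
#' envelope and instantaneous phase are computed on the continuous band-passed
#' series and only then sliced into non-overlapping `epoch_length`-second
#' epochs (a trailing partial epoch is discarded).
#'
#' @param recording Regions x samples numeric matrix.
#' @param fs Sampling rate (Hz).
#' @param bands Band definition data frame; all edges must be below `fs/2`.
#' @param epoch_length Epoch length in seconds (default 4).
#' @return A `banded_epochs` object: arrays `signal`, `amplitude`, `phase` of
#'   shape `[roi, band, epoch, sample]`, plus `fs`, `epoch_length`, `bands`.
#' @export
band_epoch <- function(recording, fs, bands = default_bands(), epoch_length = 4) {
  recording <- as.matrix(recording)
  n <- ncol(recording)
  if (n < epoch_length * fs) stop("recording shorter than one epoch")
  if (any(bands$high >= fs / 2)) stop("band edge at or above Nyquist")
  spe <- round(epoch_length * fs)
  ne <- floor(n / spe)
  nr <- nrow(recording)
  nb <- nrow(bands)
  sig <- amp <- phs <- array(NA_real_, c(nr, nb, ne, spe))
  idx <- seq_len(ne * spe)
  for (r in seq_len(nr)) {
    for (b in seq_len(nb)) {
      y <- bandpass(recording[r, ], bands$low[b], bands$high[b], fs)
      a <- analytic_signal(y)
      sig[r, b, , ] <- matrix(y[idx], ne, spe, byrow = TRUE)
      amp[r, b, , ] <- matrix(Mod(a)[idx], ne, spe, byrow = TRUE)
      phs[r, b, , ] <- matrix(Arg(a)[idx], ne, spe, byrow = TRUE)
    }
  }
  structure(list(signal = sig, amplitude = amp, phase = phs,
                 fs = fs, epoch_length = epoch_length, bands = bands),
            class = "banded_epochs")
}

#' @export
print.banded_epochs <- function(x, ...) {
  d <- dim(x$signal)
  cat("Banded epoch set:", d[1], "regions x", d[2], "bands x", d[3],
      "epochs x", d[4], "samples (", x$epoch_length, "s at", x$fs, "Hz )\n")
  invisible(x)
}
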