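#' Canonical frequency bands
#'
#' The six rhythms used throughout the package: delta 1-4, theta 4-8,
#' alpha1 8-10, alpha2 10-13, beta 13-30 and gamma 30-45 Hz.
#'
#' @return A data frame with columns `name`, `low`, `high` (Hz), one row per
#'   band, in ascending frequency order.
#' @export
default_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha1", "alpha2", "beta", "gamma"),
    low  = c(1, 4, 8, 10, 13, 30),
    high = c(4, 8, 10, 13, 30, 45),
    stringsAsFactors = FALSE
  )
}

band_index <- function(band, bands = default_bands()) {
  if (is.numeric(band)) {
    if (any(band < 1L | band > nrow(bands))) stop("unknown band id: ", band)
    return(as.integer(band))
  }
  idx <- match(band, bands$name)
  if (anyNA(idx)) stop("unknown band id: ", paste(band[is.na(idx)], collapse = ", "))
  idx
}

band_center <- function(band, bands = default_bands()) {
  i <- band_index(band, bands)
  (bands$low[i] + bands$high[i]) / 2
}

#' Coupling-mode table
#'
#' Enumerates the 21 candidate coupling modes for six bands: 6 within-band
#' modes (ids 1-6, in band order) followed by the 15 cross-band pairs
#' (ids 7-21) in fixed order delta-theta, delta-alpha1, ..., beta-gamma.
#' For cross-band modes the modulator is always the lower-frequency band.
#'
#' @param bands Band definition data frame, see [default_bands()].
#' @return Data frame with columns `mode_id`, `name`, `band_from` (modulator
#'   band index), `band_to` (modulated band index), `within` (logical).
#' @export
mode_table <- function(bands = default_bands()) {
  nb <- nrow(bands)
  within <- data.frame(
    mode_id = seq_len(nb),
    name = bands$name,
    band_from = seq_len(nb),
    band_to = seq_len(nb),
    within = TRUE,
    stringsAsFactors = FALSE
  )
  pairs <- utils::combn(nb, 2)
  cross <- data.frame(
    mode_id = nb + seq_len(ncol(pairs)),
    name = paste(bands$name[pairs[1, ]], bands$name[pairs[2, ]], sep = "-"),
    band_from = pairs[1, ],
    band_to = pairs[2, ],
    within = FALSE,
    stringsAsFactors = FALSE
  )
  rbind(within, cross)
}

#' Modulated-band set for a modulating band
#'
#' For a modulating band k the modulated set contains all strictly faster
#' bands; gamma never modulates. E.g. beta modulates only gamma.
#'
#' @param k Modulating band (name or index).
#' @param bands Band definition data frame.
#' @return Integer vector of modulated band indices.
#' @export
modulated_set <- function(k, bands = default_bands()) {
  i <- band_index(k, bands)
  if (i >= nrow(bands)) stop("the highest band has no modulated set")
  seq.int(i + 1L, nrow(bands))
}

#' Structural pipeline counts
#'
#' Book-keeping arithmetic for a full-scale run: number of undirected region
#' pairs, epochs, admissible mismatched epoch pairings for the epoch-shuffle
#' null, epoch pairs for network-stability comparisons, and the total number
#' of estimator evaluations (pairs x modes x epochs x estimators).
#'
#' @param n_roi Number of regions.
#' @param duration Recording duration in seconds.
#' @param epoch_length Epoch length in seconds.
#' @param n_modes Number of coupling modes (21 for six bands).
#' @param n_estimators Number of estimators (2: amplitude and phase).
#' @return Named list of counts.
#' @export
pipeline_counts <- function(n_roi = 78, duration = 300, epoch_length = 4,
                            n_modes = nrow(mode_table()), n_estimators = 2) {
  n_ep <- n_epochs(duration, epoch_length)
  list(
    n_epochs = n_ep,
    n_modes = n_modes,
    n_pairs = choose(n_roi, 2),
    n_mismatched_pairings = n_ep * n_ep - n_ep,
    n_epoch_pairs = choose(n_ep, 2),
    n_estimations = choose(n_roi, 2) * n_modes * n_ep * n_estimators
  )
}

#' Number of non-overlapping epochs
#'
#' @param duration Recording duration (s).
#' @param epoch_length Epoch length (s).
#' @return `floor(duration / epoch_length)`.
#' @export
n_epochs <- function(duration, epoch_length) {
  if (epoch_length <= 0) stop("epoch_length must be positive")
  floor(duration / epoch_length)
}
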