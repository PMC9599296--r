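#' Specify a planted ground-truth coupling
#'
#' Describes one directed coupling planted by the generator: a source region
#' and band influencing a target region and band after a fixed delay, either
#' through amplitude envelopes or through phase dynamics. For cross-band
#' couplings the modulator must be the slower rhythm.
#'
#' @param source_roi,target_roi Region indices.
#' @param source_band,target_band Band name or index (see [default_bands()]).
#' @param domain `"amplitude"` or `"phase"`.
#' @param delay_ms Coupling delay in milliseconds (>= 0).
#' @param strength Dimensionless coupling gain (>= 0); 0 means no coupling.
#' @param bands Band definition data frame.
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(source_roi = 1L, target_roi = 2L,
                          source_band = "alpha1", target_band = source_band,
                          domain = c("amplitude", "phase"),
                          delay_ms = 0, strength = 1,
                          bands = default_bands()) {
  domain <- match.arg(domain)
  sb <- band_index(source_band, bands)
  tb <- band_index(target_band, bands)
  if (delay_ms < 0) stop("delay_ms must be >= 0")
  if (strength < 0) stop("strength must be >= 0")
  if (sb != tb && bands$low[sb] > bands$low[tb])
    stop("cross-band coupling must have the slower band as modulator")
  structure(list(source_roi = as.integer(source_roi),
                 target_roi = as.integer(target_roi),
                 source_band = sb, target_band = tb,
                 domain = domain, delay_ms = delay_ms,
                 strength = strength),
            class = "coupling_spec")
}

# Inject a directed influence from a source band component into a free target
# band component. Amplitude: the (standardized) source envelope, delayed by
# `d` samples, multiplicatively modulates the target envelope. Phase,
# within-band: delayed Kuramoto-style pulling of the target phase toward the
# source phase; phase, cross-band: the delayed source phase additively forces
# the target's instantaneous frequency. In both phase mechanisms the
# frequency deviation is capped at ~40% of the target bandwidth so the
# entrained carrier stays inside its band.
couple_component <- function(src, free_tgt, domain, d, strength,
                             band_s, band_t, fs, bands = default_bands()) {
  if (strength == 0) return(free_tgt)
  if (domain == "amplitude") {
    z <- as.numeric(scale(envelope(src)))
    # exponential gain: positive, monotone in the delayed source envelope,
    # no clipping at any strength
    m <- exp(strength / 2 * lag_series(z, d))
    y <- bandpass(free_tgt * m, bands$low[band_t], bands$high[band_t], fs)
    y / stats::sd(y)
  } else {
    phi_x <- lag_series(instantaneous_phase(src), d)
    a <- analytic_signal(free_tgt)
    dphi_f <- c(Arg(a[1]), Arg(a[-1] * Conj(a[-length(a)])))
    bw <- bands$high[band_t] - bands$low[band_t]
    eps <- strength * 2 * pi * 0.4 * bw / fs
    n <- length(dphi_f)
    phi_y <- numeric(n)
    phi_y[1] <- dphi_f[1]
    # n:m phase pulling: the target phase is drawn toward r times the delayed
    # source phase (r = 1 within band; nearest harmonic ratio across bands)
    r <- if (band_s == band_t) 1 else
      max(2, round(band_center(band_t, bands) / band_center(band_s, bands)))
    for (t in 2:n)
      phi_y[t] <- phi_y[t - 1] + dphi_f[t] +
        eps * sin(r * phi_x[t] - phi_y[t - 1])
    y <- Mod(a) * cos(phi_y)
    y / stats::sd(y)
  }
}

free_carrier <- function(n, band, fs, bands = default_bands()) {
  x <- bandpass(stats::rnorm(n), bands$low[band], bands$high[band], fs)
  x / stats::sd(x)
}

#' Generate a pair of coupled band-limited series
#'
#' Produces two time series in which the target contains a delayed,
#' band-specific influence from the source, following `coupling`. With
#' `strength = 0` the two series are independent. Each series is a unit-variance
#' band-limited filtered-noise carrier plus additive white noise.
#'
#' @param fs Sampling rate (Hz); must be at least twice the upper edge of the
#'   highest band.
#' @param duration Recording length in seconds (>= 8).
#' @param coupling A [coupling_spec()].
#' @param noise_sd Standard deviation of the additive white noise.
#' @param seed Integer seed; identical arguments give identical output.
#' @param bands Band definition data frame.
#' @return List with elements `x` (source series), `y` (target series), `fs`,
#'   `delay_samples` and the `coupling`; class `coupled_pair`.
#' @export
make_coupled_pair <- function(fs, duration, coupling, noise_sd = 0.2,
                              seed = 1, bands = default_bands()) {
  stopifnot(inherits(coupling, "coupling_spec"))
  if (fs < 2 * max(bands$high)) stop("fs must be >= twice the highest band edge")
  if (duration < 8) stop("duration must be >= 8 s")
  if (coupling$delay_ms / 1000 >= duration / 2)
    stop("delay_ms must be below half the recording duration")
  set.seed(seed)
  n <- round(duration * fs)
  d <- round(coupling$delay_ms / 1000 * fs)
  src <- free_carrier(n, coupling$source_band, fs, bands)
  tgt <- free_carrier(n, coupling$target_band, fs, bands)
  tgt <- couple_component(src, tgt, coupling$domain, d, coupling$strength,
                          coupling$source_band, coupling$target_band, fs, bands)
  structure(list(x = src + noise_sd * stats::rnorm(n),
                 y = tgt + noise_sd * stats::rnorm(n),
                 fs = fs, delay_samples = d, coupling = coupling),
            class = "coupled_pair")
}

default_delay_ms <- function() {
  c(delta = 80, theta = 45, alpha1 = 28, alpha2 = 24, beta = 18, gamma = 15)
}

#' Default cohort generator settings
#'
#' Study conditions emulated by the generator: 5-minute recordings at 256 Hz,
#' 16 regions (8 posterior, 8 anterior), ages spread uniformly over 18-65
#' years, a posterior-to-anterior alpha1 gradient, band-specific delays
#' decreasing with frequency, and an age-dependent cross/within coupling
#' mixture peaking at 28 years (the adult maximum of the brain age
#' trajectory).
#'
#' @param ... Named overrides of any default.
#' @return Named list of generator settings.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_subjects = 12L,
    age_range = c(18, 65),
    n_roi = 16L,
    n_posterior = 8L,
    fs = 256,
    duration = 300,
    epoch_length = 4,
    bands = default_bands(),
    n_couplings = 12L,
    gradient_bands = "alpha1",
    gradient_domain = "phase",
    bai_profile = list(peak = 28, sd = 15, base = 0.2, amp = 0.6),
    delay_ms = default_delay_ms(),
    strength = 1,
    noise_sd = 0.2,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$age_range[1] < 1 || cfg$age_range[2] > 120 ||
      cfg$age_range[1] >= cfg$age_range[2])
    stop("age_range outside generator support")
  cfg
}

cross_fraction <- function(age, profile) {
  p <- profile$base + profile$amp * exp(-(age - profile$peak)^2 / (2 * profile$sd^2))
  min(max(p, 0), 1)
}

# Draw the truth list for one subject. Couplings touching a gradient band are
# always posterior -> anterior; other within-band couplings use the remaining
# bands so the gradient invariant holds by construction.
plan_couplings <- function(cfg, age) {
  bands <- cfg$bands
  nb <- nrow(bands)
  grad <- band_index(cfg$gradient_bands, bands)
  post <- seq_len(cfg$n_posterior)
  ant <- seq.int(cfg$n_posterior + 1L, cfg$n_roi)
  p_cross <- cross_fraction(age, cfg$bai_profile)
  n_cross <- round(p_cross * cfg$n_couplings)
  n_within <- cfg$n_couplings - n_cross
  out <- list()
  pick1 <- function(v) v[sample.int(length(v), 1)]  # safe for length-1 vectors
  pick_rois <- function(b_from, b_to) {
    if (b_from %in% grad || b_to %in% grad) {
      c(pick1(post), pick1(ant))
    } else {
      sample(cfg$n_roi, 2)
    }
  }
  for (i in seq_len(n_within)) {
    b <- if (i <= length(grad)) grad[i] else
      pick1(setdiff(seq_len(nb), grad))
    rois <- pick_rois(b, b)
    dom <- if (b %in% grad) cfg$gradient_domain else
      pick1(c("amplitude", "phase"))
    out[[length(out) + 1L]] <- coupling_spec(
      rois[1], rois[2], b, b, dom,
      delay_ms = cfg$delay_ms[b], strength = cfg$strength, bands = bands)
  }
  for (i in seq_len(n_cross)) {
    b_from <- pick1(setdiff(seq_len(nb - 1L), grad))
    b_to <- pick1(setdiff(modulated_set(b_from, bands), grad))
    rois <- pick_rois(b_from, b_to)
    out[[length(out) + 1L]] <- coupling_spec(
      rois[1], rois[2], b_from, b_to, pick1(c("amplitude", "phase")),
      delay_ms = cfg$delay_ms[b_from], strength = cfg$strength, bands = bands)
  }
  out
}

#' Generate a synthetic cohort with planted couplings
#'
#' Builds per-subject multichannel recordings in which every region is a sum
#' of six band-limited filtered-noise carriers plus white noise, with directed
#' couplings planted per [coupling_spec()]. Ages span the configured range
#' uniformly; the per-subject fraction of cross-band versus within-band
#' couplings follows the configured age profile, and couplings in the gradient
#' bands always run from posterior-labelled to anterior-labelled regions.
#'
#' @param config Settings from [cohort_config()].
#' @return A `synthetic_cohort`: list with `subjects` (each holding `age`,
#'   `sex`, `fs` and the `recording` matrix, regions x samples), the `truth`
#'   data frame enumerating all planted couplings, the region `partition`
#'   (posterior/anterior index sets), the `config` and `seed`.
#' @export
make_cohort <- function(config = cohort_config()) {
  cfg <- config
  if (cfg$n_subjects < 2) stop("n_subjects must be >= 2")
  n <- round(cfg$duration * cfg$fs)
  nb <- nrow(cfg$bands)
  ages <- seq(cfg$age_range[1], cfg$age_range[2], length.out = cfg$n_subjects)
  subjects <- vector("list", cfg$n_subjects)
  truth <- list()
  for (s in seq_len(cfg$n_subjects)) {
    set.seed(child_seed(cfg$seed, s))
    plan <- plan_couplings(cfg, ages[s])
    comp <- array(0, c(cfg$n_roi, nb, n))
    for (r in seq_len(cfg$n_roi)) for (b in seq_len(nb))
      comp[r, b, ] <- free_carrier(n, b, cfg$fs, cfg$bands)
    for (cp in plan) {
      d <- round(cp$delay_ms / 1000 * cfg$fs)
      comp[cp$target_roi, cp$target_band, ] <- couple_component(
        comp[cp$source_roi, cp$source_band, ],
        comp[cp$target_roi, cp$target_band, ],
        cp$domain, d, cp$strength, cp$source_band, cp$target_band,
        cfg$fs, cfg$bands)
    }
    rec <- colSums(aperm(comp, c(2, 1, 3))) +
      matrix(cfg$noise_sd * stats::rnorm(cfg$n_roi * n), cfg$n_roi, n)
    subjects[[s]] <- list(age = ages[s],
                          sex = c("F", "M")[(s %% 2) + 1L],
                          fs = cfg$fs, recording = rec)
    truth[[s]] <- data.frame(
      subject = s,
      source_roi = vapply(plan, `[[`, 1L, "source_roi"),
      target_roi = vapply(plan, `[[`, 1L, "target_roi"),
      source_band = vapply(plan, `[[`, 1L, "source_band"),
      target_band = vapply(plan, `[[`, 1L, "target_band"),
      domain = vapply(plan, `[[`, "", "domain"),
      delay_ms = vapply(plan, `[[`, 1, "delay_ms"),
      strength = vapply(plan, `[[`, 1, "strength")
    )
  }
  structure(list(subjects = subjects,
                 truth = do.call(rbind, truth),
                 partition = list(posterior = seq_len(cfg$n_posterior),
                                  anterior = seq.int(cfg$n_posterior + 1L, cfg$n_roi)),
                 config = cfg, seed = cfg$seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$subjects), "subjects,",
      x$config$n_roi, "regions,", x$config$duration, "s at",
      x$config$fs, "Hz\n")
  cat("Ages", min(x$truth$subject), ":",
      paste(round(range(vapply(x$subjects, `[[`, 0, "age")), 1), collapse = "-"),
      "years;", nrow(x$truth), "planted couplings\n")
  invisible(x)
}

#' Persist a synthetic cohort as text files
#'
#' Writes one CSV per subject recording plus `subjects.csv`, `truth.csv` and a
#' JSON echo of the generator configuration.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(
    subject = seq_along(cohort$subjects),
    age = vapply(cohort$subjects, `[[`, 0, "age"),
    sex = vapply(cohort$subjects, `[[`, "", "sex"),
    fs = vapply(cohort$subjects, `[[`, 0, "fs")
  )
  utils::write.csv(meta, file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- cohort$config
  cfg$bands <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  for (s in seq_along(cohort$subjects)) {
    utils::write.csv(t(cohort$subjects[[s]]$recording),
                     file.path(dir, sprintf("subject_%03d.csv", s)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory holding the cohort files.
#' @return A `synthetic_cohort`-shaped list (without the full config echo).
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "subjects.csv"))
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  subjects <- lapply(seq_len(nrow(meta)), function(s) {
    rec <- t(as.matrix(utils::read.csv(file.path(dir, sprintf("subject_%03d.csv", s)))))
    dimnames(rec) <- NULL
    list(age = meta$age[s], sex = meta$sex[s], fs = meta$fs[s], recording = rec)
  })
  structure(list(subjects = subjects, truth = truth,
                 partition = list(posterior = seq_len(cfg$n_posterior),
                                  anterior = seq.int(cfg$n_posterior + 1, cfg$n_roi)),
                 config = cfg, seed = cfg$seed),
            class = "synthetic_cohort")
}
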