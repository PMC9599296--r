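# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

fix_fs <- 128

band_delay_ms <- c(80, 45, 28, 24, 18, 15)  # modulator-band default delays

# A coupled pair plus the band-filtered envelopes / phases of both series.
make_pair_envelopes <- function(source_band, target_band, domain, delay_ms,
                                strength, duration, seed, noise_sd = 0.2) {
  cp <- coupling_spec(1, 2, source_band, target_band, domain,
                      delay_ms = delay_ms, strength = strength)
  pr <- make_coupled_pair(fix_fs, duration, cp, noise_sd = noise_sd, seed = seed)
  bands <- default_bands()
  bi <- function(b) match(b, bands$name)
  lo_s <- bands$low[bi(source_band)]; hi_s <- bands$high[bi(source_band)]
  lo_t <- bands$low[bi(target_band)]; hi_t <- bands$high[bi(target_band)]
  xs <- docmflow:::bandpass(pr$x, lo_s, hi_s, fix_fs)
  yt <- docmflow:::bandpass(pr$y, lo_t, hi_t, fix_fs)
  list(pair = pr,
       env_x = docmflow:::envelope(xs), env_y = docmflow:::envelope(yt),
       phase_x = docmflow:::instantaneous_phase(xs),
       phase_y = docmflow:::instantaneous_phase(yt),
       delay_samples = pr$delay_samples)
}

# Brute-force plug-in transfer entropy oracle: explicit triple loop over all
# observed (target future, target past, delayed source) triplets.
te_bruteforce <- function(target, source, d = 1, delta = 1, base = 2) {
  n <- length(target)
  t_idx <- seq.int(max(1, 1 + d - delta), n - delta + min(0, d))
  trip <- data.frame(af = target[t_idx + delta], an = target[t_idx],
                     bd = source[t_idx + delta - d])
  N <- nrow(trip)
  te <- 0
  for (af in unique(trip$af)) for (an in unique(trip$an)) for (bd in unique(trip$bd)) {
    n3 <- sum(trip$af == af & trip$an == an & trip$bd == bd)
    if (n3 == 0) next
    n_ab <- sum(trip$an == an & trip$bd == bd)
    n2 <- sum(trip$af == af & trip$an == an)
    n1 <- sum(trip$an == an)
    te <- te + (n3 / N) * log((n3 / n_ab) / (n2 / n1), base = base)
  }
  te
}

# Hand-rolled Benjamini-Hochberg: order p-values, find the largest k with
# p_(k) <= k/m * q, reject all smaller or equal.
bh_reference <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) / m * q)
  keep <- logical(m)
  if (length(k)) keep[o[seq_len(max(k))]] <- TRUE
  keep
}

# Phase matrices (epochs x samples) for a coupled pair via band_epoch.
make_phase_epochs <- function(source_band, target_band, strength, delay_ms,
                              duration, seed, noise_sd = 0.2) {
  cp <- coupling_spec(1, 2, source_band, target_band, "phase",
                      delay_ms = delay_ms, strength = strength)
  pr <- make_coupled_pair(fix_fs, duration, cp, noise_sd = noise_sd, seed = seed)
  be <- band_epoch(rbind(pr$x, pr$y), fix_fs, epoch_length = 4)
  bands <- default_bands()
  E <- dim(be$phase)[3]
  list(px = matrix(be$phase[1, match(source_band, bands$name), , ], nrow = E),
       py = matrix(be$phase[2, match(target_band, bands$name), , ], nrow = E))
}
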