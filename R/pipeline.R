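#' Pipeline configuration
#'
#' Settings for [run_pipeline()]. Defaults are desk-scale; `n_surr` counts
#' surrogates per pair and mode, `alpha` the Bonferroni family level for
#' dominant-coupling-mode selection, `q` the epoch-wise network FDR level.
#'
#' @param ... Named overrides.
#' @return Named list of settings.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    bands = default_bands(),
    epoch_length = 4,
    domains = c("phase", "amplitude"),
    n_surr = 200L,
    alpha = 0.01,
    q = 0.01,
    d_ste_set = c(-8L, -4L, -2L, 0L, 2L),
    m = 3L, tau = 1L,
    k_grid = 4L,
    env_decim = 2L,
    codebook_rows = 2000L,
    estimate_lags = TRUE,
    lag_surr = 100L,
    fbai_invert = FALSE,
    comodulogram_from = "pairs",
    split_age = 30,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$q > 0, cfg$q < 1)
  cfg
}

# Per-pair, per-mode statistics in the phase domain: observed per-epoch
# preferred-direction strength max(dPTE, 1 - dPTE), direction sign, and the
# epoch-shuffle surrogate p-value (plain-proportion convention, shared null
# across epochs).
pair_mode_stats_phase <- function(be, i, j, modes, n_surr, seed, fs, bands) {
  E <- dim(be$phase)[3]
  nm <- nrow(modes)
  stat <- p <- dir <- zs <- matrix(NA_real_, nm, E)
  raw <- matrix(NA_real_, nm, E)
  for (m in seq_len(nm)) {
    px <- matrix(be$phase[i, modes$band_from[m], , ], nrow = E)
    py <- matrix(be$phase[j, modes$band_to[m], , ], nrow = E)
    # analysis step: half the mean period of the two rhythms
    f_mean <- mean(band_center(c(modes$band_from[m], modes$band_to[m]), bands))
    dl <- max(1L, round(fs / (2 * f_mean)))
    sur <- surrogate_p_dpte_stat(px, py, delta = dl, n_surr = n_surr,
                                 seed = child_seed(seed, m))
    stat[m, ] <- sur$observed_epoch
    raw[m, ] <- sur$dpte_epoch
    dir[m, ] <- ifelse(sur$dpte_epoch >= 0.5, 1, -1)
    p[m, ] <- sur$p_epoch
    zs[m, ] <- (stat[m, ] - mean(sur$surrogates)) /
      max(stats::sd(sur$surrogates), 1e-12)
  }
  list(stat = stat, p = p, dir = dir, dpte = raw, z = zs)
}

# Epoch-shuffle null for the preferred-direction statistic.
surrogate_p_dpte_stat <- function(phase_x, phase_y, delta = 1, n_surr, seed) {
  E <- nrow(phase_x)
  dpte_e <- vapply(seq_len(E), function(e)
    dpte(pte(phase_x[e, ], phase_y[e, ], delta),
         pte(phase_y[e, ], phase_x[e, ], delta)), numeric(1))
  obs <- pmax(dpte_e, 1 - dpte_e)
  prs <- mismatched_pairings(E)
  set.seed(seed)
  if (nrow(prs) > n_surr) prs <- prs[sample.int(nrow(prs), n_surr), ]
  surr <- vapply(seq_len(nrow(prs)), function(r) {
    v <- dpte(pte(phase_x[prs$i[r], ], phase_y[prs$j[r], ], delta),
              pte(phase_y[prs$j[r], ], phase_x[prs$i[r], ], delta))
    max(v, 1 - v)
  }, numeric(1))
  list(observed_epoch = obs, dpte_epoch = dpte_e,
       p_epoch = vapply(obs, function(o) mean(surr >= o), numeric(1)),
       surrogates = surr)
}

# Amplitude-domain analogue on Hilbert envelopes: shared Neural-Gas codebook
# per pair and mode (fitted on a row subsample of the embedded, optionally
# decimated epochs), per-epoch dSTE both ways, circular-shift null with
# per-epoch baseline centering pooled across epochs (epochs differ in
# baseline TE; centering each epoch's null before pooling keeps the shared
# null calibrated).
pair_mode_stats_amplitude <- function(be, i, j, modes, cfg, seed) {
  E <- dim(be$amplitude)[3]
  nm <- nrow(modes)
  spe <- dim(be$amplitude)[4]
  keep <- seq(1, spe, by = cfg$env_decim)
  stat <- p <- dir <- zs <- matrix(NA_real_, nm, E)
  n_per <- max(2L, ceiling(cfg$n_surr / E))
  for (m in seq_len(nm)) {
    ex <- matrix(be$amplitude[i, modes$band_from[m], , ], nrow = E)[, keep, drop = FALSE]
    ey <- matrix(be$amplitude[j, modes$band_to[m], , ], nrow = E)[, keep, drop = FALSE]
    ta <- lapply(seq_len(E), function(e) delay_embed(ex[e, ], cfg$m, cfg$tau))
    tb <- lapply(seq_len(E), function(e) delay_embed(ey[e, ], cfg$m, cfg$tau))
    allrows <- rbind(do.call(rbind, ta), do.call(rbind, tb))
    set.seed(child_seed(seed, m))
    sub <- if (nrow(allrows) > cfg$codebook_rows)
      allrows[sample.int(nrow(allrows), cfg$codebook_rows), ] else allrows
    cb <- fit_codebook(sub, k_grid = cfg$k_grid, seed = child_seed(seed, m),
                       on_fail = "best")
    sy <- lapply(seq_len(E), function(e) symbolize(ta[[e]], tb[[e]], cb))
    # preferred-direction strength maximised over the candidate delay set
    # (zero-phase envelope smoothing spreads the lagged dependence, so a
    # single delay underestimates it)
    stat_dir <- function(s) {
      ab <- max(vapply(cfg$d_ste_set, function(d)
        te_plugin(s$s_b, s$s_a, s$k, s$k, d = d), numeric(1)))
      ba <- max(vapply(cfg$d_ste_set, function(d)
        te_plugin(s$s_a, s$s_b, s$k, s$k, d = d), numeric(1)))
      c(max(ab, ba), if (ab >= ba) 1 else -1)
    }
    ob <- vapply(sy, stat_dir, numeric(2))
    stat[m, ] <- ob[1, ]
    dir[m, ] <- ob[2, ]
    surr_mat <- vapply(seq_len(E), function(e) {
      sp <- sy[[e]]
      n <- length(sp$s_a)
      vapply(seq_len(n_per), function(r) {
        sh <- sample.int(n - 2, 1)
        rot <- list(s_a = c(sp$s_a[(sh + 1):n], sp$s_a[1:sh]), s_b = sp$s_b,
                    k = sp$k)
        stat_dir(rot)[1]
      }, numeric(1))
    }, numeric(n_per))
    mu_e <- colMeans(surr_mat)
    surr_c <- as.numeric(sweep(surr_mat, 2, mu_e))
    obs_c <- stat[m, ] - mu_e
    p[m, ] <- vapply(obs_c, function(o) mean(surr_c >= o), numeric(1))
    zs[m, ] <- obs_c / max(stats::sd(surr_c), 1e-12)
  }
  list(stat = stat, p = p, dir = dir, z = zs)
}

#' Per-pair, per-mode coupling statistics for one region pair
#'
#' Computes, for every candidate coupling mode, the per-epoch
#' preferred-direction strength, direction sign, surrogate p-value
#' (plain-proportion convention, as required by the Bonferroni dominant-mode
#' selection) and surrogate-normalized strength z, in the requested domain
#' (phase: epoch-shuffle null on dPTE; amplitude: circular-shift null on
#' symbolic transfer entropy of the envelopes).
#'
#' @param be A `banded_epochs` object from [band_epoch()].
#' @param i,j Region indices of the pair.
#' @param domain `"phase"` or `"amplitude"`.
#' @param config Settings from [pipeline_config()].
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed.
#' @return List of modes x epochs matrices: `stat`, `p`, `dir`, `z` (phase
#'   additionally `dpte`).
#' @export
pair_mode_statistics <- function(be, i, j, domain = c("phase", "amplitude"),
                                 config = pipeline_config(), fs, seed = 1) {
  domain <- match.arg(domain)
  modes <- mode_table(config$bands)
  if (domain == "phase")
    pair_mode_stats_phase(be, i, j, modes, config$n_surr, seed, fs, config$bands)
  else
    pair_mode_stats_amplitude(be, i, j, modes, config, seed)
}

run_domain <- function(be, cfg, domain, fs, seed) {
  R <- dim(be$signal)[1]; E <- dim(be$signal)[3]
  modes <- mode_table(cfg$bands)
  nm <- nrow(modes)
  mode_id <- array(0L, c(E, R, R))
  strength <- array(0, c(E, R, R))
  lag <- array(NA_real_, c(E, R, R))
  pv <- array(NA_real_, c(E, R, R))
  nb <- nrow(cfg$bands)
  dir_sum <- array(0, c(nb, R, R))   # within-band direction index, epoch-mean
  pooled_mode <- matrix(0L, R, R)
  pooled_strength <- matrix(0, R, R)
  prs <- utils::combn(R, 2)
  for (pp in seq_len(ncol(prs))) {
    i <- prs[1, pp]; j <- prs[2, pp]
    sd_p <- child_seed(seed, pp)
    st <- if (domain == "phase")
      pair_mode_stats_phase(be, i, j, modes, cfg$n_surr, sd_p, fs, cfg$bands)
    else
      pair_mode_stats_amplitude(be, i, j, modes, cfg, sd_p)
    if (domain == "phase") {
      for (b in seq_len(nb)) {
        d_mean <- mean(2 * st$dpte[b, ] - 1)  # epoch-mean direction index
        dir_sum[b, i, j] <- d_mean
        dir_sum[b, j, i] <- -d_mean
      }
    }
    lag_pair <- rep(NA_real_, nm)
    for (e in seq_len(E)) {
      # scenario-B strengths are surrogate-normalized (z) so modes with
      # different baseline TE levels are comparable
      asg <- docm_assign(st$p[, e], st$z[, e], alpha = cfg$alpha)
      if (asg$mode_id == 0) next
      m <- asg$mode_id
      from <- if (st$dir[m, e] >= 0) i else j
      to <- if (st$dir[m, e] >= 0) j else i
      if (cfg$estimate_lags && is.na(lag_pair[m])) {
        lag_pair[m] <- tryCatch({
          bf <- modes$band_from[m]; bt <- modes$band_to[m]
          if (domain == "phase") {
            a_s <- as.numeric(t(matrix(be$phase[i, bf, , ], nrow = E)))
            b_s <- as.numeric(t(matrix(be$phase[j, bt, , ], nrow = E)))
            ls <- lag_scan(a_s, b_s, fs, "dpte",
                           max_lag = round(cfg$epoch_length * fs / 2),
                           n_surr = cfg$lag_surr, seed = sd_p)
          } else {
            a_s <- as.numeric(t(matrix(be$amplitude[i, bf, , ], nrow = E)))
            b_s <- as.numeric(t(matrix(be$amplitude[j, bt, , ], nrow = E)))
            ls <- lag_scan(a_s, b_s, fs, "dste",
                           max_lag = round(cfg$epoch_length * fs / 2),
                           n_surr = cfg$lag_surr, seed = sd_p,
                           m = cfg$m, tau = cfg$tau, k_grid = cfg$k_grid)
          }
          abs(ls$best_lag)
        }, error = function(e) NA_real_)
      }
      mode_id[e, from, to] <- m
      strength[e, from, to] <- asg$strength
      lag[e, from, to] <- lag_pair[m]
      pv[e, from, to] <- asg$p
    }
    pool <- docm_pool(st$z, alpha = cfg$alpha)
    if (pool$mode_id > 0) {
      m <- pool$mode_id
      fwd <- mean(st$dir[m, ]) >= 0
      pooled_mode[if (fwd) i else j, if (fwd) j else i] <- m
      pooled_strength[if (fwd) i else j, if (fwd) j else i] <- pool$strength
    }
  }
  tensor <- docm_network(mode_id, strength, lag, pv, q = cfg$q, n_modes = nm)
  cm_src <- if (cfg$comodulogram_from == "pairs") pooled_mode else tensor
  cm <- tryCatch(comodulogram(cm_src, cfg$bands), error = function(e) NULL)
  list(tensor = tensor, comodulogram = cm, direction = dir_sum,
       pooled_mode = pooled_mode, pooled_strength = pooled_strength)
}

#' Run the full analysis pipeline on a cohort
#'
#' For every subject: band-filter, Hilbert-transform and epoch the recording;
#' compute per-pair, per-mode directed coupling statistics with surrogate
#' nulls (epoch shuffling for the phase domain, source-symbol permutation for
#' the amplitude domain); assign dominant coupling modes with Bonferroni
#' selection and epoch-wise network FDR; build the mode/strength/lag tensors
#' and the comodulogram; and derive the posterior-anterior index and the
#' frequency-dependent brain age index. With enough subjects per age segment
#' the cohort-level two-segment curve fits are added.
#'
#' @param cohort A `synthetic_cohort` (or compatible list of subjects with
#'   `recording`, `fs`, `age` plus a region `partition`).
#' @param config Settings from [pipeline_config()].
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return A `docm_pipeline` object: per-subject results, per-domain fBAI
#'   tables, PAI tables, curve fits and the run manifest.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  cfg <- config
  subjects <- cohort$subjects
  partition <- cohort$partition
  results <- vector("list", length(subjects))
  modes <- mode_table(cfg$bands)
  for (s in seq_along(subjects)) {
    sub <- subjects[[s]]
    be <- band_epoch(sub$recording, sub$fs, cfg$bands, cfg$epoch_length)
    doms <- lapply(cfg$domains, function(dn)
      run_domain(be, cfg, dn, sub$fs, seed = child_seed(cfg$seed, s * 131 +
                                                          match(dn, c("phase", "amplitude")))))
    names(doms) <- cfg$domains
    results[[s]] <- list(age = sub$age, domains = doms)
  }
  nb <- nrow(cfg$bands)
  fbai_tab <- do.call(rbind, lapply(seq_along(results), function(s) {
    do.call(rbind, lapply(names(results[[s]]$domains), function(dn) {
      cm <- results[[s]]$domains[[dn]]$comodulogram
      if (is.null(cm)) return(NULL)
      data.frame(subject = s, age = results[[s]]$age, domain = dn,
                 band = cfg$bands$name[seq_len(nb - 1)],
                 fbai = vapply(seq_len(nb - 1), function(k)
                   tryCatch(fbai(cm, k, invert = cfg$fbai_invert, bands = cfg$bands),
                            error = function(e) NA_real_), numeric(1)))
    }))
  }))
  pai_tab <- do.call(rbind, lapply(seq_along(results), function(s) {
    do.call(rbind, lapply(names(results[[s]]$domains), function(dn) {
      dirm <- results[[s]]$domains[[dn]]$direction
      if (dn != "phase") return(NULL)
      data.frame(subject = s, age = results[[s]]$age, domain = dn,
                 band = cfg$bands$name,
                 pai = vapply(seq_len(nb), function(b)
                   tryCatch(pai(matrix(dirm[b, , ], dim(dirm)[2]), partition),
                            error = function(e) NA_real_), numeric(1)))
    }))
  }))
  fits <- list()
  if (!is.null(fbai_tab)) {
    for (dn in unique(fbai_tab$domain)) for (b in unique(fbai_tab$band)) {
      dd <- fbai_tab[fbai_tab$domain == dn & fbai_tab$band == b, ]
      ft <- tryCatch(fit_bai_curve(dd$age, dd$fbai, cfg$split_age),
                     error = function(e) NULL)
      if (!is.null(ft)) fits[[paste(dn, b, sep = ".")]] <- ft
    }
  }
  out <- structure(list(results = results, fbai = fbai_tab, pai = pai_tab,
                        fits = fits, config = cfg,
                        manifest = list(
                          seed = cfg$seed,
                          n_subjects = length(subjects),
                          domains = cfg$domains,
                          package_version = as.character(utils::packageVersion("docmflow")),
                          timestamp = format(Sys.time(), tz = "UTC"))),
                   class = "docm_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.docm_pipeline <- function(x, ...) {
  cat("Pipeline run:", length(x$results), "subjects, domains:",
      paste(x$config$domains, collapse = ", "), "\n")
  if (!is.null(x$fbai))
    cat("fBAI rows:", nrow(x$fbai), "| curve fits:", length(x$fits), "\n")
  invisible(x)
}

# Edge table for one subject/domain: one row per significant directed edge.
edge_table <- function(tensor, modes, subject, domain) {
  idx <- which(tensor$mode_id > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  data.frame(subject = subject, domain = domain,
             epoch = idx[, 2], roi_from = idx[, 3], roi_to = idx[, 4],
             mode = modes$name[idx[, 1]],
             strength = tensor$strength[idx],
             lag_ms = tensor$lag[idx])
}

write_pipeline <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  modes <- mode_table(x$config$bands)
  edges <- do.call(rbind, lapply(seq_along(x$results), function(s)
    do.call(rbind, lapply(names(x$results[[s]]$domains), function(dn)
      edge_table(x$results[[s]]$domains[[dn]]$tensor, modes, s, dn)))))
  empty <- function(cols) stats::setNames(
    as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  utils::write.csv(edges %||% empty(c("subject", "domain", "epoch", "roi_from",
                                      "roi_to", "mode", "strength", "lag_ms")),
                   file.path(dir, "edges.csv"), row.names = FALSE)
  utils::write.csv(x$fbai %||% empty(c("subject", "age", "domain", "band", "fbai")),
                   file.path(dir, "fbai.csv"), row.names = FALSE)
  utils::write.csv(x$pai %||% empty(c("subject", "age", "domain", "band", "pai")),
                   file.path(dir, "pai.csv"), row.names = FALSE)
  for (s in seq_along(x$results)) for (dn in names(x$results[[s]]$domains)) {
    cm <- x$results[[s]]$domains[[dn]]$comodulogram
    if (!is.null(cm))
      utils::write.csv(unclass(cm),
                       file.path(dir, sprintf("comodulogram_s%02d_%s.csv", s, dn)))
  }
  fit_report <- lapply(x$fits, function(f) {
    lapply(f$segments, function(sg)
      list(best_model = sg$best_model, r = sg$r, gaussian = sg$gaussian))
  })
  jsonlite::write_json(fit_report, file.path(dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  man <- x$manifest
  man$config_hash <- sum(utf8ToInt(paste(utils::capture.output(
    utils::str(x$config[setdiff(names(x$config), "bands")])), collapse = "")))
  jsonlite::write_json(man, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
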