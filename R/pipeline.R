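#' Study configuration for the end-to-end cohort emulation
#'
#' @param n_per_group simulated animals per genotype (default 12)
#' @param duration_s recording length per animal
#' @param fs sampling rate, Hz (must be divisible by `decimate_factor`)
#' @param params base [sim_params()] (per-animal seeds are derived from
#'   `seed`)
#' @param analysis_channel channel id for spectral/spindle/SWD single-channel
#'   analyses (default 18, right somatosensory in the packaged layout)
#' @param channels channel ids simulated and analysed (default: all 32)
#' @param thresholds_mm distance thresholds for short/long pair groups
#' @param state brain state for the coherence contrast (default NREM)
#' @param decimate_factor anti-aliased downsampling factor before coherence
#' @param n_perm permutations for the bin-wise test (default 40000)
#' @param coherogram_fraction high-connectivity threshold fraction
#' @param do_coherograms compute spindle-locked coherograms (the slowest
#'   stage)
#' @param seed global seed; expands to per-animal, per-stage sub-seeds
#' @param outdir optional output directory for CSV/JSON report files
#' @return a list of class `study_config`
#' @export
study_config <- function(n_per_group = 12, duration_s = 21600, fs = 1000,
                         params = NULL, analysis_channel = 18,
                         channels = NULL, thresholds_mm = 2:10,
                         state = "NREM", decimate_factor = 8,
                         n_perm = 40000, coherogram_fraction = 0.70,
                         do_coherograms = TRUE, seed = 1, outdir = NULL) {
  if (n_per_group < 2) stop("need n >= 2 per group")
  if (any(thresholds_mm < 1 | thresholds_mm > 14))
    stop("thresholds outside [1, 14] mm")
  params <- params %||% sim_params(fs = fs, duration_s = duration_s, seed = seed)
  params$fs <- fs; params$duration_s <- duration_s
  structure(list(n_per_group = n_per_group, duration_s = duration_s, fs = fs,
                 params = params, analysis_channel = analysis_channel,
                 channels = channels, thresholds_mm = thresholds_mm,
                 state = state, decimate_factor = decimate_factor,
                 n_perm = n_perm, coherogram_fraction = coherogram_fraction,
                 do_coherograms = do_coherograms, seed = as.integer(seed),
                 outdir = outdir),
            class = "study_config")
}

#' Process one (real or simulated) animal through the full analysis chain
#'
#' Artifact masking, SWD detection and time exclusion, bout statistics,
#' state-average spectra, all-pairs state coherence, spindle detection with
#' multi-electrode grouping, and (optionally) the spindle-locked
#' pair-averaged coherogram with its high-connectivity statistic.
#'
#' @param rec an `eeg_recording`
#' @param hyp a `hypnogram`
#' @param array an `electrode_array`
#' @param cfg a [study_config()]
#' @return list of per-animal results
#' @export
analyze_animal <- function(rec, hyp, array, cfg) {
  ch <- cfg$analysis_channel
  h <- artifact_mask(rec, hyp, threshold_uV = 750)
  swd_ev <- detect_swd(channel_signal(rec, ch), rec$fs, channel = ch)
  h <- exclude_event_times(h, swd_ev)
  bouts <- bout_statistics(h)
  swd_pct <- if (nrow(swd_ev)) 100 * sum(swd_ev$end_s - swd_ev$start_s) /
    (length(h$labels) * h$epoch_s) else 0

  psds <- epoch_psds(rec, h, ch)
  state_psd <- tryCatch(state_average_psd(psds, h, cfg$state), error = function(e) NULL)

  dec <- decimate_recording(rec, cfg$decimate_factor)
  pairs_all <- tryCatch(state_coherence_all(dec, h, cfg$state),
                        error = function(e) NULL)
  groups <- list()
  if (!is.null(pairs_all))
    for (t in cfg$thresholds_mm) for (side in c("short", "long")) {
      ps <- pairs_by_threshold(array, t, side)
      ps$pairs <- ps$pairs[ps$pairs$chan_a %in% rec$channel_ids &
                           ps$pairs$chan_b %in% rec$channel_ids, ]
      if (nrow(ps$pairs))
        groups[[sprintf("%s_%dmm", side, t)]] <- group_average(pairs_all, ps)
    }

  nrem_mask <- h$labels == "NREM"
  spin <- tryCatch(
    detect_spindles(channel_signal(rec, ch), rec$fs, nrem_mask,
                    epoch_s = h$epoch_s, channel = ch),
    error = function(e) empty_events())

  short2 <- pairs_by_threshold(array, 2, "short")
  short2$pairs <- short2$pairs[short2$pairs$chan_a %in% rec$channel_ids &
                               short2$pairs$chan_b %in% rec$channel_ids, ]
  multi <- NULL; highconn <- NULL; cg <- NULL
  if (cfg$do_coherograms && nrow(spin) >= 2 && nrow(short2$pairs)) {
    cg <- tryCatch(
      spindle_coherogram(rec, spin$start_s, short2), error = function(e) NULL)
    if (!is.null(cg)) highconn <- high_connectivity(cg, cfg$coherogram_fraction)
  }
  if (nrow(spin)) {
    per_ch <- lapply(unique(c(short2$pairs$chan_a, short2$pairs$chan_b)),
                     function(cc) tryCatch(
      detect_spindles(channel_signal(rec, cc), rec$fs, nrem_mask,
                      epoch_s = h$epoch_s, channel = cc),
      error = function(e) empty_events()))
    allspin <- do.call(bind_events, per_ch)
    if (nrow(allspin)) multi <- multisite_spindles(allspin, array)
  }

  list(hypnogram = h, bouts = bouts, swd_events = swd_ev, swd_pct = swd_pct,
       state_psd = state_psd, coherence_groups = groups, spindles = spin,
       multisite = multi, coherogram = cg, high_connectivity = highconn)
}

#' Run the full two-genotype simulated study
#'
#' Simulates `n_per_group` animals per genotype, runs every per-animal
#' analysis stage, and compares groups: t-tests on bout metrics, the
#' bin-wise cluster-corrected permutation test on the short-distance
#' coherence spectra, Pearson correlations of discharge burden against bout
#' metrics and 12-22 Hz coherence, and a t-test on the high-connectivity bin
#' counts. Deterministic for a fixed seed.
#'
#' @param cfg a [study_config()]
#' @param array an `electrode_array` (default: packaged layout)
#' @return a report list; if `cfg$outdir` is set, CSV/JSON tables stamped
#'   with the config hash and seed are written there
#' @export
run_study <- function(cfg, array = default_electrode_array()) {
  stopifnot(inherits(cfg, "study_config"))
  cfg_hash <- fnv1a_hash(unclass(cfg)[setdiff(names(cfg), "outdir")])
  animals <- list()
  for (g in c("control", "mutant")) {
    preset <- genotype_preset(g)
    for (i in seq_len(cfg$n_per_group)) {
      p <- cfg$params
      p$seed <- derive_seed(cfg$seed, match(g, c("control", "mutant")), i)
      message(sprintf("[run_study] %s animal %d/%d", g, i, cfg$n_per_group))
      ss <- sample_state_sequence(p, preset, cfg$duration_s)
      sim <- synth_recording(ss$hypnogram, array, p, preset,
                             channels = cfg$channels)
      res <- analyze_animal(sim$rec, sim$hypnogram, array, cfg)
      res$genotype <- g
      res$animal <- sprintf("%s_%02d", g, i)
      animals[[res$animal]] <- res
    }
  }

  geno <- vapply(animals, `[[`, "", "genotype")
  bout_tab <- do.call(rbind, lapply(names(animals), function(a) {
    b <- animals[[a]]$bouts
    cbind(animal = a, genotype = animals[[a]]$genotype, b)
  }))

  bout_tests <- list()
  for (st in c("WAKE", "NREM", "REM"))
    for (m in c("percent_time", "n_bouts", "mean_bout_s")) {
      va <- bout_tab[bout_tab$state == st & bout_tab$genotype == "control", m]
      vb <- bout_tab[bout_tab$state == st & bout_tab$genotype == "mutant", m]
      if (all(is.finite(va)) && all(is.finite(vb)) &&
          stats::sd(c(va, vb)) > 0)
        bout_tests[[paste(st, m, sep = ".")]] <- t_test2(va, vb)
    }

  key <- sprintf("short_%dmm", min(cfg$thresholds_mm))
  gmat <- function(gn) t(vapply(animals[geno == gn], function(a)
    a$coherence_groups[[key]]$values, numeric(length(COH_GRID))))
  perm <- tryCatch(
    binwise_permutation(gmat("control"), gmat("mutant"),
                        n_perm = cfg$n_perm,
                        seed = derive_seed(cfg$seed, 99)),
    error = function(e) NULL)

  swd_pct <- vapply(animals, `[[`, 0, "swd_pct")
  mut <- geno == "mutant"
  wake_dur <- vapply(animals, function(a)
    a$bouts$mean_bout_s[a$bouts$state == "WAKE"], 0)
  coh1222 <- vapply(animals, function(a) {
    gs <- a$coherence_groups[[key]]
    mean(gs$values[gs$freq >= 12 & gs$freq <= 22])
  }, 0)
  correlations <- list(
    swd_vs_wake_bout_dur = tryCatch(pearson_r(swd_pct[mut], wake_dur[mut]),
                                    error = function(e) NULL),
    swd_vs_coh_12_22 = tryCatch(pearson_r(swd_pct[mut], coh1222[mut]),
                                error = function(e) NULL))

  hc <- vapply(animals, function(a)
    if (is.null(a$high_connectivity)) NA_real_
    else as.numeric(a$high_connectivity$n_supra_bins), 0)
  hc_test <- if (all(is.finite(hc)) && stats::sd(hc) > 0)
    t_test2(hc[!mut], hc[mut]) else NULL

  report <- list(config_hash = cfg_hash, seed = cfg$seed,
                 animals = animals, bout_table = bout_tab,
                 bout_tests = bout_tests, permutation = perm,
                 correlations = correlations,
                 high_connectivity = list(values = hc, test = hc_test))

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(df) { df$config_hash <- cfg_hash; df$seed <- cfg$seed; df }
    utils::write.csv(stamp(bout_tab),
                     file.path(cfg$outdir, "bout_statistics.csv"),
                     row.names = FALSE)
    coh_tab <- do.call(rbind, lapply(names(animals), function(a) {
      gs <- animals[[a]]$coherence_groups[[key]]
      data.frame(animal = a, genotype = animals[[a]]$genotype,
                 bin_hz = gs$freq, z_inv = gs$values)
    }))
    utils::write.csv(stamp(coh_tab),
                     file.path(cfg$outdir, "coherence_short.csv"),
                     row.names = FALSE)
    summary <- list(config_hash = cfg_hash, seed = cfg$seed,
                    bout_tests = bout_tests,
                    permutation_clusters = if (!is.null(perm)) perm$clusters,
                    correlations = correlations,
                    high_connectivity = list(
                      control = unname(hc[!mut]), mutant = unname(hc[mut]),
                      test = hc_test))
    jsonlite::write_json(summary, file.path(cfg$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(report)
}
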