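#' Default pipeline configuration
#'
#' Every numeric stage parameter under its conventional name, grouped by
#' stage. Presets select the two processing branches:
#' * `"roi_glm_branch"`: trim/resample to 4 Hz -> TDDR -> Beer-Lambert ->
#'   sensitivity-weighted ROI series -> FIR GLM with DTR modulator ->
#'   bin-averaged betas, contrasts and group models;
#' * `"image_branch"`: motion detection -> spline -> wavelet -> band-pass ->
#'   channel pruning -> Beer-Lambert -> 9-s epochs -> block averages and
#'   Tikhonov group images (no eye-tracking information).
#'
#' @param preset `"roi_glm_branch"` or `"image_branch"`.
#' @param seed Master seed; all per-subject seeds derive from it.
#' @param ... Named overrides of nested fields, e.g.
#'   `synth = list(n_subjects = 4)`. Unknown keys are rejected.
#' @return Named list of class `pipeline_config`.
#' @export
default_config <- function(preset = c("roi_glm_branch", "image_branch"),
                           seed = 1, ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset, seed = seed,
    synth = list(n_subjects = 31, n_anxiety = 25, n_trials = 27,
                 p_expected = 0.8, n_tiles = 12, rate_hz = 4.6,
                 gaze_rate_hz = 100, gaze_loss_rate = 0.05,
                 noise = default_noise_cfg(), anxiety = default_anxiety_cfg(),
                 coupling_b1 = 0.01),
    preprocess = list(tMotion = 1, tMask = 1, STDEV = 15, AMPthresh = 0.4,
                      p = 0.99, IQR = 0.8, DPF = 5.1,
                      f_lo = 0.01, f_hi = 0.5, target_hz = 4,
                      max_sep_mm = 60, cv_max = 8),
    recon = list(lam = 0.01, mua = 0.017, musp = 0.74, n_index = 1.4,
                 node_spacing_mm = 7, sep_range_mm = c(12, 45)),
    glm = list(basis = "fir", n_bins = 28, avg_bins = c(12, 24),
               fdr_q = 0.05, dtr_scale = c(0.1, 1), min_per_type = 3,
               hrf_peak_s = 4))
  merge_config(cfg, list(...))
}

merge_config <- function(cfg, over, path = "") {
  for (nm in names(over)) {
    if (!nm %in% names(cfg))
      stop_arg("unknown config key: ", paste0(path, nm))
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]] <- merge_config(cfg[[nm]], over[[nm]], paste0(path, nm, "$"))
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end pipeline on a synthetic cohort
#'
#' Generates a cohort under the configured study conditions and executes the
#' configured processing branch for every subject, then the group stage.
#' Deterministic given the configuration (including its seed); every output
#' carries the configuration hash in `provenance`.
#'
#' @param config A `pipeline_config` from [default_config()].
#' @return List of class `pipeline_result` with `tables` (data frames:
#'   `dtr`, `subject_log`, and per branch `contrasts`+`betas` or `images`),
#'   `fits` (group-stage models, ROI branch), `provenance` (config, hash,
#'   per-stage notes).
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "pipeline_config") || is.list(config))
  cfg <- config
  notes <- character()
  probe <- default_probe(n_tiles = cfg$synth$n_tiles)
  cohort <- generate_cohort(cfg$synth$n_subjects, cfg$synth$anxiety,
                            cfg$synth$coupling_b1, seed = cfg$seed,
                            n_anxiety = cfg$synth$n_anxiety)
  medium <- default_medium(cfg$recon$mua, cfg$recon$musp, cfg$recon$n_index)
  nodes <- default_node_grid(probe, spacing_mm = cfg$recon$node_spacing_mm)
  sens <- compute_sensitivity(probe, medium, nodes)
  roi_masks <- default_rois(nodes)
  roi_defs <- lapply(names(roi_masks), function(nm)
    roi_weights(sens, roi_masks[[nm]], name = nm,
                sep_range_mm = cfg$recon$sep_range_mm))
  dtr_rows <- list(); log_rows <- list(); beta_rows <- list(); image_acc <- NULL
  for (i in seq_len(cfg$synth$n_subjects)) {
    seed_i <- cfg$seed + 7919L * i
    schedule <- generate_trial_schedule(cfg$synth$n_trials, cfg$synth$p_expected,
                                        seed = seed_i)
    truth <- cohort_subject_truth(cohort, i)
    truth$dtr_true <- trial_dtr_truth(truth, schedule, seed = seed_i + 1L)
    gaze <- generate_gaze(schedule, truth, cfg$synth$gaze_rate_hz,
                          cfg$synth$gaze_loss_rate, seed = seed_i + 2L)
    dtr <- compute_dtr(gaze, schedule)
    incl <- subject_inclusion(dtr, schedule, cfg$glm$min_per_type)
    dtr_rows[[i]] <- data.frame(subject = i, trial = dtr$trial, type = dtr$type,
                                dtr = dtr$dtr, valid_time_s = dtr$valid_time_s,
                                include = incl$include)
    chd <- generate_channel_data(schedule, truth, probe, cfg$synth$noise,
                                 seed = seed_i + 3L, rate_hz = cfg$synth$rate_hz)
    log_rows[[i]] <- data.frame(
      subject = i, include = incl$include,
      usable_expected = incl$counts[["expected"]],
      usable_unexpected = incl$counts[["unexpected"]],
      planted_artifacts = nrow(chd$truth$artifacts),
      pruned_channels = NA_integer_, masked_s = NA_real_)
    if (!incl$include) next
    if (cfg$preset == "roi_glm_branch") {
      ts <- resample_trim(chd$ts, cfg$preprocess$target_hz, schedule)
      ts <- correct_tddr(ts)
      hb <- mbll(ts, dpf = cfg$preprocess$DPF)
      roi_ts <- roi_timeseries(hb, roi_defs)
      sd_scaled <- scale_dtr(dtr, cfg$glm$dtr_scale[1], cfg$glm$dtr_scale[2])
      des <- withCallingHandlers(
        build_design(schedule, sd_scaled, basis = cfg$glm$basis,
                     rate_hz = roi_ts$rate_hz, n_bins = cfg$glm$n_bins,
                     t0_s = roi_ts$t0_s, n_time = ncol(roi_ts$data),
                     hrf_peak_s = cfg$glm$hrf_peak_s),
        warning = function(w) {
          notes <<- c(notes, conditionMessage(w)); invokeRestart("muffleWarning")
        })
      for (r in seq_len(nrow(roi_ts$table))) {
        fit <- ar_irls_fit(roi_ts$data[r, ], des)
        bs <- average_bins(fit, cfg$glm$avg_bins[1], cfg$glm$avg_bins[2])
        beta_rows[[length(beta_rows) + 1L]] <- cbind(
          data.frame(subject = i, roi = roi_ts$table$roi[r],
                     chromophore = roi_ts$table$chromophore[r]),
          bs$summary, dof = bs$dof)
      }
    } else {
      mask <- detect_motion(chd$ts, cfg$preprocess$tMotion, cfg$preprocess$tMask,
                            cfg$preprocess$STDEV, cfg$preprocess$AMPthresh)
      ts <- correct_spline(chd$ts, mask, p = cfg$preprocess$p)
      ts <- correct_wavelet(ts, iqr_mult = cfg$preprocess$IQR)
      ts <- withCallingHandlers(
        bandpass(ts, cfg$preprocess$f_lo, cfg$preprocess$f_hi, strict = FALSE),
        warning = function(w) {
          notes <<- c(notes, conditionMessage(w)); invokeRestart("muffleWarning")
        })
      pr <- prune_channels(ts, probe, cfg$preprocess$max_sep_mm,
                           cfg$preprocess$cv_max, mask)
      hb_keep <- pr$keep
      ep <- block_average(ts, schedule)   # OD epochs
      win <- ep$times_s >= 3 & ep$times_s < 6
      subj_mean <- lapply(ep$means, function(m) rowMeans(m[, win, drop = FALSE]))
      subj_mean <- lapply(subj_mean, function(v) { v[!hb_keep] <- NA; v })
      if (is.null(image_acc)) image_acc <- list(expected = NULL, unexpected = NULL)
      for (cond in names(subj_mean))
        image_acc[[cond]] <- rbind(image_acc[[cond]], subj_mean[[cond]])
      log_rows[[i]]$pruned_channels <- sum(!pr$keep)
      log_rows[[i]]$masked_s <- sum(vapply(mask$segments, function(s)
        sum(s$end_s - s$start_s), numeric(1))) / nrow(chd$ts$data)
    }
  }
  tables <- list(dtr = do.call(rbind, dtr_rows),
                 subject_log = do.call(rbind, log_rows))
  fits <- list()
  if (cfg$preset == "roi_glm_branch" && length(beta_rows)) {
    betas <- do.call(rbind, beta_rows)
    tables$betas <- betas
    tables$contrasts <- roi_group_contrasts(betas, q = cfg$glm$fdr_q)
    dtab <- tables$dtr[tables$dtr$include & !is.na(tables$dtr$dtr), ]
    dtab$condition <- dtab$type
    fits$dtr_condition <- fit_random_intercept(dtab, "dtr", "condition")
    fits$dtr_habituation <- fit_random_intercept(dtab, "dtr", "trial * condition")
  } else if (!is.null(image_acc)) {
    wls <- sort(unique(probe$channels$wavelength_nm))
    imgs <- list()
    for (cond in names(image_acc)) {
      y_mean <- colMeans(image_acc[[cond]], na.rm = TRUE)
      y_mean[!is.finite(y_mean)] <- 0
      mua_img <- vapply(wls, function(wl) {
        sel <- probe$channels$wavelength_nm == wl
        tikhonov_reconstruct(sens$J[sel, , drop = FALSE], y_mean[sel],
                             lam = cfg$recon$lam)$x
      }, numeric(nrow(nodes)))
      hb_img <- unmix_images(mua_img)
      imgs[[cond]] <- data.frame(nodes, condition = cond,
                                 HbO = hb_img[, "HbO"], HbR = hb_img[, "HbR"])
    }
    tables$images <- do.call(rbind, imgs)
  }
  structure(list(tables = tables, fits = fits,
                 provenance = list(config = cfg, hash = config_hash(cfg),
                                   notes = unique(notes),
                                   package = as.character(utils::packageVersion("nidot")))),
            class = "pipeline_result")
}

#' Group-level ROI contrast table with BH correction
#'
#' One-sample group t-tests over subjects of the bin-averaged betas:
#' unexpected vs baseline and unexpected minus expected, per ROI, within
#' each chromophore — the 6 ROIs x 2 contrasts = 12 comparisons pooled by
#' the Benjamini-Hochberg correction.
#'
#' @param betas Data frame from the pipeline (`subject`, `roi`,
#'   `chromophore`, `condition`, `estimate`).
#' @param q False discovery rate (default 0.05).
#' @return Data frame: `roi`, `chromophore`, `contrast`, `estimate`, `se`,
#'   `t`, `dof`, `p`, `p_adj`, `reject`, `m`.
#' @export
roi_group_contrasts <- function(betas, q = 0.05) {
  out <- list()
  for (chrom in unique(betas$chromophore)) {
    rows <- list()
    for (roi in unique(betas$roi)) {
      b <- betas[betas$roi == roi & betas$chromophore == chrom, ]
      u <- b$estimate[b$condition == "unexpected"]
      e <- b$estimate[b$condition == "expected"]
      for (cn in c("U vs baseline", "U - E")) {
        v <- if (cn == "U vs baseline") u else u - e
        tt <- stats::t.test(v)
        rows[[length(rows) + 1L]] <- data.frame(
          roi = roi, chromophore = chrom, contrast = cn,
          estimate = mean(v), se = stats::sd(v) / sqrt(length(v)),
          t = unname(tt$statistic), dof = unname(tt$parameter),
          p = tt$p.value)
      }
    }
    tab <- do.call(rbind, rows)
    bh <- fdr_bh(tab$p, q = q)
    tab$p_adj <- bh$p_adjusted
    tab$reject <- bh$reject
    tab$m <- bh$m
    out[[chrom]] <- tab
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Write / read channel data as CSV matrix + channel table + JSON sidecar
#'
#' `<prefix>_data.csv` holds the channels x timepoints matrix,
#' `<prefix>_channels.csv` the channel table, `<prefix>_meta.json` the rate,
#' start time, kind and any generation parameters.
#'
#' @param ts A `channel_timeseries`.
#' @param prefix Path prefix.
#' @param meta Optional named list merged into the JSON sidecar.
#' @return `write_channels_csv()` returns `prefix` invisibly;
#'   `read_channels_csv()` returns a `channel_timeseries`.
#' @export
write_channels_csv <- function(ts, prefix, meta = list()) {
  utils::write.csv(ts$data, paste0(prefix, "_data.csv"), row.names = FALSE)
  utils::write.csv(ts$channel_table, paste0(prefix, "_channels.csv"),
                   row.names = FALSE)
  side <- c(list(rate_hz = ts$rate_hz, t0_s = ts$t0_s, kind = ts$kind), meta)
  jsonlite::write_json(side, paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_channels_csv
#' @export
read_channels_csv <- function(prefix) {
  dat <- as.matrix(utils::read.csv(paste0(prefix, "_data.csv")))
  tab <- utils::read.csv(paste0(prefix, "_channels.csv"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  channel_timeseries(unname(dat), meta$rate_hz, meta$t0_s, tab, meta$kind)
}

#' Write / read a trial schedule as a CSV event file
#'
#' Columns `onset_s` (cue onset), `duration_s` (cue + stimulus window) and
#' `type`; cue and stimulus durations travel in a JSON sidecar.
#'
#' @param schedule A `trial_schedule`.
#' @param path CSV path (`<path>.json` sidecar is written next to it).
#' @return `write_schedule_csv()` returns `path` invisibly;
#'   `read_schedule_csv()` returns a `trial_schedule`.
#' @export
write_schedule_csv <- function(schedule, path) {
  ev <- data.frame(onset_s = schedule$trials$cue_onset_s,
                   duration_s = schedule$cue_dur_s + schedule$stim_dur_s,
                   type = schedule$trials$type)
  utils::write.csv(ev, path, row.names = FALSE)
  jsonlite::write_json(list(cue_dur_s = schedule$cue_dur_s,
                            stim_dur_s = schedule$stim_dur_s,
                            baseline_range_s = schedule$baseline_range_s,
                            session_end_s = schedule$session_end_s),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  ev <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(trials = data.frame(cue_onset_s = ev$onset_s,
                                     stim_onset_s = ev$onset_s + meta$cue_dur_s,
                                     type = ev$type),
                 cue_dur_s = meta$cue_dur_s, stim_dur_s = meta$stim_dur_s,
                 baseline_range_s = meta$baseline_range_s,
                 session_end_s = meta$session_end_s),
            class = "trial_schedule")
}
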