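# End-to-end orchestration: preprocess -> FC inference -> ictogenicity ->
# cohort statistics, per subject and per cohort.

#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis. The `"paper"` profile
#' uses 4e6 integration steps per simulation; the `"test"` profile uses 2e5
#' (desk-scale). A `"custom"` profile accepts an explicit `n_steps`.
#'
#' @param profile `"paper"`, `"test"` or `"custom"`.
#' @param measure FC measure, `"pearson"` or `"h2"`.
#' @param alpha Significance level used throughout.
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it.
#' @param n_steps Integration steps; only honoured with
#'   `profile = "custom"`.
#' @param n_k Coupling-grid size for BNI curves (default 21).
#' @param n_surrogates IAAFT surrogates per channel (default 10).
#' @param n_realizations Noise realizations averaged per BNI* evaluation in
#'   calibration/resection (default 3).
#' @param i0,noise_sd,dt Theta-model parameters (see [theta_params()]).
#' @param target_fs Analysis sampling rate in Hz; recordings above it are
#'   down-sampled (default 512).
#' @param band,notch Filter edges in Hz (defaults 0.5-120 and 48-52).
#' @param bni_pre_target,bni_pre_tol Resection reference level and tolerance
#'   (defaults 0.5 and 0.05).
#' @param saturation_threshold BNI* level treated as saturation when fixing
#'   `[K1, K2]` (default 0.95).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(profile = c("test", "paper", "custom"),
                       measure = c("pearson", "h2"), alpha = 0.05,
                       seed = 1L, n_steps = NULL, n_k = 21L,
                       n_surrogates = 10L, n_realizations = 3L,
                       i0 = -1.2, noise_sd = 0.6, dt = 0.01,
                       target_fs = 512, band = c(0.5, 120),
                       notch = c(48, 52), bni_pre_target = 0.5,
                       bni_pre_tol = 0.05, saturation_threshold = 0.95) {
  profile <- match.arg(profile)
  measure <- match.arg(measure)
  steps <- switch(profile, paper = 4e6, test = 2e5, custom = n_steps)
  if (profile != "custom" && !is.null(n_steps) && n_steps != steps)
    stop("invalid config: `n_steps` can only be overridden with ",
         "profile = \"custom\"")
  if (is.null(steps)) stop("invalid config: custom profile needs `n_steps`")
  structure(list(profile = profile, measure = measure, alpha = alpha,
                 seed = seed, n_steps = as.integer(steps), n_k = as.integer(n_k),
                 n_surrogates = as.integer(n_surrogates),
                 n_realizations = as.integer(n_realizations), i0 = i0,
                 noise_sd = noise_sd, dt = dt, target_fs = target_fs,
                 band = band, notch = notch,
                 bni_pre_target = bni_pre_target, bni_pre_tol = bni_pre_tol,
                 saturation_threshold = saturation_threshold),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

preprocess_recording <- function(config, rec) {
  if (is.null(rec$annotations))
    stop("recording carries no epoch annotations")
  if (rec$fs > config$target_fs)
    rec <- resample_recording(rec, config$target_fs)
  rec <- rereference_median(rec)
  rec <- bandpass_notch_filter(rec, band = config$band, notch = config$notch)
  segment_peri_ictal(rec)
}

# FC networks for a list of segments; returns list of fc_network with
# midpoint times and epoch labels attached.
infer_segment_networks <- function(config, segments, seed_offset = 0L) {
  lapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    net <- segment_fc(seg, measure = config$measure,
                      n_surrogates = config$n_surrogates,
                      alpha = config$alpha,
                      seed = derive_seed(config$seed, seed_offset + i))
    net$time_s <- (seg$start_s + seg$end_s) / 2
    net$epoch <- seg$epoch_label
    net
  })
}

theta_params_from_config <- function(config, seed) {
  theta_params(i0 = config$i0, noise_sd = config$noise_sd, dt = config$dt,
               n_steps = config$n_steps, seed = seed)
}

# Mean FC over segments in the first half of the ictal period, pooled over
# both peri-ictal recordings: the substrate for the virtual resection.
ictal_first_half_fc <- function(networks_by_epoch, annotations_by_epoch) {
  mats <- list()
  for (e in seq_along(networks_by_epoch)) {
    ann <- annotations_by_epoch[[e]]
    mid <- (ann$seizure_onset_s + ann$seizure_offset_s) / 2
    for (net in networks_by_epoch[[e]])
      if (net$epoch == "ictal" && net$time_s <= mid)
        mats[[length(mats) + 1L]] <- net$weights
  }
  if (!length(mats)) {
    # fall back to every ictal segment when seizures are too short
    for (e in seq_along(networks_by_epoch))
      for (net in networks_by_epoch[[e]])
        if (net$epoch == "ictal")
          mats[[length(mats) + 1L]] <- net$weights
  }
  if (!length(mats)) stop("no ictal segments available for resection FC")
  Reduce(`+`, mats) / length(mats)
}

#' Run the full analysis for one subject
#'
#' Orchestrates, for each of the two peri-ictal recordings: preprocessing
#' (down-sampling, median re-reference, band-pass + notch), segmentation,
#' surrogate-corrected FC per segment, BNI curves with a per-subject fixed
#' coupling interval `[K1, K2]`, coupling-integrated and epoch-normalized
#' BNI time courses, and the per-epoch elevated-ictal test. The virtual
#' resection is scored on the mean FC of the first half of the ictal
#' periods, after calibrating the reference coupling to
#' `BNI* = bni_pre_target`.
#'
#' @param config A [run_config()].
#' @param recordings List of two annotated [recording()]s (the two
#'   peri-ictal epochs of the subject).
#' @param mask Integer indices of the resected channels; `NULL` skips the
#'   resection stage.
#' @param subject_id Optional identifier carried into the record.
#' @return A `"cohort_record"`: list with `subject_id`, `timecourses`
#'   (normalized, one per recording), `elevated` (per-epoch flags,
#'   p-values, subject flag), `k_interval`, `delta_bni`, `calibration`.
#' @export
run_subject <- function(config, recordings, mask = NULL,
                        subject_id = "subject") {
  stopifnot(inherits(config, "run_config"))
  if (length(recordings) != 2L)
    stop("exactly two peri-ictal recordings are required")
  segments <- lapply(seq_along(recordings), function(e)
    stage("preprocess", preprocess_recording(config, recordings[[e]])))
  networks <- lapply(seq_along(segments), function(e)
    stage("fc_inference",
          infer_segment_networks(config, segments[[e]],
                                 seed_offset = 10000L * e)))

  # -- fix [K1, K2] per subject from saturation scans of every segment
  # network. Segment significance graphs can leave nodes unattached, capping
  # BNI* below the nominal saturation level; if no segment reaches it, relax
  # the level stepwise rather than aborting the subject.
  scan_params <- theta_params_from_config(config, config$seed)
  scan_params$n_steps <- max(2000L, as.integer(config$n_steps / 4))
  k_sats <- NULL
  for (thr in config$saturation_threshold * c(1, 0.85, 0.6)) {
    k_sats <- stage("ictogenicity", unlist(lapply(networks, function(nets)
      vapply(nets, function(net)
        scan_k_saturation(net$weights, scan_params, threshold = thr),
        numeric(1)))))
    if (!all(is.na(k_sats))) {
      if (thr < config$saturation_threshold)
        warning("no segment network reaches BNI* >= ",
                config$saturation_threshold, "; coupling interval fixed at ",
                "the relaxed level ", signif(thr, 3), call. = FALSE)
      break
    }
  }
  if (all(is.na(k_sats)))
    stop("[stage ictogenicity] grid exhausted: no segment network saturates")
  k2 <- 1.2 * max(k_sats, na.rm = TRUE)
  k_grid <- seq(0, k2, length.out = config$n_k)

  # -- per-segment coupling-integrated BNI, then per-recording normalization
  timecourses <- stage("ictogenicity", lapply(seq_along(networks), function(e) {
    nets <- networks[[e]]
    bni <- vapply(seq_along(nets), function(i) {
      p <- theta_params_from_config(
        config, derive_seed(config$seed, 20000L * e + i))
      cv <- bni_curve(nets[[i]]$weights, p, k_grid)
      bni_integral(cv, 0, k2)
    }, numeric(1))
    tc <- bni_timecourse(vapply(nets, `[[`, numeric(1), "time_s"),
                         vapply(nets, `[[`, character(1), "epoch"), bni)
    normalize_timecourse(tc)
  }))

  elevated <- stage("cohort_stats", elevated_ictal_test(
    lapply(timecourses, function(tc)
      list(pre = tc$bni[tc$epoch == "preictal"],
           ictal = tc$bni[tc$epoch == "ictal"])),
    alpha = config$alpha))

  calibration <- NULL; resection <- NULL
  if (!is.null(mask) && length(mask)) {
    res <- tryCatch({
      fc_res <- ictal_first_half_fc(networks,
                                    lapply(recordings, `[[`, "annotations"))
      p <- theta_params_from_config(config, derive_seed(config$seed, 30000L))
      calibration <- calibrate_reference_coupling(
        fc_res, p, target = config$bni_pre_target, tol = config$bni_pre_tol,
        n_realizations = config$n_realizations)
      delta_bni(fc_res, mask, p, calibration$k_ref,
                n_realizations = config$n_realizations,
                bni_pre = calibration$bni_achieved)
    }, error = function(e) {
      warning("resection stage failed for ", subject_id, ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    resection <- res
  }

  structure(list(subject_id = subject_id, timecourses = timecourses,
                 elevated = elevated, k_interval = c(0, k2),
                 delta_bni = if (!is.null(resection)) resection$delta_bni,
                 resection = resection, calibration = calibration),
            class = "cohort_record")
}

# Align normalized time courses across epoch recordings: pre-ictal values
# indexed backwards from seizure onset, ictal always 10 points, post-ictal
# forwards from seizure offset; truncated to the common count.
align_timecourses <- function(tcs) {
  get_vals <- function(tc, lab) tc$bni[tc$epoch == lab]
  n_pre <- min(vapply(tcs, function(tc) sum(tc$epoch == "preictal"), integer(1)))
  n_post <- min(vapply(tcs, function(tc) sum(tc$epoch == "postictal"), integer(1)))
  pre <- do.call(rbind, lapply(tcs, function(tc)
    tail(get_vals(tc, "preictal"), n_pre)))
  ict <- do.call(rbind, lapply(tcs, function(tc) get_vals(tc, "ictal")))
  post <- do.call(rbind, lapply(tcs, function(tc)
    head(get_vals(tc, "postictal"), n_post)))
  m <- cbind(pre, ict, post)
  data.frame(
    index = seq_len(ncol(m)),
    epoch = rep(c("preictal", "ictal", "postictal"),
                c(n_pre, ncol(ict), n_post)),
    mean_bni = colMeans(m),
    se_bni = apply(m, 2L, sd) / sqrt(nrow(m)))
}

#' Run the full analysis for a cohort
#'
#' Applies [run_subject()] to every subject and assembles the cohort-level
#' statistics: the group BNI-versus-time summary (mean and standard error at
#' aligned peri-ictal time points), the Kruskal-Wallis comparison of pooled
#' epoch BNI, the elevated-ictal-versus-outcome table with its permutation
#' chi-square p-value, and the delta-BNI outcome classification (AUC within
#' the elevated and non-elevated groups, with the half-split comparison when
#' both groups support it).
#'
#' @param config A [run_config()].
#' @param cohort Either a [synthetic_spec()] (subjects are generated and
#'   processed one at a time) or the output of [generate_cohort()].
#' @param n_perm Permutations for the chi-square test (default 10000).
#' @return A `"cohort_report"`: list with `records`, `group_timecourse`,
#'   `kruskal_wallis`, `elevated_vs_outcome`, `auc` and `ground_truth`.
#' @export
run_cohort <- function(config, cohort, n_perm = 10000L) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(cohort, "synthetic_spec")) {
    spec <- cohort
    cohort <- generate_cohort(spec, recordings = FALSE)
    get_recs <- function(s) generate_subject_recordings(spec, s)
  } else {
    get_recs <- function(s) s$recordings
  }
  if (length(cohort) < 4L) stop("a cohort needs at least 4 subjects")

  records <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 1000000L + i)
    run_subject(cfg, get_recs(s), mask = s$ground_truth$resection_mask,
                subject_id = s$subject_id)
  })

  gt <- cohort_ground_truth(cohort)
  elevated <- vapply(records, function(r) r$elevated$elevated_ictal, logical(1))
  dbni <- vapply(records, function(r)
    if (is.null(r$delta_bni)) NA_real_ else r$delta_bni, numeric(1))
  gt$elevated_ictal <- elevated
  gt$delta_bni <- dbni

  all_tcs <- unlist(lapply(records, `[[`, "timecourses"), recursive = FALSE)
  group_tc <- align_timecourses(all_tcs)
  pool <- function(lab) unlist(lapply(all_tcs, function(tc)
    tc$bni[tc$epoch == lab]))
  kw <- kruskal_wallis_epochs(pool("preictal"), pool("ictal"),
                              pool("postictal"))

  outcome <- gt$good_outcome
  elev_block <- NULL
  if (min(sum(outcome), sum(!outcome)) >= 2L &&
      sum(elevated) > 0L && sum(!elevated) > 0L) {
    elev_block <- permutation_chi_square(elevated, outcome, n_perm = n_perm,
                                         seed = derive_seed(config$seed, 42L))
  } else {
    warning("elevated-vs-outcome statistics skipped: degenerate table",
            call. = FALSE)
  }

  auc_block <- NULL
  auc_for <- function(keep) {
    if (sum(keep) >= 2L && length(unique(outcome[keep])) == 2L)
      roc_auc(dbni[keep], outcome[keep]) else NA_real_
  }
  auc_elev <- auc_for(elevated & !is.na(dbni))
  auc_nelev <- auc_for(!elevated & !is.na(dbni))
  split_cmp <- NULL
  ok_a <- elevated & !is.na(dbni); ok_b <- !elevated & !is.na(dbni)
  if (sum(ok_a) >= 4L && sum(ok_b) >= 4L &&
      length(unique(outcome[ok_a])) == 2L &&
      length(unique(outcome[ok_b])) == 2L) {
    split_cmp <- half_split_auc_compare(dbni[ok_a], outcome[ok_a],
                                        dbni[ok_b], outcome[ok_b])
  }
  auc_block <- list(auc_elevated = auc_elev, auc_non_elevated = auc_nelev,
                    half_split = split_cmp)

  structure(list(records = records, ground_truth = gt,
                 group_timecourse = group_tc, kruskal_wallis = kw,
                 elevated_vs_outcome = elev_block, auc = auc_block),
            class = "cohort_report")
}

#' Serialize a cohort report to JSON
#'
#' Writes the statistics blocks of a [run_cohort()] report (not the
#' per-segment artifacts) as JSON.
#'
#' @param report A `"cohort_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_report <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  out <- list(
    ground_truth = report$ground_truth,
    group_timecourse = report$group_timecourse,
    kruskal_wallis = report$kruskal_wallis,
    elevated_vs_outcome = if (!is.null(report$elevated_vs_outcome))
      list(p.value = report$elevated_vs_outcome$p.value,
           statistic = report$elevated_vs_outcome$statistic,
           table = report$elevated_vs_outcome$table),
    auc = list(auc_elevated = report$auc$auc_elevated,
               auc_non_elevated = report$auc$auc_non_elevated,
               half_split_p = if (!is.null(report$auc$half_split))
                 report$auc$half_split$p.value))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
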