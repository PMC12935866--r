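# End-to-end study orchestration: two cohorts -> per-subject summaries ->
# group tubes, phase-resolved SPM table, scalar metric table and the
# correlation/Fisher panel.  All randomness flows from the config seed.

#' Run configuration for a full two-group study
#'
#' Validates every tunable of the end-to-end pipeline up front.  Profiles
#' are referenced by preset name (`"control"`, `"pad"`); custom
#' [gait_profile()] objects can be supplied directly to
#' [run_full_study()].
#'
#' @param n_control,n_pad cohort sizes (>= 4 each).
#' @param n_strides complete gait cycles per subject (>= 2).
#' @param T normalized resolution (points per cycle).
#' @param cutoff,filter_order zero-phase low-pass settings for marker
#'   positions (Hz / order); cutoff must be below half the profile rate.
#' @param threshold heel-strike detection threshold, N.
#' @param k ellipsoid SD-scaling constant.
#' @param window tube smoothing window, percent of cycle.
#' @param alpha significance level.
#' @param n_perm SPM permutation budget.
#' @param seed master seed (all cohort, subject and SPM seeds derive from
#'   it); must leave room for small offsets below 2^31.
#' @param control_profile,pad_profile preset names.
#' @param out_dir optional output directory for artifacts.
#' @return validated list of class `gts_config`.
#' @export
gts_config <- function(n_control = 132, n_pad = 52, n_strides = 90,
                       T = 101, cutoff = 6, filter_order = 4,
                       threshold = 20, k = 1, window = 5, alpha = 0.05,
                       n_perm = 10000, seed = 1,
                       control_profile = "control", pad_profile = "pad",
                       out_dir = NULL) {
  stopifnot(n_control >= 4, n_pad >= 4, n_strides >= 2, T >= 11,
            cutoff > 0, filter_order >= 1, threshold > 0, k > 0,
            window >= 0, window <= 100, alpha > 0, alpha < 1,
            n_perm >= 100)
  if (!is.numeric(seed) || seed < 0 || seed > 2^31 - 10) {
    stop("seed must be a non-negative integer below 2^31 - 10")
  }
  structure(list(
    n_control = as.integer(n_control), n_pad = as.integer(n_pad),
    n_strides = as.integer(n_strides), T = as.integer(T),
    cutoff = cutoff, filter_order = as.integer(filter_order),
    threshold = threshold, k = k, window = window, alpha = alpha,
    n_perm = as.integer(n_perm), seed = as.integer(seed),
    control_profile = control_profile, pad_profile = pad_profile,
    out_dir = out_dir
  ), class = "gts_config")
}

# per-subject analysis: stride extraction + summaries + tube ingredients
analyze_subject <- function(trial, config) {
  strides <- extract_strides(trial, T = config$T, cutoff = config$cutoff,
                             order = config$filter_order,
                             threshold = config$threshold)
  cs <- stride_covariance(strides)
  list(summary = subject_summary(strides, k = config$k),
       volume_waveform = volume_waveform(cs, k = config$k),
       mean_trajectory = apply(strides$values, c(2, 3), mean),
       Sigma = cs$Sigma,
       dropped = attr(strides, "dropped"))
}

analyze_cohort <- function(trials, config, group) {
  log <- list()
  res <- vector("list", length(trials))
  for (s in seq_along(trials)) {
    res[[s]] <- tryCatch(analyze_subject(trials[[s]], config),
                         error = function(e) e)
    if (inherits(res[[s]], "error")) {
      log[[length(log) + 1]] <- list(group = group, subject = s,
                                     event = "subject_dropped",
                                     reason = conditionMessage(res[[s]]))
      res[[s]] <- NULL
    } else if (nrow(res[[s]]$dropped) > 0) {
      d <- res[[s]]$dropped
      for (i in seq_len(nrow(d))) {
        log[[length(log) + 1]] <- list(group = group, subject = s,
                                       event = "cycle_dropped",
                                       cycle = d$cycle[i],
                                       reason = d$reason[i])
      }
    }
  }
  res <- Filter(Negate(is.null), res)
  if (length(res) < 4) {
    stop(sprintf("group '%s' fell below 4 analyzable subjects", group))
  }
  list(results = res, log = log)
}

# group grand-mean tube: mean of subject mean trajectories, with the
# across-stride covariance averaged over subjects
group_gait_tube <- function(results, k, window) {
  mt <- Reduce(`+`, lapply(results, `[[`, "mean_trajectory")) / length(results)
  Sg <- Reduce(`+`, lapply(results, `[[`, "Sigma")) / length(results)
  colnames(mt) <- GT_AXES
  gait_tube_from_parts(mt, Sg, k = k, window = window)
}

#' Run the full two-group study
#'
#' Simulates both cohorts from their profiles, analyzes every subject
#' through the signal-preparation and gait-tube stages, and assembles the
#' group-level outputs: per-subject summaries, scalar metric comparison
#' (Wilcoxon, correlations, Fisher r-to-z), permutation SPM of the
#' ellipsoid-volume waveform with the per-phase significance table, the
#' control-minus-patient difference waveform, and the two grand-mean gait
#' tubes.  Subjects failing quality gates are dropped and logged; the run
#' aborts if a group falls below 4 subjects.  Re-running with the same
#' config reproduces the result exactly.
#'
#' @param config a [gts_config()].
#' @param control_profile,pad_profile optional [gait_profile()] objects
#'   overriding the preset names in the config.
#' @return object of class `gts_study` with elements `config`,
#'   `summaries` (per group), `comparison` (a `group_comparison`), `spm`
#'   (an `spm_result`), `phase_table`, `group_waveforms` (volume mean/SD
#'   bands per group), `difference_waveform`, `tubes` (per group) and
#'   `log`.
#' @export
run_full_study <- function(config = gts_config(),
                           control_profile = NULL, pad_profile = NULL) {
  stopifnot(inherits(config, "gts_config"))
  profA <- if (is.null(control_profile)) preset_profile(config$control_profile)
           else control_profile
  profB <- if (is.null(pad_profile)) preset_profile(config$pad_profile)
           else pad_profile

  cohortA <- generate_cohort(profA, config$n_control,
                             n_strides = config$n_strides,
                             seed = config$seed)
  cohortB <- generate_cohort(profB, config$n_pad,
                             n_strides = config$n_strides,
                             seed = config$seed + 1L)
  resA <- analyze_cohort(cohortA, config, "control")
  resB <- analyze_cohort(cohortB, config, "pad")

  sumA <- lapply(resA$results, `[[`, "summary")
  sumB <- lapply(resB$results, `[[`, "summary")
  comparison <- compare_groups(sumA, sumB, alpha = config$alpha)

  volA <- do.call(rbind, lapply(resA$results, `[[`, "volume_waveform"))
  volB <- do.call(rbind, lapply(resB$results, `[[`, "volume_waveform"))
  spm <- spm_two_sample(volA, volB, alpha = config$alpha,
                        n_perm = config$n_perm, seed = config$seed + 2L)

  gwA <- group_mean_waveforms(lapply(resA$results, `[[`, "volume_waveform"))
  gwB <- group_mean_waveforms(lapply(resB$results, `[[`, "volume_waveform"))

  study <- structure(list(
    config = config,
    summaries = list(control = sumA, pad = sumB),
    comparison = comparison,
    spm = spm,
    phase_table = spm$per_phase,
    group_waveforms = list(control = gwA, pad = gwB),
    difference_waveform = difference_waveform(gwA$mean, gwB$mean),
    tubes = list(control = group_gait_tube(resA$results, config$k, config$window),
                 pad = group_gait_tube(resB$results, config$k, config$window)),
    log = c(resA$log, resB$log)
  ), class = "gts_study")
  if (!is.null(config$out_dir)) write_study(study, config$out_dir)
  study
}

#' @export
print.gts_study <- function(x, ...) {
  cat(sprintf("<gts_study> %d control vs %d patient subjects, %d strides each\n",
              length(x$summaries$control), length(x$summaries$pad),
              x$config$n_strides))
  print(x$comparison)
  cat(sprintf("  SPM: %d/%d gait phases significant at alpha %.3g\n",
              sum(x$phase_table$significant), nrow(x$phase_table),
              x$config$alpha))
  invisible(x)
}

# write the study artifact bundle (JSON/CSV) to a directory
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summ_df <- function(lst, group) {
    do.call(rbind, lapply(seq_along(lst), function(i) {
      s <- lst[[i]]
      data.frame(group = group, subject = i,
                 mean_ellipsoid_volume = s$mean_ellipsoid_volume,
                 var_ap = s$var_ap, var_ml = s$var_ml, var_vt = s$var_vt,
                 total_variability = s$total_variability)
    }))
  }
  utils::write.csv(rbind(summ_df(study$summaries$control, "control"),
                         summ_df(study$summaries$pad, "pad")),
                   file.path(dir, "subject_summaries.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    metrics = study$comparison$metrics,
    correlations = lapply(study$comparison$correlations, function(cc)
      list(r = cc$r, p = cc$p, n = cc$n)),
    fisher = study$comparison$fisher
  ), file.path(dir, "comparison.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    t_waveform = study$spm$t_waveform,
    critical_threshold = study$spm$critical_threshold,
    clusters = study$spm$clusters,
    per_phase = study$phase_table,
    n_permutations = study$spm$n_permutations
  ), file.path(dir, "spm.json"), auto_unbox = TRUE, digits = NA)
  T <- length(study$group_waveforms$control$mean)
  utils::write.csv(data.frame(
    t_pct = seq(0, 100, length.out = T),
    control_mean = study$group_waveforms$control$mean,
    control_sd = study$group_waveforms$control$sd,
    pad_mean = study$group_waveforms$pad$mean,
    pad_sd = study$group_waveforms$pad$sd,
    difference = study$difference_waveform
  ), file.path(dir, "volume_waveforms.csv"), row.names = FALSE)
  for (g in names(study$tubes)) {
    tube <- study$tubes[[g]]
    utils::write.csv(cbind(
      data.frame(t_pct = tube$cross_sections$t_pct),
      stats::setNames(as.data.frame(tube$mean_trajectory),
                      paste0("v_", GT_AXES)),
      stats::setNames(as.data.frame(tube$frames$tangent), paste0("tan_", GT_AXES)),
      stats::setNames(as.data.frame(tube$frames$normal), paste0("nor_", GT_AXES)),
      stats::setNames(as.data.frame(tube$frames$binormal), paste0("bin_", GT_AXES)),
      tube$cross_sections[, c("semi_major", "semi_minor", "angle", "area")]
    ), file.path(dir, sprintf("tube_%s.csv", g)), row.names = FALSE)
  }
  write_config(study$config, file.path(dir, "config.yaml"))
  jsonlite::write_json(study$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
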