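#' Pipeline configuration
#'
#' Bundles every stage's tunables with their defaults: the synthetic
#' session configuration, optical constants, filter settings (6.5 Hz
#' neural low-pass; 0.25 Hz hemodynamic low-pass; order 20, 0.2 dB
#' ripple), the 1.5-s hemodynamic lag, the 10-s correlation window with
#' single-frame step, parcellation size, and the state-fit settings.
#'
#' @param sim a [sim_config()].
#' @param optics an [optical_model()].
#' @param neural_lowpass_hz,hemo_lowpass_hz,filter_order,filter_ripple_db
#'   temporal filter settings.
#' @param lag_s hemodynamic lag applied to hemoglobin signals.
#' @param window_s,step_frames correlation window settings.
#' @param k_per_hemisphere parcellation size; `NULL` uses the generator's
#'   parcel count (so planted parcels are recoverable 1:1).
#' @param replicates k-means restarts for parcellation.
#' @param cv_folds state-fit cross-validation folds.
#' @param signal which signal to correlate: `"neural"` or `"hbt"`.
#' @param use_true_labels extract ROI time courses from the ground-truth
#'   parcel labels instead of re-estimating them (useful when the stage of
#'   interest is downstream of parcellation).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), optics = default_optics(),
                            neural_lowpass_hz = 6.5, hemo_lowpass_hz = 0.25,
                            filter_order = 20L, filter_ripple_db = 0.2,
                            lag_s = 1.5, window_s = 10, step_frames = 1L,
                            k_per_hemisphere = NULL, replicates = 10L,
                            cv_folds = 5L, signal = c("neural", "hbt"),
                            use_true_labels = FALSE) {
  structure(list(sim = sim, optics = optics,
                 neural_lowpass_hz = neural_lowpass_hz,
                 hemo_lowpass_hz = hemo_lowpass_hz,
                 filter_order = as.integer(filter_order),
                 filter_ripple_db = filter_ripple_db,
                 lag_s = lag_s, window_s = window_s,
                 step_frames = as.integer(step_frames),
                 k_per_hemisphere = k_per_hemisphere,
                 replicates = as.integer(replicates),
                 cv_folds = as.integer(cv_folds),
                 signal = match.arg(signal),
                 use_true_labels = use_true_labels),
            class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Orchestrates the stages in order: simulate a session, convert raw
#' channels (baseline normalization, Beer-Lambert hemoglobin conversion,
#' hemodynamic fluorescence correction), parcellate, extract and filter
#' ROI time courses, compute moving-window correlation maps, fit the
#' behavioral correlation states by cross-validated NNLS, and run the
#' resting-state analyses. Later stages reuse earlier artifacts; results
#' are deterministic given the configuration.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of
#'   `c("simulate", "convert", "preprocess", "parcellate", "correlate",
#'   "fit_states", "stats")`; earlier stages a requested stage depends on
#'   are run automatically.
#' @param out_dir optional directory: writes the resolved configuration
#'   (YAML), behavior and state-coefficient CSVs there.
#' @return named list of stage artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "convert", "preprocess",
                                    "parcellate", "correlate", "fit_states",
                                    "stats"),
                         out_dir = NULL) {
  all_stages <- c("simulate", "convert", "preprocess", "parcellate",
                  "correlate", "fit_states", "stats")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  last <- max(match(stages, all_stages))
  run <- all_stages[seq_len(last)]
  art <- list(config = config)

  session <- simulate_session(config$sim, config$optics)
  art$session <- session
  if (last == 1L) return(finish_pipeline(art, out_dir))

  fr <- config$sim$frame_rate
  norm <- normalize_session(session$raw)
  hemo <- convert_hemoglobin(norm$green_norm, norm$red_norm, config$optics, fr)
  fl <- correct_fluorescence(norm$fluor_norm, norm$green_norm, norm$red_norm,
                             config$optics$Pg, config$optics$Pr, fr)
  art$hemo <- hemo; art$fluor <- fl
  if (last == 2L) return(finish_pipeline(art, out_dir))

  bouts <- detect_bouts(session$behavior$wheel_velocity, fr)
  art$bouts <- bouts
  rest <- abs(session$behavior$wheel_velocity) <= attr(bouts, "threshold")

  if (config$use_true_labels) {
    parc <- parcellation_map(session$truth$parcel_labels,
                             session$truth$bilateral_pairs,
                             provenance = list(source = "ground truth"))
  } else {
    k <- config$k_per_hemisphere %||% config$sim$n_parcels_per_hemisphere
    parc <- parcellate_session(fl$dff, config$sim$image_shape, k,
                               replicates = config$replicates,
                               rest_frames = which(rest),
                               gap = config$sim$midline_gap,
                               seed = config$sim$seed)
  }
  art$parcellation <- parc

  roi_raw <- extract_roi_timecourses(fl$dff, parc, fr, "raw")
  lp <- filter_spec("lowpass", config$neural_lowpass_hz,
                    order = config$filter_order, ripple_db = config$filter_ripple_db)
  neural <- roi_matrix(zero_phase_filter(roi_raw$values, lp, fr), fr, "neural_dff")
  hbt_roi <- extract_roi_timecourses(hemo$d_hbt, parc, fr, "raw")
  lp_h <- filter_spec("lowpass", config$hemo_lowpass_hz,
                      order = config$filter_order, ripple_db = config$filter_ripple_db)
  hbt_f <- zero_phase_filter(zero_phase_filter(hbt_roi$values, lp, fr), lp_h, fr)
  lagged <- apply_lag(hbt_f, config$lag_s, fr)
  art$roi_neural <- neural
  art$roi_hbt <- roi_matrix(hbt_f, fr, "hbt")
  art$hbt_lag <- lagged
  if (last <= 4L) return(finish_pipeline(art, out_dir))

  roi <- if (config$signal == "neural") neural else art$roi_hbt
  cs <- windowed_correlation(roi, window_s = config$window_s,
                             step_frames = config$step_frames,
                             detrend = config$signal == "hbt")
  art$corr_series <- cs
  if (last == 5L) return(finish_pipeline(art, out_dir))

  wins <- extract_state_windows(bouts, fr, ncol(roi$values),
                                window_s = config$window_s)
  art$state_windows <- wins
  fit <- fit_states_nnls(cs, windows = wins, cv_folds = config$cv_folds,
                         seed = config$sim$seed)
  art$state_fit <- fit
  if (last == 6L) return(finish_pipeline(art, out_dir))

  epochs <- detect_rest_epochs(session$behavior$wheel_velocity, fr)
  art$rest_epochs <- epochs
  if (nrow(epochs)) {
    art$reciprocity <- suppressWarnings(rest_reciprocity(fit, epochs))
    art$arousal <- suppressWarnings(
      arousal_association(fit, session$behavior$pupil_diameter, epochs))
  }
  finish_pipeline(art, out_dir)
}

finish_pipeline <- function(art, out_dir) {
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- art$config
    yaml::write_yaml(list(
      sim = unclass(cfg$sim),
      filters = list(neural_lowpass_hz = cfg$neural_lowpass_hz,
                     hemo_lowpass_hz = cfg$hemo_lowpass_hz,
                     order = cfg$filter_order, ripple_db = cfg$filter_ripple_db),
      lag_s = cfg$lag_s, window_s = cfg$window_s, step_frames = cfg$step_frames,
      signal = cfg$signal, cv_folds = cfg$cv_folds,
      Pg = cfg$optics$Pg, Pr = cfg$optics$Pr
    ), file.path(out_dir, "resolved_config.yaml"))
    if (!is.null(art$session))
      write_behavior_csv(art$session$behavior, file.path(out_dir, "behavior.csv"))
    if (!is.null(art$state_fit)) {
      co <- art$state_fit$coefficients
      utils::write.csv(
        data.frame(center_frame = art$state_fit$centers, t(co)),
        file.path(out_dir, "state_coefficients.csv"), row.names = FALSE)
    }
  }
  art
}
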