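# shared synthetic-session fixtures, generated once per test run

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, config) {
  if (is.null(.session_cache[[key]]))
    .session_cache[[key]] <- suppressWarnings(simulate_session(config))
  .session_cache[[key]]
}

## small 5-min session used by several test files
small_session <- function() {
  cached_session("small",
                 sim_config(duration_s = 300, image_shape = c(24, 26), seed = 7))
}

## 10-min parcel-scale session for the state analyses
state_session <- function() {
  cached_session("state",
                 sim_config(duration_s = 600, image_shape = c(20, 22), seed = 3))
}

## ROI time courses from the ground-truth labels of a session
truth_roi <- function(ses, filtered = TRUE) {
  parc <- parcellation_map(ses$truth$parcel_labels, ses$truth$bilateral_pairs)
  roi <- extract_roi_timecourses(ses$truth$true_F, parc, ses$config$frame_rate, "raw")
  if (!filtered) return(roi)
  lp <- filter_spec("lowpass", 6.5)
  roi_matrix(zero_phase_filter(roi$values, lp, ses$config$frame_rate),
             ses$config$frame_rate, "neural_dff")
}
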