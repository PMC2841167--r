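#' Construct a gaze recording
#'
#' A gaze recording is one trial's raw eye-tracker output: sample times,
#' gaze position in stimulus-image pixel coordinates (origin top-left,
#' x rightward, y downward, 0-based, floating point), and a pupil signal in
#' which `NA` marks lost samples (blinks, track loss). The calibration scalar
#' `px_per_deg` converts pixels to degrees of visual angle; the default 25
#' corresponds to a 390-px-tall image subtending 15.6 degrees.
#'
#' @param t sample times in ms, strictly increasing and uniformly spaced
#' @param x,y gaze position in image pixels
#' @param pupil pupil signal; `NA` = missing sample
#' @param rate sampling rate in Hz (default 1000)
#' @param px_per_deg pixels per degree of visual angle (default 25)
#' @param trial_id trial identifier
#' @return an object of class `gaze_recording`
#' @export
gaze_recording <- function(t, x, y, pupil = rep(1, length(t)),
                           rate = 1000, px_per_deg = 25,
                           trial_id = "trial") {
  n <- length(t)
  if (length(x) != n || length(y) != n || length(pupil) != n)
    stop_gm("t, x, y and pupil must have equal length")
  if (n >= 2 && any(diff(t) <= 0))
    stop_gm("sample times must be strictly increasing (trial %s)", trial_id)
  if (rate <= 0) stop_gm("rate must be positive")
  if (px_per_deg <= 0) stop_gm("px_per_deg must be positive")
  if (any(is.na(x)) || any(is.na(y)))
    stop_gm("gaze coordinates must not contain NA (trial %s)", trial_id)
  structure(
    list(trial_id = trial_id, t = as.numeric(t), x = as.numeric(x),
         y = as.numeric(y), pupil = as.numeric(pupil),
         rate = rate, px_per_deg = px_per_deg),
    class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording '%s': %d samples @ %g Hz, %.0f ms, %g px/deg, %d missing>\n",
              x$trial_id, length(x$t), x$rate,
              if (length(x$t)) diff(range(x$t)) + 1000 / x$rate else 0,
              x$px_per_deg, sum(is.na(x$pupil))))
  invisible(x)
}

#' Event-parser settings
#'
#' Kinematic thresholds and merging rules for the saccade/blink/fixation
#' parser. The defaults are the standard tracker settings: a sample is
#' saccadic when velocity exceeds 30 deg/s or acceleration exceeds
#' 4000 deg/s^2; saccades closer than 20 ms and 0.30 deg are merged; three
#' or more consecutive missing-pupil samples define a blink.
#'
#' @param v_thresh saccade velocity threshold, deg/s
#' @param a_thresh saccade acceleration threshold, deg/s^2
#' @param merge_gap maximum temporal gap for saccade merging, ms
#' @param merge_dist maximum spatial gap for saccade merging, deg
#' @param blink_min_missing minimum run of missing pupil samples for a blink
#' @param v_smooth_window optional centred moving-average window (samples,
#'   odd) applied to the speed trace before thresholding; 1 = no smoothing
#' @return an object of class `parser_spec`
#' @export
parser_spec <- function(v_thresh = 30, a_thresh = 4000, merge_gap = 20,
                        merge_dist = 0.30, blink_min_missing = 3,
                        v_smooth_window = 1) {
  vals <- c(v_thresh, a_thresh, merge_gap, merge_dist, blink_min_missing,
            v_smooth_window)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_gm("all parser_spec parameters must be strictly positive")
  if (v_smooth_window %% 2 != 1)
    stop_gm("v_smooth_window must be odd")
  structure(list(v_thresh = v_thresh, a_thresh = a_thresh,
                 merge_gap = merge_gap, merge_dist = merge_dist,
                 blink_min_missing = as.integer(blink_min_missing),
                 v_smooth_window = as.integer(v_smooth_window)),
            class = "parser_spec")
}
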