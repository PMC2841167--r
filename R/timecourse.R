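#' Time-course analysis settings
#'
#' @param B number of bootstrap resamples (default 5000; >= 1000 required
#'   for inference)
#' @param alpha confidence level complement (default 0.05 -> 95% CI)
#' @param time_grid evaluation grid: absolute ms (learning, default 0-10 s in
#'   10 ms bins) or normalised percent (recognition, 0-100 in 1% bins)
#' @param area_normalize divide frequencies by the ROI area in px^2
#' @param gaps how saccade/blink periods count: `"zero"` (not in ROI) or
#'   `"exclude"` (dropped from the trial denominator)
#' @return an object of class `timecourse_spec`
#' @export
timecourse_spec <- function(B = 5000, alpha = 0.05,
                            time_grid = seq(0, 10000, by = 10),
                            area_normalize = TRUE,
                            gaps = c("zero", "exclude")) {
  if (B < 1) stop_gm("B must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_gm("alpha must lie in (0, 1)")
  if (is.unsorted(time_grid, strictly = TRUE)) stop_gm("time_grid must be increasing")
  structure(list(B = as.integer(B), alpha = alpha, time_grid = time_grid,
                 area_normalize = area_normalize, gaps = match.arg(gaps)),
            class = "timecourse_spec")
}

#' Rescale one trial's events to a normalised 0-100% time base
#'
#' Divides onsets/offsets by the trial's response time and maps them to
#' percent, so trials of different durations can be aggregated on a common
#' grid (used for the recognition phase, where viewing time varies).
#'
#' @param events event data.frame for a single trial
#' @param rt response time (= trial duration), ms
#' @return events with `onset`, `offset`, `duration` in percent of `rt`
#' @export
normalize_time <- function(events, rt) {
  if (!is.numeric(rt) || length(rt) != 1 || is.na(rt) || rt <= 0)
    stop_gm("rt must be a positive scalar")
  ev <- as.data.frame(events)
  ev$onset <- ev$onset / rt * 100
  ev$offset <- ev$offset / rt * 100
  ev$duration <- ev$offset - ev$onset
  ev
}

#' Frequency of fixations inside an ROI over time, per observer
#'
#' At each grid time the proportion of the observer's trials whose current
#' fixation centroid falls inside the ROI, optionally divided by the ROI
#' area in px^2. Trials are identified by `trial_id`; times outside a
#' trial's span never count as in-ROI.
#'
#' @param events event data.frame for one observer (all trials, on the same
#'   time base as `spec$time_grid`)
#' @param roi_mask logical matrix marking ROI pixels
#' @param spec a [timecourse_spec()]
#' @return numeric vector of length `length(spec$time_grid)`
#' @export
fixation_frequency <- function(events, roi_mask, spec = timecourse_spec()) {
  if (!any(roi_mask)) stop_gm("empty ROI")
  H <- nrow(roi_mask); W <- ncol(roi_mask)
  area <- sum(roi_mask)
  ev <- as.data.frame(events)
  fx <- ev[ev$kind == "fixation", , drop = FALSE]
  grid <- spec$time_grid
  trials <- unique(ev$trial_id)
  in_roi <- matrix(0, length(trials), length(grid))
  counted <- matrix(TRUE, length(trials), length(grid))
  for (i in seq_along(trials)) {
    tr_all <- ev[ev$trial_id == trials[i], , drop = FALSE]
    if (max(tr_all$offset) <= min(tr_all$onset)) {
      warning(sprintf("skipping zero-duration trial %s", trials[i]))
      counted[i, ] <- FALSE
      next
    }
    span <- grid >= min(tr_all$onset) & grid < max(tr_all$offset)
    counted[i, !span] <- FALSE
    tr <- fx[fx$trial_id == trials[i], , drop = FALSE]
    if (nrow(tr) == 0) next
    col <- pmin(pmax(round(tr$x), 0), W - 1) + 1L
    row <- pmin(pmax(round(tr$y), 0), H - 1) + 1L
    hit <- roi_mask[(col - 1L) * H + row]
    # which fixation (if any) is active at each grid time
    k <- findInterval(grid, tr$onset)
    active <- logical(length(grid))
    sel <- k >= 1
    active[sel] <- grid[sel] < tr$offset[k[sel]]
    in_roi[i, active] <- hit[k[active]]
    if (spec$gaps == "exclude") counted[i, span & !active] <- FALSE
  }
  denom <- colSums(counted)
  f <- ifelse(denom > 0, colSums(in_roi) / pmax(denom, 1), 0)
  if (spec$area_normalize) f <- f / area
  f
}

#' Percentile-bootstrap inference on a group difference of time courses
#'
#' Resamples observers with replacement independently within each group `B`
#' times, recomputes the group-mean difference curve for every resample, and
#' forms pointwise percentile confidence intervals; a time point is flagged
#' significant when its CI excludes zero. No correction across time points
#' is applied (pointwise inference).
#'
#' @param curves_a,curves_b numeric matrices, observers x time
#' @param spec a [timecourse_spec()]
#' @param seed optional RNG seed for reproducibility
#' @return list with `mean_diff`, `lo`, `hi`, `significant` (vectors over
#'   time), and `B`, `alpha`
#' @export
bootstrap_difference <- function(curves_a, curves_b, spec = timecourse_spec(),
                                 seed = NULL) {
  curves_a <- as.matrix(curves_a); curves_b <- as.matrix(curves_b)
  na <- nrow(curves_a); nb <- nrow(curves_b)
  if (na < 2 || nb < 2) stop_gm("need >= 2 observers per group")
  if (ncol(curves_a) != ncol(curves_b)) stop_gm("time grids must match")
  if (!is.null(seed)) set.seed(seed)
  B <- spec$B
  # resampling observers with replacement == multinomial weights on rows
  Wa <- t(stats::rmultinom(B, na, rep(1, na))) / na
  Wb <- t(stats::rmultinom(B, nb, rep(1, nb))) / nb
  boot <- Wa %*% curves_a - Wb %*% curves_b
  qs <- apply(boot, 2, stats::quantile,
              probs = c(spec$alpha / 2, 1 - spec$alpha / 2), names = FALSE)
  lo <- qs[1, ]; hi <- qs[2, ]
  list(mean_diff = colMeans(curves_a) - colMeans(curves_b),
       lo = lo, hi = hi, significant = lo > 0 | hi < 0,
       B = B, alpha = spec$alpha)
}
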