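#' Per-sample gaze kinematics
#'
#' Computes instantaneous speed (deg/s) and its time derivative (deg/s^2)
#' from a gaze recording, using symmetric finite differences over +-1 sample
#' in the interior and one-sided differences at the endpoints. Samples at or
#' adjacent to missing pupil data get `NA` kinematics: position during signal
#' loss is unreliable and must never trigger the saccade detector on its own.
#'
#' @param rec a [gaze_recording()]
#' @param spec a [parser_spec()]; only `v_smooth_window` is used here
#' @return data.frame with columns `t`, `velocity`, `acceleration`
#' @export
compute_kinematics <- function(rec, spec = parser_spec()) {
  stopifnot(inherits(rec, "gaze_recording"))
  n <- length(rec$t)
  if (n < 3) stop_gm("recording too short (%d samples, need >= 3)", n)
  dt <- 1000 / rec$rate                      # ms
  if (max(abs(diff(rec$t) - dt)) > 1e-3 * dt)
    stop_gm("non-uniform sampling in trial %s", rec$trial_id)
  dts <- dt / 1000                           # s
  xd <- rec$x / rec$px_per_deg
  yd <- rec$y / rec$px_per_deg

  vel <- numeric(n)
  i <- 2:(n - 1)
  vel[i] <- sqrt((xd[i + 1] - xd[i - 1])^2 + (yd[i + 1] - yd[i - 1])^2) / (2 * dts)
  vel[1] <- sqrt((xd[2] - xd[1])^2 + (yd[2] - yd[1])^2) / dts
  vel[n] <- sqrt((xd[n] - xd[n - 1])^2 + (yd[n] - yd[n - 1])^2) / dts

  miss <- is.na(rec$pupil)
  # a sample's velocity involves itself and its difference neighbours
  bad <- miss | c(miss[-1], FALSE) | c(FALSE, miss[-n])
  vel[bad] <- NA_real_

  if (spec$v_smooth_window > 1) {
    w <- spec$v_smooth_window
    sm <- stats::filter(vel, rep(1 / w, w), sides = 2)
    vel <- ifelse(is.na(sm), vel, as.numeric(sm))
  }

  acc <- numeric(n)
  acc[i] <- (vel[i + 1] - vel[i - 1]) / (2 * dts)
  acc[1] <- (vel[2] - vel[1]) / dts
  acc[n] <- (vel[n] - vel[n - 1]) / dts

  data.frame(t = rec$t, velocity = vel, acceleration = acc)
}

#' Parse a gaze recording into fixation, saccade and blink events
#'
#' A sample is saccadic when its velocity exceeds `v_thresh` OR the magnitude
#' of its acceleration exceeds `a_thresh`. A blink is a run of at least
#' `blink_min_missing` consecutive missing-pupil samples, extended through any
#' contiguous saccade-flagged, missing, or undefined-kinematics samples on
#' either side (the lid-closure artefact surrounding signal loss).
#' Temporally and spatially contiguous saccades are then merged (see
#' [merge_saccades()]), and every remaining maximal run of samples is a
#' fixation whose centroid is the mean sample position. Events tile the
#' recording: an event covering samples i..j has onset `t[i]` and offset
#' `t[j] + dt`, so event durations sum exactly to the recording span.
#'
#' @param rec a [gaze_recording()]
#' @param spec a [parser_spec()]
#' @return an `event_sequence`: a data.frame with columns `trial_id`, `kind`
#'   (fixation/saccade/blink), `onset`, `offset`, `duration` (ms), `x`, `y`
#'   (fixation centroid, px; `NA` otherwise) and saccade endpoint columns
#'   `x_start`, `y_start`, `x_end`, `y_end`
#' @export
parse_events <- function(rec, spec = parser_spec()) {
  stopifnot(inherits(rec, "gaze_recording"), inherits(spec, "parser_spec"))
  n <- length(rec$t)
  if (n == 0) stop_gm("empty recording")
  dt <- 1000 / rec$rate
  miss <- is.na(rec$pupil)

  if (all(miss)) {
    ev <- event_row(rec$trial_id, "blink", rec$t[1], rec$t[n] + dt)
    return(as_event_sequence(ev, rec))
  }

  kin <- compute_kinematics(rec, spec)
  sacc <- (kin$velocity > spec$v_thresh) |
    (abs(kin$acceleration) > spec$a_thresh)
  sacc[is.na(sacc)] <- FALSE

  # blink cores, extended through contiguous saccade-flagged, missing, or
  # undefined-kinematics samples (the +-1-sample halo around signal loss)
  na_kin <- is.na(kin$velocity)
  blink <- logical(n)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths >= spec$blink_min_missing)) {
    a <- starts[k]; b <- ends[k]
    while (a > 1L && (sacc[a - 1L] || miss[a - 1L] || na_kin[a - 1L])) a <- a - 1L
    while (b < n && (sacc[b + 1L] || miss[b + 1L] || na_kin[b + 1L])) b <- b + 1L
    blink[a:b] <- TRUE
  }
  sacc <- sacc & !blink

  lab <- ifelse(blink, "blink", ifelse(sacc, "saccade", "fixation"))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- vector("list", length(r$values))
  for (k in seq_along(r$values)) {
    i <- starts[k]; j <- ends[k]
    kind <- r$values[k]
    rows[[k]] <- switch(
      kind,
      fixation = event_row(rec$trial_id, kind, rec$t[i], rec$t[j] + dt,
                           x = mean(rec$x[i:j]), y = mean(rec$y[i:j])),
      saccade = event_row(rec$trial_id, kind, rec$t[i], rec$t[j] + dt,
                          x_start = rec$x[i], y_start = rec$y[i],
                          x_end = rec$x[j], y_end = rec$y[j]),
      blink = event_row(rec$trial_id, kind, rec$t[i], rec$t[j] + dt))
  }
  ev <- do.call(rbind, rows)
  merge_saccades(as_event_sequence(ev, rec), spec)
}

event_row <- function(trial_id, kind, onset, offset,
                      x = NA_real_, y = NA_real_,
                      x_start = NA_real_, y_start = NA_real_,
                      x_end = NA_real_, y_end = NA_real_) {
  data.frame(trial_id = trial_id, kind = kind, onset = onset, offset = offset,
             duration = offset - onset, x = x, y = y,
             x_start = x_start, y_start = y_start,
             x_end = x_end, y_end = y_end, stringsAsFactors = FALSE)
}

as_event_sequence <- function(ev, rec) {
  attr(ev, "px_per_deg") <- rec$px_per_deg
  attr(ev, "rate") <- rec$rate
  class(ev) <- c("event_sequence", "data.frame")
  ev
}

#' Merge temporally and spatially contiguous saccades
#'
#' Two consecutive saccades (with only fixations, if anything, between them)
#' are fused when the gap from the offset of the first to the onset of the
#' second is below `merge_gap` AND the distance from the landing point of the
#' first to the launch point of the second is below `merge_dist` degrees.
#' The fused saccade absorbs the intervening samples. Merging is repeated to
#' a fixpoint, so chains of mutually mergeable saccades collapse to one; the
#' operation is idempotent on sequences with no mergeable pair.
#'
#' @param events an `event_sequence` as returned by [parse_events()]
#' @param spec a [parser_spec()]
#' @param px_per_deg pixels per degree; defaults to the attribute stored on
#'   `events`
#' @return the merged `event_sequence`
#' @export
merge_saccades <- function(events, spec = parser_spec(),
                           px_per_deg = attr(events, "px_per_deg")) {
  if (is.null(px_per_deg)) stop_gm("px_per_deg not supplied and not an attribute")
  ats <- attributes(events)
  repeat {
    sidx <- which(events$kind == "saccade")
    if (length(sidx) < 2) break
    if (anyNA(events$x_start[sidx]))
      stop_gm("saccade endpoints required for merging")
    merged <- FALSE
    for (m in seq_len(length(sidx) - 1)) {
      k <- sidx[m]; l <- sidx[m + 1]
      between <- if (l > k + 1) events$kind[(k + 1):(l - 1)] else character(0)
      if (any(between == "blink")) next
      gap <- events$onset[l] - events$offset[k]
      d <- sqrt((events$x_start[l] - events$x_end[k])^2 +
                (events$y_start[l] - events$y_end[k])^2) / px_per_deg
      if (gap < spec$merge_gap && d < spec$merge_dist) {
        events$offset[k] <- events$offset[l]
        events$duration[k] <- events$offset[k] - events$onset[k]
        events$x_end[k] <- events$x_end[l]
        events$y_end[k] <- events$y_end[l]
        events <- events[-((k + 1):l), , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  rownames(events) <- NULL
  for (a in setdiff(names(ats), c("names", "row.names", "class")))
    attr(events, a) <- ats[[a]]
  class(events) <- c("event_sequence", "data.frame")
  events
}

#' @export
print.event_sequence <- function(x, ...) {
  cat(sprintf("<event_sequence: %d events (%d fixations, %d saccades, %d blinks)>\n",
              nrow(x), sum(x$kind == "fixation"), sum(x$kind == "saccade"),
              sum(x$kind == "blink")))
  print(as.data.frame(x), ...)
  invisible(x)
}
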