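# File formats: delimited samples/events, plain-text maps with a JSON
# sidecar, cluster JSON, 8-bit grayscale PNG stimuli. All writers are
# lossless for round trips at full double precision.

#' Write gaze recordings to a delimited samples file
#'
#' Schema: header `trial_id,t_ms,x_px,y_px,pupil`; missing pupil written as
#' `NA`.
#'
#' @param recordings a `gaze_recording` or list of them
#' @param path output file
#' @return `path`, invisibly
#' @export
write_samples <- function(recordings, path) {
  if (inherits(recordings, "gaze_recording")) recordings <- list(recordings)
  tabs <- lapply(recordings, function(r)
    data.frame(trial_id = r$trial_id, t_ms = r$t, x_px = r$x, y_px = r$y,
               pupil = r$pupil))
  data.table::fwrite(data.table::rbindlist(tabs), path, na = "NA")
  invisible(path)
}

#' Read a delimited samples file into gaze recordings
#'
#' @param path samples file (schema of [write_samples()])
#' @param rate sampling rate in Hz; `NULL` = inferred from the median time
#'   step of the first trial
#' @param px_per_deg calibration to attach
#' @return named list of `gaze_recording`s, one per trial
#' @export
read_samples <- function(path, rate = NULL, px_per_deg = 25) {
  d <- data.table::fread(path, data.table = FALSE, na.strings = c("", "NA"))
  need <- c("trial_id", "t_ms", "x_px", "y_px", "pupil")
  if (!all(need %in% names(d)))
    stop_gm("samples file %s: missing column(s) %s", path,
            paste(setdiff(need, names(d)), collapse = ", "))
  if (any(is.na(d$x_px)) || any(is.na(d$y_px))) {
    bad <- which(is.na(d$x_px) | is.na(d$y_px))[1]
    stop_gm("samples file %s: NA coordinates at line %d", path, bad + 1L)
  }
  out <- list()
  for (tid in unique(d$trial_id)) {
    s <- d[d$trial_id == tid, , drop = FALSE]
    if (any(diff(s$t_ms) <= 0))
      stop_gm("samples file %s: non-increasing time in trial %s", path, tid)
    r <- rate %||% (1000 / stats::median(diff(s$t_ms)))
    out[[as.character(tid)]] <- gaze_recording(
      t = s$t_ms, x = s$x_px, y = s$y_px, pupil = s$pupil,
      rate = r, px_per_deg = px_per_deg, trial_id = as.character(tid))
  }
  out
}

#' Write an event table to a delimited file
#'
#' Schema: `trial_id,kind,onset_ms,offset_ms,x_px,y_px,duration_ms`; x/y are
#' empty for saccades and blinks (saccade endpoint columns are in-memory
#' only).
#'
#' @param events event data.frame (see [parse_events()])
#' @param path output file
#' @return `path`, invisibly
#' @export
write_events <- function(events, path) {
  ev <- as.data.frame(events)
  data.table::fwrite(
    data.frame(trial_id = ev$trial_id, kind = ev$kind, onset_ms = ev$onset,
               offset_ms = ev$offset, x_px = ev$x, y_px = ev$y,
               duration_ms = ev$duration),
    path, na = "NA")
  invisible(path)
}

#' Read an event table written by [write_events()]
#' @param path events file
#' @return event data.frame with columns `trial_id`, `kind`, `onset`,
#'   `offset`, `duration`, `x`, `y`
#' @export
read_events <- function(path) {
  d <- data.table::fread(path, data.table = FALSE, na.strings = c("", "NA"))
  need <- c("trial_id", "kind", "onset_ms", "offset_ms", "x_px", "y_px",
            "duration_ms")
  if (!all(need %in% names(d)))
    stop_gm("events file %s: missing column(s) %s", path,
            paste(setdiff(need, names(d)), collapse = ", "))
  data.frame(trial_id = as.character(d$trial_id), kind = d$kind,
             onset = d$onset_ms, offset = d$offset_ms,
             duration = d$duration_ms, x = d$x_px, y = d$y_px,
             stringsAsFactors = FALSE)
}

#' Write a stat_map as plain text plus a JSON sidecar
#'
#' `<prefix>.txt` holds the grid (one row of the image per line, y down),
#' `<prefix>.json` the metadata.
#'
#' @param m a `stat_map`
#' @param prefix output path prefix
#' @return `prefix`, invisibly
#' @export
write_map <- function(m, prefix) {
  stopifnot(inherits(m, "stat_map"))
  utils::write.table(format(m$grid, digits = 12, trim = TRUE, scientific = TRUE),
                     paste0(prefix, ".txt"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  jsonlite::write_json(m$meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' Read a stat_map written by [write_map()]
#'
#' A sidecar without a recorded smoothing sigma triggers a warning and the
#' default of 10 px is assumed for any downstream Pixel test.
#'
#' @param prefix path prefix
#' @return a `stat_map`
#' @export
read_map <- function(prefix) {
  grid <- as.matrix(utils::read.table(paste0(prefix, ".txt")))
  dimnames(grid) <- NULL
  meta <- list()
  side <- paste0(prefix, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  sig <- meta$sigma_smooth_px
  if (is.null(sig) || length(sig) == 0 || all(is.na(sig))) {
    if (!identical(meta$kind, "raw")) {
      warning(sprintf("map %s: sidecar lacks sigma_smooth_px; assuming 10 px",
                      prefix))
      sig <- 10
    } else sig <- NA_real_
  }
  stat_map(grid, kind = meta$kind %||% "raw",
           px_per_deg = meta$px_per_deg %||% 25, sigma_smooth_px = sig,
           n_trials = meta$n_trials %||% NA_integer_,
           n_observers = meta$n_observers %||% NA_integer_)
}

#' Write a cluster set as JSON
#'
#' Pixels are stored as 0-based (x, y) coordinate pairs.
#'
#' @param clusters a `cluster_set`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_clusters <- function(clusters, path) {
  H <- clusters$dim[1]
  out <- list(
    z_crit = clusters$z_crit, height = H, width = clusters$dim[2],
    clusters = lapply(clusters$clusters, function(cl) list(
      sign = cl$sign, peak_z = cl$peak_z, area_px = cl$area_px,
      x = ((cl$pixels - 1L) %/% H), y = ((cl$pixels - 1L) %% H))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cluster set written by [write_clusters()]
#' @param path cluster JSON file
#' @return a `cluster_set`
#' @export
read_clusters <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- j$height
  cl <- lapply(seq_len(length(j$clusters$sign %||% integer(0))), function(k) {
    x <- j$clusters$x[[k]]; y <- j$clusters$y[[k]]
    list(pixels = as.integer(x * H + y + 1L), sign = j$clusters$sign[k],
         peak_z = j$clusters$peak_z[k], area_px = j$clusters$area_px[k])
  })
  structure(list(clusters = cl, z_crit = j$z_crit, dim = c(H, j$width)),
            class = "cluster_set")
}

#' Read / write grayscale stimulus images as 8-bit PNG
#'
#' Gray levels use the 1-256 convention in memory; on disk they map linearly
#' to the 8-bit 0-255 range.
#'
#' @param path PNG file
#' @return numeric matrix with values in `[1, 256]`
#' @export
read_stimulus <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3 &&
        (max(abs(a[, , 1] - a[, , 2])) > 0 || max(abs(a[, , 1] - a[, , 3])) > 0))
      stop_gm("stimulus %s is not grayscale", path)
    a <- a[, , 1]
  }
  a * 255 + 1
}

#' @rdname read_stimulus
#' @param image numeric matrix with values in `[1, 256]`
#' @export
write_stimulus <- function(image, path) {
  png::writePNG((pmin(pmax(image, 1), 256) - 1) / 255, path)
  invisible(path)
}
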