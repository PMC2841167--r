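#' Construct a statistical map
#'
#' A `stat_map` is a 2D scalar field on the stimulus pixel grid plus the
#' metadata needed to interpret it (calibration, smoothing, provenance).
#'
#' @param grid numeric matrix (rows = y, columns = x)
#' @param kind one of `"raw"`, `"smoothed"`, `"z"`, `"differential_z"`, `"sd"`,
#'   `"mean"`
#' @param px_per_deg calibration, px per degree
#' @param sigma_smooth_px smoothing kernel sigma already applied (NA if none)
#' @param n_trials,n_observers provenance counts
#' @return an object of class `stat_map`
#' @export
stat_map <- function(grid, kind = "raw", px_per_deg = 25,
                     sigma_smooth_px = NA_real_, n_trials = NA_integer_,
                     n_observers = NA_integer_) {
  if (!is.matrix(grid) || !is.numeric(grid)) stop_gm("grid must be a numeric matrix")
  if (any(!is.finite(grid))) stop_gm("stat_map values must be finite")
  if (kind == "raw" && any(grid < 0))
    stop_gm("raw maps must be non-negative")
  structure(list(grid = grid,
                 meta = list(width = ncol(grid), height = nrow(grid),
                             px_per_deg = px_per_deg, kind = kind,
                             sigma_smooth_px = sigma_smooth_px,
                             n_trials = n_trials, n_observers = n_observers)),
            class = "stat_map")
}

#' @export
as.matrix.stat_map <- function(x, ...) x$grid

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map [%s] %dx%d px, sigma=%s, sum=%.4g, range=[%.3g, %.3g]>\n",
              x$meta$kind, x$meta$height, x$meta$width,
              format(x$meta$sigma_smooth_px), sum(x$grid),
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
plot.stat_map <- function(x, ...) {
  graphics::image(t(x$grid)[, nrow(x$grid):1], useRaster = TRUE,
                  asp = nrow(x$grid) / ncol(x$grid), axes = FALSE, ...)
  invisible(x)
}

map_grid <- function(m) if (inherits(m, "stat_map")) m$grid else m

#' Accumulate a duration-weighted fixation map
#'
#' Each fixation deposits its duration (ms) at the pixel nearest its
#' centroid, so the raw map's total equals the total included fixation time
#' and a fixation's weight is proportional to the time spent there.
#' Centroids are clipped to the image bounds.
#'
#' @param events one `event_sequence` or a data.frame of (possibly
#'   concatenated) events; only `kind == "fixation"` rows contribute. An
#'   optional logical `correct` column supports correct-trial filtering.
#' @param width,height map dimensions in px
#' @param correct_only if `TRUE`, keep only events with `correct == TRUE`
#' @param px_per_deg calibration recorded in the map metadata
#' @return a `stat_map` of kind `"raw"`
#' @export
accumulate_map <- function(events, width = 382, height = 390,
                           correct_only = FALSE, px_per_deg = 25) {
  ev <- as.data.frame(events)
  if (correct_only) {
    if (is.null(ev$correct)) stop_gm("correct_only requires a 'correct' column")
    ev <- ev[!is.na(ev$correct) & ev$correct, , drop = FALSE]
  }
  ev <- ev[ev$kind == "fixation", , drop = FALSE]
  if (nrow(ev) == 0) stop_gm("empty map: no qualifying fixations")
  col <- pmin(pmax(round(ev$x), 0), width - 1) + 1L
  row <- pmin(pmax(round(ev$y), 0), height - 1) + 1L
  grid <- matrix(0, height, width)
  idx <- (col - 1L) * height + row
  acc <- rowsum(ev$duration, idx)
  grid[as.integer(rownames(acc))] <- acc[, 1]
  stat_map(grid, "raw", px_per_deg = px_per_deg,
           n_trials = length(unique(ev$trial_id)))
}

#' Smooth a map with an isotropic Gaussian kernel
#'
#' Convolution with a unit-sum discrete Gaussian (support +-4 sigma),
#' zero-padded at the boundaries: mass within 4 sigma of the border is
#' partially attenuated, interior mass is conserved.
#'
#' @param m a `stat_map` or numeric matrix
#' @param sigma kernel standard deviation in px (default 10)
#' @return a `stat_map` of kind `"smoothed"`
#' @export
smooth_map <- function(m, sigma = 10) {
  if (sigma <= 0) stop_gm("sigma must be positive")
  g <- map_grid(m)
  out <- gaussian_blur(g, sigma)
  meta <- if (inherits(m, "stat_map")) m$meta else list()
  stat_map(out, "smoothed",
           px_per_deg = meta$px_per_deg %||% 25, sigma_smooth_px = sigma,
           n_trials = meta$n_trials %||% NA_integer_,
           n_observers = meta$n_observers %||% NA_integer_)
}

#' Sum observer maps into a group map
#'
#' @param observer_maps list of `stat_map`s (or matrices) of equal dimension
#' @return a `stat_map` with `n_observers` set
#' @export
group_map <- function(observer_maps) {
  grids <- lapply(observer_maps, map_grid)
  d <- dim(grids[[1]])
  if (!all(vapply(grids, function(g) identical(dim(g), d), logical(1))))
    stop_gm("observer maps must share dimensions")
  out <- Reduce(`+`, grids)
  meta <- if (inherits(observer_maps[[1]], "stat_map")) observer_maps[[1]]$meta else list()
  stat_map(out, meta$kind %||% "raw", px_per_deg = meta$px_per_deg %||% 25,
           sigma_smooth_px = meta$sigma_smooth_px %||% NA_real_,
           n_observers = length(observer_maps))
}

#' Pooled Z-scoring of two group maps
#'
#' The mean and SD (population moments) are taken over the concatenated
#' pixel values of both maps and used to normalise each map, so the two
#' Z-maps live on a common scale and are directly comparable.
#'
#' @param group_a,group_b `stat_map`s (or matrices) of equal dimension
#' @return list with `stat_map`s `z_a`, `z_b` (kind `"z"`) and the pooled
#'   moments `mu`, `s`
#' @export
zscore_pooled <- function(group_a, group_b) {
  a <- map_grid(group_a); b <- map_grid(group_b)
  if (!identical(dim(a), dim(b))) stop_gm("maps must share dimensions")
  pooled <- c(a, b)
  mu <- mean(pooled)
  s <- sd_pop(pooled)
  if (s == 0) stop_gm("degenerate maps: zero pooled SD")
  mk <- function(g, src) {
    meta <- if (inherits(src, "stat_map")) src$meta else list()
    stat_map((g - mu) / s, "z", px_per_deg = meta$px_per_deg %||% 25,
             sigma_smooth_px = meta$sigma_smooth_px %||% NA_real_,
             n_observers = meta$n_observers %||% NA_integer_)
  }
  list(z_a = mk(a, group_a), z_b = mk(b, group_b), mu = mu, s = s)
}

#' Z-scored differential map between two groups
#'
#' Subtracts map b from map a and standardises the difference over pixels
#' (population moments), yielding a map with pixel mean 0 and SD 1 whose
#' positive values mark locations favoured by group a and negative values
#' locations favoured by group b.
#'
#' @param group_a,group_b `stat_map`s (or matrices) of equal dimension
#' @return a `stat_map` of kind `"differential_z"`
#' @export
differential_zmap <- function(group_a, group_b) {
  a <- map_grid(group_a); b <- map_grid(group_b)
  if (!identical(dim(a), dim(b))) stop_gm("maps must share dimensions")
  d <- a - b
  s <- sd_pop(c(d))
  if (s == 0) stop_gm("degenerate difference: zero SD (identical maps)")
  meta <- if (inherits(group_a, "stat_map")) group_a$meta else list()
  stat_map((d - mean(d)) / s, "differential_z",
           px_per_deg = meta$px_per_deg %||% 25,
           sigma_smooth_px = meta$sigma_smooth_px %||% NA_real_)
}
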