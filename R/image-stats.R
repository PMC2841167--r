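#' Pixelwise mean and SD of an image set
#'
#' The SD image is the pixel-space "information" map of a stimulus set: the
#' mean holds what exemplars share, the SD what distinguishes them.
#' Gray levels are expected on the 1-256 scale; the SD uses the population
#' (n) denominator.
#'
#' @param images list of >= 2 numeric matrices of identical dimension with
#'   values in `[1, 256]`
#' @return list with `stat_map`s `mean` and `sd` and the set size `n`
#' @export
group_pixel_stats <- function(images) {
  if (length(images) < 2) stop_gm("need at least 2 images")
  d <- dim(images[[1]])
  for (im in images) {
    if (!identical(dim(im), d)) stop_gm("image dimension mismatch")
    if (min(im) < 1 || max(im) > 256)
      stop_gm("gray levels must lie in [1, 256]")
  }
  n <- length(images)
  m <- Reduce(`+`, images) / n
  v <- Reduce(`+`, lapply(images, function(im) (im - m)^2)) / n
  list(mean = stat_map(m, "mean"), sd = stat_map(sqrt(v), "sd"), n = n)
}

#' Differential-SD Pixel test between two image sets
#'
#' Subtracts the pixelwise SD image of set b from that of set a, Z-scores
#' the difference over pixels, and thresholds it with the Pixel test. A
#' significant cluster marks image locations where one set is reliably more
#' variable — i.e. carries more potential diagnostic information — than the
#' other. The SD fields are not smoothed before testing; the smoothness
#' assumed by the threshold is `spec$sigma_smooth_px` (default 10 px) and is
#' recorded in the output for scrutiny.
#'
#' @param set_a,set_b lists of grayscale images (see [group_pixel_stats()])
#' @param spec a [pixel_test_spec()]
#' @return list with `zmap` (`stat_map`, kind `"differential_z"`),
#'   `clusters` (`cluster_set`), `stats_a`, `stats_b`, and
#'   `assumed_sigma_px`
#' @export
differential_sd_test <- function(set_a, set_b, spec = pixel_test_spec()) {
  sa <- group_pixel_stats(set_a)
  sb <- group_pixel_stats(set_b)
  if (!identical(dim(sa$sd$grid), dim(sb$sd$grid)))
    stop_gm("image sets must share dimensions")
  d <- sa$sd$grid - sb$sd$grid
  s <- sd_pop(c(d))
  if (s == 0) stop_gm("degenerate difference: zero SD across pixels")
  z <- stat_map((d - mean(d)) / s, "differential_z",
                sigma_smooth_px = spec$sigma_smooth_px)
  list(zmap = z, clusters = significant_clusters(z, spec),
       stats_a = sa, stats_b = sb,
       assumed_sigma_px = spec$sigma_smooth_px)
}
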