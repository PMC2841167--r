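#' Pixel-test settings
#'
#' Configuration for the random-field ("Pixel test") familywise threshold on
#' smooth Z-maps. The assumed field smoothness is the smoothing kernel
#' applied upstream (sigma in px); the corresponding FWHM is
#' `2 * sqrt(2 * log(2)) * sigma`.
#'
#' @param alpha familywise error level
#' @param tails `"one"` or `"two"`
#' @param sigma_smooth_px assumed field smoothness sigma, px
#' @param search_mask optional logical matrix restricting the search region;
#'   `NULL` = the full map
#' @return an object of class `pixel_test_spec`
#' @export
pixel_test_spec <- function(alpha = 0.05, tails = c("two", "one"),
                            sigma_smooth_px = 10, search_mask = NULL) {
  tails <- match.arg(tails)
  if (alpha <= 0 || alpha >= 1) stop_gm("alpha must lie in (0, 1)")
  if (sigma_smooth_px <= 0) stop_gm("sigma_smooth_px must be positive")
  structure(list(alpha = alpha, tails = tails,
                 sigma_smooth_px = sigma_smooth_px,
                 search_mask = search_mask,
                 fwhm = 2 * sqrt(2 * log(2)) * sigma_smooth_px),
            class = "pixel_test_spec")
}

#' Resel counts of a search region
#'
#' Resolution elements of a 2D search region for a field of the given FWHM:
#' `R2 = area / fwhm^2`, `R1 = half boundary length / fwhm` (for a w x h
#' rectangle, `(w + h) / fwhm`), and `R0` = the Euler characteristic of the
#' region (1 for a filled rectangle).
#'
#' @param mask either a logical matrix or a length-2 integer `c(height,
#'   width)` describing a full rectangle
#' @param fwhm field smoothness FWHM, px
#' @return named numeric vector `c(R0, R1, R2)`
#' @export
resel_counts <- function(mask, fwhm) {
  if (fwhm <= 0) stop_gm("fwhm must be positive")
  if (is.matrix(mask)) {
    mask <- mask != 0
    A <- sum(mask)
    if (A == 0) stop_gm("empty mask")
    if (all(mask)) return(resel_counts(dim(mask), fwhm))
    H <- nrow(mask); W <- ncol(mask)
    pad <- matrix(FALSE, H + 2, W + 2)
    pad[2:(H + 1), 2:(W + 1)] <- mask
    # exposed pixel edges = boundary length
    hadj <- sum(pad[, -1] & pad[, -(W + 2)])
    vadj <- sum(pad[-1, ] & pad[-(H + 2), ])
    perim <- 4 * A - 2 * (hadj + vadj)
    # Euler characteristic of the pixel union: V - E + F on the cell complex
    blocks <- sum(pad[-1, -1] & pad[-1, -(W + 2)] &
                  pad[-(H + 2), -1] & pad[-(H + 2), -(W + 2)])
    ec <- A - (hadj + vadj) + blocks
    return(c(R0 = ec, R1 = perim / (2 * fwhm), R2 = A / fwhm^2))
  }
  h <- mask[1]; w <- mask[2]
  if (h <= 0 || w <= 0) stop_gm("empty mask")
  c(R0 = 1, R1 = (w + h) / fwhm, R2 = w * h / fwhm^2)
}

#' Expected Euler characteristic of suprathreshold excursions
#'
#' For a unit-variance smooth Gaussian random field with resel counts
#' `(R0, R1, R2)`, the expected Euler characteristic of the excursion set
#' above level t is
#' `R0 (1 - Phi(t)) + R1 sqrt(4 log 2)/(2 pi) e^{-t^2/2} +
#'  R2 (4 log 2)/(2 pi)^{3/2} t e^{-t^2/2}`.
#' At high t this approximates the probability that the field maximum
#' exceeds t, which is what the Pixel test inverts.
#'
#' @param t threshold level (vectorised)
#' @param resels numeric `c(R0, R1, R2)`
#' @return expected Euler characteristic at each `t`
#' @export
expected_ec <- function(t, resels) {
  R0 <- resels[[1]]; R1 <- resels[[2]]; R2 <- resels[[3]]
  e <- exp(-t^2 / 2)
  R0 * stats::pnorm(t, lower.tail = FALSE) +
    R1 * sqrt(4 * log(2)) / (2 * pi) * e +
    R2 * (4 * log(2)) / (2 * pi)^(3 / 2) * t * e
}

#' Critical Z of the Pixel test
#'
#' Solves `E[EC](t) = alpha` (one-tailed) or `alpha / 2` (two-tailed, applied
#' to |Z|) for t by bisection on `[1.5, 10]` to a tolerance of 1e-6. With the
#' default geometry — a full 382 x 390 search region smoothed at sigma = 10 px
#' — the two-tailed threshold at alpha = .05 is 4.25.
#'
#' @param spec a [pixel_test_spec()]
#' @param map_dims map dimensions `c(height, width)`; ignored when the spec
#'   carries a `search_mask`
#' @param resels optional explicit `c(R0, R1, R2)`, overriding the geometry
#'   (e.g. `c(1, 0, 0)` recovers the pointwise Gaussian quantile)
#' @return the critical Z value
#' @export
critical_z <- function(spec = pixel_test_spec(), map_dims = c(390, 382),
                       resels = NULL) {
  stopifnot(inherits(spec, "pixel_test_spec"))
  mask <- spec$search_mask %||% map_dims
  res <- resels %||% resel_counts(mask, spec$fwhm)
  target <- if (spec$tails == "two") spec$alpha / 2 else spec$alpha
  f <- function(t) expected_ec(t, res) - target
  if (f(1.5) < 0 || f(10) > 0)
    stop_gm("no critical value in [1.5, 10] for this geometry/alpha")
  stats::uniroot(f, c(1.5, 10), tol = 1e-6)$root
}

#' Extract significant clusters from a Z-map
#'
#' Thresholds the map at the Pixel-test critical value (|Z| > z_crit for the
#' two-tailed test, Z > z_crit one-tailed) and labels 8-connected
#' suprathreshold clusters, keeping positive and negative excursions
#' separate.
#'
#' @param z a `stat_map` of a z kind, or a numeric matrix
#' @param spec a [pixel_test_spec()]
#' @return an object of class `cluster_set`: list with `clusters` (each a
#'   list with `pixels` — linear indices into the map —, `sign`, `peak_z`,
#'   `area_px`), `z_crit`, `dim`
#' @export
significant_clusters <- function(z, spec = pixel_test_spec()) {
  g <- map_grid(z)
  zc <- critical_z(spec, dim(g))
  inmask <- spec$search_mask %||% array(TRUE, dim(g))
  clusters <- list()
  signs <- if (spec$tails == "two") c(1, -1) else 1
  for (sgn in signs) {
    mask <- (sgn * g > zc) & inmask
    lab <- label_components(mask)
    for (k in seq_len(max(lab))) {
      px <- which(lab == k)
      clusters[[length(clusters) + 1]] <- list(
        pixels = px, sign = sgn,
        peak_z = g[px][which.max(sgn * g[px])],
        area_px = length(px))
    }
  }
  structure(list(clusters = clusters, z_crit = zc, dim = dim(g)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set: %d cluster(s) at |Z| > %.3f on %dx%d>\n",
              length(x$clusters), x$z_crit, x$dim[1], x$dim[2]))
  for (cl in x$clusters)
    cat(sprintf("  sign %+d, area %d px, peak Z %.2f\n",
                cl$sign, cl$area_px, cl$peak_z))
  invisible(x)
}

#' Union mask of a cluster set
#' @param clusters a `cluster_set`
#' @param sign optional `+1`/`-1` filter
#' @return logical matrix
#' @export
cluster_mask <- function(clusters, sign = NULL) {
  m <- matrix(FALSE, clusters$dim[1], clusters$dim[2])
  for (cl in clusters$clusters)
    if (is.null(sign) || cl$sign == sign) m[cl$pixels] <- TRUE
  m
}
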