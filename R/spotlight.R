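#' Spotlight aperture settings
#'
#' The Spotlight is a gaze-contingent Gaussian aperture: fully transparent at
#' the centre of gaze, with opacity (alpha) rising with eccentricity along a
#' Gaussian ramp and reaching 1 (complete opacity) at the aperture border.
#' Aperture diameters of 2, 5 and 8 degrees of visual angle correspond, at
#' the default calibration of 25 px/deg, to radii of 25, 62.5 and 100 px.
#'
#' @param aperture_deg aperture diameter in degrees (2, 5 or 8 in the
#'   standard design; any positive value is accepted)
#' @param px_per_deg pixels per degree of visual angle
#' @param sigma_frac Gaussian ramp scale as a fraction of the aperture radius
#' @return an object of class `spotlight_spec` with derived field `radius_px`
#' @export
spotlight_spec <- function(aperture_deg = 8, px_per_deg = 25,
                           sigma_frac = 0.5) {
  if (aperture_deg <= 0) stop_gm("aperture_deg must be positive")
  if (px_per_deg <= 0) stop_gm("px_per_deg must be positive")
  if (sigma_frac <= 0 || sigma_frac >= 1)
    stop_gm("sigma_frac must lie in (0, 1)")
  structure(list(aperture_deg = aperture_deg, px_per_deg = px_per_deg,
                 sigma_frac = sigma_frac,
                 radius_px = aperture_deg / 2 * px_per_deg),
            class = "spotlight_spec")
}

#' Aperture opacity at a given eccentricity
#'
#' Normalised Gaussian ramp: `alpha(r) = (1 - exp(-r^2 / (2 s^2))) /
#' (1 - exp(-R^2 / (2 s^2)))` for `r < R` with `s = sigma_frac * R`, and 1
#' beyond the border, so that `alpha(0) = 0` and `alpha(R) = 1` exactly.
#'
#' @param r distance from the centre of gaze, px (vectorised, >= 0)
#' @param spec a [spotlight_spec()]
#' @return opacity values in `[0, 1]`
#' @export
aperture_alpha <- function(r, spec = spotlight_spec()) {
  if (any(r < 0)) stop_gm("distances must be non-negative")
  R <- spec$radius_px
  s <- spec$sigma_frac * R
  a <- (1 - exp(-r^2 / (2 * s^2))) / (1 - exp(-R^2 / (2 * s^2)))
  a[r >= R] <- 1
  a
}

#' Render the gaze-contingent Spotlight display
#'
#' Composites the stimulus with black according to the aperture opacity:
#' within the image frame the displayed value is `(1 - alpha) * image`
#' (black has value 0); display pixels outside the image frame take the
#' background gray level. Gaze may lie anywhere, including off-image.
#'
#' @param image numeric matrix of gray levels (rows = y, columns = x)
#' @param gaze numeric length-2 vector `c(x, y)` in image pixel coordinates
#'   (0-based, as in [gaze_recording()])
#' @param spec a [spotlight_spec()]
#' @param background gray level of the display outside the image frame
#' @param display_dim display size `c(height, width)`; default = image size
#' @param image_offset position `c(x, y)` of the image's top-left corner on
#'   the display (0-based)
#' @return numeric matrix of the displayed gray levels
#' @export
apply_spotlight <- function(image, gaze, spec = spotlight_spec(),
                            background = 128, display_dim = dim(image),
                            image_offset = c(0, 0)) {
  if (!is.matrix(image) || !is.numeric(image))
    stop_gm("image must be a numeric (grayscale) matrix")
  H <- display_dim[1]; W <- display_dim[2]
  out <- matrix(background, H, W)
  h <- nrow(image); w <- ncol(image)
  r0 <- image_offset[2]; c0 <- image_offset[1]     # y, x offsets
  rows <- seq_len(h) + r0
  cols <- seq_len(w) + c0
  keep_r <- rows >= 1 & rows <= H
  keep_c <- cols >= 1 & cols <= W
  if (!any(keep_r) || !any(keep_c)) return(out)
  # pixel-centre distances to gaze, in image coordinates
  dx <- (seq_len(w) - 1) - gaze[1]
  dy <- (seq_len(h) - 1) - gaze[2]
  rr <- sqrt(outer(dy^2, dx^2, `+`))
  masked <- (1 - aperture_alpha(rr, spec)) * image
  out[rows[keep_r], cols[keep_c]] <- masked[keep_r, keep_c]
  out
}

#' Facial landmark layout
#'
#' Circular landmark regions (left eye, right eye, nose, mouth) on the
#' stimulus pixel grid. The default layout is a schematic face on the
#' 382 x 390 grid whose geometry reproduces the designed visibility
#' relations of the Spotlight paradigm: each eye fits inside its own
#' 2-degree aperture; from the nose centre, eyes and mouth are visible at
#' 8 degrees but not at 5 degrees.
#'
#' @param landmarks data.frame with columns `name`, `cx`, `cy`, `r`
#'   (centres and radii in px, 0-based coordinates)
#' @param width,height stimulus dimensions in px
#' @return an object of class `landmark_layout`
#' @export
landmark_layout <- function(landmarks = NULL, width = 382, height = 390) {
  if (is.null(landmarks)) {
    landmarks <- data.frame(
      name = c("left_eye", "right_eye", "nose", "mouth"),
      cx = c(165, 217, 191, 191),
      cy = c(190, 190, 215, 252),
      r = c(13, 13, 10, 13),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "cx", "cy", "r") %in% names(landmarks)))
  if (any(landmarks$cx - landmarks$r < 0 | landmarks$cx + landmarks$r > width - 1) ||
      any(landmarks$cy - landmarks$r < 0 | landmarks$cy + landmarks$r > height - 1))
    stop_gm("landmark regions must lie within image bounds")
  le <- landmarks[landmarks$name == "left_eye", ]
  re <- landmarks[landmarks$name == "right_eye", ]
  if (nrow(le) == 1 && nrow(re) == 1 && le$cy != re$cy)
    stop_gm("eye landmarks must be horizontally symmetric (equal cy)")
  structure(list(landmarks = landmarks, width = width, height = height),
            class = "landmark_layout")
}

landmark_pixels <- function(layout, name) {
  lm <- layout$landmarks[layout$landmarks$name == name, ]
  if (nrow(lm) != 1) stop_gm("unknown landmark '%s'", name)
  xs <- floor(lm$cx - lm$r):ceiling(lm$cx + lm$r)
  ys <- floor(lm$cy - lm$r):ceiling(lm$cy + lm$r)
  g <- expand.grid(x = xs, y = ys)
  g[(g$x - lm$cx)^2 + (g$y - lm$cy)^2 <= lm$r^2, , drop = FALSE]
}

#' Landmark visibility under the Spotlight
#'
#' A landmark counts as visible from a gaze position when at least 90% of
#' its region pixels receive transmission `1 - alpha` above `tau`.
#'
#' @param layout a [landmark_layout()]
#' @param gaze numeric `c(x, y)` gaze position, image pixels
#' @param spec a [spotlight_spec()]
#' @param tau transmission threshold in (0, 1)
#' @param names landmark names to evaluate (default: all in the layout)
#' @return named logical vector
#' @export
landmark_visibility <- function(layout, gaze, spec = spotlight_spec(),
                                tau = 0.5, names = NULL) {
  stopifnot(inherits(layout, "landmark_layout"))
  if (tau <= 0 || tau >= 1) stop_gm("tau must lie in (0, 1)")
  names <- names %||% layout$landmarks$name
  vis <- vapply(names, function(nm) {
    px <- landmark_pixels(layout, nm)
    r <- sqrt((px$x - gaze[1])^2 + (px$y - gaze[2])^2)
    mean(1 - aperture_alpha(r, spec) > tau) >= 0.9
  }, logical(1))
  stats::setNames(vis, names)
}
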