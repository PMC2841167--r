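#' Observer fixation-strategy profile
#'
#' Generative parameters for a synthetic observer: a mixture over facial
#' landmarks giving where fixations land, the scatter of landings around a
#' landmark, a Gamma model of fixation durations, slow positional jitter, and
#' a blink rate. The defaults give roughly 27-30 fixations over a 10 s
#' learning trial, matching the scale of human scanning.
#'
#' @param landmark_weights named non-negative weights over `left_eye`,
#'   `right_eye`, `nose`, `mouth`; must sum to 1
#' @param spread_deg SD of the Gaussian landing scatter around a landmark
#'   centre, degrees
#' @param fix_shape,fix_scale Gamma shape/scale of fixation durations, ms
#'   (defaults: shape 4, scale 80 -> mean 320 ms)
#' @param noise_deg SD of slow positional jitter (oculomotor drift/tremor),
#'   degrees
#' @param blink_rate expected blinks per second of fixation time
#' @param name label for reports
#' @return an object of class `observer_profile`
#' @export
observer_profile <- function(landmark_weights = c(left_eye = 0.35,
                                                  right_eye = 0.35,
                                                  nose = 0.10, mouth = 0.20),
                             spread_deg = 0.6, fix_shape = 4, fix_scale = 80,
                             noise_deg = 0.02, blink_rate = 0.05,
                             name = "observer") {
  w <- landmark_weights
  if (is.null(names(w)) || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop_gm("landmark_weights must be named, non-negative and sum to 1")
  if (any(c(spread_deg, fix_shape, fix_scale, noise_deg) <= 0) || blink_rate < 0)
    stop_gm("profile scale parameters must be positive")
  structure(list(landmark_weights = w, spread_deg = spread_deg,
                 fix_shape = fix_shape, fix_scale = fix_scale,
                 noise_deg = noise_deg, blink_rate = blink_rate, name = name),
            class = "observer_profile")
}

#' Eye/mouth-biased fixation profile
#'
#' Default strategy concentrating fixation time on the eyes (70% combined)
#' and mouth, as Western Caucasian observers typically do.
#' @return an `observer_profile`
#' @export
profile_eye_biased <- function() observer_profile(name = "eye_biased")

#' Nose-centered fixation profile
#'
#' Central-bias strategy concentrating fixation time on the nose region, as
#' East Asian observers typically show under free (8 degree) viewing.
#' @return an `observer_profile`
#' @export
profile_nose_centered <- function() observer_profile(
  landmark_weights = c(left_eye = 0.15, right_eye = 0.15,
                       nose = 0.60, mouth = 0.10),
  name = "nose_centered")

#' Experiment design
#'
#' Block structure of the face learning/recognition experiment: per block,
#' `n_learn` identities are learned (10 s exposure each) and `2 * n_learn`
#' faces (the learned ones plus as many new ones) are then judged
#' old/new; there are `blocks_per_race` blocks for each face race.
#' Behavioural accuracy depends on the Spotlight aperture: chance (0.5) at
#' 2 degrees, rising with aperture size.
#'
#' @param n_learn identities learned per block
#' @param blocks_per_race recognition blocks per face race
#' @param races face-race labels
#' @param learn_exposure_ms learning-trial exposure, ms
#' @param accuracy_by_aperture named p(correct) per aperture (degrees)
#' @param rt_by_aperture named mean recognition response time (ms) per
#'   aperture; decreasing in aperture size
#' @return an object of class `experiment_design` with derived `n_recog`
#' @export
experiment_design <- function(n_learn = 14, blocks_per_race = 2,
                              races = c("WC", "EA"),
                              learn_exposure_ms = 10000,
                              accuracy_by_aperture = c("2" = 0.50,
                                                       "5" = 0.75,
                                                       "8" = 0.90),
                              rt_by_aperture = c("2" = 3000, "5" = 2200,
                                                 "8" = 1600)) {
  if (n_learn < 1 || blocks_per_race < 1) stop_gm("counts must be >= 1")
  if (any(accuracy_by_aperture < 0 | accuracy_by_aperture > 1))
    stop_gm("accuracies must lie in [0, 1]")
  structure(list(n_learn = as.integer(n_learn),
                 n_recog = as.integer(2 * n_learn),
                 blocks_per_race = as.integer(blocks_per_race),
                 races = races, learn_exposure_ms = learn_exposure_ms,
                 accuracy_by_aperture = accuracy_by_aperture,
                 rt_by_aperture = rt_by_aperture),
            class = "experiment_design")
}

#' Generate a synthetic face-like stimulus image
#'
#' Schematic stand-in for a photographic face stimulus (the package ships no
#' real face databases): a gray background, a darker face oval, darker
#' Gaussian patches at the landmark positions, seeded per-identity
#' perturbations (landmark position/contrast jitter) and spatially smooth
#' luminance noise. Gray levels lie in `[1, 256]`.
#'
#' @param layout a [landmark_layout()]
#' @param seed per-identity RNG seed (optional; uses the current RNG state
#'   when `NULL`)
#' @return numeric matrix `height x width`
#' @export
make_face_image <- function(layout = landmark_layout(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- layout$height; W <- layout$width
  xs <- matrix(0:(W - 1), H, W, byrow = TRUE)
  ys <- matrix(0:(H - 1), H, W)
  img <- matrix(200, H, W)                       # background gray
  cx <- (W - 1) / 2; cy <- (H - 1) / 2 + 15
  oval <- ((xs - cx) / 115)^2 + ((ys - cy) / 160)^2 <= 1
  img[oval] <- 175                               # skin tone
  lm <- layout$landmarks
  for (i in seq_len(nrow(lm))) {
    px <- lm$cx[i] + stats::rnorm(1, 0, 0.5)     # identity jitter
    py <- lm$cy[i] + stats::rnorm(1, 0, 0.5)
    amp <- 70 + stats::rnorm(1, 0, 2)
    s <- lm$r[i]
    img <- img - amp * exp(-((xs - px)^2 + (ys - py)^2) / (2 * s^2))
  }
  # identity variation is dominated by spatially smooth luminance noise, so
  # the across-identity SD field is close to homogeneous (no pixel carries
  # systematically more diagnostic variance than another)
  noise <- gaussian_blur(matrix(stats::rnorm(H * W), H, W), 12)
  noise <- noise / sd_pop(c(noise)) * 8
  img <- img + noise
  pmin(pmax(img, 1), 256)
}

draw_landing <- function(profile, layout, px_per_deg) {
  nm <- sample(names(profile$landmark_weights), 1,
               prob = profile$landmark_weights)
  lm <- layout$landmarks[layout$landmarks$name == nm, ]
  if (nrow(lm) != 1) stop_gm("layout lacks landmark '%s'", nm)
  c(lm$cx, lm$cy) + stats::rnorm(2, 0, profile$spread_deg * px_per_deg)
}

#' Sample a scanpath plan for one trial
#'
#' Alternates fixations (landmark mixture draw plus Gaussian scatter;
#' Gamma-distributed durations, floored at 50 ms) and saccades whose
#' durations follow the main-sequence rule `duration_ms = 2.2 * amplitude_deg
#' + 21`; saccade targets are redrawn until at least 0.5 degrees away, so
#' every planned saccade is kinematically detectable. Blinks (80-150 ms)
#' interrupt fixations at the profile's blink rate, the eye reopening on the
#' same location (fixation-blink-fixation). The plan is trimmed to span
#' `duration_ms` exactly and always ends in a fixation or blink.
#'
#' @param profile an [observer_profile()]
#' @param layout a [landmark_layout()]
#' @param duration_ms trial duration
#' @param px_per_deg calibration
#' @param seed optional RNG seed
#' @return data.frame plan with columns `kind`, `x`, `y` (landing/held
#'   position), `duration`; attribute `px_per_deg`
#' @export
sample_scanpath <- function(profile, layout = landmark_layout(),
                            duration_ms = 10000, px_per_deg = 25,
                            seed = NULL) {
  if (duration_ms <= 0) stop_gm("duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  w <- profile$landmark_weights
  centers <- layout$landmarks[match(names(w), layout$landmarks$name),
                              c("cx", "cy")]
  if (anyNA(centers)) stop_gm("layout lacks a weighted landmark")
  centers <- as.matrix(centers)
  spread_px <- profile$spread_deg * px_per_deg
  # pooled draws: landings, fixation durations, blink gates (refilled on demand)
  m <- max(64L, 3L * ceiling(duration_ms / 70))
  land <- centers[sample(length(w), m, replace = TRUE, prob = w), ] +
    matrix(stats::rnorm(2 * m, 0, spread_px), m, 2)
  fds <- pmax(stats::rgamma(m, profile$fix_shape, scale = profile$fix_scale), 50)
  gate <- stats::runif(m)
  bds <- stats::runif(m, 80, 150)
  il <- 0L; ie <- 0L
  next_landing <- function() {
    il <<- il + 1L
    if (il > nrow(land)) {
      land <<- rbind(land, centers[sample(length(w), m, replace = TRUE,
                                          prob = w), ] +
                       matrix(stats::rnorm(2 * m, 0, spread_px), m, 2))
    }
    land[il, ]
  }
  cap <- 2L * m
  kind <- character(cap); xx <- numeric(cap); yy <- numeric(cap)
  dur <- numeric(cap); ne <- 0L
  add <- function(k, p, d) {
    ne <<- ne + 1L
    kind[ne] <<- k; xx[ne] <<- p[1]; yy[ne] <<- p[2]; dur[ne] <<- d
  }
  pos <- next_landing()
  total <- 0
  while (total < duration_ms) {
    ie <- ie + 1L
    if (ie > length(fds)) {
      fds <- c(fds, pmax(stats::rgamma(m, profile$fix_shape,
                                       scale = profile$fix_scale), 50))
      gate <- c(gate, stats::runif(m))
      bds <- c(bds, stats::runif(m, 80, 150))
    }
    fd <- fds[ie]
    add("fixation", pos, fd); total <- total + fd
    if (total >= duration_ms) break
    if (gate[ie] < profile$blink_rate * fd / 1000) {
      # blinks interrupt a fixation: the eye reopens on the same location
      add("blink", pos, bds[ie]); total <- total + bds[ie]
      next
    }
    for (try in 1:20) {
      target <- next_landing()
      amp <- sqrt(sum((target - pos)^2)) / px_per_deg
      if (amp >= 0.5) break
    }
    sd_ms <- 2.2 * amp + 21
    add("saccade", target, sd_ms); total <- total + sd_ms
    pos <- target
  }
  kind <- kind[seq_len(ne)]; xx <- xx[seq_len(ne)]; yy <- yy[seq_len(ne)]
  dur <- dur[seq_len(ne)]
  # trim to the exact duration; never end on a truncated saccade
  cum <- cumsum(dur)
  last <- which(cum >= duration_ms)[1]
  kind <- kind[1:last]; xx <- xx[1:last]; yy <- yy[1:last]; dur <- dur[1:last]
  over <- cum[last] - duration_ms
  if (kind[last] == "saccade") {
    # drop the truncated saccade and let the preceding event absorb the time
    kind <- kind[-last]; xx <- xx[-last]; yy <- yy[-last]; dur <- dur[-last]
    dur[length(dur)] <- dur[length(dur)] + (duration_ms - sum(dur))
  } else {
    dur[last] <- dur[last] - over
  }
  plan <- data.frame(kind = kind, x = xx, y = yy, duration = dur,
                     stringsAsFactors = FALSE)
  attr(plan, "px_per_deg") <- px_per_deg
  attr(plan, "noise_deg") <- profile$noise_deg
  plan
}

#' Render a scanpath plan as a raw gaze recording
#'
#' Inverse of the event parser: fixations hold position, saccades follow a
#' smooth sigmoidal trajectory (position profile `pbeta(tau, 4, 4)`, peak
#' velocity `2.1875 * amplitude / duration`, which exceeds 3x the 30 deg/s
#' detection threshold for amplitudes >= 1 degree under the main-sequence
#' durations), blinks become runs of missing pupil samples. Positional
#' jitter is temporally correlated (white noise smoothed with a 20 ms
#' Gaussian), emulating slow drift rather than sample-to-sample noise, so
#' jitter alone never trips the saccade detector.
#'
#' @param plan a scanpath plan from [sample_scanpath()]
#' @param rate sampling rate, Hz
#' @param noise_deg jitter SD in degrees (default: the plan's profile value)
#' @param px_per_deg calibration (default: the plan's value)
#' @param seed optional RNG seed
#' @param trial_id trial identifier
#' @return a [gaze_recording()]
#' @export
synthesize_trial_samples <- function(plan, rate = 1000,
                                     noise_deg = attr(plan, "noise_deg") %||% 0.02,
                                     px_per_deg = attr(plan, "px_per_deg") %||% 25,
                                     seed = NULL, trial_id = "trial") {
  if (!is.null(seed)) set.seed(seed)
  dt <- 1000 / rate
  bounds <- round(cumsum(plan$duration) / dt)
  counts <- pmax(diff(c(0, bounds)), 1L)
  n <- sum(counts)
  x <- numeric(n); y <- numeric(n); pupil <- rep(1000, n)
  prev <- c(plan$x[1], plan$y[1])
  at <- 0L
  for (i in seq_len(nrow(plan))) {
    ni <- counts[i]
    idx <- at + seq_len(ni)
    if (plan$kind[i] == "saccade") {
      tau <- (seq_len(ni) - 0.5) / ni
      s <- stats::pbeta(tau, 4, 4)
      x[idx] <- prev[1] + s * (plan$x[i] - prev[1])
      y[idx] <- prev[2] + s * (plan$y[i] - prev[2])
      prev <- c(plan$x[i], plan$y[i])
    } else {
      x[idx] <- plan$x[i]
      y[idx] <- plan$y[i]
      if (plan$kind[i] == "blink") pupil[idx] <- NA_real_
      prev <- c(plan$x[i], plan$y[i])
    }
    at <- at + ni
  }
  if (noise_deg > 0) {
    sm <- 20 * rate / 1000                       # 20 ms in samples
    k <- stats::dnorm(seq(-ceiling(4 * sm), ceiling(4 * sm)), sd = sm)
    k <- k / sum(k)
    gain <- noise_deg * px_per_deg / sqrt(sum(k^2))
    nx <- stats::filter(stats::rnorm(n), k, circular = TRUE) * gain
    ny <- stats::filter(stats::rnorm(n), k, circular = TRUE) * gain
    x <- x + as.numeric(nx); y <- y + as.numeric(ny)
  }
  gaze_recording(t = (0:(n - 1)) * dt, x = x, y = y, pupil = pupil,
                 rate = rate, px_per_deg = px_per_deg, trial_id = trial_id)
}

#' Convert a scanpath plan to its ideal event sequence
#'
#' The event table the parser would recover from a noiseless rendering of
#' the plan: onsets/offsets from cumulative durations, fixation centroids at
#' the planned landings.
#'
#' @param plan a scanpath plan
#' @param trial_id trial identifier
#' @return an event data.frame (same columns as [parse_events()] output)
#' @export
plan_to_events <- function(plan, trial_id = "trial") {
  off <- cumsum(plan$duration)
  on <- c(0, off[-length(off)])
  n <- nrow(plan)
  prevx <- c(plan$x[1], plan$x[-n]); prevy <- c(plan$y[1], plan$y[-n])
  sac <- plan$kind == "saccade"
  fix <- plan$kind == "fixation"
  data.frame(trial_id = trial_id, kind = plan$kind, onset = on, offset = off,
             duration = plan$duration,
             x = ifelse(fix, plan$x, NA_real_),
             y = ifelse(fix, plan$y, NA_real_),
             x_start = ifelse(sac, prevx, NA_real_),
             y_start = ifelse(sac, prevy, NA_real_),
             x_end = ifelse(sac, plan$x, NA_real_),
             y_end = ifelse(sac, plan$y, NA_real_),
             stringsAsFactors = FALSE)
}

#' Simulate a full two-cohort experiment
#'
#' Generates, fully seeded, the trial table and gaze data of a two-group
#' Spotlight experiment: for every observer, `blocks_per_race` blocks per
#' face race, each with `n_learn` 10 s learning trials and `2 * n_learn`
#' recognition trials (half old). Recognition outcomes are Bernoulli draws
#' from the design's aperture-dependent accuracy, and response times are
#' log-normal with aperture-dependent means. Gaze is returned either as
#' ideal event tables (`level = "events"`, fast) or as raw sample-level
#' recordings to be run through [parse_events()] (`level = "samples"`).
#'
#' @param design an [experiment_design()]
#' @param cohorts named list, one entry per group:
#'   `list(n = <observers>, profile = <observer_profile>)`
#' @param aperture_deg Spotlight aperture (2, 5 or 8)
#' @param seed RNG seed governing the whole simulation
#' @param layout a [landmark_layout()]
#' @param level `"events"` or `"samples"`
#' @param rate sampling rate for `level = "samples"`
#' @param px_per_deg calibration
#' @return list with `trials` (data.frame), `events` (data.frame of all
#'   events), `recordings` (list of `gaze_recording`, samples level only),
#'   `design`, `aperture_deg`, `seed`
#' @export
simulate_experiment <- function(design = experiment_design(), cohorts,
                                aperture_deg = 8, seed = 1,
                                layout = landmark_layout(),
                                level = c("events", "samples"),
                                rate = 1000, px_per_deg = 25) {
  level <- match.arg(level)
  stopifnot(inherits(design, "experiment_design"))
  if (any(vapply(cohorts, function(c) c$n, numeric(1)) < 2))
    stop_gm("need n >= 2 observers per group")
  set.seed(seed)
  acc <- unname(design$accuracy_by_aperture[as.character(aperture_deg)])
  mrt <- unname(design$rt_by_aperture[as.character(aperture_deg)])
  if (length(acc) != 1 || is.na(acc) || length(mrt) != 1 || is.na(mrt))
    stop_gm("aperture %s not in the design's accuracy/RT tables", aperture_deg)
  trials <- list(); events <- list(); recordings <- list()
  for (g in names(cohorts)) {
    profile <- cohorts[[g]]$profile
    for (o in seq_len(cohorts[[g]]$n)) {
      obs <- sprintf("%s%02d", g, o)
      for (race in design$races) for (b in seq_len(design$blocks_per_race)) {
        for (phase in c("learning", "recognition")) {
          ntr <- if (phase == "learning") design$n_learn else design$n_recog
          old <- if (phase == "learning") rep(NA, ntr) else
            sample(rep(c(TRUE, FALSE), each = design$n_learn))
          for (i in seq_len(ntr)) {
            dur <- if (phase == "learning") design$learn_exposure_ms else
              stats::rlnorm(1, log(mrt) - 0.4^2 / 2, 0.4)
            correct <- if (phase == "learning") TRUE else
              stats::runif(1) < acc
            tid <- sprintf("%s_%s_b%d_%s_%02d", obs, race, b,
                           substr(phase, 1, 4), i)
            trials[[length(trials) + 1]] <- data.frame(
              observer_id = obs, group = g, race = race, block = b,
              phase = phase, trial_id = tid, old = old[i],
              correct = correct, duration_ms = dur,
              aperture_deg = aperture_deg, stringsAsFactors = FALSE)
            plan <- sample_scanpath(profile, layout, dur, px_per_deg)
            events[[length(events) + 1]] <- plan_to_events(plan, tid)
            if (level == "samples")
              recordings[[tid]] <- synthesize_trial_samples(
                plan, rate = rate, px_per_deg = px_per_deg, trial_id = tid)
          }
        }
      }
    }
  }
  list(trials = do.call(rbind, trials), events = do.call(rbind, events),
       recordings = if (level == "samples") recordings,
       design = design, aperture_deg = aperture_deg, seed = seed)
}
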