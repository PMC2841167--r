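#' Z-score observer maps with moments pooled across all observers
#'
#' Normalises each observer's smoothed fixation map with the mean and
#' population SD of the concatenated pixel values of every observer map in
#' both groups, so per-observer ROI scores are directly comparable across
#' observers and groups.
#'
#' @param observer_maps named list of smoothed `stat_map`s (both groups)
#' @return list with `z_maps` (named list of `stat_map`s, kind `"z"`),
#'   `mu`, `s`
#' @export
zscore_observer_maps <- function(observer_maps) {
  pooled <- unlist(lapply(observer_maps, function(m) c(map_grid(m))))
  mu <- mean(pooled); s <- sd_pop(pooled)
  if (s == 0) stop_gm("degenerate observer maps: zero pooled SD")
  z <- lapply(observer_maps, function(m)
    stat_map((map_grid(m) - mu) / s, "z",
             px_per_deg = if (inherits(m, "stat_map")) m$meta$px_per_deg else 25,
             sigma_smooth_px = if (inherits(m, "stat_map")) m$meta$sigma_smooth_px else NA))
  list(z_maps = z, mu = mu, s = s)
}

resolve_profile <- function(p) {
  if (inherits(p, "observer_profile")) return(p)
  if (is.character(p))
    return(switch(p,
                  eye_biased = profile_eye_biased(),
                  nose_centered = profile_nose_centered(),
                  stop_gm("unknown profile '%s'", p)))
  do.call(observer_profile, p)
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Orchestrates every stage end to end: simulate two cohorts, (optionally)
#' render and parse raw samples, accumulate and smooth per-observer fixation
#' maps, form group maps and pooled Z-maps, compute the differential Z-map
#' and its Pixel-test clusters, extract per-observer ROI scores with the
#' mixed ANOVA and effect sizes, and run the bootstrap time-course analysis
#' on the dominant ROI. Deterministic given `config$seed`; the returned
#' report carries the seed and a hash of the configuration.
#'
#' @param config nested list (or path to a YAML file with the same
#'   structure). Recognised sections and their defaults:
#'   `seed` (1); `simulate` (`groups` — named list with `n` and `profile`,
#'   by default 10 eye-biased "WC" vs 10 nose-centered "EA" observers —,
#'   `aperture` 8, `level` "events", `n_learn` 14, `blocks_per_race` 2,
#'   `races`, `learn_exposure_ms` 10000, `rate` 1000);
#'   `parse` (thresholds of [parser_spec()]); `map` (`sigma` 10, `phase`
#'   "learning", `correct_only` TRUE for recognition, `width` 382, `height`
#'   390); `pixel_test` (`alpha` 0.05, `tails` "two"); `timecourse`
#'   (`B` 5000, bootstrap skipped when `B` = 0)
#' @param verbose print stage progress
#' @return a list of class `gazemap_report` with elements `trials`,
#'   `events`, `fixation_counts`, `group_maps`, `z_maps`, `differential`,
#'   `clusters`, `roi_scores`, `anova`, `region_tests`, `timecourse`,
#'   `config`, `config_hash`, `seed`
#' @export
run_pipeline <- function(config = list(), verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed %||% 1
  hash <- config_hash(config)

  sim_cfg <- config$simulate %||% list()
  groups <- sim_cfg$groups %||% list(
    WC = list(n = 10, profile = "eye_biased"),
    EA = list(n = 10, profile = "nose_centered"))
  cohorts <- lapply(groups, function(g)
    list(n = g$n %||% 10, profile = resolve_profile(g$profile %||% "eye_biased")))
  design <- experiment_design(
    n_learn = sim_cfg$n_learn %||% 14,
    blocks_per_race = sim_cfg$blocks_per_race %||% 2,
    races = sim_cfg$races %||% c("WC", "EA"),
    learn_exposure_ms = sim_cfg$learn_exposure_ms %||% 10000)
  level <- sim_cfg$level %||% "events"
  say("simulate: %d groups, aperture %s, level %s, seed %s",
      length(cohorts), sim_cfg$aperture %||% 8, level, seed)
  sim <- simulate_experiment(design, cohorts,
                             aperture_deg = sim_cfg$aperture %||% 8,
                             seed = seed, level = level,
                             rate = sim_cfg$rate %||% 1000)

  p_cfg <- config$parse %||% list()
  pspec <- parser_spec(v_thresh = p_cfg$v_thresh %||% 30,
                       a_thresh = p_cfg$a_thresh %||% 4000,
                       merge_gap = p_cfg$merge_gap %||% 20,
                       merge_dist = p_cfg$merge_dist %||% 0.30,
                       blink_min_missing = p_cfg$blink_min_missing %||% 3)
  events <- if (level == "samples") {
    say("parse: %d recordings", length(sim$recordings))
    do.call(rbind, lapply(sim$recordings, function(r)
      as.data.frame(parse_events(r, pspec))))
  } else sim$events
  events <- merge(events, sim$trials[, c("trial_id", "observer_id", "group",
                                         "phase", "correct")], by = "trial_id")

  m_cfg <- config$map %||% list()
  sigma <- m_cfg$sigma %||% 10
  W <- m_cfg$width %||% 382; H <- m_cfg$height %||% 390
  phase <- m_cfg$phase %||% "learning"
  mev <- events[events$phase == phase, , drop = FALSE]
  if (isTRUE(m_cfg$correct_only %||% (phase == "recognition")))
    mev <- mev[mev$correct, , drop = FALSE]
  say("map: phase %s, sigma %g px, %d fixations", phase, sigma,
      sum(mev$kind == "fixation"))
  obs_maps <- lapply(split(mev, mev$observer_id), function(e)
    smooth_map(accumulate_map(e, width = W, height = H), sigma))
  obs_group <- vapply(split(mev$group, mev$observer_id), function(g) g[1], "")
  gnames <- names(cohorts)
  grp_maps <- lapply(gnames, function(g)
    group_map(obs_maps[names(obs_maps)[obs_group == g]]))
  names(grp_maps) <- gnames

  pt_cfg <- config$pixel_test %||% list()
  ptspec <- pixel_test_spec(alpha = pt_cfg$alpha %||% 0.05,
                            tails = pt_cfg$tails %||% "two",
                            sigma_smooth_px = sigma)
  zz <- zscore_pooled(grp_maps[[1]], grp_maps[[2]])
  diffz <- differential_zmap(grp_maps[[1]], grp_maps[[2]])
  clusters <- significant_clusters(diffz, ptspec)
  say("pixel test: z_crit %.3f, %d cluster(s)", clusters$z_crit,
      length(clusters$clusters))

  fx <- events[events$kind == "fixation", , drop = FALSE]
  fixation_counts <- stats::aggregate(
    list(n_fixations = fx$trial_id),
    by = list(observer_id = fx$observer_id, group = fx$group,
              phase = fx$phase),
    FUN = length)
  trials_per <- stats::aggregate(
    list(n_trials = sim$trials$trial_id),
    by = list(observer_id = sim$trials$observer_id,
              phase = sim$trials$phase), FUN = length)
  fixation_counts <- merge(fixation_counts, trials_per)
  fixation_counts$per_trial <- fixation_counts$n_fixations /
    fixation_counts$n_trials

  roi_scores <- NULL; anova <- NULL; region_tests <- NULL; tc <- NULL
  if (length(clusters$clusters) > 0) {
    rois <- roi_from_clusters(clusters)
    signs <- vapply(clusters$clusters, function(c) c$sign, numeric(1))
    if (any(signs > 0) && any(signs < 0)) rois <- rois[c("pos1", "neg1")]
    oz <- zscore_observer_maps(obs_maps)
    roi_scores <- observer_roi_scores(oz$z_maps, rois, obs_group)
    if (length(rois) >= 2) {
      anova <- mixed_anova(roi_scores[roi_scores$region %in% names(rois)[1:2], ])
      region_tests <- region_group_tests(roi_scores)
      say("roi: interaction F(%d, %d) = %.2f", anova$df[1], anova$df[2], anova$F)
    }
    tc_cfg <- config$timecourse %||% list()
    B <- tc_cfg$B %||% 5000
    tspec <- timecourse_spec(
      B = max(B, 1),
      time_grid = seq(0, design$learn_exposure_ms, by = 10))
    roi_mask <- cluster_mask(clusters, sign = if (any(signs > 0)) 1 else -1)
    curves <- t(vapply(split(mev, mev$observer_id), fixation_frequency,
                       numeric(length(tspec$time_grid)),
                       roi_mask = roi_mask, spec = tspec))
    if (B >= 1000) {
      boot <- bootstrap_difference(curves[obs_group == gnames[1], ],
                                   curves[obs_group == gnames[2], ], tspec)
      tc <- list(time = tspec$time_grid, curves = curves, bootstrap = boot,
                 roi_area_px = sum(roi_mask))
    } else {
      say("timecourse: bootstrap skipped (B = %s < 1000)", B)
      tc <- list(time = tspec$time_grid, curves = curves, bootstrap = NULL,
                 roi_area_px = sum(roi_mask))
    }
  } else say("roi/timecourse skipped: no significant clusters")

  structure(list(trials = sim$trials, events = events,
                 fixation_counts = fixation_counts,
                 group_maps = grp_maps, z_maps = zz, differential = diffz,
                 clusters = clusters, roi_scores = roi_scores, anova = anova,
                 region_tests = region_tests, timecourse = tc,
                 config = config, config_hash = hash, seed = seed),
            class = "gazemap_report")
}

#' @export
print.gazemap_report <- function(x, ...) {
  cat(sprintf("<gazemap_report seed=%s config=%s>\n", x$seed, x$config_hash))
  cat(sprintf("  %d trials, %d events, %d observers\n", nrow(x$trials),
              nrow(x$events), length(unique(x$trials$observer_id))))
  cat(sprintf("  differential Pixel test: z_crit %.3f, %d cluster(s)\n",
              x$clusters$z_crit, length(x$clusters$clusters)))
  if (!is.null(x$anova))
    cat(sprintf("  Group x Region: F(%d, %d) = %.2f, p = %.3g, pes = %.2f\n",
                x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p,
                x$anova$partial_eta_sq))
  if (!is.null(x$timecourse) && !is.null(x$timecourse$bootstrap))
    cat(sprintf("  timecourse: %d/%d time points significant (B = %d)\n",
                sum(x$timecourse$bootstrap$significant),
                length(x$timecourse$time), x$timecourse$bootstrap$B))
  invisible(x)
}
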