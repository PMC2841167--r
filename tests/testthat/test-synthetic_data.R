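test_that("profiles and designs validate their invariants", {
  expect_error(observer_profile(c(left_eye = 0.5, nose = 0.4)), "sum to 1")
  expect_error(observer_profile(spread_deg = 0), "positive")
  p <- profile_eye_biased()
  expect_equal(sum(p$landmark_weights), 1)
  d <- experiment_design()
  expect_equal(d$n_recog, 2L * d$n_learn)
  expect_error(experiment_design(accuracy_by_aperture = c("2" = 1.2)),
               "0, 1")
})

test_that("generation is byte-identical under a fixed seed", {
  lay <- landmark_layout()
  expect_identical(make_face_image(lay, seed = 5), make_face_image(lay, seed = 5))
  p1 <- sample_scanpath(profile_eye_biased(), lay, 3000, seed = 6)
  p2 <- sample_scanpath(profile_eye_biased(), lay, 3000, seed = 6)
  expect_identical(p1, p2)
  r1 <- synthesize_trial_samples(p1, seed = 7)
  r2 <- synthesize_trial_samples(p2, seed = 7)
  expect_identical(r1, r2)
  s1 <- simulate_experiment(experiment_design(n_learn = 2, blocks_per_race = 1),
                            list(A = list(n = 2, profile = profile_eye_biased()),
                                 B = list(n = 2, profile = profile_nose_centered())),
                            seed = 9)
  s2 <- simulate_experiment(experiment_design(n_learn = 2, blocks_per_race = 1),
                            list(A = list(n = 2, profile = profile_eye_biased()),
                                 B = list(n = 2, profile = profile_nose_centered())),
                            seed = 9)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$events, s2$events)
})

test_that("synthetic faces are darker at landmarks and vary across identity", {
  lay <- landmark_layout()
  img <- make_face_image(lay, seed = 10)
  expect_true(all(img >= 1 & img <= 256))
  lm <- lay$landmarks
  for (i in seq_len(nrow(lm))) {
    at <- img[lm$cy[i] + 1, lm$cx[i] + 1]
    ring <- img[lm$cy[i] + 1, lm$cx[i] + 1 + 3 * lm$r[i]]
    expect_lt(at, ring)   # landmark centre darker than surrounding skin
  }
  set.seed(11)
  faces <- replicate(16, make_face_image(lay), simplify = FALSE)
  sdm <- group_pixel_stats(faces)$sd$grid
  expect_gt(mean(sdm), 0)   # nonzero identity variation everywhere
})

test_that("scanpaths follow the landmark mixture and fixation budget", {
  lay <- landmark_layout()
  # degenerate profile: everything lands on the nose centre
  pnose <- observer_profile(c(left_eye = 0, right_eye = 0, nose = 1,
                              mouth = 0), spread_deg = 1e-6)
  plan <- sample_scanpath(pnose, lay, 5000, seed = 12)
  fx <- plan[plan$kind == "fixation", ]
  expect_true(all(abs(fx$x - 191) < 0.01 & abs(fx$y - 215) < 0.01))

  # eye-biased profile: ~70% of fixation time near the eyes over many trials
  set.seed(13)
  eye_time <- tot_time <- 0; counts <- numeric(40)
  for (i in 1:40) {
    plan <- sample_scanpath(profile_eye_biased(), lay, 10000)
    fx <- plan[plan$kind == "fixation", ]
    d_le <- sqrt((fx$x - 165)^2 + (fx$y - 190)^2)
    d_re <- sqrt((fx$x - 217)^2 + (fx$y - 190)^2)
    near_eye <- pmin(d_le, d_re) < 30
    eye_time <- eye_time + sum(fx$duration[near_eye])
    tot_time <- tot_time + sum(fx$duration)
    counts[i] <- nrow(fx)
  }
  expect_gt(eye_time / tot_time, 0.60)
  expect_lt(abs(eye_time / tot_time - 0.70), 0.10)
  # 20-35 fixations per 10 s trial on average
  expect_gt(mean(counts), 20); expect_lt(mean(counts), 35)
  # plans tile the requested duration exactly
  expect_equal(sum(plan$duration), 10000)
})

test_that("synthesized recordings round-trip through the parser", {
  lay <- landmark_layout()
  # single planted fixation
  pl <- data.frame(kind = "fixation", x = 100, y = 150, duration = 600)
  ev <- parse_events(synthesize_trial_samples(pl, seed = 14))
  expect_identical(ev$kind, "fixation")

  # eight well-separated fixations recovered exactly at low noise
  quiet <- observer_profile(spread_deg = 1.2, fix_shape = 50,
                            fix_scale = 6, noise_deg = 0.05, blink_rate = 0)
  set.seed(15)
  hits <- 0
  for (i in 1:10) {
    repeat {
      plan <- sample_scanpath(quiet, lay, 8 * 321 + 7 * 27)
      if (sum(plan$kind == "fixation") == 8) break
    }
    ev <- parse_events(synthesize_trial_samples(plan))
    pf <- plan[plan$kind == "fixation", ]
    ef <- ev[ev$kind == "fixation", ]
    if (nrow(ef) == 8 &&
        max(sqrt((pf$x - ef$x)^2 + (pf$y - ef$y)^2)) / 25 < 0.2)
      hits <- hits + 1
  }
  expect_gte(hits, 9)

  # a planted 50 ms blink surfaces as exactly one blink event
  plb <- data.frame(kind = c("fixation", "blink", "fixation"),
                    x = c(120, 120, 120), y = c(80, 80, 80),
                    duration = c(400, 50, 400))
  evb <- parse_events(synthesize_trial_samples(plb, seed = 16))
  expect_equal(sum(evb$kind == "blink"), 1)
  expect_equal(sum(evb$kind == "fixation"), 2)
})

test_that("simulated experiments respect the design counts and accuracy", {
  design <- experiment_design()
  cohorts <- list(A = list(n = 2, profile = profile_eye_biased()),
                  B = list(n = 2, profile = profile_eye_biased()))
  sim <- simulate_experiment(design, cohorts, aperture_deg = 2, seed = 17)
  rec <- sim$trials[sim$trials$phase == "recognition", ]
  per_block <- aggregate(list(n = rec$trial_id),
                         by = rec[c("observer_id", "race", "block")],
                         FUN = length)
  expect_true(all(per_block$n == 28))
  olds <- aggregate(list(n_old = rec$old),
                    by = rec[c("observer_id", "race", "block")], FUN = sum)
  expect_true(all(olds$n_old == 14))
  lrn <- sim$trials[sim$trials$phase == "learning", ]
  expect_true(all(aggregate(list(n = lrn$trial_id),
                            by = lrn[c("observer_id", "race", "block")],
                            FUN = length)$n == 14))
  # at the 2 degree aperture, recognition sits at chance
  set.seed(18)
  cohorts10 <- list(A = list(n = 10, profile = profile_eye_biased()))
  sim2 <- simulate_experiment(design, cohorts10, aperture_deg = 2, seed = 19)
  rec2 <- sim2$trials[sim2$trials$phase == "recognition", ]
  expect_equal(nrow(rec2), 10 * 112)
  expect_lt(abs(mean(rec2$correct) - 0.5), 0.05)
  # RTs shrink as the aperture grows
  sim8 <- simulate_experiment(design, cohorts, aperture_deg = 8, seed = 20)
  expect_lt(mean(sim8$trials$duration_ms[sim8$trials$phase == "recognition"]),
            mean(rec$duration_ms))
  expect_error(simulate_experiment(design, cohorts, aperture_deg = 3),
               "not in the design")
})
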