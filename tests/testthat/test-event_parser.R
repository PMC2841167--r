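test_that("kinematics match hand-computed values on constructed traces", {
  # stationary gaze: identically zero
  rec <- const_rec(100)
  kin <- compute_kinematics(rec)
  expect_equal(kin$velocity, rep(0, 100))
  expect_equal(kin$acceleration, rep(0, 100))

  # 25 px per 1 ms sample at 25 px/deg -> 1 deg per 1 ms = 1000 deg/s
  n <- 50
  rec <- gaze_recording(t = 0:(n - 1), x = 25 * (0:(n - 1)), y = rep(0, n),
                        rate = 1000, px_per_deg = 25)
  kin <- compute_kinematics(rec)
  expect_equal(kin$velocity[2:(n - 1)], rep(1000, n - 2))

  # 0.01 px per sample -> 0.4 deg/s, far below the 30 deg/s threshold
  rec <- gaze_recording(t = 0:(n - 1), x = 0.01 * (0:(n - 1)), y = rep(0, n),
                        rate = 1000, px_per_deg = 25)
  expect_equal(compute_kinematics(rec)$velocity[5], 0.4)

  # samples adjacent to missing pupil have undefined kinematics
  pupil <- rep(1000, 100); pupil[40] <- NA
  rec <- const_rec(100, pupil = pupil)
  v <- compute_kinematics(rec)$velocity
  expect_true(all(is.na(v[39:41])))
  expect_false(anyNA(v[c(1:38, 42:100)]))
})

test_that("kinematics reject too-short and non-uniform recordings", {
  expect_error(compute_kinematics(const_rec(2)), "too short")
  rec <- gaze_recording(t = c(0, 1, 2.5, 3.5), x = rep(0, 4), y = rep(0, 4))
  expect_error(compute_kinematics(rec), "non-uniform")
})

test_that("parser segments fixations, saccades and blinks as specified", {
  # stationary 500 ms trace, full pupil: one fixation spanning the trial
  ev <- parse_events(const_rec(500))
  expect_identical(ev$kind, "fixation")
  expect_equal(ev$duration, 500)
  expect_equal(c(ev$x, ev$y), c(100, 120))

  # two stationary epochs joined by a fast 30-sample ramp
  n1 <- 200; nr <- 30; n2 <- 200
  x <- c(rep(100, n1), 100 + (1:nr) / nr * 100, rep(200, n2))
  rec <- gaze_recording(t = seq_along(x) - 1, x = x, y = rep(150, length(x)))
  ev <- parse_events(rec)
  expect_equal(sum(ev$kind == "fixation"), 2)
  expect_equal(sum(ev$kind == "saccade"), 1)
  expect_equal(sum(ev$kind == "blink"), 0)
  fx <- ev[ev$kind == "fixation", ]
  expect_equal(fx$x, c(100, 200))

  # 5 consecutive missing pupil samples form exactly one blink
  pupil <- rep(1000, 400); pupil[200:204] <- NA
  ev <- parse_events(const_rec(400, pupil = pupil))
  expect_equal(sum(ev$kind == "blink"), 1)

  # a 2-sample gap stays below the 3-sample blink criterion
  pupil <- rep(1000, 400); pupil[200:201] <- NA
  ev <- parse_events(const_rec(400, pupil = pupil))
  expect_equal(sum(ev$kind == "blink"), 0)

  # all-missing pupil: a single blink spanning the trial
  ev <- parse_events(const_rec(300, pupil = rep(NA_real_, 300)))
  expect_identical(ev$kind, "blink")
  expect_equal(ev$duration, 300)
})

test_that("saccade merging obeys the temporal AND spatial contiguity rule", {
  spec <- parser_spec()
  # 15 ms and 0.2 deg apart: merged into one saccade
  ev <- make_events(fix_ev(0, 100, 100, 100),
                    sacc_ev(100, 130, 100, 100, 200, 100),
                    fix_ev(130, 145, 200, 100),
                    sacc_ev(145, 175, 202, 104, 300, 100),  # 0.2 deg at 25 px/deg
                    fix_ev(175, 300, 300, 100))
  m <- merge_saccades(ev, spec)
  expect_equal(sum(m$kind == "saccade"), 1)
  s <- m[m$kind == "saccade", ]
  expect_equal(c(s$onset, s$offset), c(100, 175))
  expect_equal(c(s$x_start, s$x_end), c(100, 300))

  # 25 ms apart: temporal condition fails, no merge
  ev2 <- make_events(sacc_ev(100, 130, 100, 100, 200, 100),
                     fix_ev(130, 155, 200, 100),
                     sacc_ev(155, 185, 202, 104, 300, 100))
  expect_equal(sum(merge_saccades(ev2, spec)$kind == "saccade"), 2)

  # 15 ms but 0.5 deg apart: spatial condition fails
  ev3 <- make_events(sacc_ev(100, 130, 100, 100, 200, 100),
                     fix_ev(130, 145, 200, 100),
                     sacc_ev(145, 175, 212.5, 100, 300, 100))
  expect_equal(sum(merge_saccades(ev3, spec)$kind == "saccade"), 2)

  # merging is idempotent when nothing is mergeable
  expect_equal(as.data.frame(merge_saccades(ev2, spec)),
               as.data.frame(merge_saccades(merge_saccades(ev2, spec), spec)))
})

test_that("chained mergeable saccades collapse to one at the fixpoint", {
  sp <- parser_spec()
  chain <- make_events(
    sacc_ev(0, 30, 0, 0, 100, 0),
    fix_ev(30, 40, 100, 0),
    sacc_ev(40, 70, 102, 0, 200, 0),
    fix_ev(70, 80, 200, 0),
    sacc_ev(80, 110, 202, 0, 300, 0))
  m <- merge_saccades(chain, sp)
  expect_equal(sum(m$kind == "saccade"), 1)
  expect_equal(m$duration[m$kind == "saccade"], 110)
  # blinks block merging
  blocked <- make_events(
    sacc_ev(0, 30, 0, 0, 100, 0),
    data.frame(trial_id = "t", kind = "blink", onset = 30, offset = 40,
               duration = 10, x = NA_real_, y = NA_real_, x_start = NA_real_,
               y_start = NA_real_, x_end = NA_real_, y_end = NA_real_),
    sacc_ev(40, 70, 100, 0, 200, 0))
  expect_equal(sum(merge_saccades(blocked, sp)$kind == "saccade"), 2)
})

test_that("parsed events partition the recording span exactly", {
  set.seed(11)
  for (i in 1:10) {
    rec <- random_trace(n = sample(300:900, 1),
                        rate = sample(c(500, 1000), 1),
                        n_jumps = sample(2:6, 1),
                        missing_runs = sample(0:2, 1))
    ev <- parse_events(rec)
    dt <- 1000 / rec$rate
    expect_equal(sum(ev$duration), diff(range(rec$t)) + dt)
    expect_equal(ev$onset[-1], ev$offset[-nrow(ev)])
    expect_true(all(ev$duration > 0))
  }
})

test_that("parser agrees exactly with the brute-force per-sample oracle", {
  set.seed(21)
  for (i in 1:25) {
    rec <- random_trace(n = sample(200:1000, 1),
                        rate = sample(c(500, 1000), 1),
                        n_jumps = sample(1:7, 1),
                        missing_runs = sample(0:3, 1))
    got <- parse_events(rec)
    want <- oracle_parse(rec)
    expect_identical(got$kind, want$kind)
    expect_equal(got$onset, want$onset)
    expect_equal(got$offset, want$offset)
    expect_equal(got$x, want$x)
    expect_equal(got$y, want$y)
  }
})
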