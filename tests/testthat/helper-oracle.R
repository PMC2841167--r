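# Independent, deliberately naive re-implementations of the documented
# parsing rules, used as oracles. Everything here is plain loops; no code is
# shared with the package internals.

oracle_kinematics <- function(rec) {
  n <- length(rec$t)
  dts <- 1 / rec$rate
  xd <- rec$x / rec$px_per_deg
  yd <- rec$y / rec$px_per_deg
  miss <- is.na(rec$pupil)
  v <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i == 1) {
      if (!miss[1] && !miss[2])
        v[i] <- sqrt((xd[2] - xd[1])^2 + (yd[2] - yd[1])^2) / dts
    } else if (i == n) {
      if (!miss[n] && !miss[n - 1])
        v[i] <- sqrt((xd[n] - xd[n - 1])^2 + (yd[n] - yd[n - 1])^2) / dts
    } else if (!miss[i - 1] && !miss[i] && !miss[i + 1]) {
      v[i] <- sqrt((xd[i + 1] - xd[i - 1])^2 + (yd[i + 1] - yd[i - 1])^2) /
        (2 * dts)
    }
  }
  a <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i == 1) a[i] <- (v[2] - v[1]) / dts
    else if (i == n) a[i] <- (v[n] - v[n - 1]) / dts
    else a[i] <- (v[i + 1] - v[i - 1]) / (2 * dts)
  }
  list(v = v, a = a)
}

oracle_parse <- function(rec, spec = parser_spec()) {
  n <- length(rec$t)
  dt <- 1000 / rec$rate
  miss <- is.na(rec$pupil)
  if (all(miss)) {
    return(data.frame(kind = "blink", onset = rec$t[1],
                      offset = rec$t[n] + dt,
                      duration = rec$t[n] + dt - rec$t[1]))
  }
  kin <- oracle_kinematics(rec)
  flag <- logical(n)
  for (i in seq_len(n)) {
    s <- FALSE
    if (!is.na(kin$v[i]) && kin$v[i] > spec$v_thresh) s <- TRUE
    if (!is.na(kin$a[i]) && abs(kin$a[i]) > spec$a_thresh) s <- TRUE
    flag[i] <- s
  }
  nak <- is.na(kin$v)
  # blink cores: runs of >= blink_min_missing missing samples
  blink <- logical(n)
  i <- 1
  while (i <= n) {
    if (miss[i]) {
      j <- i
      while (j < n && miss[j + 1]) j <- j + 1
      if (j - i + 1 >= spec$blink_min_missing) {
        a <- i; b <- j
        while (a > 1 && (flag[a - 1] || miss[a - 1] || nak[a - 1])) a <- a - 1
        while (b < n && (flag[b + 1] || miss[b + 1] || nak[b + 1])) b <- b + 1
        blink[a:b] <- TRUE
      }
      i <- j + 1
    } else i <- i + 1
  }
  lab <- character(n)
  for (i in seq_len(n)) {
    lab[i] <- if (blink[i]) "blink" else if (flag[i]) "saccade" else "fixation"
  }
  # run-length segmentation
  ev <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && lab[j + 1] == lab[i]) j <- j + 1
    ev[[length(ev) + 1]] <- list(kind = lab[i], i = i, j = j)
    i <- j + 1
  }
  # iterative pairwise saccade merging to fixpoint
  repeat {
    done <- TRUE
    for (k in seq_along(ev)) {
      if (ev[[k]]$kind != "saccade") next
      l <- k + 1
      blocked <- FALSE
      while (l <= length(ev) && ev[[l]]$kind != "saccade") {
        if (ev[[l]]$kind == "blink") blocked <- TRUE
        l <- l + 1
      }
      if (l > length(ev) || blocked) next
      gap <- rec$t[ev[[l]]$i] - (rec$t[ev[[k]]$j] + dt)
      d <- sqrt((rec$x[ev[[l]]$i] - rec$x[ev[[k]]$j])^2 +
                (rec$y[ev[[l]]$i] - rec$y[ev[[k]]$j])^2) / rec$px_per_deg
      if (gap < spec$merge_gap && d < spec$merge_dist) {
        ev[[k]]$j <- ev[[l]]$j
        ev <- ev[-((k + 1):l)]
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  out <- data.frame(kind = character(0), onset = numeric(0),
                    offset = numeric(0), duration = numeric(0),
                    x = numeric(0), y = numeric(0))
  for (e in ev) {
    cx <- cy <- NA_real_
    if (e$kind == "fixation") {
      cx <- mean(rec$x[e$i:e$j]); cy <- mean(rec$y[e$i:e$j])
    }
    out <- rbind(out, data.frame(
      kind = e$kind, onset = rec$t[e$i], offset = rec$t[e$j] + dt,
      duration = rec$t[e$j] + dt - rec$t[e$i], x = cx, y = cy))
  }
  out
}

# random piecewise trace: stationary epochs joined by fast ramps, plus
# optional missing-pupil runs, for oracle-equivalence testing
random_trace <- function(n = 600, rate = 1000, px_per_deg = 25,
                         n_jumps = 4, missing_runs = 1) {
  dt <- 1000 / rate
  cuts <- sort(sample(50:(n - 50), n_jumps))
  x <- numeric(n); y <- numeric(n)
  px <- runif(1, 50, 330); py <- runif(1, 50, 340)
  start <- 1
  for (k in seq_len(n_jumps + 1)) {
    end <- if (k <= n_jumps) cuts[k] else n
    x[start:end] <- px; y[start:end] <- py
    if (k <= n_jumps) {
      ramp <- min(sample(3:25, 1), n - end)
      nx <- runif(1, 50, 330); ny <- runif(1, 50, 340)
      if (ramp > 1) {
        s <- seq(0, 1, length.out = ramp)
        x[end + seq_len(ramp)] <- px + s * (nx - px)
        y[end + seq_len(ramp)] <- py + s * (ny - py)
      }
      px <- nx; py <- ny
      start <- min(end + ramp + 1, n)
    }
  }
  x <- x + rnorm(n, 0, 0.3); y <- y + rnorm(n, 0, 0.3)
  pupil <- rep(1000, n)
  for (k in seq_len(missing_runs)) {
    at <- sample(seq_len(n - 12), 1)
    len <- sample(1:10, 1)
    pupil[at:(at + len - 1)] <- NA
  }
  gaze_recording(t = (0:(n - 1)) * dt, x = x, y = y, pupil = pupil,
                 rate = rate, px_per_deg = px_per_deg, trial_id = "rnd")
}

# hand-rolled sums-of-squares mixed ANOVA (2 groups x 2+ regions), used to
# cross-check the aov-based implementation
oracle_mixed_anova_F <- function(tab) {
  tab$observer_id <- as.character(tab$observer_id)
  obs <- unique(tab$observer_id)
  regions <- unique(tab$region)
  grand <- mean(tab$mean_z)
  r <- length(regions)
  obs_means <- sapply(obs, function(o) mean(tab$mean_z[tab$observer_id == o]))
  grp_of <- sapply(obs, function(o) tab$group[tab$observer_id == o][1])
  groups <- unique(grp_of)
  grp_means <- sapply(groups, function(g) mean(tab$mean_z[tab$group == g]))
  n_per <- length(obs) / length(groups)
  ss_group <- r * n_per * sum((grp_means - grand)^2)
  ss_subj_within <- r * sum((obs_means - grp_means[match(grp_of, groups)])^2)
  cell <- function(g, rg) mean(tab$mean_z[tab$group == g & tab$region == rg])
  reg_means <- sapply(regions, function(rg) mean(tab$mean_z[tab$region == rg]))
  ss_region <- length(obs) * sum((reg_means - grand)^2)
  ss_int <- 0
  for (g in groups) for (rg in regions) {
    ss_int <- ss_int + n_per *
      (cell(g, rg) - grp_means[match(g, groups)] -
       reg_means[match(rg, regions)] + grand)^2
  }
  ss_int <- unname(ss_int)
  ss_tot <- sum((tab$mean_z - grand)^2)
  ss_err_within <- unname(ss_tot - ss_group - ss_subj_within - ss_region -
                            ss_int)
  df_err <- (length(obs) - length(groups)) * (r - 1)
  list(F_int = (ss_int / (length(groups) - 1) / (r - 1)) /
         (ss_err_within / df_err),
       df = c((length(groups) - 1) * (r - 1), df_err),
       ss = c(group = ss_group, subj = ss_subj_within, region = ss_region,
              interaction = ss_int, error = ss_err_within, total = ss_tot))
}

# event-table builder for merge tests
make_events <- function(..., px_per_deg = 25) {
  ev <- do.call(rbind, list(...))
  attr(ev, "px_per_deg") <- px_per_deg
  class(ev) <- c("event_sequence", "data.frame")
  ev
}

sacc_ev <- function(onset, offset, x0, y0, x1, y1) {
  data.frame(trial_id = "t", kind = "saccade", onset = onset, offset = offset,
             duration = offset - onset, x = NA_real_, y = NA_real_,
             x_start = x0, y_start = y0, x_end = x1, y_end = y1)
}

fix_ev <- function(onset, offset, x, y) {
  data.frame(trial_id = "t", kind = "fixation", onset = onset,
             offset = offset, duration = offset - onset, x = x, y = y,
             x_start = NA_real_, y_start = NA_real_, x_end = NA_real_,
             y_end = NA_real_)
}

# stationary recording helper
const_rec <- function(n = 500, x = 100, y = 120, rate = 1000,
                      pupil = rep(1000, n), px_per_deg = 25) {
  gaze_recording(t = (0:(n - 1)) * (1000 / rate), x = rep(x, n),
                 y = rep(y, n), pupil = pupil, rate = rate,
                 px_per_deg = px_per_deg, trial_id = "const")
}
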