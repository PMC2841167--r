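score_table <- function(n_per = 10, regions = c("eye", "nose"),
                        gen = function(g, r) rnorm(1)) {
  rows <- list()
  for (g in c("A", "B")) for (o in seq_len(n_per)) for (r in regions) {
    rows[[length(rows) + 1]] <- data.frame(
      observer_id = sprintf("%s%02d", g, o), group = g, region = r,
      mean_z = gen(g, r))
  }
  do.call(rbind, rows)
}

test_that("ROI scores are unweighted means over cluster pixels", {
  z1 <- matrix(2, 20, 20)
  z2 <- matrix(0, 20, 20); z2[1] <- 1; z2[2] <- 3
  rois <- list(all = 1:400, pair = 1:2)
  tab <- observer_roi_scores(list(o1 = z1, o2 = z2), rois,
                             c(o1 = "A", o2 = "B"))
  expect_equal(tab$mean_z[tab$observer_id == "o1" & tab$region == "all"], 2)
  expect_equal(tab$mean_z[tab$observer_id == "o1" & tab$region == "pair"], 2)
  expect_equal(tab$mean_z[tab$observer_id == "o2" & tab$region == "pair"], 2)
  expect_error(observer_roi_scores(list(o1 = z1), list(empty = integer(0)),
                                   c(o1 = "A")), "empty region")
})

test_that("roi_from_clusters names signed regions by decreasing area", {
  g <- matrix(0, 60, 60)
  g[10:14, 10:14] <- 9; g[40:45, 40:45] <- 9; g[25:27, 50:52] <- -9
  sp <- pixel_test_spec(sigma_smooth_px = 5)
  rois <- roi_from_clusters(significant_clusters(g, sp))
  expect_named(rois, c("pos1", "pos2", "neg1"))
  expect_equal(lengths(rois), c(pos1 = 36L, pos2 = 25L, neg1 = 9L))
})

test_that("mixed ANOVA reproduces the classical decomposition", {
  # balanced 10 + 10 design: interaction df (1, 18)
  set.seed(41)
  tab <- score_table(10)
  a <- mixed_anova(tab)
  expect_equal(a$df, c(1, 18))
  expect_equal(a$n_per_group, 10L)
  # agreement with the hand-rolled sums-of-squares oracle
  want <- oracle_mixed_anova_F(tab)
  expect_equal(a$F, want$F_int, tolerance = 1e-9)
  expect_equal(a$df, want$df)
  # partial eta^2 from the within-stratum error
  expect_equal(a$partial_eta_sq,
               want$ss[["interaction"]] /
                 (want$ss[["interaction"]] + want$ss[["error"]]),
               tolerance = 1e-9)

  # small table against explicit group-mean arithmetic
  toy <- data.frame(observer_id = rep(c("a1", "a2", "b1", "b2"), each = 2),
                    group = rep(c("A", "B"), each = 4),
                    region = rep(c("eye", "nose"), 4),
                    mean_z = c(3, 1, 4, 0, 1, 3, 0, 2))
  at <- mixed_anova(toy)
  wt <- oracle_mixed_anova_F(toy)
  expect_equal(at$F, wt$F_int, tolerance = 1e-9)
  expect_equal(at$df, c(1, 2))

  # all-equal scores: no effect, F = 0
  flat <- score_table(4, gen = function(g, r) 1)
  expect_equal(mixed_anova(flat)$F, 0)
  # unbalanced tables are rejected
  expect_error(mixed_anova(tab[-1, ]), "unbalanced")
})

test_that("ANOVA sums of squares add up and F equals squared t", {
  set.seed(43)
  for (i in 1:5) {
    tab <- score_table(sample(4:12, 1))
    want <- oracle_mixed_anova_F(tab)
    expect_equal(sum(want$ss[c("group", "subj", "region", "interaction",
                               "error")]),
                 want$ss[["total"]], tolerance = 1e-9)
    # 2-level within factor: interaction F = t^2 on per-observer differences
    wide <- reshape(tab, idvar = c("observer_id", "group"),
                    timevar = "region", direction = "wide")
    d <- wide$mean_z.eye - wide$mean_z.nose
    tt <- t.test(d[wide$group == "A"], d[wide$group == "B"],
                 var.equal = TRUE)
    expect_equal(mixed_anova(tab)$F, unname(tt$statistic)^2,
                 tolerance = 1e-9)
  }
})

test_that("Cohen's d uses the pooled-SD convention", {
  expect_equal(cohens_d(c(2, 4), c(1, 3)), 1 / sqrt(2))
  expect_equal(cohens_d(c(1, 3), c(2, 4)), -1 / sqrt(2))
  set.seed(44)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_equal(cohens_d(a, a), 0)
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
  expect_error(cohens_d(c(1, 1), c(1, 1)), "degenerate")
})

test_that("per-region group tests find planted fixation biases", {
  set.seed(45)
  # group A biased to the eye region, B to the nose region
  tab <- score_table(10, gen = function(g, r) {
    mu <- if ((g == "A") == (r == "eye")) 1.5 else -1.5
    rnorm(1, mu, 0.5)
  })
  res <- region_group_tests(tab)
  expect_equal(nrow(res), 2)
  expect_true(all(res$p < 0.001))
  eye_d <- res$cohens_d[res$region == "eye"]
  nose_d <- res$cohens_d[res$region == "nose"]
  expect_gt(eye_d, 2)     # large effects, opposite directions
  expect_lt(nose_d, -2)
  expect_equal(res$df, c(18, 18))
  # Welch switch changes df but not the direction
  resw <- region_group_tests(tab, welch = TRUE)
  expect_true(all(sign(resw$t) == sign(res$t)))
})
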