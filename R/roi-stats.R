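#' Regions of interest from significant clusters
#'
#' Converts a `cluster_set` into named pixel-index regions, one per cluster,
#' named `pos1`, `neg1`, ... by sign and decreasing area unless names are
#' supplied.
#'
#' @param clusters a `cluster_set`
#' @param names optional character vector of region names, one per cluster
#' @return named list of integer pixel-index vectors
#' @export
roi_from_clusters <- function(clusters, names = NULL) {
  cl <- clusters$clusters
  if (length(cl) == 0) stop_gm("empty cluster set: no regions of interest")
  ord <- order(vapply(cl, function(c) -c$sign, numeric(1)),
               vapply(cl, function(c) -c$area_px, numeric(1)))
  cl <- cl[ord]
  if (is.null(names)) {
    sgn <- vapply(cl, function(c) c$sign, numeric(1))
    names <- paste0(ifelse(sgn > 0, "pos", "neg"),
                    stats::ave(sgn, sgn, FUN = seq_along))
  }
  if (length(names) != length(cl)) stop_gm("one name per cluster required")
  stats::setNames(lapply(cl, function(c) c$pixels), names)
}

#' Per-observer mean Z within each region of interest
#'
#' For each observer's Z-scored fixation map (normalised with the pooled
#' moments, see [zscore_pooled()]), computes the unweighted mean Z over the
#' pixels of every ROI.
#'
#' @param observer_z_maps named list of `stat_map`s or matrices (names =
#'   observer ids)
#' @param rois named list of pixel-index vectors, e.g. from
#'   [roi_from_clusters()]
#' @param groups named character vector mapping observer id to group label
#' @return data.frame with columns `observer_id`, `group`, `region`, `mean_z`
#' @export
observer_roi_scores <- function(observer_z_maps, rois, groups) {
  if (length(rois) == 0 || any(lengths(rois) == 0))
    stop_gm("empty region of interest")
  obs <- names(observer_z_maps)
  if (is.null(obs)) stop_gm("observer_z_maps must be a named list")
  rows <- list()
  for (o in obs) {
    g <- map_grid(observer_z_maps[[o]])
    for (r in names(rois)) {
      rows[[length(rows) + 1]] <- data.frame(
        observer_id = o, group = unname(groups[[o]]), region = r,
        mean_z = mean(g[rois[[r]]]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Two-way mixed-design ANOVA on ROI scores
#'
#' Classical sums-of-squares decomposition for one between-subjects factor
#' (`group`) and one within-subjects factor (`region`), fitted with
#' `aov()` and an observer error stratum. Requires a balanced table: every
#' observer contributes exactly one score per region. The Group x Region
#' interaction has numerator df `(g-1)(r-1)` and denominator df
#' `(N - g)(r - 1)`; with 10 observers per group and 2 regions this is
#' (1, 18). Partial eta squared is `SS_effect / (SS_effect + SS_error)` with
#' the error of the effect's own stratum.
#'
#' @param table data.frame with columns `observer_id`, `group`, `region`,
#'   `mean_z` (see [observer_roi_scores()])
#' @return list of class `mixed_anova` with elements `F`, `df`, `p`,
#'   `partial_eta_sq` (interaction), `effects` (all three effects), `n_per_group`
#' @export
mixed_anova <- function(table) {
  need <- c("observer_id", "group", "region", "mean_z")
  if (!all(need %in% names(table))) stop_gm("table must have columns %s",
                                            paste(need, collapse = ", "))
  tab <- table
  tab$observer_id <- factor(tab$observer_id)
  tab$group <- factor(tab$group)
  tab$region <- factor(tab$region)
  counts <- table(tab$observer_id, tab$region)
  if (any(counts != 1)) stop_gm("unbalanced table: need one score per observer x region")
  gsz <- table(tab$group[!duplicated(tab$observer_id)])
  if (length(unique(gsz)) != 1) stop_gm("unbalanced table: unequal group sizes")

  fit <- stats::aov(mean_z ~ group * region + Error(observer_id), data = tab)
  s <- summary(fit)
  between <- s[["Error: observer_id"]][[1]]
  within <- s[["Error: Within"]][[1]]
  rn <- function(df) trimws(rownames(df))

  eff <- function(stratum, term) {
    i <- match(term, rn(stratum))
    j <- match("Residuals", rn(stratum))
    ss <- stratum[["Sum Sq"]]
    F <- stratum[["F value"]][i]
    p <- stratum[["Pr(>F)"]][i]
    pes <- ss[i] / (ss[i] + ss[j])
    if (ss[i] < .Machine$double.eps^0.75 && !is.finite(F)) {
      # degenerate data (zero effect and zero error): no evidence of effect
      F <- 0; p <- 1; pes <- 0
    }
    list(F = F, df = c(stratum[["Df"]][i], stratum[["Df"]][j]), p = p,
         partial_eta_sq = pes)
  }
  effects <- list(group = eff(between, "group"),
                  region = eff(within, "region"),
                  interaction = eff(within, "group:region"))
  structure(list(F = effects$interaction$F, df = effects$interaction$df,
                 p = effects$interaction$p,
                 partial_eta_sq = effects$interaction$partial_eta_sq,
                 effects = effects, n_per_group = as.integer(gsz[1])),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("Group x Region interaction: F(%d, %d) = %.2f, p = %.3g, partial eta^2 = %.2f\n",
              x$df[1], x$df[2], x$F, x$p, x$partial_eta_sq))
  invisible(x)
}

#' Cohen's d for two independent groups
#'
#' Standardised mean difference `(mean_a - mean_b) / s_pooled`, with the
#' pooled SD using the `n_a + n_b - 2` denominator.
#'
#' @param group_a_scores,group_b_scores numeric vectors, each length >= 2
#' @return Cohen's d
#' @export
cohens_d <- function(group_a_scores, group_b_scores) {
  na <- length(group_a_scores); nb <- length(group_b_scores)
  if (na < 2 || nb < 2) stop_gm("each group needs at least 2 scores")
  sp2 <- ((na - 1) * stats::var(group_a_scores) +
          (nb - 1) * stats::var(group_b_scores)) / (na + nb - 2)
  if (sp2 == 0) stop_gm("degenerate samples: zero pooled variance")
  (mean(group_a_scores) - mean(group_b_scores)) / sqrt(sp2)
}

#' Per-region group comparisons: t-tests and Cohen's d
#'
#' Independent two-tailed t-tests comparing the two groups within each
#' region, classical equal-variance by default (set `welch = TRUE` for the
#' Welch correction), plus Cohen's d per region.
#'
#' @param table ROI score table (see [observer_roi_scores()])
#' @param welch use the Welch correction
#' @return data.frame with columns `region`, `t`, `df`, `p`, `cohens_d`
#' @export
region_group_tests <- function(table, welch = FALSE) {
  groups <- sort(unique(table$group))
  if (length(groups) != 2) stop_gm("exactly two groups required")
  out <- lapply(split(table, table$region), function(d) {
    a <- d$mean_z[d$group == groups[1]]
    b <- d$mean_z[d$group == groups[2]]
    tt <- stats::t.test(a, b, var.equal = !welch)
    data.frame(region = d$region[1], t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               cohens_d = cohens_d(a, b), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
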