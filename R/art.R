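#' Validate and normalize a long-format condition table
#'
#' The inferential layer works on a long table with one row per participant
#' x direction x coordination cell and one numeric response. The design
#' must be complete within subjects: every participant has all four cells.
#'
#' @param table data.frame with columns `participant_id, group, direction,
#'   coordination` and the response column `value_col`.
#' @param value_col name of the response column.
#' @return The table with factors normalized, invisibly checked.
#' @export
validate_long_table <- function(table, value_col = "value") {
  need <- c("participant_id", "group", "direction", "coordination", value_col)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tab <- table(table$participant_id, interaction(table$direction,
                                                 table$coordination))
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    stop("missing or duplicated within-subject cells, e.g. participant ",
         rownames(tab)[bad[1, 1]], " cell ", colnames(tab)[bad[1, 2]])
  }
  if (any(is.na(table[[value_col]]))) stop("missing response values")
  table
}

# effect estimates on the 2x2x2 factorial via unweighted cell means and
# inclusion-exclusion; returns per-row estimated contribution of `effect`
# and the full cell mean
art_components <- function(table, value_col) {
  g <- factor(table$group); d <- factor(table$direction)
  co <- factor(table$coordination)
  y <- table[[value_col]]
  cell <- interaction(g, d, co, drop = FALSE)
  cm <- tapply(y, list(g, d, co), mean)           # 2 x 2 x 2 cell means
  grand <- mean(cm)
  mg <- apply(cm, 1, mean); md <- apply(cm, 2, mean); mc <- apply(cm, 3, mean)
  mgd <- apply(cm, c(1, 2), mean); mgc <- apply(cm, c(1, 3), mean)
  mdc <- apply(cm, c(2, 3), mean)
  ig <- as.integer(g); id <- as.integer(d); ic <- as.integer(co)
  est <- list(
    group = mg[ig] - grand,
    direction = md[id] - grand,
    coordination = mc[ic] - grand,
    `group:direction` = mgd[cbind(ig, id)] - mg[ig] - md[id] + grand,
    `group:coordination` = mgc[cbind(ig, ic)] - mg[ig] - mc[ic] + grand,
    `direction:coordination` = mdc[cbind(id, ic)] - md[id] - mc[ic] + grand,
    `group:direction:coordination` =
      cm[cbind(ig, id, ic)] - mgd[cbind(ig, id)] - mgc[cbind(ig, ic)] -
      mdc[cbind(id, ic)] + mg[ig] + md[id] + mc[ic] - grand
  )
  list(estimates = est, cell_mean = cm[cbind(ig, id, ic)])
}

#' Align and rank a response for one factorial effect
#'
#' The aligned-rank-transform step: the response is aligned for the target
#' effect by subtracting the full factorial cell mean and adding back the
#' estimated contribution of that effect alone (so every other effect is
#' stripped), then midrank-transformed over the whole sample.
#'
#' @param table long table (see [validate_long_table()]).
#' @param effect one of `group`, `direction`, `coordination`,
#'   `group:direction`, `group:coordination`, `direction:coordination`,
#'   `group:direction:coordination`.
#' @param value_col response column name.
#' @return List `aligned` (aligned responses) and `ranked` (their
#'   midranks).
#' @export
align_and_rank <- function(table, effect, value_col = "value") {
  table <- validate_long_table(table, value_col)
  comp <- art_components(table, value_col)
  if (!effect %in% names(comp$estimates))
    stop("unknown effect: ", effect)
  aligned <- unname(table[[value_col]] - comp$cell_mean +
                      comp$estimates[[effect]])
  list(aligned = aligned, ranked = rank(aligned))
}

art_effects <- c("group", "direction", "coordination", "group:direction",
                 "group:coordination", "direction:coordination",
                 "group:direction:coordination")

# mixed-design ANOVA on a (ranked) response; returns F, dfs, p for `effect`
# using the participant-stratified error terms
mixed_anova_effect <- function(table, response, effect) {
  d <- data.frame(y = response,
                  group = factor(table$group),
                  direction = factor(table$direction),
                  coordination = factor(table$coordination),
                  pid = factor(table$participant_id))
  fit <- stats::aov(y ~ group * direction * coordination +
                      Error(pid / (direction * coordination)), data = d)
  s <- summary(fit)
  for (stratum in s) {
    tab <- stratum[[1]]
    hit <- which(trimws(rownames(tab)) == effect)
    if (length(hit)) {
      resid_row <- which(trimws(rownames(tab)) == "Residuals")
      return(list(F = tab[hit, "F value"], df1 = tab[hit, "Df"],
                  df2 = tab[resid_row, "Df"], p = tab[hit, "Pr(>F)"]))
    }
  }
  stop("effect not found in ANOVA strata: ", effect)
}

#' Aligned-rank-transform mixed-design ANOVA
#'
#' The nonparametric 2 x 2 x 2 factorial: for each of the seven effects the
#' response is aligned and midranked for that effect alone
#' ([align_and_rank()]), then a standard mixed-design ANOVA (one
#' between-subjects factor, two within) is run on the ranks and the F for
#' the target effect is read from its own error stratum: the between-group
#' effect against participants-within-group (df2 = n - 2), within effects
#' against their participant-interaction strata.
#'
#' @param table long table (see [validate_long_table()]).
#' @param value_col response column name.
#' @return data.frame with one row per effect: `effect, F, df1, df2, p,
#'   partial_eta_sq`.
#' @export
art_anova <- function(table, value_col = "value") {
  table <- validate_long_table(table, value_col)
  rows <- lapply(art_effects, function(eff) {
    ranked <- align_and_rank(table, eff, value_col)$ranked
    a <- mixed_anova_effect(table, ranked, eff)
    data.frame(effect = eff, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p,
               partial_eta_sq = partial_eta_sq(a$F, a$df1, a$df2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Post-hoc comparisons for an interaction
#'
#' Compares the interaction levels sharing one main level: for a two-way
#' interaction (e.g. `group:coordination`) the four comparisons are the two
#' between-group contrasts at each level of the second factor
#' (Mann-Whitney) and the two within-group contrasts across the second
#' factor (Wilcoxon signed-rank). For the three-way interaction, all
#' level-pairs of the 2 x 2 x 2 cells differing in exactly one factor are
#' enumerated (between-group pairs via Mann-Whitney, within pairs via
#' Wilcoxon). P-values are Bonferroni-corrected with m = number of
#' comparisons in the suite. Factors not named in the interaction are
#' collapsed within participant by the median.
#'
#' @param table long table (see [validate_long_table()]).
#' @param interaction_label e.g. `"group:coordination"`,
#'   `"group:direction"`, or `"group:direction:coordination"`.
#' @param value_col response column name.
#' @param alternative passed to the underlying tests.
#' @param ci logical: attach bootstrap confidence intervals.
#' @param n_boot,seed bootstrap settings for the intervals.
#' @return data.frame: one row per comparison with `comparison, test_kind,
#'   statistic, n1, n2, p_raw, p_adjusted, r_rb, ci_lower, ci_upper`.
#' @export
posthoc_suite <- function(table, interaction_label = "group:coordination",
                          value_col = "value",
                          alternative = "two_sided", ci = TRUE,
                          n_boot = 10000, seed = 1L) {
  table <- validate_long_table(table, value_col)
  facs <- strsplit(interaction_label, ":", fixed = TRUE)[[1]]
  known <- c("group", "direction", "coordination")
  if (!all(facs %in% known) || length(facs) < 2)
    stop("unknown interaction label: ", interaction_label)
  collapse <- setdiff(known, facs)
  # collapse unnamed factors within participant by the median
  keyvars <- c("participant_id", "group", intersect(known, facs))
  keyvars <- unique(keyvars)
  agg <- stats::aggregate(table[[value_col]],
                          by = lapply(keyvars, function(v) table[[v]]),
                          FUN = stats::median)
  names(agg) <- c(keyvars, "value")

  cells <- setdiff(facs, "group")
  comparisons <- list()
  level_sets <- lapply(cells, function(f) sort(unique(agg[[f]])))
  names(level_sets) <- cells
  grid <- expand.grid(level_sets, stringsAsFactors = FALSE)
  if ("group" %in% facs) {
    # between-group contrast at each combination of the other factor levels
    for (i in seq_len(nrow(grid))) {
      sel <- rep(TRUE, nrow(agg))
      for (f in cells) sel <- sel & agg[[f]] == grid[i, f]
      lab <- paste0("blind vs sighted | ",
                    paste(unlist(grid[i, , drop = FALSE]), collapse = ":"))
      comparisons[[lab]] <- list(
        kind = "mann_whitney",
        x = agg$value[sel & agg$group == "blind"],
        y = agg$value[sel & agg$group == "sighted"])
    }
  }
  # within contrasts: pairs of cells differing in exactly one non-group factor,
  # split by group when group is part of the interaction
  group_splits <- if ("group" %in% facs) sort(unique(agg$group)) else "all"
  for (gs in group_splits) {
    sub <- if (identical(gs, "all")) agg else agg[agg$group == gs, ]
    for (f in cells) {
      lv <- level_sets[[f]]
      others <- setdiff(cells, f)
      ogrid <- if (length(others))
        expand.grid(level_sets[others], stringsAsFactors = FALSE)
      else data.frame(row.names = 1)
      for (i in seq_len(nrow(ogrid))) {
        sel <- rep(TRUE, nrow(sub))
        for (of in others) sel <- sel & sub[[of]] == ogrid[i, of]
        a <- sub[sel & sub[[f]] == lv[1], ]
        b <- sub[sel & sub[[f]] == lv[2], ]
        a <- a[order(a$participant_id), ]; b <- b[order(b$participant_id), ]
        ctx <- c(if (!identical(gs, "all")) gs,
                 if (length(others)) paste(unlist(ogrid[i, , drop = FALSE]),
                                           collapse = ":"))
        lab <- paste0(lv[1], " vs ", lv[2],
                      if (length(ctx)) paste0(" | ", paste(ctx, collapse = ":")))
        comparisons[[lab]] <- list(kind = "wilcoxon_signed_rank",
                                   x = a$value, y = b$value)
      }
    }
  }
  m <- length(comparisons)
  rows <- lapply(names(comparisons), function(lab) {
    cmp <- comparisons[[lab]]
    if (cmp$kind == "mann_whitney") {
      tst <- mann_whitney_exact(cmp$x, cmp$y, alternative)
      stat <- tst$U; n1 <- tst$n1; n2 <- tst$n2
      rrb <- rank_biserial(stat, n1, n2, "mann_whitney")
      kind_ci <- "mann_whitney"
    } else {
      tst <- wilcoxon_signed_rank_exact(cmp$x, cmp$y, alternative)
      stat <- tst$W; n1 <- tst$n; n2 <- tst$n
      rrb <- rank_biserial(stat, n1, kind = "wilcoxon")
      kind_ci <- "wilcoxon"
    }
    lo <- up <- NA_real_
    if (ci) {
      bci <- rb_confidence_interval(cmp$x, cmp$y, kind_ci,
                                    n_boot = n_boot, seed = seed)
      lo <- bci$lower; up <- bci$upper
    }
    data.frame(comparison = lab, test_kind = cmp$kind, statistic = stat,
               n1 = n1, n2 = n2, p_raw = tst$p,
               p_adjusted = min(1, m * tst$p), r_rb = rrb,
               ci_lower = lo, ci_upper = up, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "m_comparisons") <- m
  out
}
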