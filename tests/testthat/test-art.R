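test_that("alignment strips every other effect", {
  set.seed(40)
  # balanced design: aligned responses sum to zero exactly
  bal <- null_long_table(10, 10)
  for (eff in c("group", "direction", "group:coordination"))
    expect_equal(sum(align_and_rank(bal, eff)$aligned), 0, tolerance = 1e-9)
  tab <- null_long_table()
  for (eff in c("group", "coordination", "group:coordination",
                "group:direction:coordination")) {
    ar <- align_and_rank(tab, eff)
    # ranks are a permutation of the midranks of 1..N
    expect_equal(sort(unname(ar$ranked)), as.numeric(seq_len(nrow(tab))))
    # stripping diagnostic: a fixed-effects factorial ANOVA on the aligned
    # (not yet ranked) response shows F ~ 0 for every effect except the target
    d <- data.frame(y = ar$aligned, g = factor(tab$group),
                    di = factor(tab$direction), co = factor(tab$coordination))
    sm <- summary(aov(y ~ g * di * co, data = d))[[1]]
    lab <- c(group = "g", direction = "di", coordination = "co",
             `group:direction` = "g:di", `group:coordination` = "g:co",
             `direction:coordination` = "di:co",
             `group:direction:coordination` = "g:di:co")
    # with the unbalanced 10/11 group sizes the stripped effects retain a
    # numerically tiny F (weighted vs unweighted margins), orders of
    # magnitude below any real effect
    for (other in setdiff(names(lab), eff)) {
      row <- which(trimws(rownames(sm)) == lab[[other]])
      expect_lt(sm[row, "F value"], 0.01)
    }
  }
  expect_error(align_and_rank(tab, "bogus"), "unknown effect")
})

test_that("the mixed design yields the printed degrees-of-freedom structure", {
  set.seed(41)
  tab <- null_long_table(10, 11)  # 21 participants
  res <- art_anova(tab)
  expect_equal(nrow(res), 7)
  expect_true(all(res$df1 == 1))
  expect_true(all(res$df2 == 19))  # n - 2 for every stratum in the 2x2x2
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_equal(res$partial_eta_sq,
               res$F * res$df1 / (res$F * res$df1 + res$df2), tolerance = 1e-12)
})

test_that("rank step depends only on the ordering of aligned responses", {
  set.seed(42)
  tab <- null_long_table()
  r1 <- align_and_rank(tab, "group")
  # any strictly increasing transform of the response changes the aligned
  # values but the rank vector of the aligned response drives the ANOVA;
  # verify ranks are invariant to monotone rescaling of the aligned values
  ord <- order(r1$aligned)
  expect_equal(rank(r1$aligned), rank(exp(r1$aligned / max(abs(r1$aligned)))),
               tolerance = 0)
  expect_equal(r1$ranked[ord], seq_len(nrow(tab)))
})

test_that("a pure group shift is detected without inflating within effects", {
  set.seed(43)
  hits <- 0; n_rep <- 200
  within_fp <- 0
  for (i in seq_len(n_rep)) {
    tab <- null_long_table()
    # observation variance is 2 (unit residual + unit subject effect), so a
    # two-standard-deviation group shift is 2*sqrt(2)
    tab$value[tab$group == "blind"] <- tab$value[tab$group == "blind"] +
      2 * sqrt(2)
    res <- art_anova(tab)
    if (res$p[res$effect == "group"] < 0.01) hits <- hits + 1
    if (res$p[res$effect == "direction:coordination"] < 0.05)
      within_fp <- within_fp + 1
  }
  expect_gte(hits / n_rep, 0.95)
  expect_lte(within_fp / n_rep, 0.10)  # 99% binomial bound around 0.05
})

test_that("missing within cells are rejected with a named cell", {
  tab <- null_long_table()
  bad <- tab[-1, ]
  expect_error(art_anova(bad), "missing")
  dup <- rbind(tab, tab[1, ])
  expect_error(art_anova(dup), "cells")
})

test_that("the two-way post-hoc suite has the 2+2 between/within split", {
  set.seed(44)
  tab <- null_long_table()
  ph <- posthoc_suite(tab, "group:coordination", ci = FALSE)
  expect_equal(nrow(ph), 4)
  expect_equal(sum(ph$test_kind == "mann_whitney"), 2)
  expect_equal(sum(ph$test_kind == "wilcoxon_signed_rank"), 2)
  expect_equal(attr(ph, "m_comparisons"), 4)
  expect_equal(ph$p_adjusted, pmin(1, 4 * ph$p_raw), tolerance = 1e-12)
  # within comparisons use the paired sizes of their own group
  wsr <- ph[ph$test_kind == "wilcoxon_signed_rank", ]
  expect_setequal(wsr$n1, c(10, 11))
})

test_that("the three-way suite enumerates only one-factor-apart cell pairs", {
  set.seed(45)
  tab <- null_long_table()
  ph <- posthoc_suite(tab, "group:direction:coordination", ci = FALSE)
  # cube of 2x2x2 cells has 12 edges: 4 between-group, 8 within
  expect_equal(nrow(ph), 12)
  expect_equal(sum(ph$test_kind == "mann_whitney"), 4)
  expect_equal(sum(ph$test_kind == "wilcoxon_signed_rank"), 8)
  expect_equal(attr(ph, "m_comparisons"), 12)
  expect_error(posthoc_suite(tab, "group:speed"), "unknown interaction")
})

test_that("bonferroni adjustment caps at one", {
  set.seed(46)
  tab <- null_long_table()
  ph <- posthoc_suite(tab, "group:coordination", ci = FALSE)
  expect_true(all(ph$p_adjusted <= 1))
})
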