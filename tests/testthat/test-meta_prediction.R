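test_that("level series pair study-level values with exposure levels", {
  tab <- fixture_appendix_like()
  s <- build_level_series(tab, "TT%ct")
  expect_equal(nrow(s), 44)
  expect_equal(sum(s$level == 2), 11)
  expect_equal(attr(s, "n_excluded"), 0)

  # RR series is plumbing over the per-study effect estimates
  s_rr <- build_level_series(tab, "RRTT")
  expect_equal(s_rr$value, study_effects(tab, "TT")$rr)

  # studies lacking a level annotation are excluded and counted
  tab2 <- tab
  tab2$ap_death_level[1:5] <- NA
  s2 <- build_level_series(tab2, "TT%ca")
  expect_equal(nrow(s2), 39)
  expect_equal(attr(s2, "n_excluded"), 5)

  none <- make_studies(case = c(10, 20, 70), ctrl = c(5, 20, 75))
  expect_error(build_level_series(none, "TT%ca"), "air-pollution")
  expect_error(build_level_series(tab, "bogus"), "cannot parse")
})

test_that("the one-split partition matches hand computation", {
  p <- partition_one_split(make_series(c(2, 2, 2, 4, 4, 4), c(1, 1, 1, 5, 5, 5)))
  expect_equal(p$left_levels, 2L)
  expect_equal(p$right_levels, 4L)
  expect_equal(c(p$left_mean, p$right_mean), c(1, 5))
  expect_equal(p$sse, 0)
  expect_true(is.finite(p$aicc))  # SSE floored before the log

  p2 <- partition_one_split(make_series(c(2, 2, 2, 3, 3, 3), c(1, 1, 2, 5, 5, 6)))
  expect_equal(p2$left_levels, 2L)
  expect_equal(p2$left_mean, 4 / 3, tolerance = 1e-12)
  expect_equal(p2$right_mean, 16 / 3, tolerance = 1e-12)
  expect_equal(p2$sse, 4 / 3, tolerance = 1e-12)

  expect_error(partition_one_split(make_series(c(2, 2, 2), 1:3)), "distinct levels")
  expect_error(partition_one_split(make_series(c(2, 3), 1:2)), "3 observations")
})

test_that("partition agrees with exhaustive enumeration of contiguous splits", {
  set.seed(17)
  for (i in 1:100) {
    lvl <- sample(2:4, 12, replace = TRUE)
    if (length(unique(lvl)) < 2) next
    val <- rnorm(12, mean = lvl)
    p <- partition_one_split(make_series(lvl, val))
    oracle <- brute_force_split(lvl, val)
    expect_equal(p$left_levels, oracle$left)
    expect_equal(p$sse, oracle$sse, tolerance = 1e-10)
  }
})

test_that("SSE ties break toward isolating the lowest level", {
  # both contiguous splits leave SSE = 1; the {2}|{3,4} split must win
  p <- partition_one_split(make_series(c(2, 2, 3, 3, 4, 4), c(0, 0, 1, 1, 0, 0)))
  expect_equal(p$left_levels, 2L)
  expect_equal(sort(p$right_levels), c(3L, 4L))
})

test_that("AICc decreases with SSE at fixed n and is undefined for tiny n", {
  a <- partition_one_split(make_series(c(2, 2, 2, 3, 3, 3), c(1, 1, 2, 5, 5, 6)))
  b <- partition_one_split(make_series(c(2, 2, 2, 3, 3, 3), c(1, 1, 3, 5, 5, 9)))
  expect_true(a$sse < b$sse)
  expect_true(a$aicc < b$aicc)

  tiny <- partition_one_split(make_series(c(2, 2, 3), c(1, 2, 5)))
  expect_true(is.na(tiny$aicc))
  expect_false(tiny$aicc_defined)
})

test_that("Tukey-Kramer comparisons match stats::TukeyHSD", {
  # two identical groups: zero difference, p = 1
  eq <- tukey_hsd(make_series(c(2, 2, 2, 3, 3, 3), c(1, 2, 3, 1, 2, 3)))
  expect_equal(eq$comparisons$difference, 0)
  expect_equal(eq$comparisons$p_adjusted, 1)

  # hand-checkable balanced case: diff 4, MSE 5/3
  s <- make_series(rep(c(2, 3), each = 4), c(1, 2, 3, 4, 5, 6, 7, 8))
  tk <- tukey_hsd(s)
  expect_equal(tk$comparisons$difference, 4)
  expect_equal(tk$mse, 5 / 3, tolerance = 1e-12)
  expect_equal(tk$df_error, 6L)

  # oracle comparison on unequal group sizes, three levels
  set.seed(23)
  s2 <- make_series(rep(c(2, 3, 4), times = c(5, 9, 12)), rnorm(26, rep(c(0, 1, 1.5), times = c(5, 9, 12))))
  tk2 <- tukey_hsd(s2)
  or <- TukeyHSD(aov(value ~ factor(level), data = s2))$`factor(level)`
  ours <- tk2$comparisons[order(tk2$comparisons$pair), ]
  expect_equal(sort(ours$difference), sort(abs(or[, "diff"])),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sort(ours$p_adjusted), sort(or[, "p adj"]),
               tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(sort(ours$ci_high - ours$ci_low),
               sort(or[, "upr"] - or[, "lwr"]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("with two groups Tukey reduces to the pooled-variance t-test", {
  set.seed(29)
  for (i in 1:20) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    s <- make_series(rep(c(2, 4), times = c(n1, n2)),
                     c(rnorm(n1), rnorm(n2, 0.8)))
    tk <- tukey_hsd(s)
    tt <- t.test(s$value[s$level == 2], s$value[s$level == 4], var.equal = TRUE)
    expect_equal(tk$comparisons$p_adjusted, tt$p.value, tolerance = 1e-5)
  }
})

test_that("Tukey adjustment is conservative and CIs agree with p at 0.05", {
  set.seed(37)
  for (i in 1:25) {
    s <- make_series(rep(2:4, each = 6), rnorm(18, rep(c(0, 0.5, 1), each = 6)))
    tk <- tukey_hsd(s)
    for (j in seq_len(nrow(tk$comparisons))) {
      # unadjusted reference on the same pooled MSE and error df
      t_stat <- tk$comparisons$difference[j] / tk$comparisons$se_difference[j]
      p_unadj <- 2 * pt(-abs(t_stat), df = tk$df_error)
      expect_true(tk$comparisons$p_adjusted[j] >= p_unadj - 1e-6)
      excl <- tk$comparisons$ci_low[j] > 0 | tk$comparisons$ci_high[j] < 0
      expect_equal(excl, tk$comparisons$p_adjusted[j] < 0.05)
    }
  }
})

test_that("Tukey refuses or trims degenerate level layouts", {
  expect_warning(tk <- tukey_hsd(make_series(c(2, 3, 3, 4, 4), c(1, 2, 3, 4, 5))),
                 "excluding")
  expect_equal(nrow(tk$group_stats), 2)
  expect_error(suppressWarnings(tukey_hsd(make_series(c(2, 3, 3), 1:3))),
               "at least 2 levels")
})

test_that("trend curves interpolate level means and flag linearity", {
  lin <- trend_curve(make_series(c(2, 3, 4, 2, 3, 4), c(1, 2, 3, 1, 2, 3)))
  expect_equal(unname(lin$coefficients["level^2"]), 0, tolerance = 1e-9)

  s <- make_series(rep(2:4, each = 2), c(5, 5, 9, 9, 8, 8))
  tc <- trend_curve(s)
  expect_equal(tc$fitted$fitted, tc$fitted$group_mean, tolerance = 1e-9)
  expect_equal(tc$residual_ss, 0, tolerance = 1e-9)
})

test_that("case trend exceeds control trend at high levels under a G-by-E tilt", {
  cfg <- synthetic_config(seed = 7, gxe_slope = 10,
                          case_n_range = c(500L, 600L),
                          ctrl_n_range = c(500L, 600L))
  tr <- genotype_trends(generate_table(cfg), "TT")
  for (lv in 3:4) {
    expect_gt(tr$fitted[tr$arm == "case" & tr$level == lv],
              tr$fitted[tr$arm == "ctrl" & tr$level == lv])
  }
})

test_that("heat-map matrices mark empty cells as missing", {
  tab <- make_studies(
    case = c(5, 45, 50, 6, 44, 50, 4, 46, 50, 40, 40, 20, 42, 38, 20, 41, 39, 20),
    ctrl = rep(c(10, 40, 50), 6),
    ap_death_level = rep(c(2, 4), each = 3))
  m <- heatmap_matrix(tab, "TT%ca", bins = 4)
  expect_true(is.na(m["2", 4]))          # no low-pollution study in the top bin
  expect_equal(m["4", 4], 3)             # high-TT studies concentrate at level 4
  expect_true(all(is.na(m) | m >= 0))

  # uniform data: a single constant cell per level
  u <- heatmap_matrix(make_studies(case = rep(c(10, 40, 50), 4),
                                   ctrl = rep(c(10, 40, 50), 4),
                                   ap_death_level = rep(c(2, 3), each = 2)),
                      "TT%ca", bins = 3)
  expect_equal(sum(!is.na(u)), 2)
  expect_true(all(u == 2, na.rm = TRUE))
})

test_that("meta-prediction outputs are invariant under row reordering", {
  tab <- fixture_appendix_like()
  set.seed(41)
  shuffled <- tab[sample(nrow(tab)), ]
  for (v in c("TT%ca", "RRCT")) {
    a <- partition_one_split(build_level_series(tab, v))
    b <- partition_one_split(build_level_series(shuffled, v))
    expect_equal(a$left_levels, b$left_levels)
    expect_equal(a$sse, b$sse, tolerance = 1e-9)
    ta <- tukey_hsd(build_level_series(tab, v))
    tb <- tukey_hsd(build_level_series(shuffled, v))
    expect_equal(ta$comparisons$p_adjusted[order(ta$comparisons$pair)],
                 tb$comparisons$p_adjusted[order(tb$comparisons$pair)],
                 tolerance = 1e-9)
  }
})
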