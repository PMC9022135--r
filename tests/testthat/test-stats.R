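test_that("rank-sum test handles identical and fully separated samples", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 9 / 2)              # n1 n2 / 2
  expect_equal(r$p_value, 1)

  r2 <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(r2$exact)
  expect_equal(r2$p_value, 0.1)                 # 2 / C(6, 3)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("the exact rank-sum path matches full enumeration", {
  set.seed(61)
  for (n in 2:6) {
    for (rep in 1:4) {
      p <- tie_free_pair(n)
      got <- wilcoxon_rank_sum(p$x, p$y)
      expect_true(got$exact)
      expect_equal(got$p_value, enum_wilcox_p(p$x, p$y), tolerance = 1e-12)
    }
  }
})

test_that("large shifted samples are detected with overwhelming power", {
  set.seed(62)
  x <- rnorm(2000); y <- rnorm(2000, 1)
  expect_lt(wilcoxon_rank_sum(y, x)$p_value, 1e-10)
})

test_that("chi-square 2x2 reproduces hand-computed values", {
  plain <- chi2_2x2(10, 20, 20, 10, yates = FALSE)
  expect_equal(plain$statistic, 20 / 3, tolerance = 1e-12)  # 4 * 25/15
  yates <- chi2_2x2(10, 20, 20, 10, yates = TRUE)
  expect_equal(yates$statistic, 5.4, tolerance = 1e-12)     # 4 * 20.25/15
  expect_identical(yates$df, 1L)

  eq <- chi2_2x2(30, 70, 60, 140, yates = FALSE)
  expect_equal(eq$statistic, 0)
  expect_equal(chi2_2x2(30, 70, 60, 140, yates = TRUE)$statistic, 0)

  expect_error(chi2_2x2(0, 0, 5, 5), "margin")
  expect_error(chi2_2x2(-1, 2, 3, 4), ">= 0")
})

test_that("uncorrected chi-square equals the brute-force Pearson sum", {
  set.seed(63)
  for (rep in 1:25) {
    tab <- sample(1:500, 4)
    got <- chi2_2x2(tab[1], tab[2], tab[3], tab[4], yates = FALSE)$statistic
    want <- brute_chi2(tab[1], tab[2], tab[3], tab[4])
    expect_lt(abs(got - want) / want, 1e-9)
  }
})

test_that("all two-sample tests are symmetric under sample swap", {
  set.seed(64)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  a <- wilcoxon_rank_sum(x, y); b <- wilcoxon_rank_sum(y, x)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic + b$statistic, length(x) * length(y))
  t1 <- chi2_2x2(12, 30, 25, 18)
  t2 <- chi2_2x2(25, 18, 12, 30)     # swapped rows
  expect_equal(t1$statistic, t2$statistic)
  expect_equal(t1$p_value, t2$p_value)
})

test_that("one-way ANOVA reproduces the hand-worked example", {
  # groups {1,2,3},{2,3,4},{3,4,5}: SSB = 6, SSW = 6, F = (6/2)/(6/6) = 3
  a <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(a$f_statistic, 3.0, tolerance = 1e-12)
  expect_equal(a$df_between, 2)
  expect_equal(a$df_within, 6)
  expect_false(a$degenerate)

  const <- anova_oneway(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_true(const$degenerate)
  expect_true(is.nan(const$f_statistic))

  expect_error(anova_oneway(list(1:3)), ">= 2 groups")
  expect_error(anova_oneway(list(1:3, 5)), ">= 2 values")
})

test_that("2D KDE has its mode near the data mode and integrates to one", {
  set.seed(3)
  x <- rnorm(2e4); y <- rnorm(2e4)
  # a mildly oversmoothed kernel pins the mode; Scott-rule KDE modes
  # of a flat-topped density wander by more than the grid spacing
  k <- kde2d_grid(x, y, n_grid = 160L, bandwidth = c(0.35, 0.35))
  peak <- which(k$z == max(k$z), arr.ind = TRUE)[1, ]
  expect_lt(abs(k$x[peak[1]]), 0.1)
  expect_lt(abs(k$y[peak[2]]), 0.1)
  expect_lt(abs(kde2d_integral(k) - 1), 0.01)
  # Scott-rule default also normalises correctly
  k_def <- kde2d_grid(x[1:5000], y[1:5000])
  expect_lt(abs(kde2d_integral(k_def) - 1), 0.01)

  # normalisation holds for modest grids too
  k64 <- kde2d_grid(rnorm(500), rnorm(500, 2), n_grid = 64L)
  expect_lt(abs(kde2d_integral(k64) - 1), 0.01)

  expect_error(kde2d_grid(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(kde2d_grid(1, 2), ">= 2")
})

test_that("condition self-comparison is exactly null", {
  set.seed(66)
  rec <- data.frame(sum_spot_53BP1 = rlnorm(300, 10, 1),
                    mean_nuclear_gH2AX = rnorm(300, 200, 40))
  cmp <- compare_conditions(rec, rec)
  for (mk in names(cmp$markers)) {
    m <- cmp$markers[[mk]]
    expect_equal(m$wilcoxon$p_value, 1)
    expect_equal(m$chi2$statistic, 0)
    expect_equal(m$delta_median, 0)
    expect_equal(m$positive_fraction_control, m$positive_fraction_treated)
  }
})

test_that("a single-marker effect moves only that marker's median", {
  cfg <- small_cfg(
    foci_rate = list("53BP1" = c(UNTREATED = 1, DMSO = 1, ETP = 8),
                     "gH2AX" = c(UNTREATED = 1, DMSO = 1, ETP = 1)),
    pan_nuclear_gh2ax = c(UNTREATED = 200, DMSO = 200, ETP = 200))
  ctrl <- simulate_cell_features(1500, cfg, "DMSO", seed = 67)
  etp <- simulate_cell_features(1500, cfg, "ETP", seed = 68)
  cmp <- compare_conditions(ctrl, etp)
  expect_gt(cmp$markers[["53BP1"]]$delta_median, 0)
  # gamma-H2AX medians differ only by sampling noise around a null effect
  null_spread <- mad(ctrl$mean_nuclear_gH2AX) / sqrt(1500)
  expect_lt(abs(cmp$markers[["gH2AX"]]$delta_median), 6 * null_spread)
})

test_that("simulated treatment effects are reported as a diagonal shift", {
  cfg <- small_cfg()
  ctrl <- simulate_cell_features(1200, cfg, "DMSO", seed = 69)
  etp <- simulate_cell_features(1200, cfg, "ETP", seed = 70)
  cmp <- compare_conditions(ctrl, etp)
  expect_gt(cmp$markers[["53BP1"]]$delta_median, 0)
  expect_gt(cmp$markers[["gH2AX"]]$delta_median, 0)
  expect_gt(cmp$markers[["53BP1"]]$positive_fraction_treated,
            cmp$markers[["53BP1"]]$positive_fraction_control)
})
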