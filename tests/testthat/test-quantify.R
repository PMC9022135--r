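make_lab <- function() {
  lab <- matrix(0L, 40, 40)
  lab[5:14, 5:14] <- 1L
  lab[25:34, 25:34] <- 2L
  lab
}

test_that("per-cell features follow their definitions", {
  lab <- make_lab()
  gh <- matrix(50, 40, 40); gh[lab == 1L] <- 100
  imgs <- list(DAPI = matrix(3000, 40, 40), "53BP1" = matrix(100, 40, 40),
               gH2AX = gh)
  spots <- list("53BP1" = data.frame(nucleus_label = c(1L, 1L),
                                     integrated_intensity = c(10, 15)))
  rec <- compute_cell_features(imgs, lab, spots, well_id = "A01",
                               field_index = 1L)
  expect_identical(nrow(rec), 2L)
  expect_equal(rec$mean_nuclear_gH2AX, c(100, 50))
  expect_equal(rec$sum_spot_53BP1, c(25, 0))       # 10 + 15; no spots
  expect_identical(rec$spot_count_53BP1, c(2L, 0L))
  expect_equal(rec$sum_spot_gH2AX, c(0, 0))
  expect_identical(rec$nucleus_area_px, c(100L, 100L))
  # zero spot count implies zero sum for that marker
  expect_true(all(rec$sum_spot_53BP1[rec$spot_count_53BP1 == 0L] == 0))
})

test_that("spots referencing unknown nuclei are a consistency error", {
  lab <- make_lab()
  imgs <- list(DAPI = matrix(1000, 40, 40))
  spots <- list("53BP1" = data.frame(nucleus_label = 7L,
                                     integrated_intensity = 5))
  expect_error(compute_cell_features(imgs, lab, spots),
               "nonexistent nucleus label")
})

test_that("the positivity threshold is exactly mean + one sample SD", {
  thr <- compute_threshold(c(1, 2, 3), "gH2AX")
  expect_equal(thr$mean, 2)
  expect_equal(thr$sd, 1)
  expect_equal(thr$threshold, 3)
  expect_identical(thr$n, 3L)
  expect_equal(thr$threshold - thr$mean - thr$sd, 0)

  expect_warning(thr0 <- compute_threshold(c(5, 5, 5, 5), "53BP1"),
                 "zero variance")
  expect_equal(thr0$threshold, 5)
  expect_error(compute_threshold(c(1), "gH2AX"), "insufficient")
})

test_that("a normal negative control classifies ~Phi(-1) of itself positive", {
  set.seed(41)
  v <- rnorm(1e5)
  thr <- compute_threshold(v, "gH2AX")
  frac <- classify_positive(v, thr)$positive_fraction
  expect_lt(abs(frac - pnorm(-1)), 0.006)
})

test_that("positivity is a strict inequality with exact fractions", {
  vals <- data.frame(mean_nuclear_gH2AX = c(1, 2, 4))
  # control {1, 2, 3}: mean 2, SD 1, threshold exactly 3
  thr_exact <- compute_threshold(c(1, 2, 3), "gH2AX")
  res <- classify_positive(vals, thr_exact)
  expect_identical(res$records$positive_gH2AX, c(FALSE, FALSE, TRUE))
  expect_equal(res$positive_fraction, 1 / 3)
  # ties at the threshold are negative
  ties <- data.frame(mean_nuclear_gH2AX = rep(thr_exact$threshold, 5))
  expect_equal(classify_positive(ties, thr_exact)$positive_fraction, 0)
  expect_error(classify_positive(vals[0, , drop = FALSE], thr_exact),
               "zero cells")
  thr53 <- suppressWarnings(compute_threshold(c(1, 1), "53BP1"))
  expect_error(classify_positive(vals, thr53, "gH2AX"), "marker")
})

test_that("adding a constant shifts the threshold but not the calls", {
  set.seed(42)
  ctrl <- rnorm(400, 100, 20); samp <- rnorm(300, 130, 25)
  thr <- compute_threshold(ctrl, "gH2AX")
  calls <- classify_positive(samp, thr)$records$positive_gH2AX
  for (shift in c(-50, 7.5, 1e4)) {
    thr2 <- compute_threshold(ctrl + shift, "gH2AX")
    expect_equal(thr2$threshold, thr$threshold + shift)
    calls2 <- classify_positive(samp + shift, thr2)$records$positive_gH2AX
    expect_identical(calls2, calls)
  }
})

test_that("well summaries use order-statistic medians and type-7 IQR", {
  rec <- data.frame(well_id = "A01",
                    sum_spot_53BP1 = c(1, 2, 3, 4),
                    mean_nuclear_gH2AX = c(10, 20, 30, 40))
  s <- summarize_well(rec)
  expect_identical(s$n_cells, 4L)
  expect_equal(s$markers[["53BP1"]]$median, 2.5)
  expect_equal(s$markers[["53BP1"]]$iqr,
               quantile(c(1, 2, 3, 4), 0.75, type = 7) -
                 quantile(c(1, 2, 3, 4), 0.25, type = 7),
               ignore_attr = TRUE)

  single <- summarize_well(rec[1, , drop = FALSE])
  expect_equal(single$markers[["53BP1"]]$median, 1)
  expect_equal(single$markers[["53BP1"]]$mean, 1)
  expect_true(is.na(single$markers[["53BP1"]]$sd))

  empty <- summarize_well(rec[0, , drop = FALSE])
  expect_true(empty$empty)
  expect_identical(empty$n_cells, 0L)

  rec2 <- rec; rec2$well_id <- c("A01", "A01", "A02", "A02")
  expect_error(summarize_well(rec2), "more than one well")
})

test_that("treated wells summarise higher than control wells", {
  cfg <- small_cfg()
  ctrl <- simulate_cell_features(500, cfg, "DMSO", seed = 51)
  etp <- simulate_cell_features(500, cfg, "ETP", seed = 52)
  ctrl$well_id <- "A01"; etp$well_id <- "A02"
  s_ctrl <- summarize_well(ctrl); s_etp <- summarize_well(etp)
  expect_gt(s_etp$markers[["53BP1"]]$median, s_ctrl$markers[["53BP1"]]$median)
  expect_gt(s_etp$markers[["gH2AX"]]$median, s_ctrl$markers[["gH2AX"]]$median)
})
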