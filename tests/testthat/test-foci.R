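# Helper: one circular "nucleus" label map with a constant-background
# image; foci are added on top.
disk_label <- function(n = 64, r = 20) {
  rr <- matrix(rep(1:n, n), n); cc <- matrix(rep(1:n, each = n), n)
  matrix(as.integer(sqrt((rr - n / 2)^2 + (cc - n / 2)^2) <= r), n, n)
}
gauss_spot <- function(img, r0, c0, amp, sigma) {
  rr <- matrix(rep(seq_len(nrow(img)), ncol(img)), nrow(img))
  cc <- matrix(rep(seq_len(ncol(img)), each = nrow(img)), nrow(img))
  img + amp * exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * sigma^2))
}

test_that("a uniform image yields no candidates", {
  lab <- disk_label()
  cands <- detect_candidates(matrix(100, 64, 64), lab)
  expect_identical(nrow(cands), 0L)
})

test_that("a single Gaussian focus is recovered with its flux", {
  lab <- disk_label()
  sigma <- 1.6; amp <- 1000
  img <- gauss_spot(matrix(100, 64, 64), 32, 32, amp, sigma)
  cands <- detect_candidates(img, lab)
  expect_identical(nrow(cands), 1L)
  expect_lt(abs(cands$centroid_row - 31), 1)   # 0-based truth = 31
  expect_lt(abs(cands$centroid_col - 31), 1)
  flux <- amp * 2 * pi * sigma^2
  expect_lt(abs(cands$integrated_intensity - flux) / flux, 0.10)
})

test_that("two nearby foci stay separate candidates", {
  lab <- disk_label()
  img <- gauss_spot(matrix(100, 64, 64), 32, 27, 800, 1.5)
  img <- gauss_spot(img, 32, 37, 800, 1.5)
  cands <- detect_candidates(img, lab)
  expect_identical(nrow(cands), 2L)
})

test_that("candidates outside nuclei are discarded", {
  lab <- disk_label(64, 10)
  img <- gauss_spot(matrix(100, 64, 64), 8, 8, 1000, 1.5)  # outside disk
  expect_identical(nrow(detect_candidates(img, lab)), 0L)
})

test_that("the worked Fisher discriminant example is exact", {
  focus <- rbind(c(2, 0), c(3, 1))
  background <- rbind(c(0, 0), c(1, -1))
  m <- fld_train(focus, background, ridge = 0)
  expect_equal(m$sw, matrix(c(1, 0, 0, 1), 2, 2), ignore_attr = TRUE)
  expect_equal(m$w, c(2, 1))
  expect_equal(m$threshold, 3.0)
  # scoring the class means
  scored <- fld_classify(m, data.frame(V1 = c(2.5, 0.5), V2 = c(0.5, -0.5)))
  expect_equal(scored$score, c(2.5, -2.5))
  expect_identical(scored$accepted, c(TRUE, FALSE))
})

test_that("identity within-class scatter aligns w with the mean difference", {
  iso <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  mu1 <- c(3, 1); mu0 <- c(0, 0)
  m <- fld_train(sweep(iso, 2, mu1, "+"), sweep(iso, 2, mu0, "+"),
                 ridge = 0)
  expect_lt(axial_dist(dir_angle(m$w), dir_angle(mu1 - mu0)), 1e-8)
})

test_that("degenerate training sets raise errors", {
  same <- rbind(c(1, 1), c(2, 0))
  expect_error(fld_train(same, same, ridge = 0), "identical class means")
  # scatter singular in one direction, ridge disabled
  f <- rbind(c(0, 0), c(1, 0)); b <- rbind(c(0, 1), c(1, 1))
  expect_error(fld_train(f, b, ridge = 0), "ridge")
  expect_error(fld_train(rbind(c(1, 1)), rbind(c(0, 0), c(0, 1))),
               ">= 2 examples")
})

test_that("classification preserves order, handles empty input and missing features", {
  m <- fld_train(rbind(c(2, 0), c(3, 1)), rbind(c(0, 0), c(1, -1)),
                 ridge = 0)
  empty <- fld_classify(m, data.frame(V1 = numeric(), V2 = numeric()))
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("score", "accepted") %in% names(empty)))
  expect_error(fld_classify(m, data.frame(V1 = 1)), "V2")
})

test_that("fine-tuning equals retraining on the pooled examples", {
  set.seed(31)
  for (rep in 1:5) {
    a1 <- matrix(rnorm(20, 2), ncol = 2); a0 <- matrix(rnorm(20), ncol = 2)
    b1 <- matrix(rnorm(12, 2.5), ncol = 2); b0 <- matrix(rnorm(8), ncol = 2)
    colnames(a1) <- colnames(a0) <- colnames(b1) <- colnames(b0) <-
      c("f1", "f2")
    m_pool <- fld_train(rbind(a1, b1), rbind(a0, b0), ridge = 0)
    m_fine <- fld_finetune(fld_train(a1, a0, ridge = 0), b1, b0, ridge = 0)
    expect_equal(m_fine$w, m_pool$w, tolerance = 1e-10)
    expect_equal(m_fine$threshold, m_pool$threshold, tolerance = 1e-10)
  }
  # no new data -> identical model; one-class update stays valid
  m <- fld_train(matrix(rnorm(20, 2), ncol = 2), matrix(rnorm(20), ncol = 2),
                 ridge = 0)
  expect_equal(fld_finetune(m, ridge = 0)$w, m$w)
  m1 <- fld_finetune(m, new_focus = matrix(rnorm(6, 2), ncol = 2), ridge = 0)
  expect_s3_class(m1, "fld_model")
  expect_identical(m1$stats0$n, m$stats0$n)
})

test_that("closed-form discriminant matches brute-force criterion maximisation", {
  set.seed(33)
  for (rep in 1:10) {
    x1 <- matrix(rnorm(24, mean = 2, sd = 1.3), ncol = 2)
    x0 <- matrix(rnorm(24), ncol = 2)
    m <- fld_train(x1, x0, ridge = 0)
    expect_lt(axial_dist(dir_angle(m$w), brute_fld_direction(x1, x0)), 1)
  }
})

test_that("rescaling intensity features never changes accept/reject calls", {
  set.seed(34)
  x1 <- matrix(rnorm(30, 2), ncol = 2); x0 <- matrix(rnorm(30), ncol = 2)
  test_pts <- matrix(rnorm(40, 1), ncol = 2)
  colnames(x1) <- colnames(x0) <- colnames(test_pts) <- c("f1", "f2")
  m <- fld_train(x1, x0, ridge = 0)
  base_calls <- fld_classify(m, as.data.frame(test_pts))$accepted
  for (c_scale in c(0.01, 3, 1e4)) {
    m2 <- fld_train(x1 * c_scale, x0 * c_scale, ridge = 0)
    calls <- fld_classify(m2, as.data.frame(test_pts * c_scale))$accepted
    expect_identical(calls, base_calls)
    expect_equal(m2$w * c_scale, m$w, tolerance = 1e-8)
  }
})

test_that("models round-trip through JSON", {
  d <- withr::local_tempdir()
  models <- get_trained_models()
  p <- file.path(d, "fld.json")
  write_fld_model(models[["53BP1"]], p)
  back <- read_fld_model(p)
  expect_equal(back$w, models[["53BP1"]]$w)
  expect_equal(back$threshold, models[["53BP1"]]$threshold)
  expect_identical(back$features, models[["53BP1"]]$features)
  # the reloaded model can still be fine-tuned (sufficient stats intact)
  expect_s3_class(fld_finetune(back), "fld_model")
})

test_that("trained classifier recovers bright foci with high precision and recall", {
  models <- get_trained_models()
  cfg <- eval_cfg()
  noise_sd <- sqrt(cfg$background + cfg$read_noise_sd^2)
  tp <- 0; fn <- 0; fp <- 0
  for (i in 1:2) {
    sim <- simulate_field(cfg, "UNTREATED", seed = 700 + i)
    lab <- segment_nuclei(sim$images$DAPI)
    for (mk in c("53BP1", "gH2AX")) {
      cands <- fld_classify(models[[mk]],
                            detect_candidates(sim$images[[mk]], lab))
      acc <- cands[cands$accepted, ]
      truth <- sim$truth$foci[sim$truth$foci$marker == mk, ]
      bright <- truth[truth$amplitude >= 5 * noise_sd, ]
      lc <- label_candidates(acc, bright)
      any_true <- label_candidates(acc, truth)
      tp <- tp + sum(lc$is_focus)
      fn <- fn + nrow(bright) - sum(lc$is_focus)
      fp <- fp + sum(!any_true$is_focus)
    }
  }
  expect_gte(tp / (tp + fn), 0.90)
  expect_gte(tp / (tp + fp), 0.90)
})
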