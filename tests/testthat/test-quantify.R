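test_that("hipix matches its literal definition on constructed frames", {
  # uniform frame: top-k mean equals the median, so the statistic is zero
  f <- matrix(7, 30, 30)
  en <- matrix(FALSE, 30, 30); en[10:20, 10:20] <- TRUE
  cl <- matrix(TRUE, 30, 30)
  expect_equal(as.numeric(hipix(f, en, cl)), 0)

  # exactly 20 pixels at 100 inside ExpNucl, rest at 10, cell median 10
  f2 <- matrix(10, 30, 30)
  bright <- which(en)[1:20]
  f2[bright] <- 100
  expect_equal(as.numeric(hipix(f2, en, cl)), 90)

  # fewer than k pixels: all used, flagged
  sm <- matrix(FALSE, 30, 30); sm[1:3, 1] <- TRUE
  h <- hipix(f2, sm, cl)
  expect_equal(attr(h, "flag"), "short")

  # empty region: missing with error flag
  h0 <- hipix(f2, matrix(FALSE, 30, 30), cl)
  expect_true(is.na(h0))
  expect_equal(attr(h0, "flag"), "empty")
})

test_that("hipix is invariant to adding a constant to the frame", {
  set.seed(1)
  f <- matrix(rnorm(900, 100, 10), 30, 30)
  en <- matrix(FALSE, 30, 30); en[5:15, 5:15] <- TRUE
  cl <- matrix(FALSE, 30, 30); cl[3:20, 3:20] <- TRUE
  expect_equal(as.numeric(hipix(f, en, cl)),
               as.numeric(hipix(f + 123.4, en, cl)))
})

test_that("connected_hipix handles scattered, block, and mixed layouts", {
  # exactly 20 bright pixels, no two adjacent: opening removes everything
  f <- matrix(10, 40, 40)
  en <- matrix(FALSE, 40, 40); en[5:35, 5:35] <- TRUE
  scatter <- rbind(cbind(seq(6, 33, by = 3), 10),
                   cbind(seq(6, 33, by = 3), 20))
  f[scatter] <- seq(150, 245, by = 5)
  expect_true(is.na(connected_hipix(f, en)))

  # a 4x5 block at 200 forms the top-20: survives, mean 200
  f2 <- matrix(10, 40, 40)
  f2[10:13, 10:14] <- 200
  expect_equal(connected_hipix(f2, en), 200)

  # a 3x3 cluster at 150 plus scattered brighter singletons: the singletons
  # die in the opening, the 9-pixel cluster remains
  f3 <- matrix(10, 40, 40)
  f3[20:22, 20:22] <- 150
  f3[cbind(c(6, 6, 30, 32, 34, 8, 12, 16, 28, 26, 24),
           c(30, 6, 6, 9, 12, 18, 32, 6, 30, 33, 8))] <- 160
  expect_equal(connected_hipix(f3, en), 150)
})

test_that("hipix and connected_hipix match brute-force oracles exactly", {
  set.seed(99)
  for (i in 1:100) {
    f <- matrix(runif(64 * 64, 0, 1000), 64, 64)
    cx <- sample(15:50, 1); cy <- sample(15:50, 1)
    en <- matrix(FALSE, 64, 64)
    en[pmax(1, cy - 8):pmin(64, cy + 8), pmax(1, cx - 8):pmin(64, cx + 8)] <- TRUE
    cl <- matrix(FALSE, 64, 64)
    cl[pmax(1, cy - 14):pmin(64, cy + 14), pmax(1, cx - 14):pmin(64, cx + 14)] <- TRUE
    # sometimes plant a compact cluster so both branches are exercised
    if (i %% 2 == 0) f[cy + (-1:1), cx + (-1:1)] <- runif(9, 2000, 3000)
    expect_equal(as.numeric(hipix(f, en, cl)), oracle_hipix(f, en, cl))
    got <- connected_hipix(f, en)
    want <- oracle_connected_hipix(f, en)
    expect_identical(is.na(got), is.na(want))
    if (!is.na(got)) expect_equal(got, want)
  }
})

test_that("connected_hipix never exceeds the ExpNucl maximum", {
  set.seed(7)
  n_detected <- 0L
  for (i in 1:25) {
    f <- matrix(runif(900, 0, 500), 30, 30)
    en <- matrix(FALSE, 30, 30)
    en[8:24, 8:24] <- TRUE
    if (i %% 2 == 0) f[14:16, 14:16] <- runif(9, 600, 900)  # plant a spot
    v <- connected_hipix(f, en)
    if (!is.na(v)) {
      n_detected <- n_detected + 1L
      expect_lte(v, max(f[en]))
    }
  }
  expect_gt(n_detected, 5)
})

test_that("trace quantification propagates validity and missingness", {
  g <- frame_grid(n_frames = 6, time_zero_frame = 4)
  cfg <- render_config(spot_jitter_sd = 0)
  lay <- layout_cells(2, cfg, seed = 30)
  intens <- rbind(c(0, 0, 0, 20, 20, 20), rep(0, 6))
  rf <- render_field(lay, intens, g, cfg, seed = 31)
  proj <- max_project(rf$gfp)
  seg <- segment_from_truth(rf$cell_mask, rf$nucleus_mask, proj[, , 1])
  fe <- seg$features
  tracks <- data.frame(cell_id = fe$label, frame = 1L, label = fe$label,
                       x = fe$x, y = fe$y, valid = TRUE)
  tr <- quantify_traces(proj, list(seg), tracks, g)
  t1 <- tr[tr$cell_id == 1, ]
  t2 <- tr[tr$cell_id == 2, ]
  # transcribing cell: detections exactly while loaded
  expect_true(all(!is.na(t1$connected_hipix[4:6])))
  expect_true(all(is.na(t1$connected_hipix[1:3])))
  expect_true(all(t1$hipix[4:6] > 100))
  # silent cell: hipix fluctuates near zero, detections absent
  expect_lt(max(abs(t2$hipix)), 25)
  expect_true(all(is.na(t2$connected_hipix)))

  # invalidated frames yield missing statistics
  tracks2 <- tracks; tracks2$valid <- FALSE
  tr0 <- quantify_traces(proj, list(seg), tracks2, g)
  expect_true(all(is.na(tr0$hipix)))
  expect_true(all(!tr0$valid))
})
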