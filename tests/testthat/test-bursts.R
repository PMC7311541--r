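test_that("candidate peaks are strict-threshold local maxima", {
  y <- c(0, 50, 100, 60, 20, 80, 90, 10, 0)
  t <- seq_along(y)  # 1-minute grid for readability
  cand <- find_candidate_peaks(y, t, start = 1, end = 9, threshold = 7)
  expect_equal(cand$value, c(100, 90))
  expect_equal(cand$idx, c(3, 7))

  # flat zero trace
  expect_equal(nrow(find_candidate_peaks(rep(0, 9), t, 1, 9)), 0)

  # single maximum of 6: below the 7-count threshold
  y6 <- c(0, 2, 6, 2, 0)
  expect_equal(nrow(find_candidate_peaks(y6, 1:5, 1, 5)), 0)

  # plateaus take the leftmost index
  yp <- c(0, 10, 10, 10, 0)
  cp <- find_candidate_peaks(yp, 1:5, 1, 5)
  expect_equal(cp$idx, 2)

  # absent window yields an empty list
  expect_equal(nrow(find_candidate_peaks(y, t, NA, NA)), 0)
})

test_that("the four-rule filter keeps or merges peak pairs correctly", {
  t <- 1:9
  # trough 20 between 100 and 90: drop 80 > 25, rise 70 > 20/3, both above
  # max/5 -> two peaks
  y2 <- c(0, 50, 100, 60, 20, 80, 90, 10, 0)
  cand <- find_candidate_peaks(y2, t, 1, 9)
  ps <- filter_peaks(cand, y2, t, 1, 9)
  expect_equal(ps$n_peaks, 2)
  expect_equal(ps$class, "2P")

  # trough 80: drop 20 < 25 -> merged into one peak (the higher, 100)
  y1 <- c(0, 50, 100, 95, 80, 85, 90, 10, 0)
  cand1 <- find_candidate_peaks(y1, t, 1, 9)
  ps1 <- filter_peaks(cand1, y1, t, 1, 9)
  expect_equal(ps1$n_peaks, 1)
  expect_equal(ps1$class, "1P")
  expect_equal(ps1$peaks$value, 100)

  # single candidate above threshold and max/5
  ys <- c(0, 5, 60, 5, 0)
  pss <- filter_peaks(find_candidate_peaks(ys, 1:5, 1, 5), ys, 1:5, 1, 5)
  expect_equal(pss$class, "1P")
})

test_that("raising the trough to the lower peak always merges the pair", {
  set.seed(3)
  for (i in 1:50) {
    pk <- sort(runif(2, 30, 100), decreasing = TRUE)
    y <- c(0, pk[1], runif(1, 0, pk[2] * 0.5), pk[2], 0)
    t <- 1:5
    base <- filter_peaks(find_candidate_peaks(y, t, 1, 5), y, t, 1, 5)
    # trough raised to (just under) the lower peak's value: the drop or the
    # rise condition must now fail and the pair merges
    y2 <- y; y2[3] <- pk[2] - 0.01
    merged <- find_candidate_peaks(y2, t, 1, 5)
    ps2 <- filter_peaks(merged, y2, t, 1, 5)
    expect_equal(ps2$n_peaks, 1)
    expect_equal(base$n_peaks, 2)
  }
})

test_that("peak durations split the transcription window at troughs", {
  # single peak spanning start 2 to end 8.6 min
  t <- seq(0, 10, by = 0.2)
  y <- 60 * exp(-(t - 5)^2 / 4)
  cand <- find_candidate_peaks(y, t, 2, 8.6)
  ps <- filter_peaks(cand, y, t, 2, 8.6)
  expect_equal(ps$n_peaks, 1)
  expect_equal(ps$peaks$duration, 6.6)

  # two peaks, trough at 5 min, start 2 / end 10: durations 3 and 5
  t2 <- seq(0, 11, by = 0.5)
  y2 <- 80 * exp(-(t2 - 3.5)^2 / 1.5) + 70 * exp(-(t2 - 7.5)^2 / 1.5)
  cand2 <- find_candidate_peaks(y2, t2, 2, 10)
  ps2 <- filter_peaks(cand2, y2, t2, 2, 10)
  expect_equal(ps2$n_peaks, 2)
  tr_t <- t2[t2 > 3.5 & t2 < 7.5][which.min(y2[t2 > 3.5 & t2 < 7.5])]
  expect_equal(tr_t, 5.5)
  expect_equal(ps2$peaks$duration, c(tr_t - 2, 10 - tr_t))

  # zero peaks: empty duration list
  empty <- filter_peaks(find_candidate_peaks(rep(0, 56), t2, 2, 10),
                        rep(0, 56), t2, 2, 10)
  expect_equal(nrow(empty$peaks), 0)
})

test_that("filter_peaks agrees with an independent rule application on
           1000 random short traces", {
  set.seed(17)
  for (i in 1:1000) {
    n <- sample(12:24, 1)
    y <- round(runif(n, 0, 100))
    y[1] <- 0; y[n] <- 0
    t <- seq_len(n)
    cand <- find_candidate_peaks(y, t, 1, n)
    got <- filter_peaks(cand, y, t, 1, n)
    want_idx <- oracle_filter_peaks(cand$idx, y, t, 1, n)
    expect_equal(got$peaks$idx, want_idx)
  }
})

test_that("burst output ignores trace content outside the window", {
  g <- frame_grid()
  hip <- rep(0, 100)
  hip[12:40] <- 30 + 20 * sin(seq(0, 3 * pi, length.out = 29))
  ch <- detections_at(12:40)
  base <- detect_bursts(hip, ch, g)
  hip2 <- hip
  hip2[60:80] <- 500   # post-end junk
  hip2[1:2] <- -100    # pre-start junk
  mod <- detect_bursts(hip2, ch, g)
  expect_equal(base$peaks$idx, mod$peaks$idx)
  expect_equal(base$class, mod$class)
})
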