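fe_row <- function(cell_id, class, start = NA, end = NA, integral = 0,
                   any_post = class != "non_responder") {
  data.frame(cell_id = cell_id, responder_class = class, start_time = start,
             end_time = end, transcription_period = end - start,
             trace_max = integral, integral = integral,
             n_detections = 0L, any_post_detection = any_post,
             no_period = is.na(start))
}

test_that("start-time CDF steps through responders only", {
  fe <- rbind(fe_row(1, "responder", 1, 5, 10),
              fe_row(2, "responder", 2, 6, 10),
              fe_row(3, "responder", 3, 7, 10),
              fe_row(4, "responder", 4, 8, 10),
              fe_row(5, "basal", -0.5, 9, 10),
              fe_row(6, "non_responder"))
  cdf <- start_time_cdf(fe)
  expect_equal(cdf$time, 1:4)
  expect_equal(cdf$fraction, c(0.25, 0.5, 0.75, 1))
  expect_false(attr(cdf, "empty"))

  # identical start times collapse to one step at 1
  fe2 <- rbind(fe_row(1, "responder", 3, 5, 1), fe_row(2, "responder", 3, 6, 1))
  cdf2 <- start_time_cdf(fe2)
  expect_equal(cdf2$time, 3)
  expect_equal(cdf2$fraction, 1)

  # zero responders: explicit empty flag
  empty <- start_time_cdf(fe_row(1, "non_responder"))
  expect_true(attr(empty, "empty"))
})

test_that("end-time survival is one minus the CDF", {
  fe <- rbind(fe_row(1, "responder", 1, 10, 1),
              fe_row(2, "responder", 1, 20, 1))
  s <- end_time_survival(fe)
  expect_equal(s$time, c(10, 20))
  expect_equal(s$fraction, c(0.5, 0))
  expect_true(attr(end_time_survival(fe_row(1, "non_responder")), "empty"))
})

test_that("monotonicity invariants hold on randomized feature tables", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    fe <- do.call(rbind, lapply(seq_len(n), function(j) {
      cls <- sample(c("responder", "basal", "non_responder"), 1)
      st <- if (cls == "non_responder") NA else round(runif(1, -1, 20), 2)
      en <- if (is.na(st)) NA else st + round(runif(1, 0, 10), 2)
      fe_row(j, cls, st, en, runif(1, 0, 100))
    }))
    cdf <- start_time_cdf(fe)
    if (nrow(cdf)) {
      expect_true(all(diff(cdf$fraction) >= 0))
      expect_equal(cdf$fraction[nrow(cdf)], 1)
      expect_true(all(cdf$fraction >= 0 & cdf$fraction <= 1))
    }
    s <- end_time_survival(fe)
    if (nrow(s)) {
      expect_true(all(diff(s$fraction) <= 0))
      expect_equal(s$fraction[nrow(s)], 0)
    }
    fr <- fractions(fe)
    expect_true(fr$fraction_basal >= 0 && fr$fraction_basal <= 1)
    expect_true(fr$fraction_responding >= 0 && fr$fraction_responding <= 1)
  }
})

test_that("basal and responding fractions count detections correctly", {
  fe0 <- rbind(fe_row(1, "non_responder"), fe_row(2, "non_responder"))
  f0 <- fractions(fe0)
  expect_equal(f0$fraction_basal, 0)
  expect_equal(f0$fraction_responding, 0)

  fe1 <- rbind(fe_row(1, "responder", 1, 2, 1), fe_row(2, "responder", 3, 4, 1))
  expect_equal(fractions(fe1)$fraction_responding, 1)

  # recovered basal fraction within the binomial CI of the generating rate
  g <- frame_grid()
  prof <- make_stimulus_profile("step", 0.2, grid = g)
  sim <- simulate_cells(300, prof, promoter = promoter_preset("permissive"),
                        seed = 70)
  tt <- truth_table(sim)
  ob <- observe_traces(sim$intensity, seed = 71)
  fe <- trace_features_table(traces_from_matrices(ob$hipix,
                                                  ob$connected_hipix, g), g)
  fr <- fractions(fe)
  p_true <- mean(tt$is_basal)
  ci <- p_true + c(-1, 1) * 1.96 * sqrt(p_true * (1 - p_true) / 300)
  expect_gte(fr$fraction_basal, ci[1] - 1e-9)
  expect_lte(fr$fraction_basal, ci[2] + 1e-9)
})

test_that("start-time quartiles summarize the integral per quartile", {
  # 8 cells, integral decreasing in start time: strictly decreasing medians
  fe <- do.call(rbind, lapply(1:8, function(j)
    fe_row(j, "responder", j, j + 5, 100 - 10 * j)))
  q <- start_quartile_output(fe)
  expect_equal(q$n, rep(2, 4))
  expect_true(all(diff(q$median) < 0))

  # identical integrals: all quartile medians equal
  fe2 <- do.call(rbind, lapply(1:9, function(j)
    fe_row(j, "responder", j, j + 5, 50)))
  q2 <- start_quartile_output(fe2)
  expect_true(all(q2$median == 50))
  expect_equal(q2$n, c(3, 2, 2, 2))  # remainder goes to the earlier quartile

  # under 8 responders: flagged, no output
  expect_warning(q3 <- start_quartile_output(fe[1:5, ]), "fewer than 8")
  expect_null(q3)
})

test_that("earlier-starting simulated cells produce larger integrals", {
  g <- frame_grid()
  prof <- make_stimulus_profile("step", 0.2, grid = g)
  sim <- simulate_cells(250, prof, seed = 81)
  ob <- observe_traces(sim$intensity, seed = 82)
  fe <- trace_features_table(traces_from_matrices(ob$hipix,
                                                  ob$connected_hipix, g), g)
  q <- start_quartile_output(fe)
  # the shutoff gate is shared, so late starters integrate less
  expect_gt(q$median[1], q$median[4])
})

test_that("adaptation/end-time correlation handles trivial and degenerate
           pairings", {
  hf <- data.frame(cell_id = 1:50, adaptation_time = seq(5, 20, length.out = 50),
                   censored = FALSE)
  fe <- do.call(rbind, lapply(1:50, function(j)
    fe_row(j, "responder", 1, seq(5, 20, length.out = 50)[j], 1)))
  r <- adaptation_endtime_correlation(hf, fe)
  expect_equal(r$r, 1)
  expect_equal(r$flag, "ok")

  # independently shuffled pairs decorrelate
  set.seed(4)
  hf2 <- data.frame(cell_id = 1:200, adaptation_time = runif(200, 5, 30),
                    censored = FALSE)
  fe2 <- do.call(rbind, lapply(1:200, function(j)
    fe_row(j, "responder", 1, runif(1, 5, 30), 1)))
  r2 <- adaptation_endtime_correlation(hf2, fe2)
  expect_lt(abs(r2$r), 0.15)

  # all censored: zero variance in x, flagged undefined
  hf3 <- data.frame(cell_id = 1:10, adaptation_time = 35, censored = TRUE)
  fe3 <- do.call(rbind, lapply(1:10, function(j)
    fe_row(j, "responder", 1, j + 3, 1)))
  r3 <- adaptation_endtime_correlation(hf3, fe3)
  expect_true(is.na(r3$r))
  expect_equal(r3$flag, "degenerate")
  expect_equal(r3$n_censored, 10)

  # under 3 pairs: undefined, flagged
  r4 <- adaptation_endtime_correlation(hf[1:2, ], fe[fe$cell_id <= 2, ])
  expect_equal(r4$flag, "too_few")
})

test_that("transcript lifetime arithmetic matches the reporter geometry", {
  lt <- expected_ts_lifetime(8000, 20)
  expect_equal(lt$seconds, 400)
  expect_equal(lt$minutes, 6.7)
  expect_error(expected_ts_lifetime(0, 20))
  expect_error(expected_ts_lifetime(8000, -1))
  # endogenous-locus geometry: 1.5 kb cassette + 1.7 kb ORF
  expect_equal(expected_ts_lifetime(3200, 20)$minutes, 2.7)
})
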