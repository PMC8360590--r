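test_that("cosine troughs are found on the expected grid", {
  t <- seq(0, 200, by = 0.5)
  tro <- detect_troughs(cos(2 * pi * t / 24), dt = 0.5)
  expected <- seq(12, 180, by = 24)
  expect_identical(length(tro), length(expected))
  expect_true(all(abs(tro - expected) <= 1))

  s <- synthetic_oscillation(200, 0.5, period = 24, noise_sd = 0.15, seed = 3)
  tro_n <- detect_troughs(s$values, dt = 0.5, smooth_window = 4)
  expect_identical(length(tro_n), length(expected))
  expect_true(all(abs(tro_n - expected) <= 1.5))

  expect_identical(detect_troughs(rep(2, 500), dt = 0.5), numeric(0))
  # peaks sit on multiples of 24 h (the boundary peaks may be smoothed away)
  pk <- detect_peaks(cos(2 * pi * t / 24), dt = 0.5)
  expect_gte(length(pk), 7)
  expect_true(all(abs(pk - 24 * round(pk / 24)) <= 1))
})

test_that("transcription tallies respect the event log", {
  ev <- synthetic_event_log(c(1, 2, 3, 5, 9.5),
                            channel = c(rep("transcription", 4), "export"),
                            compartment = c(1, 1, 1, 2, 1))
  st <- tally_transcription(ev, troughs = c(0, 10), N = 2)
  expect_identical(st$counts, matrix(c(3L, 1L), 1))
  expect_identical(st$skew_fraction, 1) # 3 > 2 * 1
  expect_identical(st$mean_fraction_smaller, 0.25)
  expect_error(tally_transcription(ev, troughs = 5, N = 2), "two troughs")

  # conservation: every in-window transcription event lands in some period
  tr <- run_ssa(clock_model(alpha = 18, N = 2), t_end = 2000, seed = 13,
                log = "transcription")
  tro <- detect_troughs(rowSums(tr$pn), 0.5)
  st2 <- tally_transcription(tr$events, tro, N = 2)
  tx <- tr$events[tr$events$channel == "transcription", ]
  n_in <- sum(tx$time >= tro[1] & tx$time < tro[length(tro)])
  expect_identical(sum(st2$counts), n_in)
  expect_true(all(st2$fraction_smaller >= 0 & st2$fraction_smaller <= 1,
                  na.rm = TRUE))
})

test_that("uniform two-nucleus labor shares are symmetric on average", {
  rs <- cache_ratio_sweep()
  uni <- rs[rs$ratio == 1, ]
  # symmetry: long-run mean share of either compartment near one half
  labor <- division_of_labor(clock_model(alpha = 18, N = 2), t_end = 5000,
                             seed = 17)
  expect_lt(abs(labor$mean_fraction_smaller - 0.5), 0.05)
  expect_true(is.na(uni$mean_fraction_smaller))
})

test_that("the synchronization experiment reports coherent summaries", {
  cr <- consistency_experiment(n_trials = 12, seed = 2)
  for (sc in c("coupled", "independent")) {
    r <- cr[[sc]]
    expect_identical(length(r$sigma), 5L)
    expect_true(all(r$sigma >= 0))
    expect_identical(r$sigma_incl[[1]], 0) # alignment peak has no spread
    expect_true(r$mean_day_length > 18 && r$mean_day_length < 32)
    expect_identical(nrow(r$peak_times) + r$n_excluded, 12L)
  }
  expect_true(all(cr$init >= 0))
})
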