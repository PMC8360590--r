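test_that("with no transcription every species decays to zero", {
  m <- clock_model(alpha = 0)
  tr <- solve_deterministic(m, init = list(Mn = 10, Mc = 5, Pc = 3, Pn = 8),
                            t_end = 300)
  final <- vapply(c("Mn", "Mc", "Pc", "Pn"),
                  function(f) tr[[f]][nrow(tr$Mn), 1], numeric(1))
  expect_true(all(final < 1e-6))
  expect_identical(as.character(classify_oscillation(tr, transient = 100)),
                   "non-oscillatory")
})

test_that("low transcription damps while high transcription sustains", {
  damped <- solve_deterministic(clock_model(alpha = 18), t_end = 400)
  expect_identical(as.character(classify_oscillation(damped, transient = 100)),
                   "damped")
  sustained <- solve_deterministic(clock_model(alpha = 5000), t_end = 2000)
  expect_identical(
    as.character(classify_oscillation(sustained, transient = 1200)),
    "sustained")
})

test_that("the classifier brackets the analytic threshold", {
  # threshold sits at ~2039; the classifier must flip somewhere in between
  below <- solve_deterministic(clock_model(alpha = 1900), t_end = 3000)
  above <- solve_deterministic(clock_model(alpha = 2200), t_end = 3000)
  expect_identical(as.character(classify_oscillation(below, transient = 2200)),
                   "damped")
  expect_identical(as.character(classify_oscillation(above, transient = 2200)),
                   "sustained")
})

test_that("synthetic series classify as expected", {
  s <- synthetic_oscillation(150, 0.1, period = 24, damping = 0.01)
  expect_identical(
    as.character(classify_oscillation(s$values, s$times, transient = 0)),
    "damped")
  s2 <- synthetic_oscillation(200, 0.1, period = 24)
  expect_identical(
    as.character(classify_oscillation(s2$values, s2$times, transient = 0)),
    "sustained")
  expect_identical(
    as.character(classify_oscillation(rep(1, 500), transient = 0)),
    "non-oscillatory")
  # oscillating but with too few extrema to judge the amplitude trend
  expect_error(classify_oscillation(sin(seq(0, 11, 0.1)), transient = 0),
               "insufficient")
  expect_error(classify_oscillation(1:5, transient = 0), "too short")
})

test_that("the fixed point is stationary under integration", {
  m <- clock_model(alpha = 18)
  ss <- steady_state(m)
  init <- list(Mn = ss[["mn"]] / m$V_n, Mc = ss[["mc"]] / m$V_c,
               Pc = ss[["pc"]] / m$V_c, Pn = ss[["pn"]] / m$V_n)
  tr <- solve_deterministic(m, init = init, t_end = 100)
  for (f in c("Mn", "Mc", "Pc", "Pn")) {
    dev <- max(abs(tr[[f]][, 1] - init[[f]])) / max(init[[f]], 1e-12)
    expect_lt(dev, 1e-4)
  }
})

test_that("shared-pool and stepwise-averaging modes agree", {
  m <- clock_model(alpha = 200, N = 2)
  a <- solve_deterministic(m, t_end = 60, dt_out = 0.1, mode = "shared")
  b <- solve_deterministic(m, t_end = 60, dt_out = 0.1, mode = "stepwise")
  expect_lt(max(abs(a$Pn - b$Pn)) / max(a$Pn), 0.01)
  # equalization: cytoplasmic protein concentration identical across
  # compartments at every output step
  expect_equal(b$Pc[, 1], b$Pc[, 2])
  # symmetric uniform geometry: compartments remain identical for all time
  expect_equal(a$Pn[, 1], a$Pn[, 2])
  expect_equal(a$Mn[, 1], a$Mn[, 2])
})
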