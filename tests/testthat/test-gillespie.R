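test_that("a silent system stays frozen without error", {
  tr <- run_ssa(clock_model(alpha = 0), t_end = 100, seed = 1, log = "all")
  expect_identical(tr$n_events, 0)
  expect_true(all(tr$mn == 0L & tr$mc == 0L & tr$pc == 0L & tr$pn == 0L))
  expect_identical(nrow(tr$events), 0L)
  expect_identical(length(tr$times), 201L)
})

test_that("identical seeds give bit-identical trajectories", {
  m <- clock_model(alpha = 18, N = 2)
  a <- run_ssa(m, t_end = 300, seed = 42, log = "all")
  b <- run_ssa(m, t_end = 300, seed = 42, log = "all")
  expect_identical(a$events, b$events)
  expect_identical(a$pn, b$pn)
  expect_identical(a$pc, b$pc)
  c_ <- run_ssa(m, t_end = 300, seed = 43, log = "all")
  expect_false(identical(a$events, c_$events))
})

test_that("redistribution conserves totals and balances uniform cells", {
  set.seed(7)
  for (N in c(2, 4, 7)) {
    lens <- rep(1, N)
    for (rep_ in 1:50) {
      pc <- sample(0:40, N, replace = TRUE)
      out <- redistribute(pc, lens)
      expect_identical(sum(out), sum(pc))
      expect_lte(max(out) - min(out), 1L)
      expect_true(all(out >= sum(pc) %/% N))
    }
  }
  # zero remainder is deterministic
  expect_identical(redistribute(c(5, 1, 0, 2), rep(1, 4)), rep(2L, 4))
  # p_tot = 7 over two compartments: (4,3) and (3,4) equally likely
  set.seed(1)
  draws <- replicate(2000, redistribute(c(7, 0), c(1, 1))[1])
  expect_true(all(draws %in% c(3L, 4L)))
  expect_lt(abs(mean(draws == 4) - 0.5), 0.05)
})

test_that("length-weighted redistribution matches the expected allocation", {
  # zero fractional remainder: deterministic split
  expect_identical(redistribute(c(9, 0), c(2, 1)), c(6L, 3L))
  # fractional remainders: per-compartment deviation <= 1, mean matches
  set.seed(2)
  draws <- replicate(4000, redistribute(c(10, 0), c(2, 1)))
  expect_true(all(abs(draws[1, ] - 20 / 3) < 1))
  expect_lt(abs(mean(draws[1, ]) - 20 / 3), 0.05)
  expect_true(all(colSums(draws) == 10))
  # multinomial alternative conserves the total
  set.seed(3)
  mdraw <- replicate(200, sum(redistribute(c(11, 4, 2), c(1, 2, 1),
                                           method = "multinomial")))
  expect_true(all(mdraw == 17))
})

test_that("uniform syncytia keep the protein pool balanced while running", {
  tr <- run_ssa(clock_model(alpha = 50, N = 4), t_end = 300, seed = 5)
  spread <- apply(tr$pc, 1, function(v) max(v) - min(v))
  expect_true(all(spread <= 1L))
  for (f in c("mn", "mc", "pc", "pn")) expect_true(all(tr[[f]] >= 0L))
})

test_that("gridded samples are the right-continuous event replay", {
  v <- sample_on_grid(1.5, 1, dt = 1, t_end = 3, v0 = 0)
  expect_identical(v, c(0, 0, 1, 1))
  expect_identical(sample_on_grid(numeric(0), numeric(0), 0.5, 2, v0 = 3),
                   rep(3, 5))
  tr <- run_ssa(clock_model(alpha = 18), t_end = 300, seed = 11, log = "all")
  rep_ <- replay_event_log(tr)
  expect_identical(rep_$mn[, 1], as.numeric(tr$mn[, 1]))
  expect_identical(rep_$mc[, 1], as.numeric(tr$mc[, 1]))
  expect_identical(rep_$pc[, 1], as.numeric(tr$pc[, 1]))
  expect_identical(rep_$pn[, 1], as.numeric(tr$pn[, 1]))
  # independent compartments are replayable too
  tr2 <- run_ssa(clock_model(alpha = 18, N = 2), t_end = 200, seed = 12,
                 log = "all", share = FALSE)
  rep2 <- replay_event_log(tr2)
  expect_identical(rep2$pc, matrix(as.numeric(tr2$pc), ncol = 2))
})

test_that("repression-free chains reach their Poisson stationary law", {
  tr <- cache_poisson()
  mu <- 18 / (2 * pi / 22) # alpha / gamma_m = alpha / delta_m = 63.03
  keep <- tr$times > 200
  expect_lt(abs(mean(tr$mn[keep, 1]) - mu) / mu, 0.02)
  expect_lt(abs(mean(tr$mc[keep, 1]) - mu) / mu, 0.02)
  # chi-square goodness of fit on near-independent subsamples
  sub <- tr$mn[keep & (tr$times %% 10 == 0), 1]
  lo <- qpois(0.005, mu); hi <- qpois(0.995, mu)
  bins <- c(-Inf, lo:hi, Inf)
  obs <- table(cut(sub, bins))
  pr <- diff(ppois(c(-Inf, lo:hi, Inf), mu))
  gof <- suppressWarnings(chisq.test(as.integer(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("trial-averaged counts track the deterministic high-copy limit", {
  mf <- cache_meanfield()
  avg_pn <- rowMeans(pn_series(mf$sims, compartment = 1))
  ode_pn <- mf$ode$Pn[, 1] * mf$model$V_n
  scale <- max(ode_pn)
  rmse <- sqrt(mean((avg_pn - ode_pn)^2))
  expect_lt(rmse / scale, 0.05)
})

test_that("uniform compartments are statistically exchangeable", {
  tr <- run_ssa(clock_model(alpha = 18, N = 4), t_end = 5000, seed = 21,
                log = "transcription")
  totals <- table(factor(tr$events$compartment, levels = 1:4))
  expect_true(all(abs(totals / mean(totals) - 1) < 0.1))
})
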