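test_that("hill repression matches the closed form and is monotone", {
  m <- clock_model()
  expect_identical(hill_repression(0, m), 1)
  # half-max concentration: pn = K * V_n molecules
  expect_equal(hill_repression(m$K * m$V_n, m), 0.5^5)
  expect_lt(hill_repression(1e6, m), 1e-15)
  grid <- hill_repression(seq(0, 500, by = 5), m)
  expect_true(all(diff(grid) < 0))
  expect_true(all(grid > 0 & grid <= 1))
  expect_error(hill_repression(-1, m), "non-negative")
})

test_that("propensities implement the count-level rate laws", {
  m <- clock_model(alpha = 18)
  zero <- clock_state(N = 1)
  a0 <- propensities(zero, m)
  expect_equal(unname(a0[1, "transcription"]), 18)
  expect_true(all(a0[1, -1] == 0))

  st <- clock_state(mn = 2, mc = 3, pc = 7, pn = 20)
  a <- propensities(st, m)
  expect_equal(unname(a[1, "transcription"]), 18 / 32) # half-max repression
  expect_equal(unname(a[1, "translation"]), 30)
  expect_equal(unname(a[1, "mrna_decay"]), 3 * 2 * pi / 22)
  expect_equal(unname(a[1, "export"]), 2 * 2 * pi / 22)
  expect_equal(unname(a[1, "import"]), 7 * 2 * pi / 22)
  expect_equal(unname(a[1, "protein_decay"]), 20 * 2 * pi / 22)

  # linearity of the five linear channels in the counts
  st2 <- clock_state(mn = 4, mc = 6, pc = 14, pn = 20)
  a2 <- propensities(st2, m)
  expect_equal(unname(a2[1, c("export", "mrna_decay", "translation",
                              "import")]),
               2 * unname(a[1, c("export", "mrna_decay", "translation",
                                 "import")]))
  expect_error(propensities(list(mn = 1, mc = 0, pc = 0), m), "mn, mc")
  expect_error(propensities(clock_state(mn = c(1, 1), N = 2), m),
               "per compartment")
})

test_that("the analytic oscillation threshold and its scalings hold", {
  expect_lt(abs(hopf_threshold(clock_model()) - 2039), 1)
  base <- hopf_threshold(clock_model())
  expect_equal(hopf_threshold(clock_model(beta = 20)), base / 2)
  nu2 <- 2 * (2 * pi / 22)
  expect_equal(hopf_threshold(clock_model(gamma_m = nu2, gamma_p = nu2,
                                          delta_m = nu2, delta_p = nu2)),
               4 * base)
  expect_error(hopf_threshold(clock_model(gamma_m = 0.5)), "requires")
  expect_error(hopf_threshold(clock_model(r = 4)), "r = 5")
})

test_that("expected allocation is proportional, conserving, scale-invariant", {
  expect_equal(expected_allocation(9, c(2, 1)), c(6, 3))
  expect_equal(expected_allocation(100, rep(1, 4)), rep(25, 4))
  expect_equal(expected_allocation(0, c(3, 2)), c(0, 0))
  alloc <- expected_allocation(137, c(1.2, 3.4, 0.7))
  expect_equal(sum(alloc), 137)
  expect_equal(expected_allocation(137, 3.7 * c(1.2, 3.4, 0.7)), alloc)
  m <- clock_model(lengths = c(1.5, 1))
  expect_equal(expected_allocation(10, m), 10 * c(1.5, 1) / 2.5)
  expect_error(expected_allocation(-1, c(1, 1)), "non-negative")
})

test_that("the model constructor validates its inputs", {
  expect_error(clock_model(beta = -1), "positive")
  expect_error(clock_model(K = 0), "positive")
  expect_error(clock_model(r = 2.5), "integer")
  expect_error(clock_model(r = -1), "integer")
  expect_error(clock_model(lengths = c(1, 0)), "positive")
  expect_error(clock_model(N = 0), "positive integer")
  m <- clock_model(N = 3)
  expect_identical(m$geometry$N, 3L)
  expect_true(m$geometry$uniform)
  expect_equal(m$geometry$weights, rep(1 / 3, 3))
  expect_named(coef(m), c("alpha", "beta", "gamma_m", "gamma_p", "delta_m",
                          "delta_p", "K", "r", "V_n", "V_c"))
})

test_that("the steady state balances every reaction channel", {
  for (alpha in c(18, 1800)) {
    m <- clock_model(alpha = alpha)
    ss <- steady_state(m)
    st <- list(mn = ss["mn"], mc = ss["mc"], pc = ss["pc"], pn = ss["pn"])
    # continuous-flow balance (counts are real-valued here on purpose)
    flux_tx <- m$alpha * hill_repression(ss["pn"], m)
    expect_equal(unname(flux_tx), unname(m$gamma_m * ss["mn"]))
    expect_equal(unname(m$gamma_m * ss["mn"]), unname(m$delta_m * ss["mc"]))
    expect_equal(unname(m$beta * ss["mc"]), unname(m$gamma_p * ss["pc"]))
    expect_equal(unname(m$gamma_p * ss["pc"]), unname(m$delta_p * ss["pn"]))
  }
})
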