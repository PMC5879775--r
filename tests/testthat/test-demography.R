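test_that("juvenile survival combines competition and background mortality", {
  p10 <- demography_params(T_L = 10, mu_J = 0)
  # at J_T = alpha the cumulative competition death over development is 0.5
  expect_equal(juvenile_survival_prob(500, 500, p10), 0.5^0.1)
  expect_equal(juvenile_survival_prob(500, 500, p10), 0.93303,
               tolerance = 1e-5)
  expect_equal(1 - juvenile_survival_prob(500, 500, p10)^10, 0.5)
  # empty pool survives the competition term fully
  expect_equal(juvenile_survival_prob(500, 0, p10), 1)
  # certain background mortality kills regardless of competition
  expect_equal(juvenile_survival_prob(500, 0, demography_params(mu_J = 1)), 0)
  # no habitat at all is lethal
  expect_equal(juvenile_survival_prob(0, 10, p10), 0)
  expect_equal(juvenile_survival_prob(0, 0, p10), 0)
})

test_that("juvenile ageing shifts cohorts and produces emergers", {
  p <- demography_params(T_L = 4, mu_J = 0)
  st <- new_population_state(2, p)
  st$J <- rbind(c(10, 20, 30, 40), c(1, 2, 3, 4))
  # alpha -> certain survival: a pure shift of the age vector
  big <- c(1e15, 1e15)
  st1 <- step_juveniles(st, big, p)
  expect_equal(st1$J, rbind(c(0, 10, 20, 30), c(0, 1, 2, 3)))
  expect_equal(st1$emergers, c(40, 4))
  # alpha = 0: everything dies, nothing emerges
  st0 <- step_juveniles(st, c(0, 0), p)
  expect_true(all(st0$J == 0))
  expect_equal(st0$emergers, c(0, 0))
})

test_that("juvenile survival draws match the binomial oracle", {
  p <- demography_params(T_L = 2, mu_J = 0)
  st <- new_population_state(1, p)
  st$J[1, ] <- c(1e5, 0)
  alpha <- 3e5   # p_s = (3/4)^(1/2)
  ps <- juvenile_survival_prob(alpha, 1e5, p)
  set.seed(4)
  st2 <- step_juveniles(st, alpha, p)
  surv <- st2$J[1, 2]
  expect_lt(abs(surv - 1e5 * ps), 3 * sqrt(1e5 * ps * (1 - ps)))
})

test_that("emergence splits evenly and conserves totals", {
  expect_equal(emerge(c(0, 0)), list(males = c(0, 0), females = c(0, 0)))
  set.seed(8)
  em <- emerge(c(1e6, 137))
  expect_equal(em$males + em$females, c(1e6, 137))
  expect_equal(em$males[1] / 1e6, 0.5, tolerance = 0.0015 / 0.5)
})

test_that("mating probability saturates in the male count", {
  expect_equal(mating_prob(100, 100), 0.5)
  expect_equal(mating_prob(0, 100), 0)
  expect_equal(mating_prob(300, 100), 0.75)
  expect_true(all(diff(mating_prob(0:1000, 100)) > 0))
})

test_that("adult survival, mating and aestivation follow the binomial chain", {
  p <- demography_params()
  a0 <- aestivation_params()
  # certain mortality removes all active adults
  st <- new_population_state(3, demography_params(mu_A = 1))
  st$M[, 1] <- 50; st$V[, 1] <- 60; st$F[, 1] <- 70
  st1 <- step_adults(st, demography_params(mu_A = 1), a0, 100)
  expect_true(all(st1$M == 0) && all(st1$V == 0) && all(st1$F == 0))
  expect_equal(attr(st1, "deaths"), 3 * (50 + 60 + 70))
  # psi = 0 books nothing into the ledger even inside the entry window
  st <- new_population_state(1, p)
  st$F[1, 1] <- 1e4
  st2 <- step_adults(st, p, a0, a0$t_A1)
  expect_true(all(st2$E == 0))
  # binomial chain: survivors * psi entrants, (1 - mu_E) of them booked
  set.seed(12)
  aest <- aestivation_params(psi = 0.01, mu_E = 0.9)
  st <- new_population_state(1, p)
  st$F[1, 1] <- 1e5
  st3 <- step_adults(st, p, aest, aest$t_A1)
  booked <- sum(st3$E)
  expected <- 1e5 * (1 - p$mu_A) * 0.01 * 0.1
  expect_lt(abs(booked - expected), 3 * sqrt(expected))
  # booked emergence days lie inside the emergence window
  expect_true(all(which(st3$E[1, ] > 0) >= aest$t_A3))
  expect_true(all(which(st3$E[1, ] > 0) <= aest$t_A4))
})

test_that("newly emerged adults can mate the same day", {
  p <- demography_params(mu_A = 0)
  st <- new_population_state(1, p)
  st$M[1, 1] <- 1e6   # p_m essentially 1
  st$V[1, 1] <- 1000
  set.seed(3)
  st1 <- step_adults(st, p, aestivation_params(), 1)
  expect_gt(st1$F[1, 1], 990)
})

test_that("aestivator release conserves the ledger", {
  p <- demography_params()
  st <- new_population_state(2, p)
  # empty ledger: no-op
  st0 <- release_aestivators(st, 160)
  expect_identical(st0$F, st$F)
  # a booked entry moves to F on its day and only then
  st$E[1, 160] <- 5
  st$E[2, 200] <- 7
  st1 <- release_aestivators(st, 159)
  expect_equal(sum(st1$F), 0)
  st2 <- release_aestivators(st, 160)
  expect_equal(st2$F[1, 1], 5)
  expect_equal(st2$E[1, 160], 0)
  expect_equal(st2$E[2, 200], 7)
  # over a full year of releases the ledger drains exactly into F
  total <- sum(st$E)
  for (doy in 1:365) st <- release_aestivators(st, doy)
  expect_equal(sum(st$F), total)
  expect_equal(sum(st$E), 0)
})

test_that("oviposition is Poisson with the superposed rate", {
  p <- demography_params(theta = 9)
  st <- new_population_state(1, p)
  expect_equal({s <- oviposit(st, p); sum(s$J)}, 0)
  st$F[1, 1] <- 100
  p0 <- demography_params(theta = 0)
  expect_equal({s <- oviposit(st, p0); sum(s$J)}, 0)
  set.seed(21)
  st$F[1, 1] <- 1e4
  eggs <- replicate(300, attr(oviposit(st, p), "eggs"))
  expect_equal(mean(eggs), 9e4, tolerance = 3 * sqrt(9e4 / 300) / 9e4)
  expect_equal(var(eggs), 9e4, tolerance = 0.15)
})

test_that("counts stay non-negative integers and zero is absorbing", {
  p <- demography_params()
  aest <- aestivation_params(psi = 0.01)
  set.seed(55)
  st <- new_population_state(4, p)
  st$J[, 1] <- c(500, 0, 20, 0)
  st$M[, 1] <- c(50, 0, 5, 0)
  st$V[, 1] <- c(10, 0, 1, 0)
  st$F[, 1] <- c(80, 0, 9, 0)
  for (t in 1:60) {
    st <- step_juveniles(st, c(800, 800, 800, 800), p)
    em <- emerge(st$emergers)
    st$M[, 1] <- st$M[, 1] + em$males
    st$V[, 1] <- st$V[, 1] + em$females
    st <- step_adults(st, p, aest, (t + 270) %% 365 + 1)
    st <- oviposit(st, p)
    for (f in c("J", "M", "V", "F", "E")) {
      expect_true(all(st[[f]] >= 0))
      expect_true(all(st[[f]] %% 1 == 0))
    }
    # settlements 2 and 4 started empty and must stay empty
    expect_equal(sum(st$J[c(2, 4), ]) + sum(st$M[c(2, 4), ]) +
                   sum(st$V[c(2, 4), ]) + sum(st$F[c(2, 4), ]) +
                   sum(st$E[c(2, 4), ]), 0)
  }
})

test_that("the longevity cap removes adults at the configured age", {
  p <- demography_params(mu_A = 0, max_adult_age = 5)
  st <- new_population_state(1, p)
  expect_equal(ncol(st$M), 5)
  st$M[1, 1] <- 100
  for (t in 1:4) {
    st <- step_adults(st, p, aestivation_params(), t)
    expect_equal(sum(st$M), 100)
  }
  st <- step_adults(st, p, aestivation_params(), 5)
  expect_equal(sum(st$M), 0)
  expect_equal(attr(st, "deaths"), 100)
})

test_that("parameter constructors reject out-of-range values", {
  expect_error(demography_params(mu_A = 1.5))
  expect_error(demography_params(beta = 0))
  expect_error(aestivation_params(t_A1 = 100, t_A2 = 200, t_A3 = 150,
                                  t_A4 = 250), "overlap")
})
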