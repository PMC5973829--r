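# Accumulator primitives: fairness, drift, bounds, simulation, and the
# deterministic choice/RT density.

test_that("fairness is the negative payoff gap", {
  expect_equal(fairness(20, 20), 0)
  expect_equal(fairness(40, 0), -40)
  expect_equal(fairness(13, 27), -14)
  expect_true(all(fairness(runif(20, 0, 40), runif(20, 0, 40)) <= 0))
})

test_that("drift increment is the weighted attribute sum", {
  p <- ddm_params(c(taste = 0.0163, health = -0.0003))
  expect_equal(drift_increment(p, c(taste = 2, health = 0)), 0.0326)
  p0 <- ddm_params(c(taste = 0, health = 0))
  expect_equal(drift_increment(p0, c(taste = -2, health = 1)), 0)
  pa <- ddm_params(c(self = 0.0082, other = 0.0010, fairness = 0.0018))
  expect_equal(drift_increment(pa, c(self = 20, other = 20, fairness = 0)),
               0.184)
  expect_error(drift_increment(p, c(taste = 1)), "missing")
})

test_that("bounds are constant pre-ndt and collapse exponentially", {
  p <- ddm_params(c(a = 0), ndt = 0.4, bound0 = 1, decay = 0.5)
  expect_equal(bound_at(p, 2.4), exp(-1))
  expect_equal(bound_at(p, 0.1), 1)
  p0 <- ddm_params(c(a = 0), decay = 0)
  tt <- seq(0, 4, by = 0.1)
  expect_true(all(bound_at(p0, tt) == p0$bound0))
  b <- bound_at(p, tt)
  expect_true(all(diff(b) <= 0))
  expect_true(all(b > 0))
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(ddm_params(c(0.01)), "named")
  expect_error(ddm_params(c(a = 0.01), bound0 = -1))
  expect_error(ddm_params(c(a = 0.01), ndt = 5), "deadline")
})

test_that("simulation is symmetric at zero drift and deterministic at huge drift", {
  set.seed(101)
  p0 <- ddm_params(c(a = 0))
  s <- simulate_trials(p0, c(a = 1), n = 1e5)
  expect_equal(mean(s$choice == "yes"), 0.5, tolerance = 0.01)
  # drift 10x the per-step noise: immediate, certain crossing
  pb <- ddm_params(c(a = 1))
  sb <- simulate_trials(pb, c(a = 1), n = 1000)
  expect_true(mean(sb$choice == "yes") > 0.99)
  expect_true(all(sb$rt <= pb$ndt + 10 * pb$dt, na.rm = TRUE))
})

test_that("mean RT decreases as the drift magnitude grows", {
  set.seed(102)
  p <- ddm_params(c(a = 1))
  mean_rt <- vapply(c(0.01, 0.03, 0.06, 0.1), function(v) {
    s <- simulate_trials(p, c(a = v / 1), n = 4000)
    mean(s$rt, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_rt) < 0))
})

test_that("density mass is conserved across a parameter sweep", {
  set.seed(103)
  for (i in 1:20) {
    p <- ddm_params(c(a = runif(1, -0.05, 0.05)),
                    ndt = runif(1, 0.1, 1), bound0 = runif(1, 0.3, 2),
                    decay = runif(1, 0, 2))
    d <- choice_rt_density(p, c(a = 1))
    expect_equal(sum(d$p_yes) + sum(d$p_no) + d$p_missed, 1,
                 tolerance = 1e-6)
    expect_true(all(c(d$p_yes, d$p_no, d$p_missed) >= 0))
  }
})

test_that("density has sign-flip symmetry and a half split at zero drift", {
  p_pos <- ddm_params(c(a = 0.02))
  p_neg <- ddm_params(c(a = -0.02))
  d1 <- choice_rt_density(p_pos, c(a = 1))
  d2 <- choice_rt_density(p_neg, c(a = 1))
  expect_equal(d1$p_yes, d2$p_no, tolerance = 1e-6)
  expect_equal(d1$p_no, d2$p_yes, tolerance = 1e-6)
  d0 <- choice_rt_density(ddm_params(c(a = 0)), c(a = 1))
  expect_equal(sum(d0$p_yes), 0.5 - d0$p_missed / 2, tolerance = 1e-6)
})

test_that("P(yes) is non-decreasing in a weight paired with a positive attribute", {
  p_yes_at <- function(w) {
    d <- choice_rt_density(ddm_params(c(a = w)), c(a = 2))
    sum(d$p_yes)
  }
  py <- vapply(seq(-0.02, 0.02, length.out = 9), p_yes_at, numeric(1))
  expect_true(all(diff(py) >= 0))
})

test_that("density matches large-sample Monte-Carlo histograms", {
  # simulation oracle: 1e6 draws of the identical discrete walk
  set.seed(104)
  cases <- data.frame(v = c(0.02, -0.01, 0.05), bound0 = c(1, 0.8, 1.5),
                      decay = c(0.5, 0.2, 1), ndt = c(0.4, 0.3, 0.6))
  for (i in seq_len(nrow(cases))) {
    p <- ddm_params(c(a = cases$v[i]), ndt = cases$ndt[i],
                    bound0 = cases$bound0[i], decay = cases$decay[i])
    d <- choice_rt_density(p, c(a = 1))
    s <- simulate_trials(p, c(a = 1), n = 1e6)
    nb <- length(d$p_yes)
    bin <- pmin(floor(s$rt / 0.05 + 1e-9) + 1, nb)
    hy <- tabulate(bin[s$choice == "yes"], nb) / nrow(s)
    hn <- tabulate(bin[s$choice == "no"], nb) / nrow(s)
    expect_lt(max(abs(hy - d$p_yes)), 0.005)
    expect_lt(max(abs(hn - d$p_no)), 0.005)
    expect_equal(mean(s$choice == "missed"), d$p_missed, tolerance = 0.005)
  }
})

test_that("density errors when the grid cannot resolve the bound", {
  p <- ddm_params(c(a = 0.01), bound0 = 0.5)
  expect_error(choice_rt_density(p, c(a = 1), n_grid = 5), "grid")
})

test_that("log-likelihood is additive over trials and handles degenerate data", {
  set.seed(105)
  p <- ddm_params(c(taste = 0.0163, health = -0.0003))
  beh <- sim_subject("food", "NC", params = p)
  ll <- log_likelihood(p, beh)
  ll_split <- sum(vapply(seq_len(nrow(beh)), function(i)
    log_likelihood(p, beh[i, ]), numeric(1)))
  expect_equal(ll, ll_split, tolerance = 1e-9)
  # all-missed data: n * log(p_missed)
  allmiss <- beh[1:5, ]
  allmiss$choice <- "missed"; allmiss$rt_s <- NA
  d <- choice_rt_density(p, allmiss[1, ])
  pm <- max(d$p_missed, 1e-10)
  expect_equal(log_likelihood(p, allmiss), 5 * log(pm))
  expect_error(log_likelihood(p, beh[0, ]), "empty")
})

test_that("log-likelihood is invariant to trial order", {
  set.seed(106)
  p <- ddm_params(c(taste = 0.01, health = 0.005))
  beh <- sim_subject("food", "NC", params = p)
  expect_equal(log_likelihood(p, beh),
               log_likelihood(p, beh[sample(nrow(beh)), ]),
               tolerance = 1e-9)
})
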