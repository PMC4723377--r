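test_that("the right-hand side implements infection, recovery and logistic recruitment", {
  p <- sir_params(alpha = 0.01, beta = 0.5, mu = 0, K = 1000)
  d <- sir_rhs(c(100, 10, 0), p)
  expect_equal(unname(d), c(-10, 5, 5))  # alpha*S*I = 10, beta*I = 5
  # no infectives and no recruitment: nothing moves
  expect_equal(unname(sir_rhs(c(50, 0, 5), sir_params(0.3, 0.2, 0, 100))),
               c(0, 0, 0))
  # recruitment enters S at the logistic rate mu * (K - N)/K * N
  d2 <- sir_rhs(c(100, 0, 0), sir_params(0, 0, mu = 0.5, K = 200))
  expect_equal(unname(d2), c(0.5 * (100 / 200) * 100, 0, 0))
  expect_error(sir_rhs(c(NA, 1, 0), p), "finite")
})

test_that("mass is conserved by the derivatives whenever recruitment is off", {
  set.seed(11)
  for (i in 1:25) {
    p <- sir_params(runif(1, 0, 0.99), runif(1, 0, 0.99), 0, runif(1, 10, 5000))
    state <- runif(3, 0, 500)
    expect_equal(sum(sir_rhs(state, p)), 0)
  }
})

test_that("parameter and state validation enforce the model's constraints", {
  expect_error(sir_params(1, 0.5, 0, 100), "alpha")
  expect_error(sir_params(0.5, -0.1, 0, 100), "beta")
  expect_error(sir_params(0.5, 0.5, -1, 100), "mu")
  expect_error(sir_params(0.5, 0.5, 0, 0), "K")
  expect_error(sir_init(-1, 1, 0), "non-negative")
  expect_silent(sir_params(0, 0, 5, 1))
})

test_that("simulation matches the exponential-decay closed form when alpha = mu = 0", {
  b <- 0.37
  traj <- simulate_sir(sir_params(0, b, 0, 100), sir_init(50, 10, 0), 15)
  expected <- 10 * exp(-b * traj$t)
  expect_lt(max(abs(traj$I - expected) / expected), 1e-4)
  expect_equal(traj$S, rep(50, 16), tolerance = 1e-6)
})

test_that("simulation matches the logistic closed form when alpha = beta = 0", {
  mu <- 0.8; K <- 1000; N0 <- 30
  traj <- simulate_sir(sir_params(0, 0, mu, K), sir_init(20, 10, 0), 12)
  expected <- K * N0 * exp(mu * traj$t) / (K + N0 * (exp(mu * traj$t) - 1))
  expect_lt(max(abs(traj$N - expected) / expected), 1e-4)
})

test_that("the adaptive integrator agrees with a fine fixed-step RK4 oracle", {
  set.seed(2024)
  for (i in 1:20) {
    p <- sir_params(alpha = runif(1, 5e-4, 0.02), beta = runif(1, 0.05, 0.9),
                    mu = runif(1, 0, 0.5), K = runif(1, 500, 5000))
    init <- sir_init(S0 = runif(1, 20, 400), I0 = runif(1, 1, 20), R0 = 0)
    traj <- simulate_sir(p, init, 20)
    oracle <- rk4_infectives(p, init, 20)
    denom <- pmax(abs(oracle), 1e-2)
    expect_lt(max(abs(traj$I - oracle) / denom), 1e-3)
  }
})

test_that("trajectories conserve N with mu = 0 and respect the carrying capacity", {
  p <- sir_params(0.004, 0.3, 0, 1200)
  traj <- simulate_sir(p, sir_init(300, 5, 0), 30)
  expect_lt(max(abs(traj$N - 305)), 1e-6 * 305)
  # with recruitment on and N0 <= K, N grows monotonically toward K
  p2 <- sir_params(0.004, 0.3, 0.4, 1200)
  tr2 <- simulate_sir(p2, sir_init(300, 5, 0), 40)
  expect_true(all(diff(tr2$N) >= -1e-8))
  expect_true(all(tr2$N <= 1200 * (1 + 1e-6)))
  # R never decreases
  expect_true(all(diff(tr2$R) >= -1e-9))
  # N = S + I + R by construction on every row
  expect_equal(tr2$N, tr2$S + tr2$I + tr2$R)
})

test_that("initial infective growth is governed by the threshold alpha*S0 - beta", {
  set.seed(7)
  for (i in 1:100) {
    p <- sir_params(runif(1, 1e-4, 0.05), runif(1, 0.01, 0.99),
                    runif(1, 0, 1), runif(1, 100, 5000))
    S0 <- runif(1, 1, 800); I0 <- runif(1, 1, 30)
    dI <- sir_rhs(c(S0, I0, 0), p)[["dI"]]
    expect_equal(sign(dI), sign(p$alpha * S0 - p$beta))
  }
})

test_that("simulation above/below threshold grows/dies as the ratio predicts", {
  # ratio < 1: infectives decline from the outset
  p_lo <- sir_params(0.002, 0.6, 0, 1000)   # ratio = 0.2/0.6 < 1 at S0 = 100
  tr <- simulate_sir(p_lo, sir_init(100, 10, 0), 5)
  expect_lt(tr$I[2], tr$I[1])
  # ratio > 1: initial growth
  p_hi <- sir_params(0.01, 0.4, 0, 1000)    # ratio = 1/0.4 > 1
  tr2 <- simulate_sir(p_hi, sir_init(100, 10, 0), 5)
  expect_gt(tr2$I[2], tr2$I[1])
})

test_that("the effective reproduction ratio is alpha * S0 / beta", {
  expect_equal(effective_reproduction_ratio(sir_params(0.02, 0.5, 0, 100), 25), 1)
  expect_equal(effective_reproduction_ratio(sir_params(0.0045, 0.6798, 0.1226, 1384), 163),
               0.0045 * 163 / 0.6798)
  expect_error(effective_reproduction_ratio(sir_params(0.1, 0, 0, 100), 10),
               "beta")
})

test_that("the Euler mode reproduces a hand-iterated monthly update", {
  p <- sir_params(0.005, 0.4, 0.1, 800)
  y <- c(200, 10, 0)
  hand <- matrix(NA_real_, 4, 3)
  hand[1, ] <- y
  for (i in 2:4) {
    y <- y + unname(sir_rhs(y, p))
    hand[i, ] <- y
  }
  tr <- simulate_sir(p, sir_init(200, 10, 0), 3, method = "euler")
  expect_equal(unname(as.matrix(tr[, c("S", "I", "R")])), hand)
})

test_that("simulation tolerates N0 > K by shrinking the population toward K", {
  p <- sir_params(0, 0, mu = 0.5, K = 100)
  tr <- simulate_sir(p, sir_init(150, 10, 0), 30)
  expect_true(all(diff(tr$N) <= 1e-8))
  expect_gt(min(tr$N), 100 - 1)
})
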