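test_that("the objective vanishes at the generating parameters and scores offsets", {
  spec <- recovery_spec(seed = 3)
  gen <- generate_series(spec)
  obs <- gen$series
  theta <- with(recovery_truth, c(alpha, beta, mu, S0, K))
  expect_lt(sir_objective(theta, obs), 1e-6 * sum(obs$count^2))
  # shifting every observation by c raises the objective to n * c^2
  shifted <- dplyr::mutate(obs, count = count + 4)
  expect_equal(sir_objective(theta, shifted, I0 = obs$count[1]),
               nrow(obs) * 16, tolerance = 1e-3)
})

test_that("the objective matches a hand-summed residual on a small candidate", {
  obs <- tibble::tibble(t = 0:4, count = c(5, 8, 12, 9, 6))
  p <- sir_params(0.01, 0.3, 0.05, 400)
  init <- sir_init(S0 = 120, I0 = 5, R0 = 0)
  ihat <- rk4_infectives(p, init, 4)
  oracle <- sum((obs$count - ihat)^2)
  expect_equal(sir_objective(c(0.01, 0.3, 0.05, 120, 400), obs),
               oracle, tolerance = 1e-4)
})

test_that("infeasible and unsimulable candidates draw the penalty, not an error", {
  obs <- tibble::tibble(t = 0:9, count = c(2, 4, 7, 11, 14, 13, 10, 7, 5, 3))
  # K below S0 + I0: infeasible initial condition
  expect_equal(sir_objective(c(0.01, 0.3, 0.1, 500, 100), obs), 1e12)
  # explosive candidate (step-size collapse territory) stays finite
  v <- sir_objective(c(0.999, 1e-6, 5, 1e5, 1e9), obs)
  expect_true(is.finite(v))
})

test_that("fit metrics reproduce MSE and R-square hand calculations", {
  m <- fit_metrics(c(1, 2, 3), c(1, 1, 3))
  expect_equal(m$mse, 1 / 3)
  expect_equal(m$r_square, 0.5)
  perfect <- fit_metrics(c(4, 7, 2), c(4, 7, 2))
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$r_square, 1)
  # predicting the mean scores exactly zero
  x <- c(3, 9, 6, 2)
  expect_equal(fit_metrics(x, rep(mean(x), 4))$r_square, 0)
  # worse than the mean: negative R-square
  expect_lt(fit_metrics(c(1, 2, 3), c(3, 3, 0))$r_square, 0)
  expect_warning(mm <- fit_metrics(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_true(is.na(mm$r_square))
  expect_error(fit_metrics(c(1, 2), c(1, 2, 3)), "mismatch")
})

test_that("the GA fit is deterministic, bounded and monotone under elitism", {
  spec <- recovery_spec(seed = 12, noise = "gaussian")
  obs <- generate_series(spec)$series
  cfg <- ga_config(population_size = 24, generations = 40, seed = 77)
  f1 <- fit_sir(obs, cfg)
  f2 <- fit_sir(obs, cfg)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$objective, f2$objective)
  # best objective never rises with elitism_count >= 1
  expect_true(all(diff(f1$history) <= 0))
  # the winning parameters respect every bound
  est <- tidy(f1)$estimate
  names(est) <- tidy(f1)$term
  expect_gte(est["alpha"], 0); expect_lt(est["alpha"], 1)
  expect_gte(est["beta"], 0); expect_lt(est["beta"], 1)
  expect_gte(est["mu"], 0); expect_lte(est["mu"], 5)
  expect_gte(est["S0"], f1$I0)
  expect_gte(est["K"], est["S0"])  # feasibility: K >= N0 enforced via penalty
  # objective identity: final objective equals mse * n
  expect_equal(f1$objective, f1$mse * nrow(f1$observed),
               tolerance = 1e-9)
  expect_gte(f1$objective, 0)
})

test_that("fitting trims leading zeros and rejects degenerate series", {
  spec <- recovery_spec(seed = 5)
  obs <- generate_series(spec)$series
  padded <- dplyr::bind_rows(
    tibble::tibble(t = 0:1, date = c("2003-11", "2003-12"), count = c(0, 0)),
    dplyr::mutate(obs, t = t + 2L)
  )
  padded$t <- seq_len(nrow(padded)) - 1L
  cfg <- ga_config(population_size = 16, generations = 10, seed = 1)
  f <- fit_sir(padded, cfg)
  expect_equal(nrow(f$observed), nrow(obs))
  expect_equal(f$I0, obs$count[1])
  expect_error(fit_sir(tibble::tibble(t = 0:9, count = rep(0, 10)), cfg),
               "no positive")
  expect_error(fit_sir(tibble::tibble(t = 0:3, count = c(1, 2, 3, 2)), cfg),
               "at least 5")
  expect_error(
    fit_sir(obs, ga_config(population_size = 16, generations = 10, seed = 1,
                           bounds = list(K = c(0.1, 0.5)))),
    "infeasible"
  )
})

test_that("fixed genes are pinned while free genes are searched", {
  obs <- generate_series(recovery_spec(seed = 9))$series
  cfg <- ga_config(population_size = 20, generations = 25, seed = 4)
  f <- fit_sir(obs, cfg, fixed = list(mu = 0.13, S0 = 100, K = 1000))
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "mu"], 0.13)
  expect_equal(td$estimate[td$term == "S0"], 100)
  expect_equal(td$estimate[td$term == "K"], 1000)
  expect_true(all(td$fixed == (td$term %in% c("mu", "S0", "K"))))
  expect_error(fit_sir(obs, cfg, fixed = list(gamma = 1)), "unknown fixed")
  expect_error(fit_sir(obs, cfg, fixed = list(beta = 0.7, mu = 0.13,
                                              S0 = 100, K = 1000)),
               "at least 2")
})

test_that("the optional polish never worsens the GA optimum", {
  obs <- generate_series(recovery_spec(seed = 2, noise = "gaussian"))$series
  cfg <- ga_config(population_size = 20, generations = 20, seed = 8)
  plain <- fit_sir(obs, cfg)
  polished <- fit_sir(obs, cfg, polish = TRUE)
  expect_lte(polished$objective, plain$objective * (1 + 1e-6))
})

test_that("glance and autoplot expose the fit summary", {
  obs <- generate_series(recovery_spec(seed = 6))$series
  f <- fit_sir(obs, ga_config(population_size = 16, generations = 12, seed = 2))
  g <- glance(f)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$n, nrow(obs))
  expect_equal(g$reproduction_ratio,
               f$params$alpha * f$S0 / f$params$beta)
  expect_s3_class(autoplot(f), "ggplot")
  expect_s3_class(autoplot(f, compartments = TRUE), "ggplot")
})
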