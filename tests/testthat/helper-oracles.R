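# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the RK4 integrator works from sir_rhs() with a
# fixed step, and the author counter is a base-R loop over string buckets.

# Fixed-step classical RK4 on the SIR system; returns I at integer months.
rk4_infectives <- function(params, init, horizon, h = 0.001) {
  y <- c(init$S0, init$I0, init$R0)
  f <- function(y) unname(sir_rhs(y, params))
  out <- numeric(horizon + 1)
  out[1] <- y[2]
  steps_per_month <- round(1 / h)
  for (m in seq_len(horizon)) {
    for (s in seq_len(steps_per_month)) {
      k1 <- f(y)
      k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2)
      k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[m + 1] <- y[2]
  }
  out
}

# Brute-force distinct-author counter: set of authors per YYYY-MM bucket,
# over the full month range, implemented with base R only.
brute_force_counts <- function(posts, topic) {
  posts <- posts[posts$topic_label == topic, ]
  month <- substr(as.character(posts$timestamp), 1, 7)
  range <- seq(as.Date(paste0(min(month), "-01")),
               as.Date(paste0(max(month), "-01")), by = "month")
  keys <- format(range, "%Y-%m")
  vapply(keys, function(k) {
    length(unique(posts$author_id[month == k]))
  }, integer(1))
}

# Crafted 12-post log spanning three months with 3, 2, 4 distinct authors.
crafted_post_log <- function() {
  tibble::tibble(
    thread_id = rep(c("t1", "t2"), 6),
    post_id = sprintf("p%02d", 1:12),
    author_id = c("ann", "bob", "ann", "cat",          # Jan: ann, bob, cat
                  "bob", "bob", "cat",                 # Feb: bob, cat
                  "ann", "dan", "eve", "bob", "eve"),  # Mar: ann, dan, eve, bob
    timestamp = c("2005-01-03 10:00:00", "2005-01-07 11:30:00",
                  "2005-01-15 09:00:00", "2005-01-28 22:10:00",
                  "2005-02-02 08:00:00", "2005-02-14 12:00:00",
                  "2005-02-20 18:45:00",
                  "2005-03-01 07:15:00", "2005-03-09 13:00:00",
                  "2005-03-17 16:30:00", "2005-03-25 20:00:00",
                  "2005-03-30 23:59:00"),
    topic_label = "wage"
  )
}

# A ten-period series with a single burst in the final period.
burst_series <- function() {
  tibble::tibble(t = 0:9, count = c(rep(1, 9), 30))
}

# Reference parameters for a clearly super-threshold outbreak and a gently
# decaying sub-threshold topic.
spikey_spec <- function(seed, noise = "gaussian", noise_scale = 0.1) {
  if (noise == "none") {
    synthetic_spec(alpha = 0.01, beta = 0.5, mu = 0.1, K = 1000, S0 = 200,
                   I0 = 1, horizon = 29, noise_model = "none", seed = seed)
  } else {
    synthetic_spec(alpha = 0.01, beta = 0.5, mu = 0.1, K = 1000, S0 = 200,
                   I0 = 1, horizon = 29, noise_model = noise,
                   noise_scale = noise_scale, seed = seed)
  }
}

chatter_spec <- function(seed) {
  synthetic_spec(alpha = 0.002, beta = 0.21, mu = 0, K = 1000, S0 = 100,
                 I0 = 5, horizon = 29, noise_model = "none", seed = seed)
}

# Study conditions of the recovery harness: the ground truth every fitting
# check uses.
recovery_truth <- list(alpha = 0.008, beta = 0.7, mu = 0.13, S0 = 100,
                       K = 1000)

recovery_spec <- function(seed, noise = "none", noise_scale = 0.1) {
  if (noise == "none") {
    synthetic_spec(alpha = recovery_truth$alpha, beta = recovery_truth$beta,
                   mu = recovery_truth$mu, K = recovery_truth$K,
                   S0 = recovery_truth$S0, I0 = 1, horizon = 29,
                   noise_model = "none", seed = seed)
  } else {
    synthetic_spec(alpha = recovery_truth$alpha, beta = recovery_truth$beta,
                   mu = recovery_truth$mu, K = recovery_truth$K,
                   S0 = recovery_truth$S0, I0 = 1, horizon = 29,
                   noise_model = noise, noise_scale = noise_scale, seed = seed)
  }
}
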