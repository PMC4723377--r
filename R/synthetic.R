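#' Specification of a synthetic topic outbreak
#'
#' Bundles everything needed to generate a ground-truth outbreak: the model
#' parameters and initial state, the horizon, an observation-noise model,
#' and the posting behaviour used when expanding the trajectory into a
#' forum-style post log. The noiseless infective curve is the truth that the
#' estimation pipeline should recover.
#'
#' Noise models: `"none"` reports `I(t)` exactly; `"gaussian"` adds
#' `N(0, (noise_scale * max I)^2)` and clips at zero (observation error on
#' counts); `"poisson"` draws counts with mean `I(t)` (count realism).
#'
#' @param alpha,beta,mu,K Model rates; see [sir_params()].
#' @param S0,I0,R0 Initial compartments; see [sir_init()].
#' @param horizon Months to simulate (`>= 5`).
#' @param noise_model `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_scale Gaussian sd as a fraction of peak `I` (ignored
#'   otherwise).
#' @param seed Integer seed; identical specs generate identical output.
#' @param posts_per_author_per_month Mean posts an active author writes in a
#'   month (each active author writes at least one).
#' @param topic Topic label stamped on generated posts.
#' @param carryover Fraction of a month's active authors drawn from the
#'   previous month's actives, making logs forum-like; distinct-author
#'   counts are unaffected by construction.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(alpha, beta, mu, K, S0, I0 = 1, R0 = 0,
                           horizon = 30,
                           noise_model = c("none", "gaussian", "poisson"),
                           noise_scale = 0.1, seed = 1,
                           posts_per_author_per_month = 3,
                           topic = "synthetic-topic", carryover = 0.5) {
  noise_model <- match.arg(noise_model)
  if (horizon < 5) abort("`horizon` must be at least 5 months.")
  if (noise_scale < 0) abort("`noise_scale` must be non-negative.")
  if (posts_per_author_per_month <= 0) {
    abort("`posts_per_author_per_month` must be positive.")
  }
  if (carryover < 0 || carryover > 1) abort("`carryover` must lie in [0, 1].")
  if (noise_model == "none" && !missing(noise_scale)) {
    warn("`noise_scale` is ignored when noise_model = \"none\".")
  }
  structure(
    list(params = sir_params(alpha, beta, mu, K),
         init = sir_init(S0, I0, R0),
         horizon = as.integer(horizon), noise_model = noise_model,
         noise_scale = noise_scale, seed = as.integer(seed),
         posts_per_author_per_month = posts_per_author_per_month,
         topic = topic, carryover = carryover),
    class = "synthetic_spec"
  )
}

# month index -> "YYYY-MM", anchored at an arbitrary synthetic origin
synthetic_month <- function(m, origin = as.Date("2004-01-01")) {
  format(seq(origin, by = "month", length.out = max(m) + 1L)[m + 1L], "%Y-%m")
}

#' Generate a synthetic observed series with its ground-truth trajectory
#'
#' Simulates the model under `spec`, then observes the infective curve at
#' integer months through the spec's noise model. The same spec (including
#' seed) always yields identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `series` (a series tibble with columns `t`, `date`,
#'   `count`) and `trajectory` (the noiseless [simulate_sir()] output).
#' @examples
#' spec <- synthetic_spec(0.008, 0.7, 0.13, K = 1000, S0 = 100,
#'                        horizon = 29, noise_model = "gaussian", seed = 3)
#' gen <- generate_series(spec)
#' head(gen$series)
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  traj <- simulate_sir(spec$params, spec$init, spec$horizon)
  counts <- with_preserved_seed(spec$seed, {
    switch(spec$noise_model,
      none = traj$I,
      gaussian = pmax(0, traj$I + rnorm(nrow(traj),
                                        sd = spec$noise_scale * max(traj$I))),
      poisson = as.numeric(rpois(nrow(traj), traj$I))
    )
  })
  series <- tibble::tibble(t = traj$t, date = synthetic_month(traj$t),
                           count = counts)
  series <- new_observed_series(series, topic = spec$topic,
                                period = "month", smoothed = FALSE)
  list(series = series, trajectory = traj)
}

#' Expand a trajectory into a forum-style post log
#'
#' For each month `m`, activates `round(I(m))` distinct synthetic authors,
#' each of whom writes `max(1, Poisson(posts_per_author_per_month))` posts at
#' timestamps uniform within the calendar month, all tagged with the spec's
#' topic label; thread ids are assigned round-robin. A `carryover` fraction
#' of each month's authors is reused from the previous month so author
#' histories span months, but within a month authors are distinct by
#' construction — so [count_distinct_authors()] recovers `round(I(m))`
#' exactly.
#'
#' @param trajectory A [simulate_sir()] trajectory.
#' @param spec A [synthetic_spec()].
#' @return A tibble of post records (`thread_id`, `post_id`, `author_id`,
#'   `timestamp`, `topic_label`).
#' @export
generate_post_log <- function(trajectory, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  active <- as.integer(round(trajectory$I))
  if (all(active == 0L)) {
    abort("empty log: round(I(m)) is zero for every month.")
  }
  months <- synthetic_month(trajectory$t)
  n_threads <- 10L
  with_preserved_seed(spec$seed + 1L, {
    next_author <- 1L
    prev <- character(0)
    post_counter <- 0L
    rows <- purrr::map(seq_along(active), function(m) {
      n_m <- active[m]
      if (n_m == 0L) return(NULL)
      n_carry <- min(length(prev), round(spec$carryover * n_m))
      carried <- if (n_carry > 0) sample(prev, n_carry) else character(0)
      n_new <- n_m - n_carry
      fresh <- if (n_new > 0) {
        ids <- sprintf("a%05d", seq(next_author, length.out = n_new))
        next_author <<- next_author + n_new
        ids
      } else {
        character(0)
      }
      authors <- c(carried, fresh)
      prev <<- authors
      n_posts <- pmax(1L, rpois(n_m, spec$posts_per_author_per_month))
      month_start <- as.POSIXct(paste0(months[m], "-01"), tz = "UTC")
      month_len <- as.numeric(
        seq(as.Date(paste0(months[m], "-01")), by = "month",
            length.out = 2)[2] - as.Date(paste0(months[m], "-01"))
      ) * 86400
      total <- sum(n_posts)
      ids <- post_counter + seq_len(total)
      post_counter <<- post_counter + total
      tibble::tibble(
        thread_id = sprintf("th%02d", (ids - 1L) %% n_threads + 1L),
        post_id = sprintf("p%07d", ids),
        author_id = rep(authors, times = n_posts),
        timestamp = format(month_start + runif(total, 0, month_len - 1),
                           "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
        topic_label = spec$topic
      )
    })
    dplyr::bind_rows(rows)
  })
}
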