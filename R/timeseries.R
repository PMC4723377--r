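#' Monthly distinct-author series for a topic
#'
#' Aggregates a raw post event log into the per-period count of distinct
#' authors writing on a topic — the observation variable of the diffusion
#' model. Every author with at least one post carrying the topic label in a
#' calendar period (commenters included) counts once; periods between the
#' first and last matching post with no activity are filled with zero so the
#' series sits on a regular grid, and periods are re-indexed `0..n-1`.
#'
#' Posts are bucketed by the calendar month (or day) of their timestamp in
#' UTC. Optionally, posts in threads that went quiet long before the end of
#' the log can be dropped via `active_window`: a thread is kept only if its
#' last post falls within `active_window` months of the log's final
#' timestamp. This filter is off by default.
#'
#' @param posts A data frame with columns `thread_id`, `post_id`, `author_id`,
#'   `timestamp` (ISO-8601 text or POSIXct), `topic_label`.
#' @param topic Topic label to select.
#' @param period `"month"` (default) or `"day"`.
#' @param active_window Optional number of months; see Details.
#' @return A tibble with columns `t` (0-based period index), `date`
#'   (`YYYY-MM` or `YYYY-MM-DD`), `count`, carrying attributes `topic`,
#'   `period` and `smoothed = FALSE`.
#' @examples
#' log <- tibble::tibble(
#'   thread_id = "th1", post_id = paste0("p", 1:3),
#'   author_id = c("a", "a", "b"),
#'   timestamp = c("2005-01-03", "2005-01-20", "2005-03-07"),
#'   topic_label = "wage"
#' )
#' count_distinct_authors(log, "wage")
#' @export
count_distinct_authors <- function(posts, topic, period = c("month", "day"),
                                   active_window = NULL) {
  period <- match.arg(period)
  need <- c("thread_id", "post_id", "author_id", "timestamp", "topic_label")
  missing_cols <- setdiff(need, names(posts))
  if (length(missing_cols)) {
    abort(paste0("`posts` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  ts <- parse_timestamp(posts$timestamp, posts$post_id)
  posts <- dplyr::mutate(tibble::as_tibble(posts), .ts = ts)
  if (!is.null(active_window)) {
    log_end <- max(posts$.ts)
    posts <- posts |>
      dplyr::group_by(.data$thread_id) |>
      dplyr::filter(as.numeric(difftime(log_end, max(.data$.ts), units = "days"))
                    <= active_window * 30.44) |>
      dplyr::ungroup()
  }
  matched <- dplyr::filter(posts, .data$topic_label == topic)
  if (nrow(matched) == 0L) {
    abort(sprintf("empty series: no posts carry topic label '%s'.", topic))
  }
  fmt <- if (period == "month") "%Y-%m" else "%Y-%m-%d"
  matched <- dplyr::mutate(matched, bucket = format(.ts, fmt, tz = "UTC"))
  grid <- period_grid(min(matched$.ts), max(matched$.ts), period)
  counted <- matched |>
    dplyr::group_by(.data$bucket) |>
    dplyr::summarise(count = dplyr::n_distinct(.data$author_id), .groups = "drop")
  out <- tibble::tibble(date = grid) |>
    dplyr::left_join(counted, by = c(date = "bucket")) |>
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L),
                  t = dplyr::row_number() - 1L) |>
    dplyr::select("t", "date", "count")
  new_observed_series(out, topic = topic, period = period, smoothed = FALSE)
}

parse_timestamp <- function(x, post_id) {
  if (inherits(x, "POSIXct")) return(x)
  if (inherits(x, "Date")) return(as.POSIXct(x, tz = "UTC"))
  x2 <- sub("T", " ", as.character(x))
  parsed <- as.POSIXct(strptime(x2, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                       tz = "UTC")
  miss <- is.na(parsed)
  if (any(miss)) {
    parsed[miss] <- as.POSIXct(strptime(x2[miss], "%Y-%m-%d", tz = "UTC"),
                               tz = "UTC")
  }
  bad <- which(is.na(parsed) | is.na(x))
  if (length(bad)) {
    abort(sprintf("unparseable timestamp for post_id %s.",
                  paste(post_id[head(bad, 5)], collapse = ", ")))
  }
  parsed
}

period_grid <- function(from, to, period) {
  if (period == "month") {
    s <- seq(as.Date(format(from, "%Y-%m-01", tz = "UTC")),
             as.Date(format(to, "%Y-%m-01", tz = "UTC")), by = "month")
    format(s, "%Y-%m")
  } else {
    format(seq(as.Date(format(from, "%Y-%m-%d", tz = "UTC")),
               as.Date(format(to, "%Y-%m-%d", tz = "UTC")), by = "day"),
           "%Y-%m-%d")
  }
}

new_observed_series <- function(x, topic = NA_character_, period = "month",
                                smoothed = FALSE) {
  attr(x, "topic") <- topic
  attr(x, "period") <- period
  attr(x, "smoothed") <- smoothed
  x
}

check_series <- function(series, min_n = 1L) {
  if (!is.data.frame(series) || !all(c("t", "count") %in% names(series))) {
    abort("`series` must be a data frame with columns `t` and `count`.")
  }
  if (nrow(series) < min_n) {
    abort(sprintf("series has %d period(s); at least %d required.",
                  nrow(series), min_n))
  }
  if (any(series$count < 0)) abort("`count` must be non-negative.")
  if (nrow(series) > 1 && !all(diff(series$t) == 1)) {
    abort("`t` must be consecutive integers (unit spacing).")
  }
  invisible(series)
}

#' Trailing moving average of an author series
#'
#' Smooths period counts with a trailing (causal) mean over the last `window`
#' periods; at the start of the series, where fewer than `window` periods
#' exist, the mean runs over all available history, so the output has the same
#' length as the input. A three-month window is the conventional choice for
#' damping month-to-month fluctuation in forum activity before model fitting.
#'
#' @param series A series tibble as returned by [count_distinct_authors()]
#'   (columns `t`, `count`).
#' @param window Positive integer window length, at most the series length.
#' @return The series with `count` replaced by the smoothed values and the
#'   `smoothed` attribute set to the window length.
#' @export
moving_average <- function(series, window = 3) {
  check_series(series)
  n <- nrow(series)
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window != round(window)) {
    abort("`window` must be a positive integer.")
  }
  if (window > n) {
    abort(sprintf("`window` (%d) exceeds the series length (%d).",
                  as.integer(window), n))
  }
  x <- as.numeric(series$count)
  cs <- cumsum(x)
  i <- seq_len(n)
  lo <- pmax(i - window, 0L)
  sm <- (cs - c(0, cs)[lo + 1L]) / (i - lo)
  out <- dplyr::mutate(series, count = sm)
  new_observed_series(out,
                      topic = attr(series, "topic", exact = TRUE),
                      period = attr(series, "period", exact = TRUE) %||% "month",
                      smoothed = as.integer(window))
}

#' Detect activity spikes in an author series
#'
#' Flags the periods whose count strictly exceeds the series mean plus two
#' standard deviations — the classical burst rule for separating
#' event-driven "spikey" topics from ongoing "chatter". The standard
#' deviation uses the population (divide-by-n) convention, and the comparison
#' is strict, so a constant series never spikes.
#'
#' @param series A series tibble (columns `t`, `count`), length at least 2.
#' @return An object of class `spike_report`: a list with `threshold`,
#'   `spike_periods` (values of `t` exceeding it), `is_spikey`, `series_mean`
#'   and `series_sd`. Use [tidy()] for a tibble view.
#' @export
detect_spikes <- function(series) {
  check_series(series, min_n = 2L)
  x <- as.numeric(series$count)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  thr <- m + 2 * s
  idx <- series$t[x > thr]
  structure(
    list(threshold = thr, spike_periods = idx, is_spikey = length(idx) > 0L,
         series_mean = m, series_sd = s),
    class = "spike_report"
  )
}

#' @export
print.spike_report <- function(x, ...) {
  cat("<spike_report>\n",
      " threshold (mean + 2 sd):", format(x$threshold), "\n",
      " spike periods:",
      if (x$is_spikey) paste(x$spike_periods, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' @method tidy spike_report
#' @export
tidy.spike_report <- function(x, ...) {
  tibble::tibble(
    series_mean = x$series_mean, series_sd = x$series_sd,
    threshold = x$threshold, n_spikes = length(x$spike_periods),
    is_spikey = x$is_spikey
  )
}

#' Classify a topic series as spikey or chatter
#'
#' A topic is "spikey" when its (unsmoothed) author series has at least one
#' period above the mean-plus-two-sigma threshold of [detect_spikes()];
#' otherwise it is "chatter". Chatter topics lack an epidemic pattern and are
#' conventionally excluded from diffusion-model fitting.
#'
#' @inheritParams detect_spikes
#' @return `"spikey"` or `"chatter"`.
#' @export
classify_topic <- function(series) {
  if (detect_spikes(series)$is_spikey) "spikey" else "chatter"
}

#' Plot an author series
#'
#' @param series A series tibble (columns `t`, `count`).
#' @param spikes Overlay the spike threshold and flag spike periods?
#' @return A ggplot object.
#' @export
plot_series <- function(series, spikes = TRUE) {
  check_series(series)
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$t, y = .data$count)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "month", y = "distinct authors",
                  title = attr(series, "topic", exact = TRUE))
  if (spikes && nrow(series) >= 2) {
    rep <- detect_spikes(series)
    p <- p + ggplot2::geom_hline(yintercept = rep$threshold,
                                 linetype = "dashed", colour = "firebrick")
    if (rep$is_spikey) {
      p <- p + ggplot2::geom_point(
        data = dplyr::filter(series, .data$t %in% rep$spike_periods),
        colour = "firebrick", size = 2
      )
    }
  }
  p
}
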