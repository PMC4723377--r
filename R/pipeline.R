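#' Run the full topic-diffusion pipeline
#'
#' Chains the analysis stages — synthetic data generation (optional), event
#' log preparation, spike classification, and model fitting — and writes a
#' reproducible report bundle: per-topic series CSVs, a fit table in the
#' conventional column layout (`topic`, `mse`, `r_square`, `S0`, `alpha`,
#' `beta`, `mu`, `K`), fitted-trajectory CSVs with the observations overlaid,
#' the resolved configuration, and a machine-readable manifest with seeds and
#' package versions sufficient to re-run the identical pipeline.
#'
#' Chatter-classified topics are excluded from fitting by default (they lack
#' an epidemic pattern); set `include_chatter = TRUE` to fit them anyway.
#' Excluded topics are listed in the manifest.
#'
#' @param config A named list (or path to a YAML/JSON file) with entries:
#'   * `out_dir` (required) — output directory, created if needed;
#'   * `stages` — subset of `c("synth", "prepare", "spikes", "fit")`
#'     (default all that apply);
#'   * `posts` — path to a post-log CSV, or a data frame (alternative to
#'     `synth`);
#'   * `synth` — a [synthetic_spec()] or list of its arguments;
#'   * `topics` — topic labels to process (default: all in the log);
#'   * `period`, `ma_window` — aggregation granularity and smoothing window
#'     (defaults `"month"`, 3);
#'   * `include_chatter` — fit chatter topics too (default `FALSE`);
#'   * `fit` — a [ga_config()] or list of its arguments;
#'   * `seed` — master seed (default 1), used for synthesis and fitting
#'     unless those carry their own.
#' @return Invisibly, a list with `series`, `spikes`, `fits` and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config_file(config)
  }
  if (is.null(config$out_dir)) abort("`config$out_dir` is required.")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  period <- config$period %||% "month"
  ma_window <- config$ma_window %||% 3
  include_chatter <- isTRUE(config$include_chatter)
  stages <- config$stages %||%
    c(if (!is.null(config$synth)) "synth", "prepare", "spikes", "fit")

  posts <- NULL
  truth <- NULL
  if ("synth" %in% stages) {
    spec <- config$synth
    if (!inherits(spec, "synthetic_spec")) {
      spec$seed <- spec$seed %||% seed
      spec <- do.call(synthetic_spec, spec)
    }
    gen <- generate_series(spec)
    truth <- gen$trajectory
    posts <- generate_post_log(gen$trajectory, spec)
    readr::write_csv(posts, file.path(out_dir, "synthetic_posts.csv"))
  } else if (!is.null(config$posts)) {
    posts <- if (is.data.frame(config$posts)) {
      tibble::as_tibble(config$posts)
    } else {
      if (!file.exists(config$posts)) {
        abort(sprintf("stage 'prepare': input '%s' does not exist.",
                      config$posts))
      }
      readr::read_csv(config$posts, show_col_types = FALSE,
                      col_types = readr::cols(.default = readr::col_character()))
    }
  }
  if (is.null(posts)) {
    abort("no input: supply `posts` or a `synth` spec.")
  }

  topics <- config$topics %||% sort(unique(posts$topic_label))
  series <- purrr::map(
    setNames(topics, topics),
    function(tp) run_stage("prepare", tp, {
      s <- count_distinct_authors(posts, tp, period = period)
      readr::write_csv(s, file.path(out_dir, paste0("series_", slug(tp), ".csv")))
      s
    })
  )

  spikes <- NULL
  if ("spikes" %in% stages || "fit" %in% stages) {
    spikes <- purrr::map(series, function(s) {
      run_stage("spikes", attr(s, "topic"), {
        rep <- detect_spikes(s)
        dplyr::mutate(tidy(rep),
                      class = if (rep$is_spikey) "spikey" else "chatter")
      })
    }) |>
      dplyr::bind_rows(.id = "topic")
    readr::write_csv(spikes, file.path(out_dir, "spike_report.csv"))
  }

  fits <- list()
  excluded <- character(0)
  fit_cfg <- NULL
  if ("fit" %in% stages) {
    fit_cfg <- config$fit
    if (!inherits(fit_cfg, "ga_config")) {
      fit_cfg <- fit_cfg %||% list()
      fit_cfg$seed <- fit_cfg$seed %||% seed
      fit_cfg <- do.call(ga_config, fit_cfg)
    }
    to_fit <- topics
    if (!include_chatter) {
      chatter <- spikes$topic[spikes$class == "chatter"]
      excluded <- intersect(topics, chatter)
      to_fit <- setdiff(topics, excluded)
    }
    fits <- purrr::map(setNames(to_fit, to_fit), function(tp) {
      run_stage("fit", tp, {
        s <- moving_average(series[[tp]], min(ma_window, nrow(series[[tp]])))
        fit <- fit_sir(s, fit_cfg)
        over <- dplyr::left_join(fit$trajectory,
                                 dplyr::rename(fit$observed,
                                               observed = "count"),
                                 by = "t")
        readr::write_csv(over,
                         file.path(out_dir, paste0("fit_", slug(tp), ".csv")))
        fit
      })
    })
    if (length(fits)) {
      fit_table <- purrr::map_dfr(fits, function(f) {
        tibble::tibble(mse = f$mse, r_square = f$r_square, S0 = f$S0,
                       alpha = f$params$alpha, beta = f$params$beta,
                       mu = f$params$mu, K = f$params$K, I0 = f$I0,
                       seed = f$seed)
      }, .id = "topic")
      readr::write_csv(fit_table, file.path(out_dir, "fit_table.csv"))
    }
  }

  resolved <- list(
    stages = stages, seed = seed, period = period, ma_window = ma_window,
    include_chatter = include_chatter, topics = topics,
    synth = if (!is.null(config$synth)) unclass_spec(config$synth),
    fit = if (!is.null(fit_cfg)) unclass(fit_cfg)
  )
  jsonlite::write_json(resolved, file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    created = "run manifest",
    seed = seed,
    stages = stages,
    topics = topics,
    chatter_excluded = excluded,
    outputs = sort(list.files(out_dir)),
    versions = list(
      sirtopics = as.character(utils::packageVersion("sirtopics")),
      R = paste(R.version$major, R.version$minor, sep = ".")
    ),
    config = resolved
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(series = series, spikes = spikes, fits = fits,
                 truth = truth, manifest = manifest))
}

run_stage <- function(stage, topic, code) {
  tryCatch(code, error = function(e) {
    abort(sprintf("stage '%s' failed on topic '%s': %s",
                  stage, topic, conditionMessage(e)))
  })
}

slug <- function(x) gsub("[^a-z0-9]+", "-", tolower(x))

unclass_spec <- function(spec) {
  if (inherits(spec, "synthetic_spec")) {
    spec <- unclass(spec)
    spec$params <- unclass(spec$params)
    spec$init <- unclass(spec$init)
  }
  spec
}

read_config_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist.", path))
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
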