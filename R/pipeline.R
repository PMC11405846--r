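#' Analysis pipeline configuration
#'
#' Bundles every tunable parameter of the analysis with the defaults used
#' throughout: 30 ms response windows, 5 ms strength windows, later-touch
#' threshold 2, 5% outlier discard, 4 strength bins, and the session
#' inclusion thresholds (at least 40 Go trials and at least 2
#' touch-responsive units).
#'
#' @param response_window_ms Spike-count window from touch onset, default 30.
#' @param strength_window_ms Curvature averaging window from onset, default 5.
#' @param later_min First touch order counted as "later", default 2.
#' @param adapted_min First order defining the adapted state in the
#'   whisker-specific analysis, default 3.
#' @param asymptote_min Order threshold for asymptotic-state summaries,
#'   default 5 (orders > 4).
#' @param outlier_frac Fraction of strongest touches discarded before tuning
#'   fits, default 0.05.
#' @param n_bins Equipopulated strength bins, default 4.
#' @param min_go_trials Session inclusion: minimum Go trials, default 40.
#' @param min_responsive_units Session inclusion: minimum touch-responsive
#'   units, default 2.
#' @param alpha_level Significance level for unit screening, default 0.05.
#' @param seed Seed recorded in the report provenance block.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(response_window_ms = 30,
                            strength_window_ms = 5,
                            later_min = 2,
                            adapted_min = 3,
                            asymptote_min = 5,
                            outlier_frac = 0.05,
                            n_bins = 4,
                            min_go_trials = 40,
                            min_responsive_units = 2,
                            alpha_level = 0.05,
                            seed = 1L) {
  stopifnot(
    response_window_ms > 0, strength_window_ms > 0,
    outlier_frac > 0, outlier_frac < 1, n_bins >= 2,
    later_min >= 2, adapted_min >= 2
  )
  structure(as.list(environment()), class = "pipeline_config")
}

#' Session inclusion check
#'
#' A session enters the analysis when the mouse performed at least
#' `min_go_trials` Go trials and the recording yielded at least
#' `min_responsive_units` touch-responsive single units.
#'
#' @param trials Trial table.
#' @param screen Output of [screen_units()].
#' @param config A [pipeline_config()].
#' @return A list: `include` (logical), `n_go`, `n_responsive`, `reasons`
#'   (character vector of failed criteria, empty when included).
#' @export
include_session <- function(trials, screen, config = pipeline_config()) {
  n_go <- sum(trials$kind == "Go")
  n_resp <- sum(screen$responsive, na.rm = TRUE)
  reasons <- character()
  if (n_go < config$min_go_trials) reasons <- c(reasons, "min_go_trials")
  if (n_resp < config$min_responsive_units) {
    reasons <- c(reasons, "min_units")
  }
  list(
    include = length(reasons) == 0, n_go = n_go, n_responsive = n_resp,
    reasons = reasons
  )
}

read_session_dir <- function(data_dir) {
  need <- c("trials.csv", "touches.csv")
  for (f in need) {
    if (!file.exists(file.path(data_dir, f))) {
      stop("Input file missing: ", f, call. = FALSE)
    }
  }
  trials <- readr::read_csv(
    file.path(data_dir, "trials.csv"),
    show_col_types = FALSE
  )
  touches <- readr::read_csv(
    file.path(data_dir, "touches.csv"),
    show_col_types = FALSE
  )
  for (col in c("trial_id", "whisker_id", "onset_ms", "offset_ms")) {
    if (!col %in% names(touches)) {
      stop("touches.csv is missing column `", col, "`.", call. = FALSE)
    }
  }
  spikes <- NULL
  counts <- NULL
  sp_path <- file.path(data_dir, "spikes.csv")
  ct_path <- file.path(data_dir, "counts.csv")
  if (file.exists(sp_path)) {
    spikes <- readr::read_csv(sp_path, show_col_types = FALSE)
    if (nrow(spikes) == 0) spikes <- NULL
  }
  if (file.exists(ct_path)) {
    counts <- readr::read_csv(ct_path, show_col_types = FALSE)
  }
  if (is.null(spikes) && is.null(counts)) {
    stop("Need spikes.csv (non-empty) or counts.csv.", call. = FALSE)
  }
  list(trials = trials, touches = touches, spikes = spikes, counts = counts)
}

#' Run the full adaptation analysis on a session directory
#'
#' Loads `trials.csv`, `touches.csv` and `spikes.csv` (or precomputed
#' `counts.csv`) from `data_dir`; assigns touch order; screens units for
#' touch responsiveness; checks session inclusion; and computes touch
#' statistics, per-order normalised attenuation, the ROC discriminability
#' table, first/later tuning curves per unit, the population
#' attenuation decomposition (alpha) and the whisker-specific adaptation
#' table. Reports are written as CSV plus a machine-readable
#' `summary.json` carrying a provenance block (config hash, seed, package
#' version); identical inputs produce identical reports.
#'
#' @param data_dir Directory with the input tables.
#' @param out_dir Report directory (created if needed). `NULL` skips
#'   writing.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every report table and the summary.
#' @export
run_pipeline <- function(data_dir, out_dir = NULL,
                         config = pipeline_config()) {
  inp <- read_session_dir(data_dir)
  touches <- inp$touches
  if (!"order" %in% names(touches)) touches <- order_touches(touches)
  if (!"abs_strength" %in% names(touches) &&
    "strength" %in% names(touches)) {
    touches$abs_strength <- abs(touches$strength)
  }

  aligned <- if (!is.null(inp$counts)) {
    tibble::as_tibble(inp$counts)
  } else {
    touch_aligned_counts(inp$spikes, touches,
      window_ms = config$response_window_ms
    )
  }

  screen <- screen_units(aligned, alpha = config$alpha_level)
  inclusion <- include_session(inp$trials, screen, config)

  stats_tbl <- touch_statistics(touches, inp$trials)
  atten <- attenuation_curve(aligned)

  roc_tbl <- NULL
  if (!is.null(inp$spikes)) {
    roc_tbl <- touch_detection_auc(
      inp$spikes, touches, inp$trials,
      window_ms = config$response_window_ms, later_min = config$later_min
    )
  }

  # per-unit first vs later tuning curves
  tc_rows <- list()
  for (u in unique(aligned$unit_id)) {
    au <- aligned[aligned$unit_id == u, , drop = FALSE]
    first <- au[au$order == 1, , drop = FALSE]
    later <- au[au$order >= config$later_min, , drop = FALSE]
    for (cls in list(list(d = first, lab = "1"),
      list(d = later, lab = paste0("later>=", config$later_min)))) {
      if (nrow(cls$d) >= config$n_bins) {
        tc <- fit_tuning_curve(cls$d,
          order_label = cls$lab,
          n_bins = config$n_bins, outlier_frac = config$outlier_frac
        )
        tc_rows[[length(tc_rows) + 1]] <-
          dplyr::mutate(glance(tc), unit_id = u, .before = 1)
      }
    }
  }
  tuning_tbl <- dplyr::bind_rows(tc_rows)

  pop <- population_response(aligned)
  alpha_res <- attenuation_decomposition(
    pop,
    later_min = config$later_min,
    n_bins = config$n_bins, outlier_frac = config$outlier_frac
  )

  wsa_tbl <- suppressMessages(wsa_analysis(
    aligned,
    adapted_min = config$adapted_min,
    n_bins = config$n_bins, outlier_frac = config$outlier_frac
  ))

  cfg_plain <- unclass(config)
  summary <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("whiskadapt")),
      config = cfg_plain,
      config_hash = rlang::hash(cfg_plain),
      seed = config$seed
    ),
    inclusion = inclusion,
    alpha = glance(alpha_res),
    wsa = list(
      n_units = nrow(wsa_tbl),
      mean_index = if (nrow(wsa_tbl)) mean(wsa_tbl$index_i) else NA,
      frac_positive = if (nrow(wsa_tbl)) mean(wsa_tbl$index_i > 0) else NA
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(stats_tbl$summary, file.path(out_dir, "touch_stats.csv"))
    readr::write_csv(atten, file.path(out_dir, "attenuation_curve.csv"))
    if (!is.null(roc_tbl)) {
      readr::write_csv(roc_tbl, file.path(out_dir, "roc.csv"))
    }
    readr::write_csv(tuning_tbl, file.path(out_dir, "tuning_curves.csv"))
    readr::write_csv(glance(alpha_res), file.path(out_dir, "alpha.csv"))
    readr::write_csv(wsa_tbl, file.path(out_dir, "wsa.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }

  invisible(list(
    inclusion = inclusion, screen = screen, touch_stats = stats_tbl,
    attenuation = atten, roc = roc_tbl, tuning = tuning_tbl,
    alpha = alpha_res, wsa = wsa_tbl, summary = summary
  ))
}
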