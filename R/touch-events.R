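#' Assign within-trial touch order
#'
#' Numbers the touches of each trial 1, 2, 3, ... by ascending onset time,
#' pooling all whiskers: the ordinal number of a touch in its trial is defined
#' irrespective of whisker identity. Simultaneous onsets across whiskers are
#' broken by ascending whisker label and flagged in `order_tied`. Overlapping
#' touches of the *same* whisker are a tracking inconsistency and raise an
#' error.
#'
#' @param touches A data frame of touch events with columns `trial_id`,
#'   `whisker_id`, `onset_ms`, `offset_ms` (ms; `offset_ms > onset_ms`).
#' @return The touches as a tibble, sorted by trial and onset, with integer
#'   `order` and logical `order_tied` columns.
#' @export
order_touches <- function(touches) {
  tt <- tibble::as_tibble(touches)
  if (any(tt$offset_ms <= tt$onset_ms)) {
    stop("Every touch must satisfy offset_ms > onset_ms.", call. = FALSE)
  }
  tt <- dplyr::arrange(tt, .data$trial_id, .data$onset_ms, .data$whisker_id)
  # same-whisker overlap check (closed intervals)
  ov <- dplyr::mutate(
    dplyr::group_by(tt, .data$trial_id, .data$whisker_id),
    .overlap = .data$onset_ms <= dplyr::lag(.data$offset_ms, default = -Inf)
  )
  if (any(ov$.overlap)) {
    bad <- dplyr::filter(dplyr::ungroup(ov), .data$.overlap)
    stop(
      "Overlapping same-whisker touches (tracking inconsistency), e.g. ",
      "trial ", bad$trial_id[1], " whisker ", bad$whisker_id[1],
      " at onset ", bad$onset_ms[1], " ms.",
      call. = FALSE
    )
  }
  out <- dplyr::mutate(
    dplyr::group_by(tt, .data$trial_id),
    order = seq_len(dplyr::n()),
    order_tied = duplicated(.data$onset_ms) |
      duplicated(.data$onset_ms, fromLast = TRUE)
  )
  dplyr::ungroup(out)
}

#' Summary statistics of touch behaviour
#'
#' Per-trial touch counts, inter-touch intervals (between consecutive touch
#' onsets within a trial), touch durations and touch strengths, overall and
#' stratified by trial outcome (hit vs miss), mirroring the behavioural
#' variability summaries of an active-touch session.
#'
#' @param touches A touch table (see [order_touches()]); a `strength` column
#'   is used if present.
#' @param trials A trial table with columns `trial_id`, `kind` (`"Go"` or
#'   `"NoGo"`) and `outcome` (`"hit"`, `"miss"`, `"correct_rejection"`,
#'   `"false_alarm"`).
#' @return A list with tibbles `per_trial` (touch counts), `intervals`
#'   (inter-touch intervals, ms), `durations` (ms), `strengths` (1/mm, if
#'   available) and `summary` (means split by outcome group).
#' @export
touch_statistics <- function(touches, trials) {
  tr <- tibble::as_tibble(trials)
  go <- dplyr::filter(tr, .data$kind == "Go")
  if (nrow(go) == 0) stop("Need at least one Go trial.", call. = FALSE)
  tt <- dplyr::inner_join(
    tibble::as_tibble(touches),
    dplyr::select(go, "trial_id", "outcome"),
    by = "trial_id"
  )
  tt <- dplyr::arrange(tt, .data$trial_id, .data$onset_ms)

  per_trial <- dplyr::left_join(
    dplyr::select(go, "trial_id", "outcome"),
    dplyr::count(tt, .data$trial_id, name = "n_touches"),
    by = "trial_id"
  )
  per_trial$n_touches[is.na(per_trial$n_touches)] <- 0L

  intervals <- dplyr::filter(
    dplyr::mutate(
      dplyr::group_by(tt, .data$trial_id),
      interval_ms = .data$onset_ms - dplyr::lag(.data$onset_ms),
      outcome = .data$outcome
    ),
    !is.na(.data$interval_ms)
  )
  intervals <- dplyr::select(
    dplyr::ungroup(intervals), "trial_id", "outcome", "interval_ms"
  )

  durations <- dplyr::transmute(
    tt,
    trial_id = .data$trial_id, outcome = .data$outcome,
    duration_ms = .data$offset_ms - .data$onset_ms
  )

  strengths <- NULL
  if ("strength" %in% names(tt)) {
    strengths <- dplyr::select(
      tt, "trial_id", "outcome", "strength", dplyr::any_of("abs_strength")
    )
  }

  grp_mean <- function(df, col) {
    dplyr::bind_rows(
      dplyr::summarise(df,
        outcome = "all", mean = mean(.data[[col]]), n = dplyr::n()
      ),
      dplyr::summarise(dplyr::group_by(df, .data$outcome),
        mean = mean(.data[[col]]), n = dplyr::n(), .groups = "drop"
      )
    )
  }
  summary <- dplyr::bind_rows(
    dplyr::mutate(grp_mean(per_trial, "n_touches"),
      statistic = "touches_per_trial"
    ),
    dplyr::mutate(grp_mean(intervals, "interval_ms"),
      statistic = "inter_touch_interval_ms"
    ),
    dplyr::mutate(grp_mean(durations, "duration_ms"),
      statistic = "touch_duration_ms"
    ),
    if (!is.null(strengths)) {
      dplyr::mutate(grp_mean(
        dplyr::mutate(strengths, abs_strength = abs(.data$strength)),
        "abs_strength"
      ), statistic = "abs_strength")
    }
  )
  summary <- dplyr::relocate(summary, "statistic")

  list(
    per_trial = per_trial, intervals = intervals, durations = durations,
    strengths = strengths, summary = summary
  )
}

#' Select trials eligible for whisker-specific adaptation analysis
#'
#' A trial qualifies when (1) at least its first two touches ("adapting")
#' were produced by the same whisker, the adapting whisker `w_adapt`; (2) at
#' least one subsequent touch ("test") was produced by the other whisker,
#' `w_test`; and (3) the test touch does not overlap in time (closed
#' intervals) with any touch of any other whisker. Test touches are by
#' construction 3rd-or-later touches of the trial.
#'
#' @param touches An ordered touch table (see [order_touches()]) from a
#'   two-whisker session.
#' @return A tibble with one row per eligible test touch: `trial_id`,
#'   `w_adapt`, `w_test`, `order`, `onset_ms`, plus `strength`/`abs_strength`
#'   when present. Empty (zero rows) when no trial qualifies.
#' @export
select_wsa_trials <- function(touches) {
  tt <- tibble::as_tibble(touches)
  if (!"order" %in% names(tt)) tt <- order_touches(tt)
  tt <- dplyr::arrange(tt, .data$trial_id, .data$order)

  one_trial <- function(df) {
    if (nrow(df) < 3) {
      return(NULL)
    }
    w_ad <- df$whisker_id[1]
    if (df$whisker_id[2] != w_ad) {
      return(NULL)
    }
    cand <- df[df$order >= 3 & df$whisker_id != w_ad, , drop = FALSE]
    if (nrow(cand) == 0) {
      return(NULL)
    }
    # test touch must not overlap any touch of a different whisker
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      other <- df[df$whisker_id != cand$whisker_id[i], , drop = FALSE]
      !any(cand$onset_ms[i] <= other$offset_ms &
        cand$offset_ms[i] >= other$onset_ms)
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) {
      return(NULL)
    }
    dplyr::mutate(cand, w_adapt = w_ad, w_test = .data$whisker_id)
  }

  out <- dplyr::bind_rows(
    lapply(split(tt, tt$trial_id), one_trial)
  )
  if (nrow(out) == 0) {
    return(tibble::tibble(
      trial_id = character(), w_adapt = character(), w_test = character(),
      order = integer(), onset_ms = numeric()
    ))
  }
  dplyr::relocate(
    dplyr::arrange(out, .data$trial_id, .data$order),
    "trial_id", "w_adapt", "w_test", "order", "onset_ms"
  )
}
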