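#' Count spikes in a half-open window
#'
#' Number of spike times `t` with `start <= t < end`. All response and
#' baseline measures in the pipeline are spike counts in 30 ms non-overlapping
#' windows; the half-open convention makes adjacent windows partition time.
#'
#' @param spike_times Numeric vector of spike times (ms), sorted ascending.
#' @param start,end Window bounds (ms), `start < end`.
#' @return Integer count.
#' @export
count_spikes <- function(spike_times, start, end) {
  if (end <= start) stop("Window must satisfy start < end.", call. = FALSE)
  sum(spike_times >= start & spike_times < end)
}

#' Touch-aligned spike counts for every unit
#'
#' For each unit and each touch, counts spikes in the response window
#' `[onset, onset + window_ms)` and in the matching pre-touch window
#' `[onset - window_ms, onset)`.
#'
#' @param spikes A data frame with columns `unit_id` and `spike_time_ms`
#'   (session-relative ms; trial times are assumed already on a common
#'   session clock, with `trial_id` identifying the trial a spike belongs
#'   to when provided).
#' @param touches A touch table with `trial_id`, `onset_ms` and (if present)
#'   `order`, `whisker_id`, `strength`, `abs_strength` carried through.
#' @param window_ms Response window length, default 30 ms.
#' @return A tibble with one row per unit x touch: touch columns plus
#'   `unit_id`, `count`, `pre_count`.
#' @export
touch_aligned_counts <- function(spikes, touches, window_ms = 30) {
  sp <- tibble::as_tibble(spikes)
  tt <- tibble::as_tibble(touches)
  tt$.touch_id <- seq_len(nrow(tt))
  units <- unique(sp$unit_id)
  by_trial <- "trial_id" %in% names(sp)
  out <- purrr::map(units, function(u) {
    su <- sp[sp$unit_id == u, , drop = FALSE]
    cnt <- numeric(nrow(tt))
    pre <- numeric(nrow(tt))
    for (i in seq_len(nrow(tt))) {
      st <- if (by_trial) {
        su$spike_time_ms[su$trial_id == tt$trial_id[i]]
      } else {
        su$spike_time_ms
      }
      cnt[i] <- sum(st >= tt$onset_ms[i] & st < tt$onset_ms[i] + window_ms)
      pre[i] <- sum(st >= tt$onset_ms[i] - window_ms & st < tt$onset_ms[i])
    }
    dplyr::mutate(tt, unit_id = u, count = cnt, pre_count = pre)
  })
  dplyr::select(dplyr::bind_rows(out), -".touch_id")
}

#' Screen units for touch responsiveness
#'
#' A unit is touch-responsive when its mean firing rate increases shortly
#' after touch onset: the post-touch spike count (30 ms from onset) exceeds
#' the pre-touch count (30 ms before onset) under a paired one-sided Wilcoxon
#' signed-rank test at `alpha`. Spike counts are non-Gaussian, hence the rank
#' test. Units with fewer than `min_touches` touches are flagged
#' undetermined.
#'
#' @param aligned Output of [touch_aligned_counts()].
#' @param alpha Significance level, default 0.05.
#' @param min_touches Minimum touches required for a determination,
#'   default 10.
#' @return A tibble per unit: `unit_id`, `n_touches`, `mean_post`,
#'   `mean_pre`, `effect` (mean post - pre), `p_value`, `responsive`,
#'   `determined`.
#' @export
screen_units <- function(aligned, alpha = 0.05, min_touches = 10) {
  one <- function(df) {
    n <- nrow(df)
    d <- df$count - df$pre_count
    determined <- n >= min_touches
    p <- NA_real_
    if (determined) {
      if (all(d == 0)) {
        p <- 1
      } else {
        p <- suppressWarnings(
          stats::wilcox.test(d, alternative = "greater")$p.value
        )
      }
    }
    tibble::tibble(
      n_touches = n,
      mean_post = mean(df$count), mean_pre = mean(df$pre_count),
      effect = mean(d), p_value = p,
      responsive = determined & !is.na(p) & p < alpha,
      determined = determined
    )
  }
  out <- dplyr::group_modify(
    dplyr::group_by(tibble::as_tibble(aligned), .data$unit_id),
    ~ one(.x)
  )
  dplyr::ungroup(out)
}

#' Event-aligned peri-stimulus time histogram
#'
#' Mean firing rate around a set of alignment events (touch onsets), in
#' spikes/s. Optional boxcar smoothing (e.g. 5 ms) is label-preserving and
#' intended for display only.
#'
#' @param spike_times Numeric vector of spike times (ms).
#' @param events Numeric vector of alignment times (ms); must be non-empty.
#' @param window Two-element numeric, peri-event range in ms relative to the
#'   event, default `c(-30, 60)`.
#' @param bin_ms Bin width, >= 1 ms; default 1.
#' @param smooth_ms Boxcar width in ms (0 = no smoothing).
#' @return A tibble with `time_ms` (bin left edge, event-relative) and `rate`
#'   (spikes/s).
#' @export
psth <- function(spike_times, events, window = c(-30, 60), bin_ms = 1,
                 smooth_ms = 0) {
  if (length(events) == 0) stop("`events` must be non-empty.", call. = FALSE)
  if (bin_ms < 1) stop("`bin_ms` must be >= 1 ms.", call. = FALSE)
  edges <- seq(window[1], window[2], by = bin_ms)
  lefts <- edges[-length(edges)]
  counts <- numeric(length(lefts))
  for (ev in events) {
    rel <- spike_times - ev
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel) > 0) {
      idx <- floor((rel - window[1]) / bin_ms) + 1
      tb <- tabulate(idx, nbins = length(lefts))
      counts <- counts + tb
    }
  }
  rate <- counts / length(events) / (bin_ms / 1000)
  if (smooth_ms > 0) {
    k <- max(1L, round(smooth_ms / bin_ms))
    kern <- rep(1 / k, k)
    rate <- as.numeric(stats::filter(rate, kern, sides = 2))
    # boxcar edges: fall back to unsmoothed values where the kernel overhangs
    na <- is.na(rate)
    rate[na] <- (counts / length(events) / (bin_ms / 1000))[na]
  }
  tibble::tibble(time_ms = lefts, rate = rate)
}

#' First-crossing response latency from a 1 ms PSTH
#'
#' Latency is the first time in `(0, max_ms]` after touch onset at which the
#' 1 ms PSTH exceeds the baseline mean + 2 SD, where baseline is the 30 ms
#' pre-touch period of the same PSTH. Returns `NA` when the threshold is
#' never exceeded. This crossing rule is the least-constrained convention in
#' the pipeline: a reasonable default, not a canonical definition.
#'
#' @param spike_times Numeric vector of spike times (ms).
#' @param events Touch-onset times (ms).
#' @param max_ms Latest latency considered, default 30 ms.
#' @param baseline_ms Baseline period before onset, default 30 ms.
#' @return A list with `latency_ms` (or `NA`), `threshold`, `baseline_mean`,
#'   `baseline_sd`.
#' @export
response_latency <- function(spike_times, events, max_ms = 30,
                             baseline_ms = 30) {
  h <- psth(spike_times, events,
    window = c(-baseline_ms, max_ms), bin_ms = 1
  )
  base <- h$rate[h$time_ms < 0]
  mu <- mean(base)
  sd <- stats::sd(base)
  thr <- mu + 2 * sd
  post <- h[h$time_ms >= 0, ]
  hit <- which(post$rate > thr)
  lat <- if (length(hit) == 0) NA_real_ else post$time_ms[hit[1]]
  list(
    latency_ms = lat, threshold = thr, baseline_mean = mu, baseline_sd = sd
  )
}

#' Area under the ROC curve for touch detection
#'
#' Discriminability of touch-evoked spike counts ("signal") from ongoing
#' activity ("noise"), as the area under the ROC curve traced by sweeping a
#' count threshold. Computed exactly as the rank statistic
#' \eqn{P(s > n) + \frac{1}{2} P(s = n)} over all signal/noise pairs;
#' identical count distributions give chance performance, AUC = 0.5.
#'
#' @param signal_counts,noise_counts Non-empty numeric vectors of spike
#'   counts.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(signal_counts, noise_counts) {
  if (length(signal_counts) == 0 || length(noise_counts) == 0) {
    stop("Both count vectors must be non-empty.", call. = FALSE)
  }
  ns <- length(signal_counts)
  nn <- length(noise_counts)
  r <- rank(c(signal_counts, noise_counts), ties.method = "average")
  (sum(r[seq_len(ns)]) - ns * (ns + 1) / 2) / (ns * nn)
}

#' Deterministic noise windows for ROC analysis
#'
#' Ongoing-activity ("noise") windows of length `window_ms`, non-overlapping
#' with each other and with every response window `[onset, onset +
#' window_ms)`. For first touches, windows tile the interval from trial start
#' to the first touch onset; for later touches they tile inter-touch onset
#' intervals of at least `window_ms` + response window. All available windows
#' are used, deterministically.
#'
#' @param touches Ordered touch table (columns `trial_id`, `onset_ms`,
#'   `order`).
#' @param trials Trial table with `trial_id` and `pole_up_ms` (trial start of
#'   the in-reach period).
#' @param window_ms Window length, default 30 ms.
#' @return A tibble with `trial_id`, `start_ms`, `class` (`"first"` or
#'   `"later"`).
#' @export
noise_windows <- function(touches, trials, window_ms = 30) {
  tt <- dplyr::arrange(
    tibble::as_tibble(touches), .data$trial_id, .data$onset_ms
  )
  tr <- tibble::as_tibble(trials)
  out <- lapply(split(tt, tt$trial_id), function(df) {
    tid <- df$trial_id[1]
    t0 <- tr$pole_up_ms[match(tid, tr$trial_id)]
    res <- list()
    # tile [trial start, first onset)
    first_on <- df$onset_ms[1]
    n1 <- floor((first_on - t0) / window_ms)
    if (n1 > 0) {
      res[[1]] <- tibble::tibble(
        trial_id = tid,
        start_ms = t0 + (seq_len(n1) - 1) * window_ms,
        class = "first"
      )
    }
    # gaps between a response window's end and the next onset
    if (nrow(df) > 1) {
      gap_start <- df$onset_ms[-nrow(df)] + window_ms
      gap_end <- df$onset_ms[-1]
      for (g in seq_along(gap_start)) {
        k <- floor((gap_end[g] - gap_start[g]) / window_ms)
        if (k > 0) {
          res[[length(res) + 1]] <- tibble::tibble(
            trial_id = tid,
            start_ms = gap_start[g] + (seq_len(k) - 1) * window_ms,
            class = "later"
          )
        }
      }
    }
    dplyr::bind_rows(res)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      trial_id = tt$trial_id[0], start_ms = numeric(), class = character()
    )
  }
  out
}

#' Touch-detection discriminability table
#'
#' Per-unit AUC of touch responses against ongoing activity, split first vs
#' later touches and hit vs miss trials. First-touch responses are compared
#' with pre-first-touch noise windows; later-touch responses with
#' inter-touch noise windows.
#'
#' @param spikes Spike table (`unit_id`, `trial_id`, `spike_time_ms`).
#' @param touches Ordered touch table.
#' @param trials Trial table with `outcome` and `pole_up_ms`.
#' @param window_ms Count window, default 30 ms.
#' @param later_min First order counted as "later", default 2.
#' @return A tibble `unit_id`, `touch_class`, `outcome`, `auc`, `n_signal`,
#'   `n_noise`.
#' @export
touch_detection_auc <- function(spikes, touches, trials, window_ms = 30,
                                later_min = 2) {
  tt <- tibble::as_tibble(touches)
  if (!"order" %in% names(tt)) tt <- order_touches(tt)
  tr <- tibble::as_tibble(trials)
  nw <- noise_windows(tt, tr, window_ms = window_ms)
  tt <- dplyr::mutate(
    dplyr::left_join(tt, dplyr::select(tr, "trial_id", "outcome"),
      by = "trial_id"
    ),
    touch_class = ifelse(.data$order >= later_min, "later", "first")
  )
  nw <- dplyr::left_join(nw, dplyr::select(tr, "trial_id", "outcome"),
    by = "trial_id"
  )
  sp <- tibble::as_tibble(spikes)
  units <- unique(sp$unit_id)
  grid <- tidyr::expand_grid(
    unit_id = units,
    touch_class = c("first", "later"),
    outcome = intersect(c("hit", "miss"), unique(tt$outcome))
  )
  count_in <- function(su, tid, start) {
    st <- su$spike_time_ms[su$trial_id == tid]
    sum(st >= start & st < start + window_ms)
  }
  res <- purrr::pmap(grid, function(unit_id, touch_class, outcome) {
    su <- sp[sp$unit_id == unit_id, , drop = FALSE]
    sig_tt <- tt[tt$touch_class == touch_class & tt$outcome == outcome, ]
    noi <- nw[nw$class == touch_class & nw$outcome == outcome, ]
    if (nrow(sig_tt) == 0 || nrow(noi) == 0) {
      return(tibble::tibble(auc = NA_real_, n_signal = nrow(sig_tt),
        n_noise = nrow(noi)
      ))
    }
    s <- mapply(count_in, tid = sig_tt$trial_id, start = sig_tt$onset_ms,
      MoreArgs = list(su = su)
    )
    n <- mapply(count_in, tid = noi$trial_id, start = noi$start_ms,
      MoreArgs = list(su = su)
    )
    tibble::tibble(
      auc = roc_auc(s, n), n_signal = length(s), n_noise = length(n)
    )
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}

#' Summed population response per touch
#'
#' The summed activity of a simultaneously recorded population: for each
#' touch, the sum over units of the 30 ms post-onset spike counts. Used for
#' robustness in the attenuation decomposition.
#'
#' @param aligned Output of [touch_aligned_counts()] for all units of one
#'   session.
#' @return A tibble with one row per touch: the touch columns plus
#'   `pop_count` and `n_units`.
#' @export
population_response <- function(aligned) {
  al <- tibble::as_tibble(aligned)
  if (nrow(al) == 0 || length(unique(al$unit_id)) == 0) {
    stop("Empty population.", call. = FALSE)
  }
  keys <- intersect(
    c(
      "trial_id", "whisker_id", "onset_ms", "offset_ms", "order",
      "order_tied", "strength", "abs_strength"
    ),
    names(al)
  )
  out <- dplyr::summarise(
    dplyr::group_by(al, dplyr::across(dplyr::all_of(keys))),
    pop_count = sum(.data$count),
    n_units = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$trial_id, .data$onset_ms)
}

#' Normalised response attenuation curve
#'
#' Per unit, the mean spike count at each touch order divided by the mean
#' count at order 1, describing how responses attenuate over a touch
#' sequence.
#'
#' @param aligned Output of [touch_aligned_counts()] with an `order` column.
#' @param max_order Largest order reported, default 8.
#' @return A tibble `unit_id`, `order`, `mean_count`, `norm_response`, `n`.
#' @export
attenuation_curve <- function(aligned, max_order = 8) {
  al <- dplyr::filter(tibble::as_tibble(aligned), .data$order <= max_order)
  per <- dplyr::summarise(
    dplyr::group_by(al, .data$unit_id, .data$order),
    mean_count = mean(.data$count), n = dplyr::n(), .groups = "drop_last"
  )
  per <- dplyr::mutate(
    per,
    norm_response = .data$mean_count / .data$mean_count[.data$order == 1][1]
  )
  dplyr::ungroup(per)
}
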