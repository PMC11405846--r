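#' Configuration for a synthetic active-touch session
#'
#' Defines the generative model used to validate the pipeline end-to-end:
#' Go/NoGo trials with variable touch counts (more touches on hits than on
#' misses), log-normal inter-touch intervals and touch strengths, a
#' multiplicative per-order decay of touch strength (motor adaptation), and
#' units whose spike counts are linearly tuned to absolute touch strength
#' with order-dependent intercept and slope (sensory adaptation). Counts are
#' drawn Poisson around the linear expectation
#' `max(0, slope_k * |dk| + intercept_k) + baseline` (or equal the
#' expectation exactly in noiseless mode).
#'
#' Defaults emulate the behavioural statistics of a head-fixed pole-detection
#' session: ~10.5 touches per hit trial vs ~5 per miss (negative binomial),
#' inter-touch intervals mostly under ~100 ms (log-normal, capped at
#' `iti_max_ms`), touch strengths of order 0.01-0.1 /mm, and a later/first
#' tuning intercept ratio of 0.32.
#'
#' @param n_trials Number of trials.
#' @param p_go Probability a trial is Go.
#' @param hit_rate Probability a Go trial is a hit.
#' @param touches_mean_hit,touches_sd_hit Mean/SD of touches per hit trial
#'   (negative binomial, truncated at >= 1).
#' @param touches_mean_miss,touches_sd_miss Same for miss trials.
#' @param iti_meanlog,iti_sdlog Log-normal inter-touch onset interval (ms).
#' @param iti_max_ms Upper cap on intervals (ms).
#' @param duration_meanlog,duration_sdlog Log-normal touch duration (ms).
#' @param strength_meanlog,strength_sdlog Log-normal absolute touch strength
#'   (1/mm) before motor decay.
#' @param p_positive Probability a touch's signed strength is positive.
#' @param motor_decay Multiplicative strength factor per touch order:
#'   expected strength at order k is scaled by `motor_decay^(k-1)`; 1 = no
#'   motor adaptation.
#' @param n_units Number of simultaneously recorded units.
#' @param slope_mean,slope_sd Per-unit baseline tuning slope (counts per
#'   (1/mm)); unit slopes are drawn once per session.
#' @param intercept_mean,intercept_sd Per-unit tuning intercept (counts per
#'   30 ms window).
#' @param intercept_ratio Sensory-adaptation intercept multiplier applied
#'   for touch orders >= `sa_onset_order`; 1 = no sensory adaptation.
#' @param slope_ratio Same for the slope.
#' @param sa_onset_order First adapted order, default 2 (first touch is the
#'   unadapted state).
#' @param whisker_specific If `TRUE` the adaptation schedule follows each
#'   whisker's own touch count; if `FALSE` it follows the pooled touch order.
#' @param two_whiskers Generate touches from two whiskers (`"C1"`, `"C2"`).
#' @param p_dominant Probability each touch is made by the trial's dominant
#'   whisker (two-whisker sessions).
#' @param noise `"poisson"` or `"none"` (counts equal their expectation;
#'   used for exact limit-case checks).
#' @param baseline_rate Baseline firing rate (spikes/s) added everywhere.
#' @param rest_kappa Resting base curvature (1/mm) used when rendering
#'   Bezier frames.
#' @param pole_up_ms,pole_down_ms In-reach period within each trial (ms).
#' @param seed Mandatory integer seed.
#' @return A validated `session_config` list.
#' @export
session_config <- function(n_trials = 100,
                           p_go = 0.5,
                           hit_rate = 0.81,
                           touches_mean_hit = 10.5, touches_sd_hit = 5.7,
                           touches_mean_miss = 5, touches_sd_miss = 7.7,
                           iti_meanlog = log(60), iti_sdlog = 0.4,
                           iti_max_ms = 200,
                           duration_meanlog = log(35), duration_sdlog = 0.5,
                           strength_meanlog = log(0.03),
                           strength_sdlog = 0.5,
                           p_positive = 0.8,
                           motor_decay = 0.85,
                           n_units = 8,
                           slope_mean = 100, slope_sd = 20,
                           intercept_mean = 1.5, intercept_sd = 0.4,
                           intercept_ratio = 0.32,
                           slope_ratio = 1,
                           sa_onset_order = 2,
                           whisker_specific = FALSE,
                           two_whiskers = TRUE,
                           p_dominant = 0.8,
                           noise = c("poisson", "none"),
                           baseline_rate = 2,
                           rest_kappa = 0.05,
                           pole_up_ms = 100, pole_down_ms = 1100,
                           seed = NULL) {
  noise <- match.arg(noise)
  if (is.null(seed)) stop("`seed` is mandatory.", call. = FALSE)
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(
      n_trials >= 1, p_go > 0, p_go <= 1, hit_rate >= 0, hit_rate <= 1,
      touches_mean_hit > 0, touches_mean_miss > 0,
      motor_decay > 0, motor_decay <= 1,
      intercept_ratio > 0, intercept_ratio <= 1,
      slope_ratio > 0, slope_ratio <= 1,
      sa_onset_order >= 2, n_units >= 1,
      baseline_rate >= 0, rest_kappa >= 0,
      pole_down_ms > pole_up_ms
    )
  })
  if (cfg$touches_sd_hit^2 <= cfg$touches_mean_hit ||
    cfg$touches_sd_miss^2 <= cfg$touches_mean_miss) {
    stop("Touch-count SDs must exceed sqrt(mean) (negative binomial).",
      call. = FALSE
    )
  }
  structure(cfg, class = "session_config")
}

nbinom_size <- function(mu, sd) mu^2 / (sd^2 - mu)

# tuning multipliers at touch order k (step schedule)
sa_multipliers <- function(cfg, k) {
  adapted <- k >= cfg$sa_onset_order
  list(
    slope = ifelse(adapted, cfg$slope_ratio, 1),
    intercept = ifelse(adapted, cfg$intercept_ratio, 1)
  )
}

#' Generate a synthetic session
#'
#' Draws a full session — trial table, touch table with signed strengths and
#' pooled touch order, per-unit spike counts aligned to every touch (and
#' spike times under Poisson noise), and the ground-truth record of the
#' injected schedules — deterministically from `config$seed`.
#'
#' @param config A [session_config()].
#' @return A list of class `synthetic_session`: `trials`, `touches`,
#'   `counts` (unit x touch aligned counts, the shape of
#'   [touch_aligned_counts()] output), `spikes` (empty in noiseless mode),
#'   `units` (true per-unit tuning), `ground_truth` (config, per-order
#'   schedules, implied alpha), and `config`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  cfg <- config
  set.seed(cfg$seed)

  # ---- trials ----
  kind <- ifelse(stats::runif(cfg$n_trials) < cfg$p_go, "Go", "NoGo")
  outcome <- ifelse(
    kind == "Go",
    ifelse(stats::runif(cfg$n_trials) < cfg$hit_rate, "hit", "miss"),
    ifelse(stats::runif(cfg$n_trials) < 0.9, "correct_rejection",
      "false_alarm"
    )
  )
  trials <- tibble::tibble(
    trial_id = seq_len(cfg$n_trials),
    kind = kind, outcome = outcome,
    pole_up_ms = cfg$pole_up_ms, pole_down_ms = cfg$pole_down_ms
  )

  # ---- unit tuning (drawn once per session) ----
  units <- tibble::tibble(
    unit_id = paste0("u", seq_len(cfg$n_units)),
    slope = pmax(1, stats::rnorm(cfg$n_units, cfg$slope_mean, cfg$slope_sd)),
    intercept = pmax(
      0.1, stats::rnorm(cfg$n_units, cfg$intercept_mean, cfg$intercept_sd)
    )
  )

  # ---- touches ----
  whiskers <- if (cfg$two_whiskers) c("C1", "C2") else "C1"
  touch_list <- vector("list", cfg$n_trials)
  for (ti in seq_len(cfg$n_trials)) {
    if (kind[ti] != "Go") next
    mu <- if (outcome[ti] == "hit") cfg$touches_mean_hit else
      cfg$touches_mean_miss
    sd <- if (outcome[ti] == "hit") cfg$touches_sd_hit else
      cfg$touches_sd_miss
    n_t <- max(1L, stats::rnbinom(1, size = nbinom_size(mu, sd), mu = mu))
    iti <- pmin(
      cfg$iti_max_ms,
      stats::rlnorm(n_t, cfg$iti_meanlog, cfg$iti_sdlog)
    )
    onsets <- cfg$pole_up_ms + 20 + cumsum(c(0, iti[-1]))
    onsets <- round(onsets)
    keep <- onsets + 35 < cfg$pole_down_ms
    onsets <- onsets[keep]
    n_t <- length(onsets)
    if (n_t == 0) next
    dur <- round(stats::rlnorm(n_t, cfg$duration_meanlog, cfg$duration_sdlog))
    dur <- pmax(5, dur)
    if (n_t > 1) { # same-whisker touches must not overlap
      gap <- diff(onsets)
      dur[-n_t] <- pmin(dur[-n_t], gap - 1)
    }
    dur[n_t] <- min(dur[n_t], cfg$pole_down_ms - onsets[n_t] - 1)
    dom <- sample(whiskers, 1)
    wid <- if (cfg$two_whiskers) {
      ifelse(stats::runif(n_t) < cfg$p_dominant, dom, setdiff(whiskers, dom))
    } else {
      rep("C1", n_t)
    }
    # first two touches from the dominant whisker (stabilises WSA eligibility)
    if (cfg$two_whiskers && n_t >= 2) wid[1:2] <- dom
    k <- seq_len(n_t)
    raw <- stats::rlnorm(n_t, cfg$strength_meanlog, cfg$strength_sdlog)
    mag <- raw * cfg$motor_decay^(k - 1)
    sgn <- ifelse(stats::runif(n_t) < cfg$p_positive, 1, -1)
    touch_list[[ti]] <- tibble::tibble(
      trial_id = ti, whisker_id = wid,
      onset_ms = onsets, offset_ms = onsets + dur,
      strength = sgn * mag, abs_strength = mag
    )
  }
  touches <- dplyr::bind_rows(touch_list)
  if (nrow(touches) == 0) stop("Config produced no touches.", call. = FALSE)
  touches <- order_touches(touches)
  touches <- dplyr::mutate(
    dplyr::group_by(touches, .data$trial_id, .data$whisker_id),
    whisker_order = seq_len(dplyr::n())
  )
  touches <- dplyr::ungroup(touches)

  # ---- spike counts ----
  k_sched <- if (cfg$whisker_specific) {
    touches$whisker_order
  } else {
    touches$order
  }
  mult <- sa_multipliers(cfg, k_sched)
  base_count <- cfg$baseline_rate * 30 / 1000
  counts_list <- vector("list", cfg$n_units)
  for (ui in seq_len(cfg$n_units)) {
    lam <- pmax(
      0,
      units$slope[ui] * mult$slope * touches$abs_strength +
        units$intercept[ui] * mult$intercept
    ) + base_count
    cnt <- if (cfg$noise == "poisson") stats::rpois(nrow(touches), lam) else
      lam
    pre <- if (cfg$noise == "poisson") {
      stats::rpois(nrow(touches), base_count)
    } else {
      rep(base_count, nrow(touches))
    }
    counts_list[[ui]] <- dplyr::mutate(
      touches,
      unit_id = units$unit_id[ui], count = cnt, pre_count = pre,
      expected_count = lam
    )
  }
  counts <- dplyr::bind_rows(counts_list)

  # ---- spike times (Poisson mode only) ----
  spikes <- tibble::tibble(
    unit_id = character(), trial_id = integer(), spike_time_ms = numeric()
  )
  if (cfg$noise == "poisson") {
    idx <- rep(seq_len(nrow(counts)), counts$count)
    ev <- tibble::tibble(
      unit_id = counts$unit_id[idx],
      trial_id = counts$trial_id[idx],
      spike_time_ms = counts$onset_ms[idx] +
        stats::runif(length(idx), 0, 30)
    )
    trial_len <- cfg$pole_down_ms + 200
    grid <- tidyr::expand_grid(
      unit_id = units$unit_id, trial_id = trials$trial_id
    )
    n_base <- stats::rpois(
      nrow(grid), cfg$baseline_rate * trial_len / 1000
    )
    gidx <- rep(seq_len(nrow(grid)), n_base)
    bs <- tibble::tibble(
      unit_id = grid$unit_id[gidx],
      trial_id = grid$trial_id[gidx],
      spike_time_ms = stats::runif(length(gidx), 0, trial_len)
    )
    spikes <- dplyr::arrange(
      dplyr::bind_rows(ev, bs),
      .data$unit_id, .data$trial_id, .data$spike_time_ms
    )
  }

  gt <- list(
    config = unclass(cfg),
    units = units,
    sa_onset_order = cfg$sa_onset_order,
    intercept_ratio = cfg$intercept_ratio,
    slope_ratio = cfg$slope_ratio,
    motor_decay = cfg$motor_decay,
    whisker_specific = cfg$whisker_specific,
    implied_alpha = implied_alpha(cfg)
  )

  structure(
    list(
      trials = trials, touches = touches, counts = counts,
      spikes = spikes, units = units, ground_truth = gt, config = cfg
    ),
    class = "synthetic_session"
  )
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf(
    "<synthetic_session> %d trials, %d touches, %d units, noise = %s\n",
    nrow(x$trials), nrow(x$touches), nrow(x$units), x$config$noise
  ))
  invisible(x)
}

#' Render Bezier frames for a synthetic session
#'
#' Produces a 1 kHz per-whisker frame table whose closed-form base curvature
#' reproduces each touch's target strength: during the 5 ms strength window
#' of a touch the base curvature equals `rest_kappa + strength` (to machine
#' precision), during the rest of a touch it relaxes to the same value, and
#' contact-free frames carry the resting curvature with smooth sinusoidal
#' base motion (whisking). Control points are laid out as
#' `P0 = B`, `P1 = B + (d, 0, 0)`, `P2 = B + (2d, h, 0)` with
#' `h = 2 d^2 kappa`, for which the base curvature is exactly
#' `h / (2 d^2)`.
#'
#' @param session A [generate_session()] result.
#' @param trial_ids Trials to render (default: all Go trials). Rendering is
#'   1 row per whisker per ms, so restrict to a few trials for tests.
#' @param d Control-point spacing along the whisker (mm), default 5.
#' @return A frames tibble (`time_ms`, `trial_id`, `whisker_id`,
#'   `p0x ... p2z`).
#' @export
generate_bezier_frames <- function(session, trial_ids = NULL, d = 5) {
  stopifnot(inherits(session, "synthetic_session"))
  cfg <- session$config
  if (is.null(trial_ids)) {
    trial_ids <- session$trials$trial_id[session$trials$kind == "Go"]
  }
  whiskers <- unique(session$touches$whisker_id)
  t_end <- cfg$pole_down_ms + 50
  out <- list()
  for (tid in trial_ids) {
    tt <- session$touches[session$touches$trial_id == tid, , drop = FALSE]
    for (w in whiskers) {
      tw <- tt[tt$whisker_id == w, , drop = FALSE]
      times <- 0:t_end
      kappa <- rep(cfg$rest_kappa, length(times))
      for (i in seq_len(nrow(tw))) {
        idx <- times >= tw$onset_ms[i] & times <= tw$offset_ms[i]
        kappa[idx] <- cfg$rest_kappa + tw$strength[i]
      }
      if (any(kappa < 0)) {
        stop("Unreachable curvature target: strength below -rest_kappa.",
          call. = FALSE
        )
      }
      # whisking: smooth sinusoidal base motion, ~12 Hz, 1 mm amplitude
      bx <- sin(2 * pi * 12 * times / 1000 + match(w, whiskers))
      h <- 2 * d^2 * kappa
      out[[length(out) + 1]] <- tibble::tibble(
        time_ms = times, trial_id = tid, whisker_id = w,
        p0x = bx, p0y = 0, p0z = 0,
        p1x = bx + d, p1y = 0, p1z = 0,
        p2x = bx + 2 * d, p2y = h, p2z = 0
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Model-implied alpha under the generative model
#'
#' Closed-form value of the attenuation-decomposition index for a
#' configuration, computed from the generator's noiseless expectations: mean
#' absolute strength at order k is `E|dk| * motor_decay^(k-1)`, expected
#' counts follow the per-order linear tuning, order weights are the
#' probabilities `P(N_touch >= k)` under the hit/miss touch-count mixture,
#' and the pooled later-touch tuning line is the weighted least-squares fit
#' through the per-order expectation points. With identical tuning across
#' orders this pooled line coincides with the common line, so alpha = 0;
#' with stationary strengths the pooled line is degenerate and its constant
#' prediction equals the later-touch expectation, so alpha = 1.
#'
#' @param config A [session_config()].
#' @param max_order Truncation for the order distribution, default 30.
#' @return Alpha implied by the model; `NA` when the model has no
#'   first-to-later attenuation.
#' @export
implied_alpha <- function(config, max_order = 30) {
  cfg <- config
  p_hit <- cfg$hit_rate
  size_h <- nbinom_size(cfg$touches_mean_hit, cfg$touches_sd_hit)
  size_m <- nbinom_size(cfg$touches_mean_miss, cfg$touches_sd_miss)
  k <- seq_len(max_order)
  # P(N >= k) under the hit/miss mixture (N truncated at >= 1)
  surv <- function(size, mu) {
    p0 <- stats::dnbinom(0, size = size, mu = mu)
    (1 - stats::pnbinom(k - 1, size = size, mu = mu)) / (1 - p0)
  }
  w <- p_hit * surv(size_h, cfg$touches_mean_hit) +
    (1 - p_hit) * surv(size_m, cfg$touches_mean_miss)
  mu_s <- exp(cfg$strength_meanlog + cfg$strength_sdlog^2 / 2)
  s_k <- mu_s * cfg$motor_decay^(k - 1)
  slope0 <- cfg$slope_mean
  int0 <- cfg$intercept_mean
  base <- cfg$baseline_rate * 30 / 1000
  m <- sa_multipliers(cfg, k)
  f_k <- pmax(0, slope0 * m$slope * s_k + int0 * m$intercept) + base

  fr1 <- f_k[1]
  lk <- k >= 2
  wl <- w[lk] / sum(w[lk])
  fr_later <- sum(wl * f_k[lk])
  # pooled later tuning: weighted LS through the per-order expectation points
  xs <- s_k[lk]
  ys <- f_k[lk]
  if (max(xs) - min(xs) < 1e-12) {
    fr1_pred <- fr_later # degenerate abscissa: constant prediction
  } else {
    xbar <- sum(wl * xs)
    ybar <- sum(wl * ys)
    b <- sum(wl * (xs - xbar) * (ys - ybar)) / sum(wl * (xs - xbar)^2)
    a0 <- ybar - b * xbar
    fr1_pred <- max(0, b * s_k[1] + a0)
  }
  if (abs(fr1 - fr_later) < 1e-12) {
    return(NA_real_)
  }
  (fr1 - fr1_pred) / (fr1 - fr_later)
}

#' Write a synthetic session to plain-text files
#'
#' Writes `trials.csv`, `touches.csv`, `spikes.csv`, `ground_truth.json`
#' and, optionally, `frames.csv` into a directory, in the schemas consumed
#' by [run_pipeline()].
#'
#' @param session A [generate_session()] result.
#' @param dir Output directory (created if needed).
#' @param frames Optional frames table from [generate_bezier_frames()].
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, frames = NULL) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(session$trials, file.path(dir, "trials.csv"))
  readr::write_csv(session$touches, file.path(dir, "touches.csv"))
  readr::write_csv(session$spikes, file.path(dir, "spikes.csv"))
  readr::write_csv(session$counts, file.path(dir, "counts.csv"))
  gt <- session$ground_truth
  gt$units <- as.data.frame(gt$units)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(frames)) {
    readr::write_csv(frames, file.path(dir, "frames.csv"))
  }
  invisible(dir)
}
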