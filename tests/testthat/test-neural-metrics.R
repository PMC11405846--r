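test_that("spike counting uses half-open windows that partition time", {
  sp <- c(5, 10, 35)
  expect_equal(count_spikes(sp, 0, 30), 2)
  expect_equal(count_spikes(sp, 30, 60), 1)
  expect_equal(count_spikes(c(30), 0, 30), 0) # boundary spike excluded
  expect_error(count_spikes(sp, 30, 30), "start < end")

  # partition property: counts over sub-windows sum to the whole
  set.seed(3)
  spikes <- sort(stats::runif(200, 0, 120))
  whole <- count_spikes(spikes, 0, 120)
  parts <- sum(
    count_spikes(spikes, 0, 30), count_spikes(spikes, 30, 60),
    count_spikes(spikes, 60, 90), count_spikes(spikes, 90, 120)
  )
  expect_identical(parts, whole)
})

test_that("touch-aligned counts pair each touch with its pre-window", {
  touches <- tibble::tibble(
    trial_id = c(1, 1), whisker_id = "C1",
    onset_ms = c(100, 200), offset_ms = c(140, 240), order = 1:2
  )
  spikes <- tibble::tibble(
    unit_id = "u1", trial_id = 1,
    spike_time_ms = c(80, 105, 110, 129.5, 130, 195, 205)
  )
  al <- touch_aligned_counts(spikes, touches)
  expect_equal(al$count, c(3, 1))
  expect_equal(al$pre_count, c(1, 1))
})

test_that("responsiveness screening uses a paired one-sided rank test", {
  touches <- tibble::tibble(
    trial_id = 1, whisker_id = "C1",
    onset_ms = seq(100, 1000, by = 100), offset_ms = seq(140, 1040, 100),
    order = 1:10
  )
  mk_aligned <- function(post, pre) {
    tibble::tibble(
      trial_id = 1, onset_ms = touches$onset_ms, unit_id = "u1",
      count = post, pre_count = pre
    )
  }
  # clear response: post all 5, pre all 0
  s1 <- screen_units(mk_aligned(rep(5, 10), rep(0, 10)))
  expect_true(s1$responsive)
  # identical distributions: not responsive
  s2 <- screen_units(mk_aligned(rep(2, 10), rep(2, 10)))
  expect_false(s2$responsive)
  expect_equal(s2$p_value, 1)
  # post mean 2.0 vs pre 1.9 with high variance: not significant
  post <- c(0, 4, 1, 3, 0, 4, 2, 2, 0, 4)
  pre <- c(4, 0, 3, 1, 4, 0, 2, 2, 3, 0)
  s3 <- screen_units(mk_aligned(post, pre))
  expect_false(s3$responsive)
  expect_gt(s3$p_value, 0.05)
  # fewer than 10 touches: undetermined
  s4 <- screen_units(mk_aligned(rep(5, 10), rep(0, 10))[1:5, ])
  expect_false(s4$determined)
  expect_false(s4$responsive)
})

test_that("PSTH converts to spikes/s and averages over events", {
  h <- psth(c(1.5, 2.5), events = 0, window = c(-5, 5), bin_ms = 1)
  expect_equal(h$rate[h$time_ms == 1], 1000)
  expect_equal(h$rate[h$time_ms == 2], 1000)
  expect_equal(sum(h$rate), 2000)
  # no spikes: all-zero
  h0 <- psth(numeric(0), events = c(0, 50))
  expect_true(all(h0$rate == 0))
  # two events with identical offset patterns = one event
  h1 <- psth(c(11, 12), events = 10, window = c(0, 5))
  h2 <- psth(c(11, 12, 111, 112), events = c(10, 110), window = c(0, 5))
  expect_equal(h2$rate, h1$rate)
  expect_error(psth(1:3, events = numeric(0)), "non-empty")
  # boxcar smoothing preserves the time labels
  hs <- psth(c(11, 12), events = 10, window = c(0, 10), smooth_ms = 5)
  expect_equal(hs$time_ms, 0:9)
})

test_that("latency is the first PSTH crossing of baseline + 2 SD", {
  # zero baseline, response stepping up at +8 ms on every touch
  events <- seq(100, 2000, by = 100)
  spikes <- sort(c(outer(events, c(8.2, 8.7, 9.5), `+`)))
  lat <- response_latency(spikes, events)
  expect_equal(lat$latency_ms, 8)
  # flat spike train: never crosses
  flat <- response_latency(seq(0, 2000, by = 7.3), events)
  expect_true(is.na(flat$latency_ms))
  # threshold-crossing rule agrees with a direct reimplementation
  set.seed(9)
  spikes2 <- sort(c(
    stats::runif(300, 0, 2100), # ongoing activity
    outer(events, 12 + stats::rexp(5, 1 / 3), `+`) # touch response
  ))
  lat2 <- response_latency(spikes2, events)
  h <- psth(spikes2, events, window = c(-30, 30), bin_ms = 1)
  base <- h$rate[h$time_ms < 0]
  thr <- mean(base) + 2 * stats::sd(base)
  post <- h[h$time_ms >= 0, ]
  expect_equal(lat2$latency_ms, post$time_ms[which(post$rate > thr)[1]])
  expect_false(is.na(lat2$latency_ms))
})

test_that("ROC AUC is the exact rank statistic", {
  expect_identical(roc_auc(c(1, 2, 2, 5), c(1, 2, 2, 5)), 0.5)
  expect_identical(roc_auc(c(2, 3), c(0, 1)), 1)
  # exhaustive pair counting over 4 pairs: (0>1)=0, (0=1)x0, (2>1)x2 -> 0.5
  expect_identical(roc_auc(c(0, 2), c(1, 1)), 0.5)
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("AUC properties: complement, monotone invariance, oracle", {
  set.seed(5)
  for (i in 1:20) {
    a <- stats::rpois(30, 3)
    b <- stats::rpois(25, 2)
    auc <- roc_auc(a, b)
    expect_equal(auc + roc_auc(b, a), 1)
    expect_equal(roc_auc(exp(a), exp(b)), auc) # strictly monotone transform
  }
  skip_if_not_installed("pROC")
  for (i in 1:10) {
    a <- stats::rpois(40, 4)
    b <- stats::rpois(40, 2)
    ref <- suppressMessages(pROC::auc(
      response = rep(c(1, 0), c(40, 40)), predictor = c(a, b),
      direction = "<"
    ))
    expect_equal(roc_auc(a, b), as.numeric(ref))
  }
})

test_that("noise windows tile pre-touch time and avoid response windows", {
  touches <- order_touches(tibble::tibble(
    trial_id = 1, whisker_id = "C1",
    onset_ms = c(200, 260, 400), offset_ms = c(230, 290, 430)
  ))
  trials <- tibble::tibble(
    trial_id = 1, kind = "Go", outcome = "hit", pole_up_ms = 100,
    pole_down_ms = 1100
  )
  nw <- noise_windows(touches, trials, window_ms = 30)
  first <- nw[nw$class == "first", ]
  expect_equal(first$start_ms, c(100, 130, 160)) # tiles [100, 200)
  later <- nw[nw$class == "later", ]
  # gap 230->260 fits 1 window; gap 290->400 fits 3
  expect_equal(later$start_ms, c(230, 290, 320, 350))
  # no overlap with any response window [onset, onset+30)
  for (st in nw$start_ms) {
    expect_true(all(st + 30 <= touches$onset_ms | st >= touches$onset_ms + 30))
  }
})

test_that("population response sums unit counts per touch", {
  al <- tibble::tibble(
    trial_id = 1, onset_ms = c(100, 200, 100, 200), order = c(1, 2, 1, 2),
    unit_id = c("u1", "u1", "u2", "u2"), count = c(1, 2, 3, 4),
    pre_count = 0
  )
  pop <- population_response(al)
  expect_equal(pop$pop_count, c(4, 6))
  # single unit: identity
  pop1 <- population_response(al[al$unit_id == "u1", ])
  expect_equal(pop1$pop_count, c(1, 2))
  # permutation invariance
  pop2 <- population_response(al[c(4, 1, 3, 2), ])
  expect_equal(pop2$pop_count, pop$pop_count)
  expect_error(population_response(al[0, ]), "Empty population")
})

test_that("attenuation curve normalises by the first-touch response", {
  al <- tibble::tibble(
    trial_id = rep(1:2, each = 3), onset_ms = rep(c(100, 200, 300), 2),
    order = rep(1:3, 2), unit_id = "u1",
    count = c(10, 6, 4, 10, 4, 2), pre_count = 0
  )
  ac <- attenuation_curve(al)
  expect_equal(ac$norm_response[ac$order == 1], 1)
  expect_equal(ac$norm_response[ac$order == 2], 0.5)
  expect_equal(ac$norm_response[ac$order == 3], 0.3)
})

test_that("detection AUC separates strong first-touch responses", {
  cfg <- session_config(
    n_trials = 60, two_whiskers = FALSE, n_units = 3,
    slope_mean = 150, intercept_mean = 3, baseline_rate = 2, seed = 14
  )
  s <- generate_session(cfg)
  tbl <- touch_detection_auc(s$spikes, s$touches, s$trials)
  hit_first <- tbl$auc[tbl$touch_class == "first" & tbl$outcome == "hit"]
  expect_true(all(hit_first > 0.6, na.rm = TRUE))
  expect_true(all(tbl$auc >= 0 & tbl$auc <= 1, na.rm = TRUE))
})
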