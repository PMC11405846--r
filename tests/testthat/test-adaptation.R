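test_that("outlier filter removes exactly the strongest ceil(5%) touches", {
  set.seed(2)
  s <- stats::rnorm(100)
  keep <- filter_outliers(s)
  expect_equal(sum(!keep), 5)
  expect_true(min(abs(s[!keep])) >= max(abs(s[keep])))

  # 20 touches, one extreme value: that one removed
  s20 <- c(stats::rnorm(19, 0, 0.1), 50)
  keep20 <- filter_outliers(s20)
  expect_equal(which(!keep20), 20L)

  # all-equal values: the tie-break removes the last ceil(0.05 n) by index
  keep_eq <- filter_outliers(rep(1, 40))
  expect_equal(which(!keep_eq), c(39L, 40L))

  expect_warning(kf <- filter_outliers(stats::rnorm(10)), "Fewer than 20")
  expect_true(all(kf))
})

test_that("equipopulated bins hold counts differing by at most one", {
  b8 <- equipopulated_bins(8:1, n_bins = 4)
  expect_equal(b8$counts, rep(2L, 4))
  expect_equal(b8$assignment, c(4, 4, 3, 3, 2, 2, 1, 1))

  b100 <- equipopulated_bins(stats::runif(100), n_bins = 4)
  expect_equal(b100$counts, rep(25L, 4))

  # duplicates spanning a quantile: rank-based, stable, counts differ <= 1
  v <- c(1, 2, 2, 2, 2, 3, 4, 5, 6)
  bd <- equipopulated_bins(v, n_bins = 4)
  expect_true(max(table(bd$assignment)) - min(table(bd$assignment)) <= 1)
  expect_true(all(diff(bd$assignment[order(v, seq_along(v))]) >= 0))

  expect_error(equipopulated_bins(1:3, n_bins = 4), "at least")

  # property: random sizes and ties
  set.seed(8)
  for (i in 1:20) {
    n <- sample(4:200, 1)
    v <- sample(stats::rpois(n, 3))
    bb <- equipopulated_bins(v)
    tab <- table(bb$assignment)
    expect_equal(length(tab), 4)
    expect_lte(max(tab) - min(tab), 1)
    expect_equal(sum(tab), n)
  }
})

test_that("tuning fit is OLS through the four bin means", {
  # distinct strengths, counts exactly on y = 2x + 1
  d <- tibble::tibble(abs_strength = c(1, 2, 3, 4), count = c(3, 5, 7, 9))
  tc <- fit_tuning_curve(d, order_label = "1")
  expect_equal(tc$slope, 2)
  expect_equal(tc$intercept, 1)
  expect_false(tc$degenerate)

  # constant counts: slope 0, intercept c
  dc <- tibble::tibble(abs_strength = c(1, 2, 3, 4), count = 7)
  tcc <- fit_tuning_curve(dc)
  expect_equal(tcc$slope, 0)
  expect_equal(tcc$intercept, 7)

  # all strengths equal: degenerate, intercept = mean count
  dd <- tibble::tibble(abs_strength = rep(2, 6), count = c(1, 2, 3, 4, 5, 6))
  tdd <- fit_tuning_curve(dd)
  expect_true(tdd$degenerate)
  expect_true(is.na(tdd$slope))
  expect_equal(tdd$intercept, 3.5)

  # closed-form OLS oracle on noisy bin means
  set.seed(4)
  s <- stats::runif(40, 0, 1)
  y <- 3 * s + 2 + stats::rnorm(40, 0, 0.3)
  tc2 <- fit_tuning_curve(
    tibble::tibble(abs_strength = s, count = y),
    outlier_frac = 0.05
  )
  bm <- tc2$bins
  sl <- sum((bm$bin_mean_strength - mean(bm$bin_mean_strength)) *
    (bm$bin_mean_count - mean(bm$bin_mean_count))) /
    sum((bm$bin_mean_strength - mean(bm$bin_mean_strength))^2)
  expect_equal(tc2$slope, sl)
  expect_equal(tc2$intercept, mean(bm$bin_mean_count) -
    sl * mean(bm$bin_mean_strength))
})

test_that("noiseless linear data recovers slope and intercept to 1e-9", {
  set.seed(6)
  s <- stats::rlnorm(200, log(0.03), 0.5)
  d <- tibble::tibble(abs_strength = s, count = 120 * s + 1.4)
  tc <- fit_tuning_curve(d)
  expect_equal(tc$slope, 120, tolerance = 1e-9)
  expect_equal(tc$intercept, 1.4, tolerance = 1e-9)
})

test_that("prediction is the line floored at zero, constant if degenerate", {
  d <- tibble::tibble(abs_strength = c(1, 2, 3, 4), count = c(3, 5, 7, 9))
  tc <- fit_tuning_curve(d)
  tc$slope <- 0.1
  tc$intercept <- 1
  expect_equal(predict(tc, 5), 1.5)
  tc$slope <- -1
  expect_equal(predict(tc, 5), 0) # floored at zero counts
  dd <- tibble::tibble(abs_strength = rep(2, 4), count = c(1, 2, 3, 4))
  tdd <- fit_tuning_curve(dd)
  expect_warning(p <- predict(tdd, c(0, 10)), "Degenerate")
  expect_equal(p, c(2.5, 2.5))
})

test_that("leave-one-out refits change noisy predictions but not
           noiseless ones", {
  set.seed(10)
  s <- stats::runif(30, 0, 1)
  noiseless <- tibble::tibble(abs_strength = s, count = 2 * s + 1)
  tc0 <- fit_tuning_curve(noiseless)
  expect_equal(predict_loo(tc0), predict(tc0, tc0$data$strength),
    tolerance = 1e-9
  )
  noisy <- tibble::tibble(
    abs_strength = s, count = 2 * s + 1 + stats::rnorm(30, 0, 0.5)
  )
  tc1 <- fit_tuning_curve(noisy)
  expect_false(isTRUE(all.equal(
    predict_loo(tc1), predict(tc1, tc1$data$strength)
  )))
})

test_that("alpha limit cases and arithmetic", {
  expect_equal(alpha_index(10, 10, 4), 0)
  expect_equal(alpha_index(10, 4, 4), 1)
  expect_equal(alpha_index(10, 7, 4), 0.5)
  expect_warning(a <- alpha_index(5, 5, 5), "undefined")
  expect_true(is.na(a))
})

test_that("alpha is invariant under common affine rescaling of rates", {
  set.seed(12)
  for (i in 1:20) {
    fr <- sort(stats::runif(3, 1, 20), decreasing = TRUE)
    a <- alpha_index(fr[1], fr[2], fr[3])
    k <- stats::runif(1, 0.1, 5)
    b <- stats::runif(1, -2, 2)
    expect_equal(alpha_index(k * fr[1] + b, k * fr[2] + b, k * fr[3] + b), a)
  }
})

test_that("WSA index arithmetic, antisymmetry and bounds", {
  expect_equal(wsa_index(3, 3), 0)
  expect_equal(wsa_index(6, 2), 0.5)
  expect_equal(wsa_index(2, 6), -0.5)
  expect_warning(w <- wsa_index(0, 0), "undefined")
  expect_true(is.na(w))
  set.seed(13)
  for (i in 1:20) {
    ab <- stats::runif(2, 0, 10)
    expect_equal(wsa_index(ab[1], ab[2]), -wsa_index(ab[2], ab[1]))
    expect_lte(abs(wsa_index(ab[1], ab[2])), 1)
  }
})

test_that("attenuation decomposition hits its closed-form limit cases", {
  # identical tuning across orders, strengths decay: alpha = 0
  cfg0 <- session_config(
    n_trials = 60, noise = "none", intercept_ratio = 1, slope_ratio = 1,
    motor_decay = 0.8, two_whiskers = FALSE, seed = 31
  )
  s0 <- generate_session(cfg0)
  a0 <- attenuation_decomposition(population_response(s0$counts))
  expect_equal(a0$alpha, 0, tolerance = 1e-12)

  # constant strengths, intercept drop only: alpha = 1
  cfg1 <- session_config(
    n_trials = 60, noise = "none", intercept_ratio = 0.32, motor_decay = 1,
    strength_sdlog = 0, two_whiskers = FALSE, seed = 31
  )
  s1 <- generate_session(cfg1)
  a1 <- suppressWarnings(
    attenuation_decomposition(population_response(s1$counts))
  )
  expect_equal(a1$alpha, 1, tolerance = 1e-12)

  # mixed intercept drop + motor decay: alpha strictly between 0 and 1,
  # near the model-implied value
  cfgm <- session_config(
    n_trials = 400, noise = "none", intercept_ratio = 0.5,
    motor_decay = 0.8, two_whiskers = FALSE, seed = 31
  )
  sm <- generate_session(cfgm)
  am <- attenuation_decomposition(population_response(sm$counts))
  expect_gt(am$alpha, 0)
  expect_lt(am$alpha, 1)
  expect_lt(abs(am$alpha - implied_alpha(cfgm)), 0.1)
})

test_that("tidy and glance methods expose fits as tibbles", {
  d <- tibble::tibble(abs_strength = c(1, 2, 3, 4), count = c(3, 5, 7, 9))
  tc <- fit_tuning_curve(d, order_label = "1")
  td <- generics::tidy(tc)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  gl <- generics::glance(tc)
  expect_equal(gl$slope, 2)

  cfg <- session_config(
    n_trials = 50, noise = "none", two_whiskers = FALSE, seed = 2
  )
  ar <- attenuation_decomposition(
    population_response(generate_session(cfg)$counts)
  )
  expect_equal(nrow(generics::tidy(ar)), 4)
  expect_named(
    generics::glance(ar),
    c("fr1", "fr_later", "fr1_pred", "alpha", "n_first", "n_later",
      "later_min")
  )
})

test_that("WSA analysis: zero in shared adaptation, positive when
           whisker-specific", {
  shared <- generate_session(session_config(
    n_trials = 120, noise = "none", whisker_specific = FALSE, seed = 5
  ))
  w0 <- wsa_analysis(shared$counts)
  expect_gt(nrow(w0), 0)
  expect_equal(w0$index_i, rep(0, nrow(w0)), tolerance = 1e-9)

  spec <- generate_session(session_config(
    n_trials = 120, noise = "none", whisker_specific = TRUE, seed = 5
  ))
  w1 <- wsa_analysis(spec$counts)
  expect_gt(nrow(w1), 0)
  expect_true(all(w1$index_i > 0))
})
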