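#' Discard the strongest touches as outliers
#'
#' Removes the `ceiling(frac * n)` touches with greatest absolute strength
#' before tuning-curve estimation; by default the strongest 5%. Ties at the
#' cutoff are broken by input position: among equal absolute strengths the
#' later-indexed samples are removed first (stable, deterministic). With
#' fewer than 20 samples no removal is performed and a warning is issued.
#'
#' @param strengths Numeric vector of signed touch strengths (1/mm).
#' @param frac Fraction to discard, default 0.05.
#' @return Logical vector, `TRUE` for retained samples (in input order).
#' @export
filter_outliers <- function(strengths, frac = 0.05) {
  n <- length(strengths)
  if (n < 20) {
    warning("Fewer than 20 samples; outlier filter not applied.",
      call. = FALSE
    )
    return(rep(TRUE, n))
  }
  k <- ceiling(frac * n)
  # order by |strength| descending, later index first among ties
  ord <- order(abs(strengths), seq_len(n), decreasing = TRUE)
  keep <- rep(TRUE, n)
  keep[ord[seq_len(k)]] <- FALSE
  keep
}

#' Equipopulated binning of touch strengths
#'
#' Discretises values into `n_bins` bins holding equal numbers of samples
#' (differing by at most 1 when `n` is not divisible by `n_bins`).
#' Assignment is by sorted rank — stable under duplicated values spanning a
#' quantile — and edges are the empirical boundaries between consecutive
#' bins.
#'
#' @param values Numeric vector, `length(values) >= n_bins`.
#' @param n_bins Number of bins, default 4.
#' @return A list with `assignment` (integer bin per input value, in input
#'   order), `edges` (length `n_bins + 1`), and `counts`.
#' @export
equipopulated_bins <- function(values, n_bins = 4) {
  n <- length(values)
  if (n < n_bins) {
    stop("Need at least as many values as bins.", call. = FALSE)
  }
  ord <- order(values, seq_len(n)) # stable
  # split ranks into n_bins contiguous chunks, sizes differing by <= 1
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  bin_of_rank <- rep(seq_len(n_bins), times = sizes)
  assignment <- integer(n)
  assignment[ord] <- bin_of_rank
  sorted <- values[ord]
  cum <- cumsum(sizes)
  inner <- (sorted[cum[-n_bins]] + sorted[cum[-n_bins] + 1]) / 2
  edges <- c(sorted[1], inner, sorted[n])
  list(assignment = assignment, edges = edges, counts = sizes)
}

#' Fit a spike-count tuning curve for one touch-order class
#'
#' The tuning curve relates spike count (30 ms window from touch onset) to
#' touch strength for touches of a given ordinal class (first touch, second
#' touch, "later" touch, ...). The strongest 5% of touches are discarded as
#' outliers, the remainder discretised into 4 equipopulated strength bins,
#' and an ordinary least-squares line fitted to the 4 (bin mean strength,
#' bin mean count) points. Tuning is linear to good approximation over the
#' strength range this analysis considers.
#'
#' @param data A data frame with one row per touch of the class.
#' @param strength,count Column names (strings) holding the tuning abscissa
#'   (typically absolute strength `abs_strength`) and the spike count.
#' @param order_label Label of the touch-order class (e.g. `"1"`,
#'   `"later>=2"`).
#' @param n_bins Number of equipopulated bins, default 4.
#' @param outlier_frac Fraction of strongest touches discarded, default 0.05.
#' @param bin_means Fit on the `n_bins` bin means (default, the canonical
#'   procedure) or on the raw filtered samples (`FALSE`).
#' @return An object of class `tuning_curve`: slope (count per (1/mm)),
#'   intercept (count), bin table, the retained samples, and a `degenerate`
#'   flag (all strengths equal; slope undefined, intercept = mean count).
#' @export
fit_tuning_curve <- function(data, strength = "abs_strength",
                             count = "count", order_label = "later",
                             n_bins = 4, outlier_frac = 0.05,
                             bin_means = TRUE) {
  s_all <- data[[strength]]
  y_all <- data[[count]]
  if (length(s_all) < n_bins) {
    stop("Need at least `n_bins` touches to fit a tuning curve.",
      call. = FALSE
    )
  }
  keep <- if (length(s_all) >= 20) {
    filter_outliers(s_all, frac = outlier_frac)
  } else {
    rep(TRUE, length(s_all))
  }
  s <- s_all[keep]
  y <- y_all[keep]
  if (length(s) < n_bins) {
    stop("Too few touches left after outlier filtering.", call. = FALSE)
  }
  degenerate <- length(unique(s)) == 1L
  if (degenerate) {
    slope <- NA_real_
    intercept <- mean(y)
    bins <- tibble::tibble(
      bin = 1L, bin_mean_strength = s[1], bin_mean_count = mean(y),
      n = length(y)
    )
  } else {
    bn <- equipopulated_bins(s, n_bins = n_bins)
    bins <- dplyr::summarise(
      dplyr::group_by(
        tibble::tibble(bin = bn$assignment, s = s, y = y), .data$bin
      ),
      bin_mean_strength = mean(.data$s),
      bin_mean_count = mean(.data$y),
      n = dplyr::n(), .groups = "drop"
    )
    if (bin_means) {
      fit <- stats::lm(bin_mean_count ~ bin_mean_strength, data = bins)
    } else {
      fit <- stats::lm(y ~ s)
    }
    co <- stats::coef(fit)
    slope <- unname(co[2])
    intercept <- unname(co[1])
    if (!is.finite(slope)) { # bin means collapsed onto one abscissa
      degenerate <- TRUE
      slope <- NA_real_
      intercept <- mean(y)
    }
  }
  structure(
    list(
      order_label = order_label,
      slope = slope, intercept = intercept,
      bins = bins, degenerate = degenerate,
      n_samples = length(s),
      data = tibble::tibble(strength = s, count = y),
      n_bins = n_bins, outlier_frac = outlier_frac, bin_means = bin_means
    ),
    class = "tuning_curve"
  )
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(
    "<tuning_curve> order ", x$order_label, ": ",
    if (x$degenerate) {
      sprintf("degenerate (intercept %.3g)", x$intercept)
    } else {
      sprintf("slope %.4g, intercept %.4g", x$slope, x$intercept)
    },
    ", n = ", x$n_samples, "\n",
    sep = ""
  )
  invisible(x)
}

#' Predict spike counts from a tuning curve
#'
#' Evaluates `slope * strength + intercept`, floored at 0 counts (a linear
#' fit can extrapolate below zero, but negative firing is unphysical). For a
#' degenerate curve the constant intercept is returned with a warning.
#'
#' When a queried touch contributed to the curve's fit, its prediction must
#' not use itself: pass its position in the curve's retained sample set via
#' `loo_index` and the curve is re-fitted without that sample — including
#' re-binning — before predicting (leave-one-out cross-validation, one touch
#' at a time).
#'
#' @param object A [fit_tuning_curve()] object.
#' @param strengths Strength values to predict at.
#' @param loo_index Optional integer vector, same length as `strengths`:
#'   index of each queried touch in `object$data` (NA for touches outside
#'   the fit set).
#' @param ... Unused.
#' @return Numeric vector of predicted counts (>= 0).
#' @export
predict.tuning_curve <- function(object, strengths, loo_index = NULL, ...) {
  eval_tc <- function(tc, s) {
    if (tc$degenerate) {
      pmax(0, rep(tc$intercept, length(s)))
    } else {
      pmax(0, tc$slope * s + tc$intercept)
    }
  }
  if (object$degenerate) {
    warning("Degenerate tuning curve: constant prediction.", call. = FALSE)
  }
  if (is.null(loo_index)) {
    return(eval_tc(object, strengths))
  }
  stopifnot(length(loo_index) == length(strengths))
  out <- numeric(length(strengths))
  plain <- is.na(loo_index)
  out[plain] <- eval_tc(object, strengths[plain])
  for (i in which(!plain)) {
    d <- object$data[-loo_index[i], , drop = FALSE]
    tc_i <- fit_tuning_curve(
      d,
      strength = "strength", count = "count",
      order_label = object$order_label, n_bins = object$n_bins,
      outlier_frac = 0, bin_means = object$bin_means
    )
    out[i] <- eval_tc(tc_i, strengths[i])
  }
  out
}

#' Leave-one-out predictions for a tuning curve's own fit set
#'
#' Convenience wrapper over [predict.tuning_curve()] that predicts every
#' retained touch of the fit with that touch excluded from the fit.
#'
#' @param tc A [fit_tuning_curve()] object.
#' @return Numeric vector of LOO-predicted counts, one per row of
#'   `tc$data`.
#' @export
predict_loo <- function(tc) {
  n <- nrow(tc$data)
  predict(tc, tc$data$strength, loo_index = seq_len(n))
}

#' Attenuation-decomposition index alpha
#'
#' \eqn{\alpha = (FR_1 - FR_1') / (FR_1 - FR_{later})}: the fraction of the
#' first-to-later response attenuation attributable to sensory adaptation
#' (a change in neuronal sensitivity) rather than to weaker touches.
#' \eqn{FR_1'} is the first-touch response predicted by the later-touch
#' tuning curve; when the later tuning matches the first-touch tuning,
#' \eqn{FR_1' = FR_1} and \eqn{\alpha = 0}; when the attenuation is entirely
#' sensory, \eqn{FR_1' = FR_{later}} and \eqn{\alpha = 1}.
#'
#' @param fr1 Median response to first touch.
#' @param fr1_pred Median predicted first-touch response (\eqn{FR_1'}).
#' @param fr_later Median response to later touch.
#' @return Alpha (dimensionless); `NA` with a warning when
#'   `fr1 == fr_later` (no attenuation to decompose).
#' @export
alpha_index <- function(fr1, fr1_pred, fr_later) {
  if (fr1 == fr_later) {
    warning("FR1 equals FR_later: no attenuation; alpha undefined.",
      call. = FALSE
    )
    return(NA_real_)
  }
  (fr1 - fr1_pred) / (fr1 - fr_later)
}

#' Whisker-specific adaptation index I
#'
#' \eqn{I = (FR_{test} - FR_{predicted}) / (FR_{test} + FR_{predicted})}:
#' positive when a test whisker's touch evokes a stronger response than
#' predicted from that whisker's adapted-state tuning (adaptation did not
#' transfer from the adapting whisker), zero when adaptation spreads across
#' whiskers. Bounded in \[-1, 1\] for non-negative rates.
#'
#' @param fr_test Mean response to test touches.
#' @param fr_predicted Tuning-predicted response at matched strengths.
#' @return Index I; `NA` with a warning when the denominator is zero.
#' @export
wsa_index <- function(fr_test, fr_predicted) {
  den <- fr_test + fr_predicted
  if (den <= 0) {
    warning("FR_test + FR_predicted is not positive; I undefined.",
      call. = FALSE
    )
    return(NA_real_)
  }
  (fr_test - fr_predicted) / den
}

#' Decompose population response attenuation into sensory and motor parts
#'
#' For one simultaneously recorded population: computes the median
#' population response to first touch (\eqn{FR_1}) and to later touch
#' (\eqn{FR_{later}}); fits the population tuning curve to absolute touch
#' strength for later touches; predicts the median first-touch response from
#' that curve (\eqn{FR_1'}); and reports \eqn{\alpha} via [alpha_index()].
#' The tuning fit uses the outlier filter and equipopulated binning of
#' [fit_tuning_curve()]; the medians use all touches.
#'
#' @param pop Output of [population_response()]: one row per touch with
#'   `order`, `abs_strength` and `pop_count`.
#' @param later_min Smallest touch order counted as "later", default 2.
#' @param ... Passed to [fit_tuning_curve()].
#' @return An object of class `alpha_result` with fields `fr1`, `fr_later`,
#'   `fr1_pred`, `alpha`, `tuning_later` (the fitted curve), `n_first`,
#'   `n_later`.
#' @export
attenuation_decomposition <- function(pop, later_min = 2, ...) {
  pp <- tibble::as_tibble(pop)
  first <- dplyr::filter(pp, .data$order == 1)
  later <- dplyr::filter(pp, .data$order >= later_min)
  if (nrow(first) < 1 || nrow(later) < 4) {
    stop("Need at least 1 first touch and 4 later touches.", call. = FALSE)
  }
  tc <- fit_tuning_curve(
    later,
    strength = "abs_strength", count = "pop_count",
    order_label = paste0("later>=", later_min), ...
  )
  fr1 <- stats::median(first$pop_count)
  fr_later <- stats::median(later$pop_count)
  pred <- suppressWarnings(predict(tc, first$abs_strength))
  fr1_pred <- stats::median(pred)
  a <- alpha_index(fr1, fr1_pred, fr_later)
  structure(
    list(
      fr1 = fr1, fr_later = fr_later, fr1_pred = fr1_pred, alpha = a,
      tuning_later = tc, n_first = nrow(first), n_later = nrow(later),
      later_min = later_min
    ),
    class = "alpha_result"
  )
}

#' @export
print.alpha_result <- function(x, ...) {
  cat(sprintf(
    "<alpha_result> FR1 %.4g, FR_later %.4g, FR1' %.4g -> alpha %.4g\n",
    x$fr1, x$fr_later, x$fr1_pred, x$alpha
  ))
  invisible(x)
}

#' Whisker-specific adaptation analysis
#'
#' For each unit: selects test touches via [select_wsa_trials()]; fits the
#' test whisker's adapted-state tuning curve from that whisker's 3rd-or-later
#' touches (pooled over the session), excluding the test touches themselves
#' as a cross-validation step; computes \eqn{FR_{test}} (mean observed
#' response to the test touches) and \eqn{FR_{predicted}} (mean tuning
#' prediction at the test touches' absolute strengths); and reports the WSA
#' index I.
#'
#' @param aligned Output of [touch_aligned_counts()] with `order`,
#'   `whisker_id` and `abs_strength` columns.
#' @param selection Optional precomputed [select_wsa_trials()] output;
#'   derived from `aligned`'s touch columns when `NULL`.
#' @param adapted_min Smallest order defining the adapted state, default 3.
#' @param ... Passed to [fit_tuning_curve()].
#' @return A tibble with one row per unit x test whisker: `unit_id`,
#'   `w_test`, `fr_test`, `fr_predicted`, `index_i`, `n_test`, `n_fit`.
#'   Zero rows (with a message) when no trial is eligible.
#' @export
wsa_analysis <- function(aligned, selection = NULL, adapted_min = 3, ...) {
  al <- tibble::as_tibble(aligned)
  touch_cols <- setdiff(names(al), c("unit_id", "count", "pre_count"))
  touches <- dplyr::distinct(al[, touch_cols])
  if (is.null(selection)) selection <- select_wsa_trials(touches)
  empty <- tibble::tibble(
    unit_id = al$unit_id[0], w_test = character(), fr_test = numeric(),
    fr_predicted = numeric(), index_i = numeric(), n_test = integer(),
    n_fit = integer()
  )
  if (nrow(selection) == 0) {
    message("No whisker-specific-adaptation-eligible trials in session.")
    return(empty)
  }
  sel_key <- paste(selection$trial_id, selection$onset_ms)
  units <- unique(al$unit_id)
  out <- purrr::map(units, function(u) {
    au <- al[al$unit_id == u, , drop = FALSE]
    au_key <- paste(au$trial_id, au$onset_ms)
    purrr::map(unique(selection$w_test), function(w) {
      test_keys <- sel_key[selection$w_test == w]
      is_test <- au_key %in% test_keys
      test <- au[is_test, , drop = FALSE]
      fit_set <- au[!is_test & au$whisker_id == w &
        au$order >= adapted_min, , drop = FALSE]
      if (nrow(test) == 0 || nrow(fit_set) < 4) {
        return(NULL)
      }
      tc <- fit_tuning_curve(
        fit_set,
        strength = "abs_strength", count = "count",
        order_label = paste0("adapted>=", adapted_min, ":", w), ...
      )
      fr_test <- mean(test$count)
      fr_pred <- mean(suppressWarnings(predict(tc, test$abs_strength)))
      tibble::tibble(
        unit_id = u, w_test = w, fr_test = fr_test,
        fr_predicted = fr_pred,
        index_i = suppressWarnings(wsa_index(fr_test, fr_pred)),
        n_test = nrow(test), n_fit = nrow(fit_set)
      )
    })
  })
  res <- dplyr::bind_rows(purrr::flatten(out))
  if (nrow(res) == 0) {
    message("No unit had enough adapted-state touches for WSA.")
    return(empty)
  }
  res
}
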