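#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tuning curve into its bin table
#'
#' One row per equipopulated strength bin, with the bin means the line was
#' fitted through.
#'
#' @param x A [fit_tuning_curve()] object.
#' @param ... Unused.
#' @return A tibble with `order_label`, `bin`, `bin_mean_strength`,
#'   `bin_mean_count`, `n`.
#' @exportS3Method generics::tidy
tidy.tuning_curve <- function(x, ...) {
  dplyr::mutate(x$bins, order_label = x$order_label, .before = 1)
}

#' One-row summary of a tuning curve fit
#'
#' @param x A [fit_tuning_curve()] object.
#' @param ... Unused.
#' @return A tibble with `order_label`, `slope`, `intercept`, `n_samples`,
#'   `degenerate`.
#' @exportS3Method generics::glance
glance.tuning_curve <- function(x, ...) {
  tibble::tibble(
    order_label = x$order_label, slope = x$slope, intercept = x$intercept,
    n_samples = x$n_samples, degenerate = x$degenerate
  )
}

#' Tidy an attenuation decomposition
#'
#' @param x An [attenuation_decomposition()] object.
#' @param ... Unused.
#' @return A long tibble of the decomposition's component rates and alpha.
#' @exportS3Method generics::tidy
tidy.alpha_result <- function(x, ...) {
  tibble::tibble(
    quantity = c("fr1", "fr_later", "fr1_pred", "alpha"),
    value = c(x$fr1, x$fr_later, x$fr1_pred, x$alpha)
  )
}

#' One-row summary of an attenuation decomposition
#'
#' @param x An [attenuation_decomposition()] object.
#' @param ... Unused.
#' @return A one-row tibble: `fr1`, `fr_later`, `fr1_pred`, `alpha`,
#'   `n_first`, `n_later`, `later_min`.
#' @exportS3Method generics::glance
glance.alpha_result <- function(x, ...) {
  tibble::tibble(
    fr1 = x$fr1, fr_later = x$fr_later, fr1_pred = x$fr1_pred,
    alpha = x$alpha, n_first = x$n_first, n_later = x$n_later,
    later_min = x$later_min
  )
}
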