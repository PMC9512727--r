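#' Weighted linear trend in on-treatment fracture rates
#'
#' Fits a weighted least-squares line to the fracture rate per 1000
#' person-years over the four on-treatment windows (period index 1..4).
#' The slope is the rate change per on-treatment period.  The published
#' analysis states only that the model was "weighted"; person-years are
#' used by default (precision weighting) and the choice is recorded in the
#' result.
#'
#' @param rates Window-rate data frame (as produced by [window_rates()] or
#'   one cohort x fracture-type block of an [owncontrol()] fit); only
#'   on-treatment windows are used.
#' @param weights `"person_years"` or `"equal"`.
#' @return An object of class `octrend` with `slope`, `intercept`,
#'   `weights_used` and the underlying `lm` fit, or a flagged empty fit if
#'   fewer than two windows have person-time.
#' @examples
#' r <- data.frame(window = c("m4_12", "m13_24", "m25_36", "m37_48"),
#'                 rate_per_1000py = c(50, 40, 30, 20),
#'                 person_years = c(100, 100, 100, 100))
#' coef(fit_trend(r))
#' @export
fit_trend <- function(rates, weights = c("person_years", "equal")) {
  weights <- match.arg(weights)
  on <- rates[rates$window %in% ON_TREATMENT_WINDOWS, , drop = FALSE]
  on <- on[match(ON_TREATMENT_WINDOWS, on$window), , drop = FALSE]
  on <- on[!is.na(on$window) & on$person_years > 0, , drop = FALSE]
  if (nrow(on) < 2) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          weights_used = weights, fit = NULL,
                          n_windows = nrow(on),
                          note = "fewer than 2 usable windows"),
                     class = "octrend"))
  }
  period <- match(on$window, ON_TREATMENT_WINDOWS)
  w <- if (weights == "person_years") on$person_years
       else rep(1, nrow(on))
  fit <- stats::lm(rate_per_1000py ~ period,
                   data = data.frame(rate_per_1000py = on$rate_per_1000py,
                                     period = period),
                   weights = w)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 weights_used = weights, fit = fit, n_windows = nrow(on),
                 note = NULL),
            class = "octrend")
}

#' @export
coef.octrend <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
print.octrend <- function(x, ...) {
  cat("On-treatment fracture-rate trend (weighted least squares)\n")
  if (!is.null(x$note)) {
    cat("  ", x$note, "\n", sep = "")
  } else {
    cat(sprintf("  slope: %+.2f per 1000 PY per period (weights: %s, %d windows)\n",
                x$slope, x$weights_used, x$n_windows))
  }
  invisible(x)
}
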