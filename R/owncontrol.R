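#' Fit the own-control incidence analysis
#'
#' The package's central estimator.  For each treatment cohort (and
#' optionally each stratum of a baseline covariate), as-treated person-time
#' is partitioned into the early-treatment baseline window (days 0-89 from
#' index) and four on-treatment windows, windowed fracture incidence rates
#' per 1000 person-years are computed, and each on-treatment window is
#' compared with the early-treatment window by an incidence rate ratio with
#' a 95% confidence interval.  Because every patient's baseline is their
#' own early-treatment rate, time-stable confounders cancel; within-person
#' correlation across windows is not adjusted for in the intervals (see the
#' package vignette).
#'
#' @param members Member table from [select_cohort()] (optionally with
#'   baseline covariates).
#' @param episodes Episode table from [build_episodes()].
#' @param events Fracture events from [find_fracture_events()].
#' @param fracture_types Character vector; `"all"` and/or individual sites.
#' @param by Optional member column to fit per cohort (default
#'   `treatment_group`; use `NULL` for a single pooled cohort).
#' @param strata Optional member column (e.g. `prior_fracture` or
#'   `prior_osteoporosis_treatment`) for a stratified analysis; empty strata
#'   are omitted with a message.
#' @param ci_method Interval method passed to [irr()].
#' @param conf_level Confidence level of all intervals.
#' @param windows Window definition, see [analysis_windows()].
#' @return An object of class `owncontrol` with components `rates` (one row
#'   per cohort x fracture type x window: events, person-years, rate) and
#'   `irr` (one row per cohort x fracture type x on-treatment window: N,
#'   IRR, CI bounds, percent reduction, interval method used).
#' @examples
#' bundle <- generate_bundle(sim_config(n_patients = 2000, seed = 7))
#' sel <- select_cohort(bundle)
#' eps <- build_episodes(sel$members, bundle$prescriptions, bundle$code_map)
#' ev <- find_fracture_events(bundle)
#' fit <- owncontrol(sel$members, eps, ev, fracture_types = "all")
#' fit
#' @export
owncontrol <- function(members, episodes, events,
                       fracture_types = c("all", "clinical_vertebral",
                                          "hip", "wrist_forearm"),
                       by = "treatment_group", strata = NULL,
                       ci_method = c("auto", "wald", "exact"),
                       conf_level = 0.95, windows = analysis_windows()) {
  ci_method <- match.arg(ci_method)
  cohorts <- if (is.null(by)) list(pooled = seq_len(nrow(members)))
             else split(seq_len(nrow(members)), members[[by]])
  strat <- if (is.null(strata)) list(all = seq_len(nrow(members)))
           else split(seq_len(nrow(members)), members[[strata]])

  rates_list <- list(); irr_list <- list()
  for (co in names(cohorts)) for (st in names(strat)) {
    rows <- intersect(cohorts[[co]], strat[[st]])
    mem <- members[rows, , drop = FALSE]
    if (!is.null(mem$fx_eligible)) mem <- mem[mem$fx_eligible, , drop = FALSE]
    if (!nrow(mem)) {
      if (!is.null(strata))
        message(sprintf("stratum '%s' of cohort '%s' is empty; omitted",
                        st, co))
      next
    }
    for (ft in fracture_types) {
      rw <- window_rates(mem, episodes, events, fracture_type = ft,
                         windows = windows)
      rw <- cbind(cohort = co, fracture_type = ft, stratum = st, rw,
                  stringsAsFactors = FALSE)
      rates_list[[length(rates_list) + 1L]] <- rw
      early <- rw[rw$window == "early", , drop = FALSE]
      if (early$person_years <= 0) next
      for (w in setdiff(windows$window, "early")) {
        on <- rw[rw$window == w, , drop = FALSE]
        if (on$person_years <= 0) next
        r <- irr(early, on, method = ci_method, conf_level = conf_level)
        irr_list[[length(irr_list) + 1L]] <- data.frame(
          cohort = co, fracture_type = ft, stratum = st, window = w,
          N = r$n_ontx, irr = r$irr, ci_low = r$ci_low, ci_high = r$ci_high,
          pct_reduction = r$pct_reduction, method = r$method_used,
          flagged = r$flagged, stringsAsFactors = FALSE)
      }
    }
  }
  rates <- do.call(rbind, rates_list)
  irrtab <- if (length(irr_list)) do.call(rbind, irr_list) else NULL
  if (is.null(strata)) {
    rates$stratum <- NULL
    if (!is.null(irrtab)) irrtab$stratum <- NULL
  }
  structure(list(rates = rates, irr = irrtab, ci_method = ci_method,
                 conf_level = conf_level, by = by, strata = strata,
                 windows = windows, n_members = nrow(members),
                 call = match.call()),
            class = "owncontrol")
}

#' Stratified own-control analysis
#'
#' Re-runs the full rate/IRR machinery within each stratum of a baseline
#' covariate.
#'
#' @inheritParams owncontrol
#' @param stratifier Member column name, e.g. `"prior_fracture"` or
#'   `"prior_osteoporosis_treatment"`.
#' @param ... Passed to [owncontrol()].
#' @return An `owncontrol` object with a `stratum` column in both tables.
#' @export
stratified_analysis <- function(members, episodes, events, stratifier, ...) {
  stopifnot(stratifier %in% names(members))
  owncontrol(members, episodes, events, strata = stratifier, ...)
}

#' @export
print.owncontrol <- function(x, digits_rate = 1, digits_irr = 2, ...) {
  cat("Own-control incidence analysis\n")
  cat(sprintf("  members: %d; CI method: %s (%.0f%%)\n", x$n_members,
              x$ci_method, 100 * x$conf_level))
  if (is.null(x$irr)) {
    cat("  no estimable windows\n")
    return(invisible(x))
  }
  tab <- x$irr
  tab$IRR <- sprintf(paste0("%.", digits_irr, "f (%.", digits_irr,
                            "f-%.", digits_irr, "f)"),
                     tab$irr, tab$ci_low, tab$ci_high)
  keep <- intersect(c("cohort", "fracture_type", "stratum", "window", "N",
                      "IRR"), names(tab))
  print(tab[, keep], row.names = FALSE)
  invisible(x)
}

#' @export
summary.owncontrol <- function(object, ...) {
  structure(list(fit = object), class = "summary.owncontrol")
}

#' @export
print.summary.owncontrol <- function(x, ...) {
  print(x$fit)
  cat("\nWindowed rates (per 1000 person-years):\n")
  r <- x$fit$rates
  r$rate_per_1000py <- round(r$rate_per_1000py, 1)
  r$person_years <- round(r$person_years, 1)
  print(r, row.names = FALSE)
  invisible(x)
}

#' @export
coef.owncontrol <- function(object, ...) {
  if (is.null(object$irr)) return(numeric(0))
  tab <- object$irr
  nm <- paste(tab$cohort, tab$fracture_type, tab$window, sep = ".")
  if (!is.null(tab$stratum))
    nm <- paste(tab$cohort, tab$fracture_type, tab$stratum, tab$window,
                sep = ".")
  stats::setNames(tab$irr, nm)
}

#' @export
confint.owncontrol <- function(object, parm, level, ...) {
  tab <- object$irr
  ci <- cbind(tab$ci_low, tab$ci_high)
  rownames(ci) <- names(coef(object))
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - object$conf_level) / 2,
                                             1 - (1 - object$conf_level) / 2))
  ci
}

#' @export
plot.owncontrol <- function(x, fracture_type = "all", ...) {
  r <- x$rates[x$rates$fracture_type == fracture_type, , drop = FALSE]
  if (!nrow(r)) stop("no rates for fracture type ", fracture_type)
  wins <- x$windows$window
  cohorts <- unique(r$cohort)
  m <- sapply(cohorts, function(co) {
    sub <- r[r$cohort == co, , drop = FALSE]
    sub$rate_per_1000py[match(wins, sub$window)]
  })
  graphics::matplot(seq_along(wins), m, type = "b", pch = 19, lty = 1,
                    xaxt = "n", xlab = "analysis window",
                    ylab = "fracture rate per 1000 person-years",
                    main = paste("Fracture incidence by window:",
                                 fracture_type), ...)
  graphics::axis(1, at = seq_along(wins), labels = wins)
  graphics::legend("topright", legend = cohorts, col = seq_along(cohorts),
                   pch = 19, lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
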