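#' Person-window count table for the age-adjusted model
#'
#' Builds the long table the conditional Poisson model consumes: one row
#' per member and window with the event count, person-years at risk and the
#' member's age at the midpoint of their observed time in the window
#' (index age plus the midpoint offset in years) — age advances across
#' windows as a time-varying covariate.
#'
#' @param members Member table (fracture-eligible rows are used).
#' @param episodes Episode table.
#' @param events Fracture events.
#' @param fracture_type `"all"` or a site subset.
#' @param windows Window definition.
#' @return Data frame: `person_id`, `window`, `events`, `person_years`,
#'   `age_mid`.
#' @export
build_age_table <- function(members, episodes, events,
                            fracture_type = "all",
                            windows = analysis_windows()) {
  if (!is.null(members$fx_eligible))
    members <- members[members$fx_eligible, , drop = FALSE]
  episodes <- episodes[episodes$person_id %in% members$person_id, ,
                       drop = FALSE]
  if (!nrow(episodes))
    return(data.frame(person_id = character(), window = character(),
                      events = integer(), person_years = numeric(),
                      age_mid = numeric(), stringsAsFactors = FALSE))
  D <- pmin(episodes$duration_days, max(windows$hi))
  age0 <- members$age_at_index[match(episodes$person_id, members$person_id)]

  ev <- events
  if (!identical(fracture_type, "all"))
    ev <- ev[ev$site %in% fracture_type, , drop = FALSE]
  mi <- match(ev$person_id, members$person_id)
  off <- as.numeric(ev$event_date) - as.numeric(members$index_date[mi])
  Dev <- D[match(ev$person_id, episodes$person_id)]
  ok <- !is.na(mi) & !is.na(Dev) & off >= 0 & off < Dev
  evk <- paste(ev$person_id[ok],
               windows$window[findInterval(off[ok], windows$lo)])

  out <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    lo <- windows$lo[i]; hi <- windows$hi[i]
    days <- pmax(0, pmin(D, hi) - lo)
    mid <- (lo + pmin(D, hi)) / 2
    data.frame(person_id = episodes$person_id, window = windows$window[i],
               days = days, age_mid = age0 + mid / DAYS_PER_YEAR,
               stringsAsFactors = FALSE)
  }))
  out <- out[out$days > 0, , drop = FALSE]
  cnt <- table(evk)
  out$events <- as.integer(cnt[paste(out$person_id, out$window)])
  out$events[is.na(out$events)] <- 0L
  out$person_years <- out$days / DAYS_PER_YEAR
  out$days <- NULL
  rownames(out) <- NULL
  out
}

#' Age-adjusted conditional Poisson regression
#'
#' Person-stratified Poisson model of window event counts with a
#' log-person-years offset, on-treatment window indicators (early window as
#' reference) and age at the window midpoint as a time-varying covariate.
#' Conditioning on each person's total event count removes the per-person
#' baseline rate (the model reduces to a multinomial likelihood over each
#' person's windows), so only within-person covariate effects remain.
#' Persons with zero events drop out of the conditional likelihood by
#' construction.  The exponentiated age coefficient is the fracture rate
#' ratio per additional year of age.
#'
#' @param age_table Table from [build_age_table()].
#' @param conf_level Confidence level.
#' @return An object of class `ocpoisson` with `coef` (log scale),
#'   `irr_per_year_of_age` and its CI, age-adjusted window IRRs, `vcov`,
#'   convergence info and counts; a flagged, estimate-free object when the
#'   conditional likelihood is degenerate (fewer than two informative
#'   persons).
#' @export
fit_age_adjusted <- function(age_table, conf_level = 0.95) {
  tab <- age_table[age_table$person_years > 0, , drop = FALSE]
  tot <- tapply(tab$events, tab$person_id, sum)
  keep_persons <- names(tot)[tot > 0]
  tab <- tab[tab$person_id %in% keep_persons, , drop = FALSE]
  ## informative persons have events and more than one window at risk
  nwin <- tapply(tab$window, tab$person_id, length)
  informative <- sum(nwin > 1)
  if (informative < 2) {
    return(structure(list(converged = FALSE, coef = NULL,
                          note = "degenerate conditional likelihood: fewer than 2 informative persons",
                          n_persons = length(keep_persons)),
                     class = "ocpoisson"))
  }
  pid <- factor(tab$person_id)
  win <- factor(tab$window, levels = analysis_windows()$window)
  X <- cbind(stats::model.matrix(~ win)[, -1, drop = FALSE],
             age = tab$age_mid)
  colnames(X) <- sub("^win", "", colnames(X))
  y <- tab$events
  off <- log(tab$person_years)
  ni <- as.numeric(tapply(y, pid, sum))[as.integer(pid)]  # person totals

  negll <- function(beta) {
    eta <- off + as.numeric(X %*% beta)
    ## per-person log-sum-exp
    mx <- tapply(eta, pid, max)[as.integer(pid)]
    lse <- log(rowsum(exp(eta - mx), pid)[, 1]) + tapply(eta, pid, max)
    n_i <- rowsum(y, pid)[, 1]
    -(sum(y * eta) - sum(n_i * lse))
  }
  grad <- function(beta) {
    eta <- off + as.numeric(X %*% beta)
    mx <- tapply(eta, pid, max)[as.integer(pid)]
    w <- exp(eta - mx)
    denom <- rowsum(w, pid)[, 1][as.integer(pid)]
    p <- w / denom
    mu <- ni * p
    -as.numeric(t(X) %*% (y - mu))
  }
  fit <- stats::optim(rep(0, ncol(X)), negll, grad, method = "BFGS",
                      hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  vc <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  beta <- stats::setNames(fit$par, colnames(X))
  se <- stats::setNames(
    if (!is.null(vc)) sqrt(pmax(diag(vc), 0)) else rep(NA_real_, length(beta)),
    colnames(X))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- cbind(low = beta - z * se, high = beta + z * se)
  structure(list(
    converged = fit$convergence == 0 && !is.null(vc),
    coef = beta, se = se, vcov = vc,
    irr_per_year_of_age = unname(exp(beta["age"])),
    irr_age_ci = unname(exp(ci["age", ])),
    window_irr = exp(beta[setdiff(names(beta), "age")]),
    window_irr_ci = exp(ci[setdiff(names(beta), "age"), , drop = FALSE]),
    conf_level = conf_level,
    n_persons = nlevels(pid), n_rows = nrow(tab),
    logLik = -fit$value, note = NULL),
    class = "ocpoisson")
}

#' @export
coef.ocpoisson <- function(object, ...) object$coef

#' @export
vcov.ocpoisson <- function(object, ...) object$vcov

#' @export
confint.ocpoisson <- function(object, parm, level, ...) {
  z <- stats::qnorm(1 - (1 - object$conf_level) / 2)
  cbind(low = object$coef - z * object$se,
        high = object$coef + z * object$se)
}

#' @export
print.ocpoisson <- function(x, ...) {
  cat("Age-adjusted conditional Poisson model (person-stratified)\n")
  if (!is.null(x$note)) {
    cat("  flagged: ", x$note, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  persons with events: %d; converged: %s\n", x$n_persons,
              x$converged))
  cat(sprintf("  IRR per year of age: %.3f (%.0f%% CI %.3f-%.3f)\n",
              x$irr_per_year_of_age, 100 * x$conf_level,
              x$irr_age_ci[1], x$irr_age_ci[2]))
  cat("  age-adjusted window IRRs:\n")
  for (w in names(x$window_irr))
    cat(sprintf("    %-7s %.3f (%.3f-%.3f)\n", w, x$window_irr[w],
                x$window_irr_ci[w, 1], x$window_irr_ci[w, 2]))
  invisible(x)
}
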