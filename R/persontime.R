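#' Partition as-treated person-time into analysis windows
#'
#' Each member's episode duration (index date to episode end, capped at
#' 1460 days) is split over the early-treatment window and the four
#' on-treatment windows with closed-open day boundaries.  Window days sum
#' to `min(duration, 1460)` per member.
#'
#' @param episodes Episode table from [build_episodes()].
#' @param windows Window definition, see [analysis_windows()].
#' @return Long data frame: `person_id`, `window`, `days`.
#' @export
split_person_time <- function(episodes, windows = analysis_windows()) {
  if (any(episodes$duration_days < 0)) stop("negative episode duration")
  if (!nrow(episodes))
    return(data.frame(person_id = character(), window = character(),
                      days = numeric(), stringsAsFactors = FALSE))
  D <- pmin(episodes$duration_days, max(windows$hi))
  out <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    data.frame(person_id = episodes$person_id,
               window = windows$window[i],
               days = pmax(0, pmin(D, windows$hi[i]) - windows$lo[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Windowed fracture incidence rates
#'
#' Counts events in the window containing their date offset from index
#' (multiple events per person are all counted) and divides by window
#' person-years.  Only events occurring during the as-treated episode
#' (offset in `[0, min(duration, 1460))`) contribute.
#'
#' @param members Member table (provides index dates); only rows with
#'   `fx_eligible = TRUE` (if present) are used.
#' @param episodes Episode table.
#' @param events Fracture-event table from [merge_events()].
#' @param fracture_type `"all"` or one of the selected sites
#'   (`"clinical_vertebral"`, `"hip"`, `"wrist_forearm"`, ...).
#' @param windows Window definition.
#' @return Data frame: `window`, `events`, `person_years`,
#'   `rate_per_1000py`.
#' @export
window_rates <- function(members, episodes, events, fracture_type = "all",
                         windows = analysis_windows()) {
  if (!is.null(members$fx_eligible))
    members <- members[members$fx_eligible, , drop = FALSE]
  episodes <- episodes[episodes$person_id %in% members$person_id, ,
                       drop = FALSE]
  pt <- split_person_time(episodes, windows)
  py <- tapply(pt$days, factor(pt$window, levels = windows$window), sum)
  py <- as.numeric(py) / DAYS_PER_YEAR
  py[is.na(py)] <- 0

  ev <- events
  if (!identical(fracture_type, "all"))
    ev <- ev[ev$site %in% fracture_type, , drop = FALSE]
  mi <- match(ev$person_id, members$person_id)
  ei <- match(ev$person_id, episodes$person_id)
  off <- as.numeric(ev$event_date) -
    as.numeric(members$index_date[mi])
  D <- pmin(episodes$duration_days[ei], max(windows$hi))
  counted <- !is.na(mi) & !is.na(ei) & off >= 0 & off < D
  wi <- findInterval(off[counted], windows$lo)
  nev <- tabulate(wi, nbins = nrow(windows))

  if (any(nev > 0 & py <= 0))
    stop("window with events but zero person-years")
  data.frame(window = windows$window, events = nev, person_years = py,
             rate_per_1000py = ifelse(py > 0, 1000 * nev / py, 0),
             stringsAsFactors = FALSE)
}

#' Incidence rate ratio between an on-treatment and the early window
#'
#' `irr = (N_ontx / PY_ontx) / (N_early / PY_early)`.  The default Wald
#' interval is computed on the log scale,
#' `exp(log irr +/- z * sqrt(1/N_ontx + 1/N_early))`; for small counts
#' (either window below `exact_below`) an exact-conditional interval is
#' used instead: given the total event count, the on-treatment count is
#' binomial with success probability `PY_ontx * irr / (PY_ontx * irr +
#' PY_early)`, and a Clopper-Pearson interval on that probability is
#' transformed back to the ratio scale.  Zero events in the early window
#' leave the point estimate undefined (flagged, never an error).
#'
#' @param early,ontx Single rows (lists or one-row data frames) with
#'   `events` and `person_years`.
#' @param method `"auto"` (Wald, falling back to exact when
#'   `min(N) < exact_below`), `"wald"` or `"exact"`.
#' @param conf_level Confidence level.
#' @param exact_below Count threshold for the automatic exact fallback.
#' @return A list: `irr`, `ci_low`, `ci_high`, `pct_reduction`,
#'   `method_used`, `n_ontx`, `n_early`, `flagged`.
#' @examples
#' irr(list(events = 20, person_years = 100),
#'     list(events = 10, person_years = 100))
#' @export
irr <- function(early, ontx, method = c("auto", "wald", "exact"),
                conf_level = 0.95, exact_below = 5) {
  method <- match.arg(method)
  n1 <- ontx$events; py1 <- ontx$person_years
  n0 <- early$events; py0 <- early$person_years
  if (py0 <= 0 || py1 <= 0)
    stop("both windows need positive person-years")
  flagged <- n0 == 0
  est <- if (n0 > 0) (n1 / py1) / (n0 / py0) else NA_real_
  use <- if (method == "auto") {
    if (min(n0, n1) < exact_below) "exact" else "wald"
  } else method
  alpha <- 1 - conf_level
  if (use == "wald" && !flagged && n1 > 0) {
    z <- stats::qnorm(1 - alpha / 2)
    se <- sqrt(1 / n1 + 1 / n0)
    ci <- est * exp(c(-1, 1) * z * se)
  } else {
    ## exact-conditional: N_ontx | N ~ Binomial(N, p),
    ## p = py1 * irr / (py1 * irr + py0)
    N <- n0 + n1
    if (N == 0) {
      ci <- c(NA_real_, NA_real_)
    } else {
      p_lo <- if (n1 == 0) 0 else stats::qbeta(alpha / 2, n1, N - n1 + 1)
      p_hi <- if (n1 == N) 1 else stats::qbeta(1 - alpha / 2, n1 + 1, N - n1)
      to_irr <- function(p) if (p >= 1) Inf else (p / (1 - p)) * (py0 / py1)
      ci <- c(to_irr(p_lo), to_irr(p_hi))
    }
    use <- "exact"
  }
  list(irr = est, ci_low = ci[1], ci_high = ci[2],
       pct_reduction = pct_reduction(est), method_used = use,
       n_ontx = n1, n_early = n0, flagged = flagged)
}

#' Percent reduction implied by an incidence rate ratio
#'
#' @param irr Numeric vector of rate ratios.
#' @return `(1 - irr) * 100`.
#' @examples
#' pct_reduction(c(0.62, 0.50, 0.44, 0.33))
#' @export
pct_reduction <- function(irr) (1 - irr) * 100
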