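#' Default episode-construction parameters
#'
#' @param gap_days Maximum permissible gap after the expected refill date
#'   before the episode ends.
#' @param switch_window_days Window after the expected refill date in which a
#'   fill of a different osteoporosis class is classified as a switch.
#' @param end_at Where a discontinued episode ends: `"supply_end"` (the
#'   expected refill date, i.e. end of supplied coverage — the default, so
#'   as-treated person-time contains no unexposed grace days) or
#'   `"grace_end"` (expected refill date + `gap_days`).
#' @return A list of parameters.
#' @export
episode_params <- function(gap_days = 60, switch_window_days = 60,
                           end_at = c("supply_end", "grace_end")) {
  list(gap_days = gap_days, switch_window_days = switch_window_days,
       end_at = match.arg(end_at))
}

#' Build index-treatment episodes for a cohort
#'
#' Implements the refill-gap persistence rule: after each fill the expected
#' refill date is the fill date plus days supplied (a refill before supply
#' exhaustion resets it — supplies are not stockpiled); the episode
#' continues while the next index-class fill arrives within `gap_days`
#' after the expected refill date.  When it does not, the episode ends at
#' the expected refill date with reason `discontinued`, unless a fill of a
#' different osteoporosis class occurs within the switch window after the
#' expected refill date, in which case the episode ends at that fill's date
#' with reason `switched`.  Death, disenrollment and the administrative end
#' of study truncate the episode earlier.
#'
#' @param members Member table from [select_cohort()].
#' @param prescriptions Prescription table (all classes).
#' @param code_map Code map (drug classes).
#' @param params See [episode_params()].
#' @return A data frame with one row per member: `person_id`, `start`,
#'   `supply_end`, `episode_end`, `end_reason` (one of `discontinued`,
#'   `switched`, `death`, `disenrollment`, `admin_end`), `switched_to`,
#'   `duration_days`.
#' @export
build_episodes <- function(members, prescriptions,
                           code_map = default_code_map(),
                           params = episode_params()) {
  rx <- prescriptions
  rx$drug_class[rx$drug_class == "estrogen_only"] <- "hrt"
  rx <- rx[rx$drug_class %in% code_map$drug_classes, , drop = FALSE]
  mi <- match(rx$person_id, members$person_id)
  rx <- rx[!is.na(mi), , drop = FALSE]
  mi <- mi[!is.na(mi)]
  idx <- members$index_date[mi]
  grp <- members$treatment_group[mi]
  cens <- members$followup_end[mi]

  late <- rx$fill_date > cens
  if (any(late)) {
    warning(sum(late), " fill(s) after the censor date dropped")
    rx <- rx[!late, , drop = FALSE]; mi <- mi[!late]
    idx <- idx[!late]; grp <- grp[!late]
  }

  is_index <- rx$drug_class == grp & rx$fill_date >= idx
  ix <- rx[is_index, , drop = FALSE]
  ixm <- mi[is_index]
  o <- order(ixm, ix$fill_date)
  ix <- ix[o, , drop = FALSE]; ixm <- ixm[o]
  dupes <- duplicated(paste(ixm, ix$fill_date))
  if (any(dupes)) {
    warning(sum(dupes), " duplicate same-day fill(s) collapsed")
    ix <- ix[!dupes, , drop = FALSE]; ixm <- ixm[!dupes]
  }

  ## continuation: next fill within (expected refill + gap]; first violation
  ## truncates the fill chain
  expect <- as.numeric(ix$fill_date) + ix$days_supplied
  nxt <- c(as.numeric(ix$fill_date[-1]), Inf)
  same <- c(ixm[-1] == ixm[-length(ixm)], FALSE)
  ok <- !same | nxt <= expect + params$gap_days
  keep <- as.logical(stats::ave(ok, ixm, FUN = function(z) cumprod(c(1, z[-length(z)]))))
  ix <- ix[keep, , drop = FALSE]; ixm <- ixm[keep]
  expect <- expect[keep]

  ## expected refill date after the last accepted fill = end of coverage
  last <- !duplicated(ixm, fromLast = TRUE)
  supply_end_num <- expect[last]
  who <- ixm[last]  # row index into members, ascending

  ep <- members[who, c("person_id", "index_date", "followup_end",
                       "censor_backbone", "treatment_group"), drop = FALSE]
  ep$supply_end <- as.Date(supply_end_num, origin = "1970-01-01")

  ## switch detection among other-class fills in (supply_end, supply_end + w]
  oth <- rx[rx$drug_class != grp, , drop = FALSE]
  othm <- mi[rx$drug_class != grp]
  se_of <- supply_end_num[match(othm, who)]
  d <- as.numeric(oth$fill_date)
  cand <- !is.na(se_of) & d > se_of & d <= se_of + params$switch_window_days
  sw_date <- rep(NA_real_, length(who))
  sw_to <- rep(NA_character_, length(who))
  if (any(cand)) {
    oc <- oth[cand, , drop = FALSE]
    ocm <- match(othm[cand], who)
    oo <- order(ocm, oc$fill_date)
    oc <- oc[oo, , drop = FALSE]; ocm <- ocm[oo]
    fst <- !duplicated(ocm)
    sw_date[ocm[fst]] <- as.numeric(oc$fill_date[fst])
    sw_to[ocm[fst]] <- oc$drug_class[fst]
  }

  disc_end <- if (params$end_at == "grace_end")
    supply_end_num + params$gap_days else supply_end_num
  cand_end <- ifelse(is.na(sw_date), disc_end, sw_date)
  cand_reason <- ifelse(is.na(sw_date), "discontinued", "switched")

  cens_num <- as.numeric(ep$followup_end)
  use_censor <- cens_num < cand_end
  ep$episode_end <- as.Date(pmin(cand_end, cens_num), origin = "1970-01-01")
  ep$end_reason <- ifelse(use_censor, ep$censor_backbone, cand_reason)
  ep$switched_to <- ifelse(!use_censor & cand_reason == "switched", sw_to,
                           NA_character_)
  ep$duration_days <- as.numeric(ep$episode_end - ep$index_date)
  if (any(ep$duration_days < 0)) stop("negative episode duration")

  out <- data.frame(person_id = ep$person_id,
                    treatment_group = ep$treatment_group,
                    start = ep$index_date, supply_end = ep$supply_end,
                    episode_end = ep$episode_end, end_reason = ep$end_reason,
                    switched_to = ep$switched_to,
                    duration_days = ep$duration_days,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build a single person's treatment episode
#'
#' Single-person interface to the episode algorithm of [build_episodes()].
#'
#' @param fills Data frame of index-class fills (`fill_date`,
#'   `days_supplied`), or a vector of fill dates.
#' @param other_fills Optional data frame of other-class fills (`fill_date`,
#'   `drug_class`, `days_supplied`).
#' @param censor_date Date at which follow-up ends regardless of fills.
#' @param censor_reason Reason attached when the censor date truncates the
#'   episode (`death`, `disenrollment` or `admin_end`).
#' @param days_supplied Default days supplied when `fills` has no
#'   `days_supplied` column.
#' @param params See [episode_params()].
#' @return A one-row episode data frame (see [build_episodes()]).
#' @examples
#' # one 30-day fill, no refill: discontinued at day 30
#' build_episode(as.Date("2014-01-01"), days_supplied = 30)
#' @export
build_episode <- function(fills, other_fills = NULL,
                          censor_date = as.Date("2018-12-31"),
                          censor_reason = "admin_end",
                          days_supplied = NULL,
                          params = episode_params()) {
  if (!is.data.frame(fills))
    fills <- data.frame(fill_date = as_date(fills))
  if (!is.null(days_supplied) && is.null(fills$days_supplied))
    fills$days_supplied <- days_supplied
  stopifnot(!is.null(fills$days_supplied), all(fills$days_supplied > 0))
  fills$person_id <- "p1"
  fills$drug_class <- "denosumab"
  if (is.null(other_fills)) {
    other_fills <- fills[0, , drop = FALSE]
  } else {
    other_fills$person_id <- "p1"
    if (is.null(other_fills$drug_class))
      other_fills$drug_class <- "oral_bisphosphonate"
    if (is.null(other_fills$days_supplied)) other_fills$days_supplied <- 30
  }
  rx <- rbind(fills[, c("person_id", "drug_class", "fill_date",
                        "days_supplied")],
              other_fills[, c("person_id", "drug_class", "fill_date",
                              "days_supplied")])
  members <- data.frame(person_id = "p1", treatment_group = "denosumab",
                        index_date = min(as_date(fills$fill_date)),
                        followup_end = as_date(censor_date),
                        censor_backbone = censor_reason,
                        stringsAsFactors = FALSE)
  build_episodes(members, rx, params = params)
}

#' Treatment-duration summary
#'
#' Median and interquartile range of episode duration, overall and by prior
#' osteoporosis treatment, per treatment group.
#'
#' @param episodes Episode table from [build_episodes()].
#' @param members Member table with a `prior_osteoporosis_treatment` column
#'   (see [baseline_covariates()]); optional — without it only the overall
#'   rows are produced.
#' @return Data frame with `treatment_group`, `stratum`, `n`,
#'   `median_days`, `iqr_days` (empty strata yield `NA` markers).
#' @export
duration_summary <- function(episodes, members = NULL) {
  strata <- list(overall = rep(TRUE, nrow(episodes)))
  if (!is.null(members) && !is.null(members$prior_osteoporosis_treatment)) {
    pt <- members$prior_osteoporosis_treatment[
      match(episodes$person_id, members$person_id)]
    strata$no_prior_treatment <- !pt %in% TRUE
    strata$prior_treatment <- pt %in% TRUE
  }
  groups <- sort(unique(episodes$treatment_group))
  out <- do.call(rbind, lapply(names(strata), function(s) {
    do.call(rbind, lapply(groups, function(g) {
      d <- episodes$duration_days[strata[[s]] & episodes$treatment_group == g]
      data.frame(treatment_group = g, stratum = s, n = length(d),
                 median_days = if (length(d)) stats::median(d) else NA_real_,
                 iqr_days = if (length(d)) stats::IQR(d, type = 7) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
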