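#' Default cohort selection parameters
#'
#' @param index_start,index_end Inclusion window for the index prescription.
#' @param min_age Minimum age (years) at the index date.
#' @param history_months Required continuous enrollment before index.
#' @param washout_months New-user washout: no fill of the index class within
#'   this many months before index.
#' @param min_followup_days Minimum available follow-up (index to earliest of
#'   death, disenrollment or administrative end) required for the fracture
#'   analysis; members below it are retained for treatment-pattern analysis
#'   but flagged `fx_eligible = FALSE`.
#' @param admin_end Administrative censoring date.
#' @return A list of selection parameters.
#' @export
selection_params <- function(index_start = "2013-01-01",
                             index_end = "2017-12-31",
                             min_age = 50,
                             history_months = 24,
                             washout_months = 24,
                             min_followup_days = 183,
                             admin_end = "2018-12-31") {
  list(index_start = as_date(index_start), index_end = as_date(index_end),
       min_age = min_age,
       history_days = round(history_months * DAYS_PER_YEAR / 12),
       washout_days = round(washout_months * DAYS_PER_YEAR / 12),
       min_followup_days = min_followup_days,
       admin_end = as_date(admin_end))
}

# hierarchical assignment for all persons at once; returns one row per person
# with >= 1 qualifying fill in the index window
assign_groups <- function(prescriptions, procedures, code_map,
                          index_start, index_end) {
  rx <- prescriptions
  ## oestrogen-only preparations count as HRT only for women with a
  ## hysterectomy procedure anywhere on record
  eo <- rx$drug_class == "estrogen_only"
  if (any(eo)) {
    hyst_persons <- unique(procedures$person_id[
      startswith_any(procedures$code, code_map$hysterectomy_procedures)])
    qualifies <- rx$person_id %in% hyst_persons
    rx$drug_class[eo & qualifies] <- "hrt"
    rx <- rx[!(eo & !qualifies), , drop = FALSE]
  }
  rx <- rx[rx$drug_class %in% code_map$drug_classes &
             rx$fill_date >= index_start & rx$fill_date <= index_end, ,
           drop = FALSE]
  if (!nrow(rx))
    return(data.frame(person_id = character(), treatment_group = character(),
                      index_date = as.Date(character()),
                      stringsAsFactors = FALSE))
  tier <- tier_of(rx$drug_class, code_map)
  ## order by (person, tier, date): the first row per person is the first
  ## fill of the highest-priority tier; within the IV tier the first-filled
  ## sub-class wins and sets the index date
  o <- order(rx$person_id, tier, rx$fill_date)
  rx <- rx[o, , drop = FALSE]
  first <- rx[!duplicated(rx$person_id), , drop = FALSE]
  data.frame(person_id = first$person_id,
             treatment_group = first$drug_class,
             index_date = first$fill_date, stringsAsFactors = FALSE)
}

# age in years at `date` under the mid-year (July 1) birth-date convention
age_at <- function(date, birth_year) {
  if (!length(birth_year)) return(numeric(0))
  as.numeric(date - as.Date(paste0(birth_year, "-07-01"))) / DAYS_PER_YEAR
}

tier_of <- function(drug_class, code_map) {
  tiers <- code_map$hierarchy
  out <- rep(NA_integer_, length(drug_class))
  for (i in seq_along(tiers)) out[drug_class %in% tiers[[i]]] <- i
  out
}

#' Assign one person's treatment group hierarchically
#'
#' Applies the priority order denosumab > intravenous bisphosphonates >
#' oral bisphosphonates > teriparatide > raloxifene > HRT to a person's
#' fills inside the inclusion window.  Within the intravenous tier, the
#' first-filled sub-class wins.  The index date is the first fill of the
#' chosen class.
#'
#' @param fills Data frame with columns `person_id`, `drug_class`,
#'   `fill_date` (and optionally `days_supplied`) for one person.
#' @param procedures The person's procedure rows (used for the
#'   hysterectomy rule on oestrogen-only fills); may be empty.
#' @param code_map Code map.
#' @param index_start,index_end Inclusion window.
#' @return A list with `treatment_group` and `index_date`, or `NULL` if no
#'   qualifying fill exists.
#' @export
assign_treatment_group <- function(fills, procedures = NULL,
                                   code_map = default_code_map(),
                                   index_start = "2013-01-01",
                                   index_end = "2017-12-31") {
  if (is.null(procedures))
    procedures <- data.frame(person_id = character(), code = character(),
                             date = as.Date(character()),
                             stringsAsFactors = FALSE)
  res <- assign_groups(fills, procedures, code_map,
                       as_date(index_start), as_date(index_end))
  if (!nrow(res)) return(NULL)
  list(treatment_group = res$treatment_group[1],
       index_date = res$index_date[1])
}

#' Select the analysis cohort
#'
#' Applies the eligibility funnel to a claims bundle: women aged `min_age`
#' or older with at least one qualifying osteoporosis prescription in the
#' inclusion window; at least `history_months` of continuous enrollment
#' before index; no history of cancer, Paget's disease or osteogenesis
#' imperfecta on or before index; and no fill of the index class during the
#' washout period (new users).  Members whose available follow-up is below
#' `min_followup_days` are retained but flagged ineligible for the fracture
#' analysis.
#'
#' @param bundle A `claims_bundle`.
#' @param params See [selection_params()].
#' @return A list with `members` (one row per cohort member: identifiers,
#'   treatment group, index date, age, follow-up bounds, censor reasons) and
#'   `attrition` (one row per criterion with counts before/excluded/after).
#' @export
select_cohort <- function(bundle, params = selection_params()) {
  check_bundle(bundle)
  map <- bundle$code_map
  en <- bundle$enrollment

  asg <- assign_groups(bundle$prescriptions, bundle$procedures, map,
                       params$index_start, params$index_end)
  m <- merge(asg, en, by = "person_id", sort = TRUE)

  attrition <- data.frame(criterion = character(), n_before = integer(),
                          n_excluded = integer(), n_after = integer(),
                          stringsAsFactors = FALSE)
  note <- function(criterion, keep) {
    attrition <<- rbind(attrition, data.frame(
      criterion = criterion, n_before = nrow(m),
      n_excluded = sum(!keep), n_after = sum(keep),
      stringsAsFactors = FALSE))
    m[keep, , drop = FALSE]
  }

  attrition <- rbind(attrition, data.frame(
    criterion = "qualifying osteoporosis prescription in inclusion window",
    n_before = nrow(en), n_excluded = nrow(en) - nrow(m),
    n_after = nrow(m), stringsAsFactors = FALSE))

  m <- note("female", m$sex == "F")
  m$age_at_index <- age_at(m$index_date, m$birth_year)
  m <- note(sprintf("age >= %g at index", params$min_age),
            m$age_at_index >= params$min_age)
  m <- note(sprintf(">= %d days enrollment before index", params$history_days),
            as.numeric(m$index_date - m$coverage_start) >= params$history_days)

  ## exclusion diagnoses over all available pre-index history
  dx <- bundle$diagnoses
  excl_persons <- unique(dx$person_id[
    is_exclusion_code(dx$code, map) &
      dx$date <= m$index_date[match(dx$person_id, m$person_id)]])
  m <- note("no cancer / Paget's disease / osteogenesis imperfecta",
            !(m$person_id %in% excl_persons))

  ## new-user washout on the index class
  rx <- bundle$prescriptions
  rx$drug_class[rx$drug_class == "estrogen_only"] <- "hrt"
  key <- paste(rx$person_id, rx$drug_class)
  mk <- match(paste(m$person_id, m$treatment_group), key)  # any match exists?
  washout_hit <- logical(nrow(m))
  if (nrow(m) && nrow(rx)) {
    idx_of <- m$index_date[match(rx$person_id, m$person_id)]
    grp_of <- m$treatment_group[match(rx$person_id, m$person_id)]
    bad <- !is.na(idx_of) & rx$drug_class == grp_of &
      rx$fill_date < idx_of &
      as.numeric(idx_of - rx$fill_date) <= params$washout_days
    washout_hit <- m$person_id %in% rx$person_id[bad]
  }
  m <- note(sprintf("no index-class fill in prior %d days (new user)",
                    params$washout_days), !washout_hit)

  ## available follow-up and censoring backbone
  fu_end <- pmin(m$coverage_end, params$admin_end)
  fu_reason <- ifelse(!is.na(m$death_date) & m$death_date <= fu_end, "death",
                ifelse(m$coverage_end < params$admin_end, "disenrollment",
                       "admin_end"))
  m$followup_end <- fu_end
  m$censor_backbone <- fu_reason
  m$fx_eligible <- as.numeric(fu_end - m$index_date) >= params$min_followup_days
  attrition <- rbind(attrition, data.frame(
    criterion = sprintf(">= %d days follow-up (fracture analysis flag)",
                        params$min_followup_days),
    n_before = nrow(m), n_excluded = sum(!m$fx_eligible),
    n_after = sum(m$fx_eligible), stringsAsFactors = FALSE))

  members <- m[, c("person_id", "treatment_group", "index_date",
                   "age_at_index", "followup_end", "censor_backbone",
                   "death_date", "coverage_end", "fx_eligible")]
  rownames(members) <- NULL
  list(members = members, attrition = attrition)
}

#' Baseline covariates from pre-index claims
#'
#' Computes prior-fracture flags (any and per selected site) and the
#' prior-osteoporosis-treatment flag strictly from claims inside the
#' lookback window before the index date.
#'
#' @param members Member table from [select_cohort()].
#' @param bundle The claims bundle.
#' @param lookback_months Lookback window length.
#' @return `members` with added logical columns `prior_fracture`,
#'   `prior_vertebral`, `prior_hip`, `prior_wrist`,
#'   `prior_osteoporosis_treatment`.
#' @export
baseline_covariates <- function(members, bundle, lookback_months = 24) {
  lb <- round(lookback_months * DAYS_PER_YEAR / 12)
  map <- bundle$code_map
  dx <- bundle$diagnoses
  dx$site <- classify_site(dx$code, map)
  dx <- dx[!is.na(dx$site), , drop = FALSE]
  idx <- members$index_date[match(dx$person_id, members$person_id)]
  inwin <- !is.na(idx) & dx$date < idx & as.numeric(idx - dx$date) <= lb
  dx <- dx[inwin, , drop = FALSE]
  flag <- function(sites) members$person_id %in%
    dx$person_id[dx$site %in% sites]
  members$prior_fracture <- flag(names(map$fracture_sites))
  members$prior_vertebral <- flag("clinical_vertebral")
  members$prior_hip <- flag("hip")
  members$prior_wrist <- flag("wrist_forearm")

  rx <- bundle$prescriptions
  rx$drug_class[rx$drug_class == "estrogen_only"] <- "hrt"
  rx <- rx[rx$drug_class %in% map$drug_classes, , drop = FALSE]
  idxr <- members$index_date[match(rx$person_id, members$person_id)]
  grp <- members$treatment_group[match(rx$person_id, members$person_id)]
  prior_rx <- !is.na(idxr) & rx$fill_date < idxr &
    as.numeric(idxr - rx$fill_date) <= lb & rx$drug_class != grp
  members$prior_osteoporosis_treatment <-
    members$person_id %in% rx$person_id[prior_rx]
  members
}
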