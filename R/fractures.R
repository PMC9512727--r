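#' Qualify fracture diagnoses
#'
#' Applies the claims case definition: an inpatient fracture diagnosis
#' qualifies outright; an outpatient fracture diagnosis qualifies only in
#' combination with a fracture-related (inpatient or outpatient) procedure
#' within `proc_window_days` days.  Codes that map to no site in the code
#' map are ignored (their count is attached as the `n_unmapped` attribute).
#'
#' @param diagnoses Diagnosis table (`person_id`, `code`, `date`, `setting`).
#' @param procedures Procedure table (`person_id`, `code`, `date`).
#' @param code_map Code map; sites are assigned by first prefix match over
#'   the ordered site list.
#' @param proc_window_days Half-width of the diagnosis-to-procedure linkage
#'   window (the claims source does not pin this down; 30 days is the
#'   package default and it is configurable).
#' @return Data frame of qualified diagnoses: `person_id`, `site`, `date`,
#'   `source` (`inpatient` or `outpatient_plus_procedure`).
#' @export
qualify_diagnoses <- function(diagnoses, procedures,
                              code_map = default_code_map(),
                              proc_window_days = 30) {
  dx <- diagnoses
  dx$site <- classify_site(dx$code, code_map)
  n_unmapped <- sum(is.na(dx$site))
  dx <- dx[!is.na(dx$site), , drop = FALSE]

  pr <- procedures[startswith_any(procedures$code,
                                  code_map$fracture_procedures), ,
                   drop = FALSE]
  qualified <- dx$setting == "inpatient"
  outp <- which(!qualified)
  if (length(outp) && nrow(pr)) {
    ## nearest fracture-related procedure of the same person via a single
    ## sorted lookup: key = person rank * span + date offset
    persons <- sort(unique(c(dx$person_id, pr$person_id)))
    all_dates <- c(as.numeric(dx$date), as.numeric(pr$date))
    d0 <- min(all_dates); span <- max(all_dates) - d0 + 2 * proc_window_days + 3
    keyp <- (match(pr$person_id, persons) - 1) * span +
      (as.numeric(pr$date) - d0) + 1
    keyp <- sort(keyp)
    keyd <- (match(dx$person_id[outp], persons) - 1) * span +
      (as.numeric(dx$date[outp]) - d0) + 1
    lo <- findInterval(keyd - proc_window_days - 1, keyp) + 1
    hi <- findInterval(keyd + proc_window_days, keyp)
    qualified[outp] <- hi >= lo
  }
  out <- dx[qualified, c("person_id", "site", "date", "setting"),
            drop = FALSE]
  out$source <- ifelse(out$setting == "inpatient", "inpatient",
                       "outpatient_plus_procedure")
  out$setting <- NULL
  rownames(out) <- NULL
  structure(out, n_unmapped = n_unmapped)
}

#' Merge qualified diagnoses into fracture events
#'
#' Per person and site, diagnoses are chained transitively: a diagnosis
#' within `merge_window_days` days of the previous diagnosis in the chain
#' belongs to the same fracture event ("three months" is fixed at 90 days).
#' The event date is the first diagnosis of the chain.  Different sites
#' never merge.
#'
#' @param qualified Qualified diagnosis table from [qualify_diagnoses()].
#' @param merge_window_days Maximum gap between successive same-site
#'   diagnoses of one event.
#' @return Data frame of fracture events: `person_id`, `site`,
#'   `event_date`, `source`, `n_diagnoses`.
#' @export
merge_events <- function(qualified, merge_window_days = 90) {
  q <- qualified
  if (!nrow(q))
    return(data.frame(person_id = character(), site = character(),
                      event_date = as.Date(character()),
                      source = character(), n_diagnoses = integer(),
                      stringsAsFactors = FALSE))
  o <- order(q$person_id, q$site, q$date)
  q <- q[o, , drop = FALSE]
  key <- paste(q$person_id, q$site)
  gap <- c(Inf, diff(as.numeric(q$date)))
  new_chain <- gap > merge_window_days | key != c("", key[-length(key)])
  event_id <- cumsum(new_chain)
  first <- !duplicated(event_id)
  out <- data.frame(person_id = q$person_id[first], site = q$site[first],
                    event_date = q$date[first], source = q$source[first],
                    n_diagnoses = as.integer(tabulate(event_id)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Identify fracture events in a claims bundle
#'
#' Convenience wrapper: [qualify_diagnoses()] followed by [merge_events()].
#'
#' @param bundle A `claims_bundle`.
#' @param proc_window_days,merge_window_days See the two stage functions.
#' @return Fracture-event data frame (see [merge_events()]).
#' @export
find_fracture_events <- function(bundle, proc_window_days = 30,
                                 merge_window_days = 90) {
  q <- qualify_diagnoses(bundle$diagnoses, bundle$procedures,
                         bundle$code_map, proc_window_days)
  merge_events(q, merge_window_days)
}
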