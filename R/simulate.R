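#' Generate a synthetic claims bundle
#'
#' Simulates the four claims tables (enrollment, prescriptions, diagnoses,
#' procedures) of an administrative-claims extract with known ground truth.
#' Fracture events are drawn from an inhomogeneous Poisson process that is
#' piecewise constant on the clock starting at each person's index
#' prescription: the per-site baseline hazards apply during days 0-89 and
#' are multiplied by the configured window rate ratios thereafter.  Each
#' simulated fracture presents either as an inpatient diagnosis or as an
#' outpatient diagnosis plus a fracture-related procedure on the same date,
#' so both arms of the case definition are exercised; an optional follow-up
#' diagnosis of the same site within 60 days exercises event merging.
#'
#' Treatment history seeded before the inclusion window (washout violators,
#' prior other-class treatment) is always dated before `index_start`, so the
#' generator's index date and the cohort builder's reconstructed index date
#' agree for every person.
#'
#' @param cfg A validated [sim_config()].
#' @return An object of class `claims_bundle`: a list with data frames
#'   `enrollment` (`person_id`, `sex`, `birth_year`, `coverage_start`,
#'   `coverage_end`, `death_date`), `prescriptions` (`person_id`,
#'   `drug_class`, `fill_date`, `days_supplied`), `diagnoses` (`person_id`,
#'   `code`, `date`, `setting`), `procedures` (`person_id`, `code`, `date`),
#'   plus the `code_map` and the generating `config`.
#' @examples
#' b <- generate_bundle(sim_config(n_patients = 200, seed = 42))
#' b
#' @export
generate_bundle <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  map <- cfg$code_map
  n <- cfg$n_patients
  if (n == 0) return(new_bundle(empty_tables(), map, cfg))

  s0 <- as.integer(cfg$study_start); s1 <- as.integer(cfg$study_end)
  i0 <- as.integer(cfg$index_start); i1 <- as.integer(cfg$index_end)
  classes <- map$drug_classes

  pid <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < cfg$male_prob, "M", "F")
  age_target <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)

  ## enrollment spans
  late <- stats::runif(n) < cfg$late_entry_prob
  cov_start <- rep(s0, n)
  if (any(late))
    cov_start[late] <- s0 + floor(stats::runif(sum(late)) * (s1 - 365 - s0))
  t_death <- cov_start + rexp_safe(n, cfg$death_rate) * DAYS_PER_YEAR
  t_dis <- cov_start + rexp_safe(n, cfg$disenroll_rate) * DAYS_PER_YEAR
  cov_end <- pmin(s1, floor(t_death), floor(t_dis))
  died <- floor(t_death) <= pmin(s1, floor(t_dis))

  ## index class and date
  cls <- sample(names(cfg$drug_mix), n, replace = TRUE, prob = cfg$drug_mix)
  idx_lo <- pmax(i0, cov_start)
  idx_hi <- pmin(i1, cov_end)
  active <- idx_hi >= idx_lo
  index <- rep(NA_integer_, n)
  u_idx <- stats::runif(n)
  index[active] <- as.integer(idx_lo[active] +
    floor(u_idx[active] * (idx_hi[active] - idx_lo[active] + 1)))

  ref_date <- ifelse(active, index, cov_start)
  birth_year <- as.integer(format(as.Date(ref_date, origin = "1970-01-01"),
                                  "%Y")) - as.integer(round(age_target))
  age_at_index <- (ref_date -
    as.integer(as.Date(paste0(birth_year, "-07-01")))) / DAYS_PER_YEAR

  ## index-class fill streams: fill k at index + sum_{j<k}(supply + delay_j)
  sup <- unname(cfg$days_supplied[cls])
  gapm <- unname(cfg$refill_gap_mean[cls])
  stopp <- unname(cfg$persistence_stop_prob[cls])
  horizon <- pmax(0L, cov_end - index)
  horizon[!active] <- 0L
  cap <- ifelse(active, ceiling(horizon / sup) + 1L, 0L)
  nf <- pmin(1L + stats::rgeom(n, pmin(pmax(stopp, 1e-9), 1)), cap)
  nf[!active] <- 0L
  fp <- rep(seq_len(n), nf)
  tot <- length(fp)
  delay <- numeric(tot)
  if (tot) {
    delay <- round(stats::rexp(tot, 1 / pmax(gapm[fp], 1e-9)))
    delay[gapm[fp] <= 0] <- 0
    step <- sup[fp] + delay
    cs <- cumsum(step)
    firsts <- !duplicated(fp)
    cs <- cs - rep((cs - step)[firsts], nf[nf > 0L])
    fdate <- index[fp] + as.integer(cs - step)
    keep <- fdate <= cov_end[fp]
    rx <- data.frame(person_id = pid[fp][keep], drug_class = cls[fp][keep],
                     fill_date = fdate[keep],
                     days_supplied = sup[fp][keep],
                     stringsAsFactors = FALSE)
  } else {
    rx <- empty_tables()$prescriptions
    rx$fill_date <- as.integer(rx$fill_date)
  }

  ## pre-window treatment history: washout violators (same class) and prior
  ## other-class treatment; both dated before the inclusion window start
  wv <- active & stats::runif(n) < cfg$prior_index_fill_prob
  wdate <- pmin(index - (30L + as.integer(floor(stats::runif(n) * 671))), i0 - 1L)
  wv <- wv & !is.na(wdate) & wdate >= cov_start
  if (any(wv))
    rx <- rbind(rx, data.frame(person_id = pid[wv], drug_class = cls[wv],
                               fill_date = wdate[wv],
                               days_supplied = sup[wv],
                               stringsAsFactors = FALSE))
  pot <- active & stats::runif(n) < cfg$prior_other_treatment_prob
  pos <- match(cls, classes)
  k <- 1L + as.integer(floor(stats::runif(n) * (length(classes) - 1L)))
  ocls <- classes[k + (k >= pos)]
  pdate <- pmin(index - (30L + as.integer(floor(stats::runif(n) * 701))), i0 - 1L)
  pot <- pot & !is.na(pdate) & pdate >= cov_start
  if (any(pot))
    rx <- rbind(rx, data.frame(person_id = pid[pot], drug_class = ocls[pot],
                               fill_date = pdate[pot],
                               days_supplied = unname(cfg$days_supplied[ocls[pot]]),
                               stringsAsFactors = FALSE))

  ## oestrogen-only HRT users and hysterectomy procedures
  eo <- active & cls == "hrt" & stats::runif(n) < cfg$estrogen_only_prob
  hyst <- eo & stats::runif(n) < cfg$hysterectomy_prob
  if (any(eo)) {
    eo_ids <- pid[eo]
    relabel <- rx$person_id %in% eo_ids & rx$drug_class == "hrt"
    rx$drug_class[relabel] <- "estrogen_only"
  }
  proc <- empty_tables()$procedures
  proc$date <- as.integer(proc$date)
  if (any(hyst)) {
    hdate <- cov_start + as.integer(
      floor(stats::runif(n) * pmax(1L, index - cov_start)))
    proc <- rbind(proc, data.frame(
      person_id = pid[hyst],
      code = map$hysterectomy_procedures[[1]],
      date = pmin(hdate[hyst], index[hyst]), stringsAsFactors = FALSE))
  }

  ## exclusion-condition diagnoses in pre-index history
  dx <- empty_tables()$diagnoses
  dx$date <- as.integer(dx$date)
  ex <- active & stats::runif(n) < cfg$exclusion_prev
  ecode <- sample(c("C50.9", "C61", "M88.0", "Q78.0"), n, replace = TRUE,
                  prob = c(0.5, 0.2, 0.2, 0.1))
  edate <- cov_start + as.integer(
    floor(stats::runif(n) * pmax(1L, index - cov_start)))
  if (any(ex))
    dx <- rbind(dx, data.frame(person_id = pid[ex], code = ecode[ex],
                               date = pmin(edate[ex], index[ex]),
                               setting = "outpatient",
                               stringsAsFactors = FALSE))

  ## latent high-risk stratum: seeded pre-index fracture diagnosis + hazard
  ## multiplier (renormalised so the marginal early rate stays at baseline)
  sites <- names(cfg$baseline_hazard)
  site_prob <- cfg$baseline_hazard / sum(cfg$baseline_hazard)
  if (sum(cfg$baseline_hazard) == 0) site_prob <- rep(1 / length(sites), length(sites))
  hr <- active & stats::runif(n) < cfg$prior_fracture_prob
  pf_site <- sample(sites, n, replace = TRUE, prob = site_prob)
  pf_date <- pmax(index - (120L + as.integer(floor(stats::runif(n) * 601))),
                  cov_start)
  if (any(hr))
    dx <- rbind(dx, data.frame(person_id = pid[hr],
                               code = site_code(pf_site[hr], map),
                               date = pf_date[hr], setting = "inpatient",
                               stringsAsFactors = FALSE))

  ## fracture event process from index to coverage end
  norm <- (1 - cfg$prior_fracture_prob) +
    cfg$prior_fracture_prob * cfg$prior_fracture_rate_ratio
  mult <- ifelse(hr, cfg$prior_fracture_rate_ratio, 1) / norm
  btot <- sum(cfg$baseline_hazard)
  rmult <- c(1, unname(cfg$hazard_ratio_by_window[ON_TREATMENT_WINDOWS]))
  rmult <- c(rmult, rmult[length(rmult)])  # beyond 48 months: keep last ratio
  lo_b <- c(0, 90, 365, 730, 1095, 1460)
  hi_b <- c(90, 365, 730, 1095, 1460, Inf)
  ev_p <- integer(0); ev_off <- integer(0)
  A <- cfg$age_rate_ratio
  for (s in seq_along(lo_b)) {
    seg_lo <- pmin(horizon, lo_b[s])
    seg_hi <- pmin(horizon, hi_b[s])
    len <- pmax(0, seg_hi - seg_lo)
    mid_age <- age_at_index + (seg_lo + pmin(seg_hi, horizon)) / 2 / DAYS_PER_YEAR
    lam <- btot * rmult[s] * mult * A^(mid_age - cfg$age_mean) * len / DAYS_PER_YEAR
    lam[!active | len <= 0] <- 0
    kk <- stats::rpois(n, lam)
    if (any(kk > 0)) {
      who <- rep(seq_len(n), kk)
      off <- seg_lo[who] + floor(stats::runif(length(who)) * len[who])
      ev_p <- c(ev_p, who); ev_off <- c(ev_off, as.integer(off))
    }
  }
  if (length(ev_p)) {
    K <- length(ev_p)
    ev_site <- sample(sites, K, replace = TRUE, prob = site_prob)
    ev_date <- index[ev_p] + ev_off
    inp <- stats::runif(K) < cfg$p_inpatient
    dx <- rbind(dx, data.frame(person_id = pid[ev_p],
                               code = site_code(ev_site, map),
                               date = ev_date,
                               setting = ifelse(inp, "inpatient", "outpatient"),
                               stringsAsFactors = FALSE))
    if (any(!inp)) {
      pcode <- map$fracture_procedures[
        1L + as.integer(floor(stats::runif(K) * length(map$fracture_procedures)))]
      proc <- rbind(proc, data.frame(person_id = pid[ev_p][!inp],
                                     code = pcode[!inp], date = ev_date[!inp],
                                     stringsAsFactors = FALSE))
    }
    ## follow-up diagnosis of the same site within 60 days
    dup <- stats::runif(K) < cfg$dup_dx_prob
    dup_date <- ev_date + 1L + as.integer(floor(stats::runif(K) * 60))
    dup_inp <- stats::runif(K) < cfg$p_inpatient
    dup <- dup & dup_date <= cov_end[ev_p]
    if (any(dup)) {
      dx <- rbind(dx, data.frame(person_id = pid[ev_p][dup],
                                 code = site_code(ev_site[dup], map),
                                 date = dup_date[dup],
                                 setting = ifelse(dup_inp[dup], "inpatient",
                                                  "outpatient"),
                                 stringsAsFactors = FALSE))
      out_dup <- dup & !dup_inp
      if (any(out_dup)) {
        pcode2 <- map$fracture_procedures[
          1L + as.integer(floor(stats::runif(K) * length(map$fracture_procedures)))]
        proc <- rbind(proc, data.frame(person_id = pid[ev_p][out_dup],
                                       code = pcode2[out_dup],
                                       date = dup_date[out_dup],
                                       stringsAsFactors = FALSE))
      }
    }
  }

  enrollment <- data.frame(
    person_id = pid, sex = sex, birth_year = birth_year,
    coverage_start = as.Date(cov_start, origin = "1970-01-01"),
    coverage_end = as.Date(cov_end, origin = "1970-01-01"),
    death_date = as.Date(ifelse(died, cov_end, NA_integer_),
                         origin = "1970-01-01"),
    stringsAsFactors = FALSE)

  rx <- rx[order(rx$person_id, rx$fill_date, rx$drug_class), , drop = FALSE]
  rx$fill_date <- as.Date(rx$fill_date, origin = "1970-01-01")
  dx <- dx[order(dx$person_id, dx$date, dx$code), , drop = FALSE]
  dx$date <- as.Date(dx$date, origin = "1970-01-01")
  proc <- proc[order(proc$person_id, proc$date, proc$code), , drop = FALSE]
  proc$date <- as.Date(proc$date, origin = "1970-01-01")
  rownames(rx) <- rownames(dx) <- rownames(proc) <- NULL

  new_bundle(list(enrollment = enrollment, prescriptions = rx,
                  diagnoses = dx, procedures = proc), map, cfg)
}

rexp_safe <- function(n, rate) {
  u <- stats::rexp(n, pmax(rate, 1e-12))
  if (rate <= 0) u[] <- Inf
  u
}

# draw a representative code for a site (first listed prefix)
site_code <- function(site, map) {
  vapply(map$fracture_sites, `[[`, character(1), 1L)[site]
}

empty_tables <- function() {
  list(
    enrollment = data.frame(person_id = character(), sex = character(),
                            birth_year = integer(),
                            coverage_start = as.Date(character()),
                            coverage_end = as.Date(character()),
                            death_date = as.Date(character()),
                            stringsAsFactors = FALSE),
    prescriptions = data.frame(person_id = character(),
                               drug_class = character(),
                               fill_date = as.Date(character()),
                               days_supplied = numeric(),
                               stringsAsFactors = FALSE),
    diagnoses = data.frame(person_id = character(), code = character(),
                           date = as.Date(character()),
                           setting = character(), stringsAsFactors = FALSE),
    procedures = data.frame(person_id = character(), code = character(),
                            date = as.Date(character()),
                            stringsAsFactors = FALSE)
  )
}

new_bundle <- function(tables, code_map, config = NULL) {
  structure(c(tables, list(code_map = code_map, config = config)),
            class = "claims_bundle")
}

#' Assemble a claims bundle from four tables
#'
#' @param enrollment,prescriptions,diagnoses,procedures Data frames with the
#'   schemas described in [generate_bundle()].
#' @param code_map Code map used to interpret diagnosis/procedure codes.
#' @return A `claims_bundle`.
#' @export
claims_bundle <- function(enrollment, prescriptions, diagnoses, procedures,
                          code_map = default_code_map()) {
  b <- new_bundle(list(enrollment = enrollment, prescriptions = prescriptions,
                       diagnoses = diagnoses, procedures = procedures),
                  code_map)
  check_bundle(b)
  b
}

check_bundle <- function(bundle) {
  req <- list(
    enrollment = c("person_id", "sex", "birth_year", "coverage_start",
                   "coverage_end", "death_date"),
    prescriptions = c("person_id", "drug_class", "fill_date", "days_supplied"),
    diagnoses = c("person_id", "code", "date", "setting"),
    procedures = c("person_id", "code", "date"))
  for (tab in names(req)) {
    missing <- setdiff(req[[tab]], names(bundle[[tab]]))
    if (length(missing))
      stop(sprintf("bundle table '%s' is missing column(s): %s", tab,
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(bundle)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("Claims bundle\n")
  cat(sprintf("  enrollment:    %6d persons\n", nrow(x$enrollment)))
  cat(sprintf("  prescriptions: %6d fills\n", nrow(x$prescriptions)))
  cat(sprintf("  diagnoses:     %6d rows\n", nrow(x$diagnoses)))
  cat(sprintf("  procedures:    %6d rows\n", nrow(x$procedures)))
  invisible(x)
}

#' Write / read a claims bundle as CSV files
#'
#' Writes the four tables as CSV with ISO-8601 dates, the code map as YAML,
#' and (for simulated bundles) a run manifest echoing the seed and
#' configuration.
#'
#' @param bundle A `claims_bundle`.
#' @param dir Directory to write to (created if needed).
#' @return `write_bundle()` returns `dir` invisibly; `read_bundle()` returns
#'   a `claims_bundle`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in c("enrollment", "prescriptions", "diagnoses", "procedures"))
    utils::write.csv(bundle[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  write_code_map(bundle$code_map, file.path(dir, "code_map.yaml"))
  if (!is.null(bundle$config)) {
    cfg <- bundle$config
    manifest <- list(
      seed = cfg$seed, n_patients = cfg$n_patients,
      study_start = as.character(cfg$study_start),
      study_end = as.character(cfg$study_end),
      package_version = as.character(utils::packageVersion("owncontrol")),
      config = lapply(unclass(cfg)[setdiff(names(cfg), "code_map")],
                      function(v) if (inherits(v, "Date")) as.character(v) else v))
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  }
  invisible(dir)
}

#' @rdname write_bundle
#' @param code_map Optional code map; defaults to `code_map.yaml` in `dir`
#'   if present, else [default_code_map()].
#' @export
read_bundle <- function(dir, code_map = NULL) {
  if (is.null(code_map)) {
    cm_path <- file.path(dir, "code_map.yaml")
    code_map <- if (file.exists(cm_path)) read_code_map(cm_path)
                else default_code_map()
  }
  rd <- function(tab, datecols, classes = NA) {
    d <- utils::read.csv(file.path(dir, paste0(tab, ".csv")),
                         stringsAsFactors = FALSE, colClasses = classes)
    for (dc in datecols) d[[dc]] <- as.Date(d[[dc]])
    d
  }
  claims_bundle(
    enrollment = rd("enrollment", c("coverage_start", "coverage_end",
                                    "death_date"),
                    classes = c(sex = "character")),
    prescriptions = rd("prescriptions", "fill_date"),
    diagnoses = rd("diagnoses", "date"),
    procedures = rd("procedures", "date"),
    code_map = code_map)
}
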