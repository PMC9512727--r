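# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# Day-by-day walk of the refill grace-period rule: coverage ends at the
# expected refill date (fill + supply, no stockpiling); a fill accepted only
# while the day is within the grace window; the episode ends when the walk
# passes expected refill + gap, at the expected refill date (discontinued)
# or at the first other-class fill inside the switch window (switched).
oracle_episode <- function(fill_days, supply, other_days = numeric(0),
                           censor = 10000, gap = 60, swin = 60) {
  o <- order(fill_days)
  fill_days <- fill_days[o]
  supply <- rep_len(supply, length(fill_days))[o]
  keep <- fill_days <= censor
  fill_days <- fill_days[keep]; supply <- supply[keep]
  other_days <- other_days[other_days <= censor]
  cur_end <- fill_days[1] + supply[1]
  i <- 2
  day <- fill_days[1]
  repeat {
    day <- day + 1
    while (i <= length(fill_days) && fill_days[i] == day) {
      if (day <= cur_end + gap) cur_end <- day + supply[i]
      i <- i + 1
    }
    if (day > cur_end + gap) {
      sw <- other_days[other_days > cur_end & other_days <= cur_end + swin]
      if (length(sw)) {
        end <- min(sw); reason <- "switched"
      } else {
        end <- cur_end; reason <- "discontinued"
      }
      break
    }
  }
  if (censor < end) {
    end <- censor; reason <- "censored"
  }
  list(end = end, reason = reason)
}

# Transitive closure of the pairwise (same person, same site, <= window days
# apart) relation, via min-label propagation to a fixed point.
oracle_merge <- function(q, window = 90) {
  n <- nrow(q)
  if (!n) return(q[0, c("person_id", "site", "date")])
  d <- as.numeric(q$date)
  same <- outer(seq_len(n), seq_len(n), function(i, j)
    q$person_id[i] == q$person_id[j] & q$site[i] == q$site[j] &
      abs(d[i] - d[j]) <= window)
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[same[i, ]]), numeric(1))
    if (identical(new, comp)) break
    comp <- new
  }
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(ix)
    data.frame(person_id = q$person_id[ix[1]], site = q$site[ix[1]],
               event_date = min(q$date[ix]), stringsAsFactors = FALSE)))
  out <- out[order(out$person_id, out$site, out$event_date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Closed-form weighted least squares via the normal equations.
oracle_wls <- function(x, y, w) {
  X <- cbind(1, x)
  solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1]
}

# Random single-person fill scenario for episode oracle comparisons.
random_fill_case <- function() {
  nf <- sample(1:12, 1)
  gaps <- sample(0:250, nf - 1, replace = TRUE)
  days <- cumsum(c(0, 1 + gaps))
  supply <- sample(1:200, nf, replace = TRUE)
  n_other <- sample(0:3, 1)
  other <- if (n_other) sort(sample(1:1500, n_other)) else numeric(0)
  censor <- if (stats::runif(1) < 0.3)
    sample(seq(max(days), 2500), 1) else 4000
  list(days = days, supply = supply, other = other, censor = censor)
}

# Build a date-based single-person episode via the package and return the
# end offset (days from first fill) and reason.
run_episode_case <- function(case, gap = 60, swin = 60) {
  origin <- as.Date("2013-01-01")
  fills <- data.frame(fill_date = origin + case$days,
                      days_supplied = case$supply)
  other <- if (length(case$other))
    data.frame(fill_date = origin + case$other,
               drug_class = "oral_bisphosphonate", days_supplied = 30)
    else NULL
  ep <- suppressWarnings(build_episode(
    fills, other_fills = other, censor_date = origin + case$censor,
    censor_reason = "censored",
    params = episode_params(gap_days = gap, switch_window_days = swin)))
  list(end = as.numeric(ep$episode_end - origin), reason = ep$end_reason)
}

# Random qualified-diagnosis set for merge oracle comparisons.
random_dx_case <- function() {
  n <- sample(3:10, 1)
  data.frame(
    person_id = sample(c("a", "b", "c"), n, replace = TRUE),
    site = sample(c("hip", "clinical_vertebral", "wrist_forearm"), n,
                  replace = TRUE),
    date = as.Date("2014-01-01") + sample(0:400, n, replace = TRUE),
    source = "inpatient", stringsAsFactors = FALSE)
}

# Minimal hand-built bundle: one row per specification in `persons`, a list
# of lists with fields pid, birth_year, fills (data frame drug_class,
# fill_date, days_supplied), dx, proc.
tiny_bundle <- function(persons, cov_start = "2011-01-01",
                        cov_end = "2018-12-31") {
  en <- do.call(rbind, lapply(persons, function(p)
    data.frame(person_id = p$pid, sex = p$sex %||% "F",
               birth_year = p$birth_year %||% 1945,
               coverage_start = as.Date(p$cov_start %||% cov_start),
               coverage_end = as.Date(p$cov_end %||% cov_end),
               death_date = as.Date(p$death %||% NA),
               stringsAsFactors = FALSE)))
  grab <- function(field, proto) {
    rows <- lapply(persons, function(p) {
      d <- p[[field]]
      if (is.null(d) || !nrow(d)) return(NULL)
      d$person_id <- p$pid
      d
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(proto)
    do.call(rbind, lapply(rows, function(d) d[, names(proto), drop = FALSE]))
  }
  rx0 <- data.frame(person_id = character(), drug_class = character(),
                    fill_date = as.Date(character()),
                    days_supplied = numeric(), stringsAsFactors = FALSE)
  dx0 <- data.frame(person_id = character(), code = character(),
                    date = as.Date(character()), setting = character(),
                    stringsAsFactors = FALSE)
  pr0 <- data.frame(person_id = character(), code = character(),
                    date = as.Date(character()), stringsAsFactors = FALSE)
  claims_bundle(enrollment = en,
                prescriptions = grab("fills", rx0),
                diagnoses = grab("dx", dx0),
                procedures = grab("proc", pr0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fills_df <- function(drug_class, dates, days_supplied) {
  data.frame(drug_class = drug_class, fill_date = as.Date(dates),
             days_supplied = days_supplied, stringsAsFactors = FALSE)
}

dx_df <- function(code, dates, setting = "inpatient") {
  data.frame(code = code, date = as.Date(dates), setting = setting,
             stringsAsFactors = FALSE)
}

proc_df <- function(code, dates) {
  data.frame(code = code, date = as.Date(dates), stringsAsFactors = FALSE)
}

# single-class scenario used by the simulation-based checks
denosumab_scenario <- function(n, seed, r = c(m4_12 = 0.62, m13_24 = 0.50,
                                              m25_36 = 0.44, m37_48 = 0.33),
                               ...) {
  sim_config(
    n_patients = n, seed = seed, hazard_ratio_by_window = r,
    drug_mix = c(denosumab = 1, oral_bisphosphonate = 0, iv_ibandronate = 0,
                 iv_zoledronate = 0, teriparatide = 0, raloxifene = 0,
                 hrt = 0), ...)
}
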