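qdx <- function(person, code, day, setting) {
  data.frame(person_id = person, code = code,
             date = as.Date("2014-01-01") + day, setting = setting,
             stringsAsFactors = FALSE)
}

test_that("the two-arm case definition qualifies diagnoses", {
  dx <- rbind(qdx("p1", "S72.0", 0, "inpatient"),      # qualifies alone
              qdx("p2", "S52.1", 0, "outpatient"),     # no procedure: out
              qdx("p3", "S52.1", 100, "outpatient"),   # procedure day 110
              qdx("p4", "S52.1", 100, "outpatient"))   # procedure day 135: out
  pr <- rbind(proc_df("5-79", as.Date("2014-01-01") + 110),
              proc_df("5-79", as.Date("2014-01-01") + 135))
  pr$person_id <- c("p3", "p4")
  q <- qualify_diagnoses(dx, pr, proc_window_days = 30)
  expect_setequal(q$person_id, c("p1", "p3"))
  expect_equal(q$site[q$person_id == "p1"], "hip")
  expect_equal(q$source[q$person_id == "p3"], "outpatient_plus_procedure")
})

test_that("unmapped codes are ignored and counted", {
  dx <- rbind(qdx("p1", "S72.0", 0, "inpatient"),
              qdx("p1", "Z99.9", 5, "inpatient"))
  q <- qualify_diagnoses(dx, proc_df(character(0), as.Date(character(0))))
  expect_equal(nrow(q), 1)
  expect_equal(attr(q, "n_unmapped"), 1)
})

test_that("same-site diagnoses chain transitively into one event", {
  q1 <- qualify_diagnoses(rbind(qdx("p", "S22.0", 10, "inpatient"),
                                qdx("p", "S22.0", 40, "inpatient")),
                          proc_df(character(0), as.Date(character(0))))
  e1 <- merge_events(q1)
  expect_equal(nrow(e1), 1)
  expect_equal(e1$event_date, as.Date("2014-01-01") + 10)

  ## rolling chain: 0 -> 80 -> 160, each link <= 90 days
  q2 <- qualify_diagnoses(rbind(qdx("p", "S22.0", 0, "inpatient"),
                                qdx("p", "S22.0", 80, "inpatient"),
                                qdx("p", "S22.0", 160, "inpatient")),
                          proc_df(character(0), as.Date(character(0))))
  expect_equal(nrow(merge_events(q2)), 1)

  ## a 91-day gap starts a new event
  q3 <- qualify_diagnoses(rbind(qdx("p", "S22.0", 0, "inpatient"),
                                qdx("p", "S22.0", 91, "inpatient")),
                          proc_df(character(0), as.Date(character(0))))
  expect_equal(nrow(merge_events(q3)), 2)
})

test_that("different body sites never merge", {
  q <- qualify_diagnoses(rbind(qdx("p", "S72.0", 0, "inpatient"),
                               qdx("p", "S52.0", 5, "inpatient")),
                         proc_df(character(0), as.Date(character(0))))
  e <- merge_events(q)
  expect_equal(nrow(e), 2)
  expect_setequal(e$site, c("hip", "wrist_forearm"))
})

test_that("merging is idempotent, order-independent and never increases counts", {
  set.seed(12)
  for (i in 1:60) {
    q <- random_dx_case()
    e1 <- merge_events(q)
    ## idempotence: merging the merged events changes nothing
    e2 <- merge_events(data.frame(person_id = e1$person_id, site = e1$site,
                                  date = e1$event_date, source = e1$source))
    expect_equal(e2[, c("person_id", "site", "event_date")],
                 e1[, c("person_id", "site", "event_date")])
    ## permutation invariance
    e3 <- merge_events(q[sample(nrow(q)), , drop = FALSE])
    expect_equal(e3[, c("person_id", "site", "event_date")],
                 e1[, c("person_id", "site", "event_date")])
    expect_lte(nrow(e1), nrow(q))
    gaps_ok <- all(tapply(as.numeric(q$date), paste(q$person_id, q$site),
                          function(d) all(diff(sort(d)) > 90)))
    expect_equal(nrow(e1) == nrow(q), gaps_ok)
  }
})
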