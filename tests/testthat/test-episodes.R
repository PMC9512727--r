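origin <- as.Date("2013-01-01")

test_that("single fill discontinues at the end of supplied coverage", {
  ep <- build_episode(origin, days_supplied = 30)
  expect_equal(ep$duration_days, 30)
  expect_equal(ep$end_reason, "discontinued")
  expect_equal(ep$supply_end, origin + 30)
})

test_that("a fill within the grace window continues the episode", {
  ## fills day 0 and day 85 with 30-day supply: expected refill day 30,
  ## gap 55 <= 60 -> continuous; next expected refill day 115
  ep <- build_episode(origin + c(0, 85), days_supplied = 30)
  expect_equal(ep$duration_days, 115)
  expect_equal(ep$end_reason, "discontinued")
  ## day 91 would be beyond the grace window
  ep2 <- build_episode(origin + c(0, 91), days_supplied = 30)
  expect_equal(ep2$duration_days, 30)
})

test_that("another class started in the switch window ends the episode as a switch", {
  ep <- build_episode(origin, days_supplied = 180,
                      other_fills = data.frame(fill_date = origin + 200,
                                               drug_class = "oral_bisphosphonate",
                                               days_supplied = 30))
  expect_equal(ep$end_reason, "switched")
  expect_equal(ep$switched_to, "oral_bisphosphonate")
  expect_equal(ep$duration_days, 200)
  ## outside the switch window (day 241 > 180 + 60): discontinuation
  ep2 <- build_episode(origin, days_supplied = 180,
                       other_fills = data.frame(fill_date = origin + 241,
                                                drug_class = "oral_bisphosphonate",
                                                days_supplied = 30))
  expect_equal(ep2$end_reason, "discontinued")
  expect_equal(ep2$duration_days, 180)
})

test_that("a concurrent other-class fill during active supply is ignored", {
  ep <- build_episode(origin + c(0, 185), days_supplied = 180,
                      other_fills = data.frame(fill_date = origin + 100,
                                               drug_class = "raloxifene",
                                               days_supplied = 30))
  expect_equal(ep$end_reason, "discontinued")
  expect_equal(ep$duration_days, 365)
})

test_that("death, disenrollment and study end truncate the episode", {
  ep <- build_episode(origin, days_supplied = 180,
                      censor_date = origin + 100, censor_reason = "death")
  expect_equal(ep$duration_days, 100)
  expect_equal(ep$end_reason, "death")
  ## censoring exactly at the natural end keeps the discontinuation label
  ep2 <- build_episode(origin, days_supplied = 180,
                       censor_date = origin + 180, censor_reason = "death")
  expect_equal(ep2$end_reason, "discontinued")
})

test_that("unsorted or duplicated fills are normalised with a warning", {
  f <- data.frame(fill_date = origin + c(85, 0, 0), days_supplied = 30)
  expect_warning(ep <- build_episode(f), "duplicate")
  expect_equal(ep$duration_days, 115)
})

test_that("lengthening days supplied never shortens the episode", {
  set.seed(42)
  for (i in 1:40) {
    case <- random_fill_case()
    base <- run_episode_case(case)
    longer <- case
    longer$supply <- pmin(case$supply + sample(0:60, length(case$supply),
                                               replace = TRUE), 260)
    ext <- run_episode_case(longer)
    expect_gte(ext$end, base$end)
  }
})

test_that("the episode builder agrees with the day-grid oracle", {
  set.seed(7)
  for (i in 1:150) {
    case <- random_fill_case()
    got <- run_episode_case(case)
    want <- oracle_episode(case$days, case$supply, case$other, case$censor)
    expect_equal(got$end, want$end, info = paste("case", i))
    expect_equal(got$reason, want$reason, info = paste("case", i))
  }
})

test_that("simulated persistence preserves the reported ordering of medians", {
  ## the generator is calibrated so denosumab persistence exceeds oral
  ## bisphosphonates (587 vs 258 days); the episode builder must preserve
  ## that qualitative ordering
  s <- run_study(sim_config(n_patients = 8000, seed = 23),
                 fracture_types = "all")
  d <- duration_summary(s$episodes, s$members)
  d <- d[d$stratum == "overall", ]
  md <- function(g) d$median_days[d$treatment_group == g]
  expect_gt(md("denosumab"), md("oral_bisphosphonate"))
  expect_gt(md("iv_ibandronate"), md("oral_bisphosphonate"))
})

test_that("duration summaries report medians and IQRs by stratum", {
  eps <- data.frame(person_id = c("a", "b", "c"),
                    treatment_group = "denosumab",
                    duration_days = c(100, 200, 300))
  s <- duration_summary(eps)
  expect_equal(s$median_days[s$stratum == "overall"], 200)
  one <- duration_summary(data.frame(person_id = "a",
                                     treatment_group = "hrt",
                                     duration_days = 150))
  expect_equal(one$median_days, 150)
  expect_equal(one$iqr_days, 0)
  mem <- data.frame(person_id = c("a", "b", "c"),
                    prior_osteoporosis_treatment = c(TRUE, TRUE, TRUE))
  s2 <- duration_summary(eps, mem)
  empty_row <- s2[s2$stratum == "no_prior_treatment", ]
  expect_equal(empty_row$n, 0)
  expect_true(is.na(empty_row$median_days))
})
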