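mk_eps <- function(durs) {
  data.frame(person_id = sprintf("p%d", seq_along(durs)),
             duration_days = durs, stringsAsFactors = FALSE)
}

test_that("person-time splits across windows and is conserved", {
  pt <- split_person_time(mk_eps(400))
  expect_equal(pt$days, c(90, 275, 35, 0, 0))
  expect_equal(sum(pt$days), 400)
  expect_equal(split_person_time(mk_eps(90))$days, c(90, 0, 0, 0, 0))
  expect_equal(sum(split_person_time(mk_eps(2000))$days), 1460)
  set.seed(3)
  durs <- sample(0:2500, 200, replace = TRUE)
  pt <- split_person_time(mk_eps(durs))
  expect_equal(sum(pt$days), sum(pmin(durs, 1460)))
  by_person <- tapply(pt$days, pt$person_id, sum)
  expect_equal(as.numeric(by_person[paste0("p", 1:200)]),
               pmin(durs, 1460)[1:200])
  expect_error(split_person_time(mk_eps(-5)), "negative")
})

test_that("window rates are events per 1000 person-years", {
  members <- data.frame(person_id = c("p1", "p2"),
                        index_date = as.Date("2014-01-01"),
                        fx_eligible = TRUE)
  eps <- data.frame(person_id = c("p1", "p2"), duration_days = c(400, 300))
  no_events <- data.frame(person_id = character(), site = character(),
                          event_date = as.Date(character()))
  r0 <- window_rates(members, eps, no_events)
  expect_equal(r0$rate_per_1000py, rep(0, 5))
  ev <- data.frame(person_id = c("p1", "p1", "p2"),
                   site = c("hip", "clinical_vertebral", "hip"),
                   event_date = as.Date("2014-01-01") + c(10, 100, 395))
  r <- window_rates(members, eps, ev)
  expect_equal(r$events, c(1, 1, 0, 0, 0))  # day-395 event is past episode end
  expect_equal(r$person_years[1], 180 / 365.25)
  expect_equal(r$rate_per_1000py[1], 1000 * 1 / (180 / 365.25))
  rh <- window_rates(members, eps, ev, fracture_type = "hip")
  expect_equal(rh$events, c(1, 0, 0, 0, 0))
})

test_that("irr matches the log-scale Wald formula", {
  r <- irr(list(events = 20, person_years = 100),
           list(events = 10, person_years = 100))
  expect_equal(r$irr, 0.5)
  expect_equal(r$method_used, "wald")
  ## independent arithmetic: exp(ln 0.5 +/- 1.96 sqrt(1/10 + 1/20))
  expect_equal(r$ci_low, 0.234, tolerance = 2e-3)
  expect_equal(r$ci_high, 1.068, tolerance = 2e-3)
  eq <- irr(list(events = 30, person_years = 150),
            list(events = 30, person_years = 150))
  expect_equal(eq$irr, 1)
  expect_true(eq$ci_low < 1 && 1 < eq$ci_high)
})

test_that("irr is symmetric and converts to percent reduction", {
  a <- list(events = 17, person_years = 120)
  b <- list(events = 33, person_years = 80)
  expect_equal(irr(a, b)$irr, 1 / irr(b, a)$irr)
  expect_equal(pct_reduction(0.62), 38)
  expect_equal(pct_reduction(c(0.5, 1, 1.25)), c(50, 0, -25))
})

test_that("small counts fall back to the exact-conditional interval", {
  r <- irr(list(events = 20, person_years = 100),
           list(events = 2, person_years = 100))
  expect_equal(r$method_used, "exact")
  expect_true(r$ci_low < r$irr && r$irr < r$ci_high)
  ## exact interval is a transformed Clopper-Pearson on the binomial split
  p_lo <- qbeta(0.025, 2, 21)
  p_hi <- qbeta(0.975, 3, 20)
  expect_equal(r$ci_low, p_lo / (1 - p_lo), tolerance = 1e-10)
  expect_equal(r$ci_high, p_hi / (1 - p_hi), tolerance = 1e-10)
})

test_that("zero early events give a flagged result, not an error", {
  r <- irr(list(events = 0, person_years = 50),
           list(events = 3, person_years = 100))
  expect_true(r$flagged)
  expect_true(is.na(r$irr))
  expect_true(is.finite(r$ci_low))
  expect_error(irr(list(events = 1, person_years = 0),
                   list(events = 1, person_years = 1)), "person-years")
})
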