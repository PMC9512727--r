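mk_rates <- function(rates, py = rep(100, 4)) {
  data.frame(window = c("m4_12", "m13_24", "m25_36", "m37_48"),
             rate_per_1000py = rates, person_years = py,
             stringsAsFactors = FALSE)
}

test_that("the rate trend recovers exact lines and ignores weights when collinear", {
  expect_equal(fit_trend(mk_rates(c(50, 40, 30, 20)))$slope, -10)
  expect_equal(fit_trend(mk_rates(c(33, 33, 33, 33)))$slope, 0)
  ## collinear data: weights cannot change the fit
  tr <- fit_trend(mk_rates(c(60, 50, 40, 30), py = c(4, 3, 2, 1)))
  expect_equal(tr$slope, -10)
  expect_equal(tr$weights_used, "person_years")
})

test_that("weighted least squares matches the closed-form normal equations", {
  set.seed(5)
  for (i in 1:25) {
    y <- rnorm(4, 40, 10)
    w <- runif(4, 1, 50)
    tr <- fit_trend(mk_rates(y, py = w))
    want <- oracle_wls(1:4, y, w)
    expect_equal(unname(coef(tr)), unname(want), tolerance = 1e-9)
  }
})

test_that("equal weights reduce to ordinary least squares", {
  y <- c(48, 41, 29, 26)
  tr_eq <- fit_trend(mk_rates(y), weights = "equal")
  tr_py <- fit_trend(mk_rates(y, py = rep(7, 4)))
  expect_equal(tr_eq$slope, tr_py$slope)
  expect_equal(tr_eq$slope, unname(coef(lm(y ~ x, data.frame(y = y, x = 1:4)))[2]))
})

test_that("fewer than two usable windows is flagged, not an error", {
  r <- mk_rates(c(10, NA, NA, NA), py = c(50, 0, 0, 0))
  tr <- fit_trend(r)
  expect_true(is.na(tr$slope))
  expect_match(tr$note, "fewer than 2")
})

sim_age_table <- function(n_person = 40, seed = 1, beta_age = 0.05,
                          beta_win = c(0, -0.3, -0.5, -0.7, -0.9)) {
  set.seed(seed)
  wins <- analysis_windows()$window
  tab <- expand.grid(person_id = sprintf("p%02d", 1:n_person),
                     window = wins, stringsAsFactors = FALSE)
  tab$person_years <- runif(nrow(tab), 0.05, 1)
  age0 <- runif(n_person, 55, 90)
  tab$age_mid <- age0[match(tab$person_id, sprintf("p%02d", 1:n_person))] +
    match(tab$window, wins) / 2 + runif(nrow(tab), 0, 0.5)
  alpha <- rnorm(n_person, -1, 0.8)
  eta <- alpha[match(tab$person_id, sprintf("p%02d", 1:n_person))] +
    beta_win[match(tab$window, wins)] + beta_age * (tab$age_mid - 70) +
    log(tab$person_years)
  tab$events <- rpois(nrow(tab), exp(eta))
  tab
}

test_that("the conditional likelihood matches Poisson fixed-effects glm", {
  tab <- sim_age_table(seed = 11)
  fit <- fit_age_adjusted(tab)
  expect_true(fit$converged)
  keep <- tab$person_id %in% names(which(tapply(tab$events, tab$person_id,
                                                sum) > 0))
  d <- tab[keep, ]
  g <- glm(events ~ factor(person_id) + factor(window, levels = analysis_windows()$window) +
             age_mid + offset(log(person_years)),
           family = poisson, data = d)
  gc <- coef(g)
  expect_equal(unname(fit$coef["age"]), unname(gc["age_mid"]),
               tolerance = 1e-4)
  gwin <- gc[grepl("factor\\(window", names(gc))]
  expect_equal(unname(fit$coef[1:4]), unname(gwin), tolerance = 1e-4)
})

test_that("conditioning removes per-person baseline rates", {
  tab <- sim_age_table(seed = 13)
  fit1 <- fit_age_adjusted(tab)
  ## scaling one person's person-time (all windows) leaves the fit unchanged
  tab2 <- tab
  one <- tab2$person_id == "p05"
  tab2$person_years[one] <- tab2$person_years[one] * 37
  fit2 <- fit_age_adjusted(tab2)
  expect_equal(fit1$coef, fit2$coef, tolerance = 1e-5)
})

test_that("a single informative person degenerates to a flagged fit", {
  tab <- data.frame(person_id = "p1",
                    window = c("early", "m4_12"),
                    events = c(1L, 2L), person_years = c(0.2, 0.7),
                    age_mid = c(70, 70.5))
  fit <- fit_age_adjusted(tab)
  expect_false(fit$converged)
  expect_match(fit$note, "degenerate")
})

test_that("a null age effect is recovered as an IRR near one", {
  tab <- sim_age_table(n_person = 300, seed = 17, beta_age = 0)
  fit <- fit_age_adjusted(tab)
  expect_true(fit$converged)
  expect_true(fit$irr_age_ci[1] <= 1 && 1 <= fit$irr_age_ci[2])
})
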