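person <- function(pid, fills, dx = NULL, proc = NULL, birth_year = 1945,
                   sex = "F", ...) {
  c(list(pid = pid, fills = fills, dx = dx, proc = proc,
         birth_year = birth_year, sex = sex), list(...))
}

test_that("age at index is computed from birth year and enforced at 50", {
  ## mid-year convention: born 1965 -> 49.9 years on 2015-06-01 (excluded);
  ## born 1964 -> 50.9 (included)
  b <- tiny_bundle(list(
    person("p1", fills_df("denosumab", "2015-06-01", 180), birth_year = 1965),
    person("p2", fills_df("denosumab", "2015-06-01", 180), birth_year = 1964)))
  sel <- select_cohort(b)
  expect_equal(sel$members$person_id, "p2")
  age_row <- sel$attrition[grepl("age >=", sel$attrition$criterion), ]
  expect_equal(age_row$n_excluded, 1)
})

test_that("new-user washout excludes recent index-class fills only", {
  ## same-class fill ~23 months pre-index -> excluded; ~25 months -> kept
  b <- tiny_bundle(list(
    person("p1", fills_df("denosumab", c("2011-07-01", "2013-06-01"),
                          c(180, 180))),
    person("p2", fills_df("denosumab", c("2011-05-01", "2013-06-01"),
                          c(180, 180)))))
  sel <- select_cohort(b)
  expect_equal(sel$members$person_id, "p2")
  expect_equal(sel$members$index_date, as.Date("2013-06-01"))
})

test_that("exclusion conditions anywhere in pre-index history exclude", {
  b <- tiny_bundle(list(
    person("p1", fills_df("oral_bisphosphonate", "2014-03-01", 30),
           dx = dx_df("C50.9", "2011-06-01", "outpatient")),
    person("p2", fills_df("oral_bisphosphonate", "2014-03-01", 30)),
    person("p3", fills_df("oral_bisphosphonate", "2014-03-01", 30),
           dx = dx_df("Q78.0", "2012-02-01", "outpatient"))))
  sel <- select_cohort(b)
  expect_equal(sel$members$person_id, "p2")
})

test_that("hierarchical assignment follows the priority order", {
  b <- tiny_bundle(list(
    person("p1", rbind(fills_df("oral_bisphosphonate", "2014-02-01", 30),
                       fills_df("denosumab", "2015-06-01", 180))),
    person("p2", fills_df("hrt", "2014-05-01", 90)),
    person("p3", rbind(fills_df("iv_ibandronate", "2013-05-01", 90),
                       fills_df("iv_zoledronate", "2014-01-01", 365)))))
  sel <- select_cohort(b)
  m <- sel$members
  expect_equal(m$treatment_group[m$person_id == "p1"], "denosumab")
  expect_equal(m$index_date[m$person_id == "p1"], as.Date("2015-06-01"))
  expect_equal(m$treatment_group[m$person_id == "p2"], "hrt")
  ## within the IV tier the first-filled sub-class wins
  expect_equal(m$treatment_group[m$person_id == "p3"], "iv_ibandronate")
  expect_equal(m$index_date[m$person_id == "p3"], as.Date("2013-05-01"))
})

test_that("oestrogen-only fills qualify as HRT only after hysterectomy", {
  b <- tiny_bundle(list(
    person("p1", fills_df("estrogen_only", "2014-05-01", 90)),
    person("p2", fills_df("estrogen_only", "2014-05-01", 90),
           proc = proc_df("5-683", "2012-01-01"))))
  sel <- select_cohort(b)
  expect_equal(sel$members$person_id, "p2")
  expect_equal(sel$members$treatment_group, "hrt")
})

test_that("cohort selection is invariant to input row order and partitions persons", {
  cfg <- sim_config(n_patients = 600, seed = 31)
  b <- generate_bundle(cfg)
  sel1 <- select_cohort(b)
  set.seed(99)
  b2 <- b
  for (tab in c("prescriptions", "diagnoses", "procedures"))
    b2[[tab]] <- b2[[tab]][sample(nrow(b2[[tab]])), , drop = FALSE]
  sel2 <- select_cohort(b2)
  o1 <- sel1$members[order(sel1$members$person_id), ]
  o2 <- sel2$members[order(sel2$members$person_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  expect_equal(anyDuplicated(sel1$members$person_id), 0)
  expect_true(all(diff(sel1$attrition$n_after) <= 0))
  expect_equal(sel1$attrition$n_before[-1],
               sel1$attrition$n_after[-nrow(sel1$attrition)])
})

test_that("baseline covariates come strictly from the pre-index lookback", {
  b <- tiny_bundle(list(
    person("p1", fills_df("denosumab", "2015-06-01", 180)),
    person("p2", fills_df("denosumab", "2015-06-01", 180),
           dx = dx_df("S22.0", "2014-12-01", "inpatient")),   # 6 months before
    person("p3", rbind(fills_df("raloxifene", "2014-06-01", 30),
                       fills_df("denosumab", "2015-06-01", 180))),
    person("p4", fills_df("denosumab", "2015-06-01", 180),
           dx = dx_df("S22.0", "2015-08-01", "inpatient"))))  # post-index
  sel <- select_cohort(b)
  m <- baseline_covariates(sel$members, b)
  get <- function(p, col) m[[col]][m$person_id == p]
  expect_false(get("p1", "prior_fracture"))
  expect_false(get("p1", "prior_osteoporosis_treatment"))
  expect_true(get("p2", "prior_fracture"))
  expect_true(get("p2", "prior_vertebral"))
  expect_false(get("p2", "prior_hip"))
  expect_true(get("p3", "prior_osteoporosis_treatment"))
  expect_false(get("p4", "prior_fracture"))
})

test_that("empty bundles give an empty cohort with a full attrition table", {
  b <- generate_bundle(sim_config(n_patients = 0))
  sel <- select_cohort(b)
  expect_equal(nrow(sel$members), 0)
  expect_gte(nrow(sel$attrition), 5)
  expect_true(all(sel$attrition$n_after == 0))
})
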