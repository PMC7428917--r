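mc <- toy_med_classes()

test_that("index date requires an asthma code with a same-day asthma medication", {
  r <- toy_record(list(
    list(day = 0, dx = "493.90", meds = "fluticasone")))
  expect_equal(find_index_date(r, mc), as.Date("2010-01-01"))

  # first asthma visit lacks the co-prescription; second qualifies
  r <- toy_record(list(
    list(day = 0, dx = "493.90"),
    list(day = 7, dx = "493.90", meds = "albuterol")))
  expect_equal(find_index_date(r, mc), as.Date("2010-01-08"))

  # OCS alone does not qualify as an asthma medication
  r <- toy_record(list(list(day = 0, dx = "493.90", meds = "prednisone")))
  expect_null(find_index_date(r, mc))

  # no asthma code anywhere
  r <- toy_record(list(list(day = 0, dx = "401.9", meds = "albuterol")))
  expect_null(find_index_date(r, mc))

  # unknown medication is treated as non-asthma, not an error
  r <- toy_record(list(list(day = 0, dx = "493.90", meds = "mystery_drug")))
  expect_null(find_index_date(r, mc))
})

test_that("exacerbation requires primary asthma dx at ED/inpatient plus same-day OCS", {
  base <- list(list(day = 0, dx = "493.90", meds = "albuterol"))
  idx <- as.Date("2010-01-01")

  r <- toy_record(c(base, list(list(day = 30, dx = "493.92", primary = 1L,
                                    enc = "ED", meds = "prednisone"))))
  expect_equal(find_exacerbation_date(r, idx, mc), idx + 30)

  # missing the OCS
  r <- toy_record(c(base, list(list(day = 30, dx = "493.92", primary = 1L,
                                    enc = "ED"))))
  expect_null(find_exacerbation_date(r, idx, mc))

  # outpatient encounter fails the setting condition
  r <- toy_record(c(base, list(list(day = 30, dx = "493.92", primary = 1L,
                                    enc = "OUTPATIENT",
                                    meds = "prednisone"))))
  expect_null(find_exacerbation_date(r, idx, mc))

  # asthma dx not primary
  r <- toy_record(c(base, list(list(day = 30, dx = "493.92", primary = 0L,
                                    enc = "ED", meds = "prednisone"))))
  expect_null(find_exacerbation_date(r, idx, mc))

  # the index-date visit itself never qualifies (strictly after)
  r <- toy_record(list(list(day = 0, dx = c("493.90"), primary = 1L,
                            enc = "ED",
                            meds = c("albuterol", "prednisone"))))
  expect_null(find_exacerbation_date(r, idx, mc))
})

test_that("365-day labeling is inclusive at the boundary", {
  d0 <- as.Date("2010-01-01")
  expect_equal(assign_label(d0, d0 + 100), "case")
  expect_equal(assign_label(d0, d0 + 365), "case")
  expect_equal(assign_label(d0, d0 + 366), "control")
  expect_equal(assign_label(d0, d0 + 400), "control")
  expect_equal(assign_label(d0, NULL), "control")
})

test_that("label function agrees with a brute-force scan on random toy records", {
  set.seed(42)
  for (k in 1:25) {
    n <- sample(3:8, 1)
    days <- sort(sample(0:500, n))
    has_exac <- sample(c(TRUE, FALSE), 1)
    exac_day <- if (has_exac) max(days) + sample(1:200, 1) else NULL
    vs <- c(list(list(day = 0L, dx = "493.90", meds = "albuterol")),
            lapply(days[-1], function(d) list(day = d, dx = "SYM.1")))
    if (has_exac) vs[[length(vs) + 1L]] <-
        list(day = exac_day, dx = "493.92", primary = 1L, enc = "ED",
             meds = "prednisone")
    r <- toy_record(vs)
    idx <- find_index_date(r, mc)
    exc <- find_exacerbation_date(r, idx, mc)
    got <- assign_label(idx, exc)
    # brute force: scan all visit-date pairs for the defining pattern
    want <- "control"
    if (has_exac && exac_day <= 365) want <- "case"
    expect_identical(got, want)
  }
})

test_that("prediction dates follow the mode-specific rules", {
  d0 <- as.Date("2010-01-01")
  # case, training: visit before the exacerbation date
  dates <- d0 + c(0, 10, 20, 30)
  expect_equal(prediction_date(dates, d0, d0 + 40, "case", "training"),
               d0 + 30)
  # testA: the fifth visit counting the index visit as first
  dates <- d0 + c(0, 5, 9, 14, 21, 30)
  expect_equal(prediction_date(dates, d0, NULL, "control", "testA"),
               d0 + 21)
  # testB / training control: penultimate visit within 365 days
  dates <- d0 + c(0, 5, 9, 14, 21)
  expect_equal(prediction_date(dates, d0, NULL, "control", "testB"),
               d0 + 14)
  # a late visit beyond the 365-day horizon is ignored for the penultimate rule
  dates <- d0 + c(0, 5, 9, 14, 21, 400)
  expect_equal(prediction_date(dates, d0, NULL, "control", "training"),
               d0 + 14)
  # testA with a case whose exacerbation precedes the fifth visit: excluded
  dates <- d0 + c(0, 5, 9, 14, 21, 30)
  pd <- prediction_date(dates, d0, d0 + 12, "case", "testA")
  expect_true(is.na(pd))
  expect_equal(attr(pd, "reason"), "exacerbation_before_fifth_visit")
})

test_that("exclusion filters fire in order with an audited reason", {
  mk <- function(n_visits, age = 40L, gender = "M", exac_day = NULL) {
    tb <- toy_tables(toy_asthma_visits(n_visits, exac_day), age = age,
                     gender = gender)
    tb
  }
  cases <- list(
    list(tb = mk(4), retained = FALSE, reason = "visits<5"),
    list(tb = mk(6), retained = TRUE, reason = ""),
    list(tb = mk(6, age = 17L), retained = FALSE, reason = "age"),
    list(tb = mk(6, age = 18L), retained = TRUE, reason = ""),
    list(tb = mk(6, age = 80L), retained = TRUE, reason = ""),
    list(tb = mk(6, age = 81L), retained = FALSE, reason = "age"),
    list(tb = mk(6, gender = "U"), retained = FALSE, reason = "gender")
  )
  for (cs in cases) {
    rec <- as_patient_records(cs$tb$patients, cs$tb$events)
    res <- apply_inclusion_exclusion(rec, mc)
    expect_identical(res$audit$retained, cs$retained)
    expect_identical(res$audit$reason, cs$reason)
  }

  # unparseable time stamps
  tb <- mk(6)
  tb$events$date[3] <- "not-a-date"
  res <- apply_inclusion_exclusion(as_patient_records(tb$patients, tb$events), mc)
  expect_false(res$audit$retained)
  expect_identical(res$audit$reason, "time")
})

test_that("filtering conserves patients and relaxing the visit threshold is monotone", {
  sim <- generate_cohort(sim_config(60, seed = 31))
  # perturb some patients so filters actually fire
  sim$patients$age_years[1:5] <- c(17L, 81L, 99L, 16L, 85L)
  sim$patients$gender[6:8] <- "U"
  rec <- as_patient_records(sim$patients, sim$events)
  res5 <- apply_inclusion_exclusion(rec, read_med_classes(), min_visits = 5L)
  res4 <- apply_inclusion_exclusion(rec, read_med_classes(), min_visits = 4L)
  expect_identical(length(res5$cohort) + sum(!res5$audit$retained), 60L)
  expect_true(all(res5$audit$reason[!res5$audit$retained] != ""))
  expect_gte(length(res4$cohort), length(res5$cohort))
})

test_that("window visits fall inside [index, prediction] and case windows end before exacerbation", {
  sim <- generate_cohort(sim_config(
    80, planted_factors = list(planted_factor("R", 3, prevalence = 0.6)),
    seed = 13))
  ch <- build_cohort(sim$patients, sim$events, read_med_classes())
  for (s in ch$cohort) {
    dates <- as.Date(vapply(s$window_visits,
                            function(v) as.integer(v$date), integer(1)),
                     origin = "1970-01-01")
    expect_true(all(dates >= s$index_date & dates <= s$prediction_date))
    if (s$label == 1L) {
      expect_true(s$exacerbation_date > s$prediction_date)
      expect_lte(as.numeric(s$exacerbation_date - s$index_date), 365)
    }
  }
})
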