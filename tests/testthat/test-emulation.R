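test_that("method specs freeze time zero, exclusions and covariates", {
  m1 <- method_spec("method1")
  m2 <- method_spec("method2")
  m3 <- method_spec("method3")
  expect_false(m1$exclude_first_interval_cvd)
  expect_equal(m1$time_zero, "enrolment")
  expect_equal(m1$modelled_intervals, 1:10)
  expect_true(all(c("smoking0", "diuretics0") %in% m1$covariate_set))
  expect_false(any(c("smoking1", "diuretics1") %in% m1$covariate_set))

  expect_equal(m2$time_zero, "first_followup")
  expect_true(m2$exclude_first_interval_cvd)
  expect_true(m2$reindex)
  # modelled follow-up spans 18 years on a re-indexed clock
  expect_equal(length(m2$modelled_intervals) * 2, 18)
  expect_false(any(c("smoking0", "diuretics0") %in% m2$covariate_set))

  expect_equal(m3$time_zero, "enrolment")
  expect_true(all(c("smoking0", "smoking1", "diuretics0", "diuretics1")
                  %in% m3$covariate_set))
  expect_equal(m3$baseline_period_years, 2)
  expect_error(method_spec("method4"))
})

test_that("exclusions drop exactly the first-interval cases required", {
  co <- small_cohort(n = 1500, seed = 9)
  n1 <- sum(co$subjects$event_interval == 1L, na.rm = TRUE)
  expect_gt(n1, 0)

  ex1 <- apply_exclusions(co, method_spec("method1"))
  expect_equal(nrow(ex1$subjects), 1500)
  expect_equal(sum(ex1$exclusions), 0)

  ex3 <- apply_exclusions(co, method_spec("method3"))
  expect_equal(nrow(ex3$subjects), 1500 - n1)
  expect_equal(unname(ex3$exclusions["first_interval_cvd"]), n1)

  # chronic exclusion as an additional, separately counted rule
  exc <- apply_exclusions(co, method_spec("method3",
                                          exclude_first_interval_chronic = TRUE))
  extra <- sum(co$subjects$chronic1 == 1L &
               (is.na(co$subjects$event_interval) |
                co$subjects$event_interval > 1L))
  expect_equal(unname(exc$exclusions["first_interval_chronic"]), extra)

  # hand-built five-subject cohort, subject 2 has a first-interval event
  hand <- manual_cohort(manual_subjects(c(NA, 1L, 3L, NA, 10L)))
  kept <- apply_exclusions(hand, method_spec("method3"))
  expect_equal(kept$subjects$id, c(1L, 3L, 4L, 5L))

  # vacuous exclusion leaves the cohort untouched
  none <- manual_cohort(manual_subjects(c(NA, NA, 5L)))
  expect_equal(nrow(apply_exclusions(none, method_spec("method2"))$subjects), 3)
})

test_that("person-period expansion follows each method's clock", {
  # single event-free subject, method 1: 10 records, all event = 0
  one <- manual_cohort(manual_subjects(NA))
  pp1 <- expand_person_periods(one, method_spec("method1"))
  expect_equal(nrow(pp1), 10)
  expect_equal(pp1$interval, 1:10)
  expect_true(all(pp1$event == 0))

  # single subject with event in interval 3, method 2: re-indexed 1..2
  ev3 <- manual_cohort(manual_subjects(3L))
  pp2 <- expand_person_periods(ev3, method_spec("method2"))
  expect_equal(pp2$interval, c(1L, 2L))
  expect_equal(pp2$event, c(0L, 1L))

  # same subject under method 3 keeps the enrolment clock
  pp3 <- expand_person_periods(ev3, method_spec("method3"))
  expect_equal(pp3$interval, c(2L, 3L))
  expect_equal(pp3$event, c(0L, 1L))

  # 100 event-free subjects, method 3: 100 x intervals 2..10
  many <- manual_cohort(manual_subjects(rep(NA_integer_, 100)))
  expect_equal(nrow(expand_person_periods(many, method_spec("method3"))), 900)

  # event indicator only in the final at-risk interval
  ev7 <- manual_cohort(manual_subjects(7L))
  pp <- expand_person_periods(ev7, method_spec("method1"))
  expect_equal(sum(pp$event), 1)
  expect_equal(pp$interval[pp$event == 1], 7L)

  bad <- manual_cohort(manual_subjects(12L))
  expect_error(expand_person_periods(bad, method_spec("method1")),
               "event_interval")
})

test_that("method 1 populates exposure from the future weight change", {
  co <- small_cohort(n = 200, seed = 14)
  pp <- expand_person_periods(co, method_spec("method1"))
  first <- pp[pp$interval == 1L, ]
  s <- co$subjects
  expect_equal(first$exposure_loss, as.integer(s$change_category == "loss"))
  # methods 2 and 3 never model interval 1
  for (m in c("method2", "method3")) {
    sp <- method_spec(m)
    ppm <- expand_person_periods(apply_exclusions(co, sp), sp)
    native <- if (sp$reindex) ppm$interval + 1L else ppm$interval
    expect_true(all(native >= 2L))
  }
})

test_that("methods 2 and 3 share subjects and risk sets", {
  co <- small_cohort(n = 1200, seed = 16)
  sp2 <- method_spec("method2"); sp3 <- method_spec("method3")
  ex2 <- apply_exclusions(co, sp2); ex3 <- apply_exclusions(co, sp3)
  expect_identical(ex2$subjects$id, ex3$subjects$id)
  pp2 <- expand_person_periods(ex2, sp2)
  pp3 <- expand_person_periods(ex3, sp3)
  expect_equal(nrow(pp2), nrow(pp3))
  # identical risk sets interval by interval once clocks are aligned
  expect_identical(table(pp2$interval + 1L), table(pp3$interval))
  expect_identical(pp2$event, pp3$event)
})

test_that("row counts match the brute-force per-subject loop", {
  set.seed(99)
  for (seed in 1:25) {
    n <- sample(2:20, 1)
    co <- simulate_cohort(sim_params(n_subjects = n), seed = seed)
    m <- sample(c("method1", "method2", "method3"), 1)
    sp <- method_spec(m)
    ex <- apply_exclusions(co, sp)
    if (nrow(ex$subjects) == 0) next
    pp <- expand_person_periods(ex, sp)
    expect_equal(nrow(pp), oracle_pp_count(ex$subjects, sp))
  }
})
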