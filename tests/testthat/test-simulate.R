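test_that("simulation is deterministic in (params, seed)", {
  p <- sim_params(n_subjects = 300)
  a <- simulate_cohort(p, seed = 42)
  b <- simulate_cohort(p, seed = 42)
  expect_identical(a$subjects, b$subjects)
  # byte-identical on disk too
  fa <- tempfile(); fb <- tempfile()
  write_cohort(a, fa); write_cohort(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_false(identical(simulate_cohort(p, seed = 43)$subjects, a$subjects))
})

test_that("subjects respect eligibility and exposure-definition invariants", {
  co <- small_cohort(n = 2000, seed = 3)
  s <- co$subjects
  expect_true(all(s$bmi0 >= 25 & s$bmi0 < 29.9))
  expect_equal(s$bmi0, s$weight0 / s$height^2, tolerance = 1e-12)
  frac <- (s$weight1 - s$weight0) / s$weight0
  expect_true(all(s$change_category[frac <= -0.05] == "loss"))
  expect_true(all(s$change_category[frac >= 0.05] == "gain"))
  expect_true(all(s$change_category[abs(frac) < 0.05] == "maintain"))
  # weight1 exists for everyone, including first-interval cases
  expect_false(any(is.na(s$weight1)))
  # all three exposure groups are estimable
  expect_true(all(table(s$change_category) / nrow(s) >= 0.10))
})

test_that("first-interval events occur and match the marginal hazard", {
  p <- sim_params()
  co <- simulate_cohort(p, seed = 8)
  s <- co$subjects
  n1 <- sum(s$event_interval == 1L, na.rm = TRUE)
  expect_gt(n1, 0)
  # recompute the interval-1 marginal hazard from params and covariates
  ce <- p$confounder_effects$hazard
  lp <- p$baseline_hazard_logits[1] +
    ce[["smoking0"]] * s$smoking0 + ce[["diuretics0"]] * s$diuretics0 +
    ce[["age0"]] * (s$age0 - 52.5) + ce[["sex"]] * s$sex +
    ce[["famhist"]] * s$famhist + ce[["weight0"]] * (s$weight0 - 80) +
    p$chronic_disease_params$on_hazard * s$chronic1
  expected <- sum(plogis(lp))
  expect_lt(abs(n1 - expected), 4 * sqrt(expected))
})

test_that("null-confounding cohorts have exposure independent of confounders", {
  co <- simulate_cohort(zero_confounding(sim_params(n_subjects = 4000)),
                        seed = 21)
  s <- co$subjects
  p <- suppressWarnings(
    chisq.test(table(s$change_category, s$smoking1))$p.value)
  expect_gt(p, 0.001)
  p2 <- suppressWarnings(
    chisq.test(table(s$change_category, s$chronic1))$p.value)
  expect_gt(p2, 0.001)
})

test_that("event frequency among gainers rises with the true gain effect", {
  freqs <- sapply(c(0, 0.4, 0.8), function(eff) {
    co <- simulate_cohort(sim_params(n_subjects = 3000,
                                     true_gain_effect = eff), seed = 77)
    s <- co$subjects
    mean(!is.na(s$event_interval[s$change_category == "gain"]))
  })
  expect_true(all(diff(freqs) > 0))
})

test_that("equal risks across groups when effects and confounding are off", {
  p0 <- zero_confounding(sim_params(n_subjects = 6000, true_gain_effect = 0))
  s <- simulate_cohort(p0, seed = 13)$subjects
  risks <- tapply(!is.na(s$event_interval), s$change_category, mean)
  overall <- mean(!is.na(s$event_interval))
  se <- sqrt(overall * (1 - overall) / min(table(s$change_category)))
  expect_true(all(abs(risks - overall) < 4 * se))
})

test_that("cohort files round-trip and are validated on read", {
  co <- small_cohort(n = 100, seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$subjects, co$subjects, tolerance = 1e-12)
  expect_equal(back$params$n_subjects, 100L)
  expect_equal(back$seed_used, 5L)

  # missing column
  tab <- read.delim(path)
  broken <- tempfile(fileext = ".tsv")
  write.table(tab[, setdiff(names(tab), "change_category")], broken,
              sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(broken), "change_category")

  # eligibility violation is caught and names the row
  tab2 <- read.delim(path)
  tab2$bmi0[3] <- 31
  broken2 <- tempfile(fileext = ".tsv")
  write.table(tab2, broken2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(broken2), "row 3.*eligibility|eligibility")
})
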