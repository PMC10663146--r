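#' Simulate a confounded overweight cohort
#'
#' Draws a cohort from the discrete-time data-generating process described
#' in [sim_params()].  For each subject: fixed covariates (age uniform on
#' 45-60, sex, family history; BMI uniform on 25-29.9 converted to kg via
#' a sex-specific height draw), enrolment confounders (smoking, diuretic
#' use), first-follow-up confounders drawn conditionally on their
#' enrolment values, an interval-1 chronic-disease indicator, a
#' three-level weight-change category from a multinomial logit in all of
#' the above, a year-2 weight consistent with that category, and a CVD
#' event interval from the per-interval logistic hazard.  Exposure and the
#' follow-up confounders enter the hazard only from interval 2 onwards;
#' the chronic disease raises the interval-1 hazard only.  No subject dies
#' or is censored before the outcome.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; identical \code{(params, seed)} give an
#'   identical cohort.  Defaults to \code{params$master_seed}.
#' @return An object of class \code{tte_cohort}: a list with
#'   \code{subjects} (data frame, one row per subject), \code{params} and
#'   \code{seed_used}.
#' @examples
#' co <- simulate_cohort(sim_params(n_subjects = 200), seed = 1)
#' table(co$subjects$change_category)
#' @export
simulate_cohort <- function(params = sim_params(),
                            seed = params$master_seed) {
  validate_params(params)
  n <- params$n_subjects
  K <- params$n_intervals
  cp <- params$covariate_params
  ce <- params$confounder_effects
  cd <- params$chronic_disease_params

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  age0 <- stats::runif(n, 45, 60)
  sex <- stats::rbinom(n, 1L, cp$p_sex)              # 1 = male
  famhist <- stats::rbinom(n, 1L, cp$p_famhist)
  bmi0 <- stats::runif(n, 25, 29.9)
  height <- ifelse(sex == 1L,
                   stats::rnorm(n, 1.77, 0.07),
                   stats::rnorm(n, 1.63, 0.06))
  weight0 <- bmi0 * height^2
  smoking0 <- stats::rbinom(n, 1L, cp$p_smoking0)
  diuretics0 <- stats::rbinom(n, 1L, cp$p_diuretics0)

  smoking1 <- ifelse(smoking0 == 1L,
                     stats::rbinom(n, 1L, 1 - cp$smoke_cessation),
                     stats::rbinom(n, 1L, cp$smoke_initiation))
  p_diur1 <- stats::plogis(cp$diur1_intercept +
                           cp$diur1_on_diuretics0 * diuretics0 +
                           cp$diur1_on_age * (age0 - AGE_CENTER))
  diuretics1 <- stats::rbinom(n, 1L, p_diur1)
  chronic1 <- stats::rbinom(n, 1L, cd$incidence)

  X <- cbind(smoking0 = smoking0, diuretics0 = diuretics0,
             smoking1 = smoking1, diuretics1 = diuretics1,
             age0 = age0 - AGE_CENTER, sex = sex, famhist = famhist,
             weight0 = weight0 - WEIGHT0_CENTER)
  cn <- confounder_names()

  # three-category exposure: multinomial logit, maintenance as reference
  lp_loss <- params$exposure_intercepts[["loss"]] +
    drop(X %*% ce$exposure_loss[cn]) + cd$on_loss * chronic1
  lp_gain <- params$exposure_intercepts[["gain"]] +
    drop(X %*% ce$exposure_gain[cn]) + cd$on_gain * chronic1
  e_loss <- exp(lp_loss); e_gain <- exp(lp_gain)
  denom <- 1 + e_loss + e_gain
  u <- stats::runif(n)
  change_category <- ifelse(u < e_loss / denom, "loss",
                     ifelse(u < (e_loss + e_gain) / denom, "gain",
                            "maintain"))

  # year-2 weight drawn uniformly within the category's band
  thr <- params$change_threshold
  frac <- stats::runif(n)  # one uniform per subject, mapped per category
  change_frac <- ifelse(change_category == "loss",
                        -thr - frac * 2 * thr,
                 ifelse(change_category == "gain",
                        thr + frac * 2 * thr,
                        -thr + frac * 2 * thr * 0.999 + thr * 0.001))
  weight1 <- weight0 * (1 + change_frac)

  # discrete-time hazard; exposure and measurement-1 covariates act from
  # interval 2, chronic disease acts on interval 1 only
  bh <- ce$hazard[cn]
  lp_c0 <- drop(X[, c("smoking0", "diuretics0", "age0", "sex", "famhist",
                      "weight0"), drop = FALSE] %*%
                bh[c("smoking0", "diuretics0", "age0", "sex", "famhist",
                     "weight0")])
  lp_c1 <- drop(X[, c("smoking1", "diuretics1"), drop = FALSE] %*%
                bh[c("smoking1", "diuretics1")])
  expo <- params$true_loss_effect * (change_category == "loss") +
    params$true_gain_effect * (change_category == "gain")
  base <- params$baseline_hazard_logits
  lp1 <- base[1] + lp_c0 + cd$on_hazard * chronic1
  haz <- matrix(0, n, K)
  haz[, 1] <- stats::plogis(lp1)
  for (t in 2:K)
    haz[, t] <- stats::plogis(base[t] + lp_c0 + lp_c1 + expo)
  U <- matrix(stats::runif(n * K), n, K)
  ev <- U < haz
  first <- apply(ev, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1] else NA_integer_
  })

  subjects <- data.frame(
    id = seq_len(n), age0 = age0, sex = sex, famhist = famhist,
    height = height, weight0 = weight0, bmi0 = bmi0,
    smoking0 = smoking0, diuretics0 = diuretics0,
    smoking1 = smoking1, diuretics1 = diuretics1, chronic1 = chronic1,
    weight1 = weight1,
    change_category = categorise_change(weight0, weight1, thr),
    event_interval = as.integer(first))
  stopifnot(identical(subjects$change_category, change_category))

  structure(list(subjects = subjects, params = params,
                 seed_used = as.integer(seed)),
            class = "tte_cohort")
}

#' Classify relative weight change at the +/- threshold
#'
#' @param weight0,weight1 Weights (kg) at enrolment and first follow-up.
#' @param threshold Relative-change threshold (default 0.05): change
#'   <= -threshold is \code{"loss"}, >= +threshold is \code{"gain"},
#'   otherwise \code{"maintain"}.
#' @return Character vector.
#' @export
categorise_change <- function(weight0, weight1, threshold = 0.05) {
  frac <- (weight1 - weight0) / weight0
  ifelse(frac <= -threshold, "loss",
         ifelse(frac >= threshold, "gain", "maintain"))
}

#' @export
print.tte_cohort <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("Simulated overweight cohort: %d subjects, %d intervals (seed %d)\n",
              nrow(s), x$params$n_intervals, x$seed_used))
  tab <- table(factor(s$change_category,
                      levels = c("loss", "maintain", "gain")))
  cat("  exposure: ", paste(sprintf("%s %.1f%%", names(tab),
                                    100 * tab / nrow(s)), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  events: %d (%.1f%%), of which %d in interval 1\n",
              sum(!is.na(s$event_interval)),
              100 * mean(!is.na(s$event_interval)),
              sum(s$event_interval == 1L, na.rm = TRUE)))
  invisible(x)
}

cohort_columns <- c("id", "age0", "sex", "famhist", "height", "weight0",
                    "bmi0", "smoking0", "diuretics0", "smoking1",
                    "diuretics1", "chronic1", "weight1", "change_category",
                    "event_interval")

#' Write / read a cohort as delimited text
#'
#' The subject table is written as a tab-separated file with the
#' documented column contract (one row per subject, columns exactly the
#' \code{Subject} fields, \code{event_interval} empty for event-free
#' subjects) and the parameters as a JSON sidecar at
#' \code{<path>.params.json}.  \code{read_cohort()} validates eligibility
#' (BMI 25-29.9) and category consistency and reports the first offending
#' row or missing column.
#'
#' @param cohort A \code{tte_cohort}.
#' @param path File path for the subject table.
#' @return \code{write_cohort()} returns \code{path} invisibly;
#'   \code{read_cohort()} returns a \code{tte_cohort}.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "tte_cohort"))
  utils::write.table(cohort$subjects[, cohort_columns], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- paste0(path, ".params.json")
  meta <- unclass(cohort$params)
  meta$confounder_effects <- lapply(meta$confounder_effects, as.list)
  meta$exposure_intercepts <- as.list(meta$exposure_intercepts)
  meta$seed_used <- cohort$seed_used
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  subjects <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(cohort_columns, names(subjects))
  if (length(missing))
    stop("cohort file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(subjects$bmi0 < 25 | subjects$bmi0 >= 29.9)
  if (length(bad))
    stop("row ", bad[1], ": bmi0 = ", subjects$bmi0[bad[1]],
         " violates eligibility (BMI must lie in [25, 29.9))")
  sidecar <- paste0(path, ".params.json")
  params <- NULL
  seed_used <- NA_integer_
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    seed_used <- meta$seed_used
    meta$seed_used <- NULL
    meta$confounder_effects <- lapply(meta$confounder_effects, unlist)
    meta$exposure_intercepts <- unlist(meta$exposure_intercepts)
    params <- structure(meta, class = "sim_params")
    params$n_subjects <- as.integer(params$n_subjects)
    params$n_intervals <- as.integer(params$n_intervals)
    params$master_seed <- as.integer(params$master_seed)
    validate_params(params)
    recat <- categorise_change(subjects$weight0, subjects$weight1,
                               params$change_threshold)
    bad <- which(recat != subjects$change_category)
    if (length(bad))
      stop("row ", bad[1], ": change_category '",
           subjects$change_category[bad[1]],
           "' inconsistent with weights (expected '", recat[bad[1]], "')")
    if (nrow(subjects) != params$n_subjects)
      stop("cohort file has ", nrow(subjects),
           " subjects but params say ", params$n_subjects)
  }
  subjects$event_interval <- as.integer(subjects$event_interval)
  structure(list(subjects = subjects, params = params,
                 seed_used = as.integer(seed_used)),
            class = "tte_cohort")
}
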