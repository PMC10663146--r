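# Emulation strategies: each method fixes a time zero, an exclusion rule
# and a covariate set, then expands the cohort into person-period records
# for pooled logistic regression.
#
# method1  time zero at enrolment, nobody excluded, enrolment confounders
#          only.  Its person-period records for interval 1 already carry
#          the exposure indicators even though weight change is only
#          observed at the end of that interval -- the deliberate
#          misalignment that defines the method.
# method2  time zero at the first follow-up, first-interval CVD cases
#          excluded, confounders at the first follow-up only; the clock is
#          re-indexed so the modelled follow-up spans 18 years.
# method3  time zero at enrolment, first-interval CVD cases excluded,
#          confounders at both measurement times; interval 1 is a
#          structural zero-risk baseline period (2 + 18 = 20 years).

FIXED_COVS <- c("age0", "sex", "famhist", "weight0")

#' Emulation method specification
#'
#' Returns the frozen definition of one of the three emulation strategies:
#' its time zero, exclusion rules, covariate set and modelled intervals.
#'
#' @param name \code{"method1"}, \code{"method2"} or \code{"method3"}.
#' @param exclude_first_interval_chronic Also exclude subjects with an
#'   interval-1 chronic disease (the toy example's exclusion rule); off by
#'   default, where only first-interval CVD cases are excluded.
#' @param n_intervals Number of intervals on the enrolment clock
#'   (default 10).
#' @return An object of class \code{method_spec}.
#' @examples
#' method_spec("method3")$covariate_set
#' @export
method_spec <- function(name = c("method1", "method2", "method3"),
                        exclude_first_interval_chronic = FALSE,
                        n_intervals = 10) {
  name <- match.arg(name)
  n_intervals <- as.integer(n_intervals)
  spec <- switch(name,
    method1 = list(
      name = "method1", time_zero = "enrolment",
      exclude_first_interval_cvd = FALSE,
      exclude_first_interval_chronic = FALSE,
      covariate_set = c(FIXED_COVS, "smoking0", "diuretics0"),
      modelled_intervals = seq_len(n_intervals),
      reindex = FALSE, baseline_period_years = 0),
    method2 = list(
      name = "method2", time_zero = "first_followup",
      exclude_first_interval_cvd = TRUE,
      exclude_first_interval_chronic = exclude_first_interval_chronic,
      covariate_set = c(FIXED_COVS, "smoking1", "diuretics1"),
      modelled_intervals = seq(2L, n_intervals),
      reindex = TRUE, baseline_period_years = 0),
    method3 = list(
      name = "method3", time_zero = "enrolment",
      exclude_first_interval_cvd = TRUE,
      exclude_first_interval_chronic = exclude_first_interval_chronic,
      covariate_set = c(FIXED_COVS, "smoking0", "diuretics0",
                        "smoking1", "diuretics1"),
      modelled_intervals = seq(2L, n_intervals),
      reindex = FALSE, baseline_period_years = 2))
  spec$n_intervals <- n_intervals
  structure(spec, class = "method_spec")
}

#' @export
print.method_spec <- function(x, ...) {
  cat(sprintf("<%s> time zero: %s; modelled intervals %d..%d%s\n",
              x$name, x$time_zero, min(x$modelled_intervals),
              max(x$modelled_intervals),
              if (x$reindex) " (re-indexed from time zero)" else ""))
  cat(sprintf("  exclude first-interval CVD: %s; chronic: %s\n",
              x$exclude_first_interval_cvd, x$exclude_first_interval_chronic))
  cat("  covariates:", paste(x$covariate_set, collapse = ", "), "\n")
  invisible(x)
}

#' Apply a method's exclusion rules to a cohort
#'
#' Drops subjects with a CVD event in interval 1 when the method requires
#' it, and additionally subjects with an interval-1 chronic disease when
#' \code{exclude_first_interval_chronic} is set.  Method 1 drops nobody.
#'
#' @param cohort A \code{tte_cohort}.
#' @param spec A [method_spec()].
#' @return A \code{tte_cohort} with an added \code{exclusions} element:
#'   named counts of subjects dropped by reason.
#' @export
apply_exclusions <- function(cohort, spec) {
  stopifnot(inherits(cohort, "tte_cohort"), inherits(spec, "method_spec"))
  s <- cohort$subjects
  drop_cvd <- spec$exclude_first_interval_cvd &
    !is.na(s$event_interval) & s$event_interval == 1L
  drop_chronic <- spec$exclude_first_interval_chronic &
    s$chronic1 == 1L & !drop_cvd
  cohort$subjects <- s[!(drop_cvd | drop_chronic), , drop = FALSE]
  cohort$exclusions <- c(first_interval_cvd = sum(drop_cvd),
                         first_interval_chronic = sum(drop_chronic))
  cohort
}

#' Expand a cohort into person-period records
#'
#' One record per subject per at-risk interval on the method's clock, up
#' to and including the event interval.  Method 1 contributes records for
#' intervals 1..K with exposure indicators populated throughout (its
#' defining flaw); method 2 contributes intervals 2..K re-indexed to
#' 1..K-1; method 3 contributes intervals 2..K on the enrolment clock,
#' interval 1 being a structural zero-risk baseline period that appears in
#' risk curves but not in the regression.
#'
#' @param cohort A \code{tte_cohort} with exclusions already applied.
#' @param spec A [method_spec()].
#' @return A data frame of class \code{person_period} with columns
#'   \code{id}, \code{interval} (method clock), \code{event},
#'   \code{exposure_loss}, \code{exposure_gain} and the method's covariate
#'   columns; attributes \code{method_spec} and \code{n_subjects}.
#' @export
expand_person_periods <- function(cohort, spec) {
  stopifnot(inherits(cohort, "tte_cohort"), inherits(spec, "method_spec"))
  s <- cohort$subjects
  K <- spec$n_intervals
  ev <- s$event_interval
  if (any(!is.na(ev) & (ev < 1L | ev > K)))
    stop("event_interval outside 1..", K, " for subject id ",
         s$id[which(!is.na(ev) & (ev < 1L | ev > K))[1]])
  first <- min(spec$modelled_intervals)
  if (spec$exclude_first_interval_cvd && any(!is.na(ev) & ev < first))
    stop("subjects with first-interval events present: apply exclusions first")
  last <- pmin(ifelse(is.na(ev), K, ev), K)   # last at-risk interval
  n_rec <- last - first + 1L
  stopifnot(all(n_rec >= 1L))
  idx <- rep.int(seq_len(nrow(s)), n_rec)
  interval <- (first - 1L) + sequence(n_rec)
  event <- as.integer(!is.na(ev[idx]) & interval == ev[idx])
  if (spec$reindex) interval <- interval - (first - 1L)
  pp <- data.frame(id = s$id[idx], interval = interval, event = event,
                   exposure_loss = as.integer(s$change_category[idx] == "loss"),
                   exposure_gain = as.integer(s$change_category[idx] == "gain"))
  for (v in spec$covariate_set) pp[[v]] <- s[[v]][idx]
  attr(pp, "method_spec") <- spec
  attr(pp, "n_subjects") <- nrow(s)
  class(pp) <- c("person_period", "data.frame")
  pp
}
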