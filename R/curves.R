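# Cumulative-incidence curve estimators on the method's clock.  There is
# no censoring in the data-generating process, so the Kaplan-Meier product
# over discrete intervals is an exact cumulative-incidence estimator and
# weighting only has to remove confounding, not informative dropout.

EXPOSURE_LEVELS <- c("loss", "maintain", "gain")

curve_frame <- function(method, estimator, group, time, risk) {
  out <- data.frame(method = method, estimator = estimator, group = group,
                    time = time, risk = risk)
  rownames(out) <- NULL
  out
}

# years since the method's time zero for modelled interval indices,
# prepending the time-zero point (and the baseline period for method 3)
curve_times <- function(spec) {
  iv <- 2  # years per interval
  if (spec$reindex) {
    list(lead_t = 0, lead_r = 0,
         times = iv * seq_along(spec$modelled_intervals))
  } else if (spec$baseline_period_years > 0) {
    list(lead_t = c(0, spec$baseline_period_years), lead_r = c(0, 0),
         times = iv * spec$modelled_intervals)
  } else {
    list(lead_t = 0, lead_r = 0, times = iv * spec$modelled_intervals)
  }
}

#' Inverse-probability-weighted Kaplan-Meier risk curves
#'
#' Fits a three-category exposure model (multinomial logit of weight-change
#' category on the method's covariate set, via \code{nnet::multinom}),
#' forms stabilised weights (marginal category frequency divided by the
#' fitted conditional probability of the subject's observed category), and
#' computes the weighted discrete-time Kaplan-Meier cumulative risk per
#' exposure group on the method's clock.  Method 3 curves start at
#' enrolment and are flat at zero through the 2-year baseline period.
#' Subjects with a fitted probability below \code{positivity_floor} for
#' their observed category trigger a warning with a count.
#'
#' @param cohort A \code{tte_cohort} with the method's exclusions already
#'   applied (see [apply_exclusions()]).
#' @param spec A [method_spec()].
#' @param positivity_floor Warn when fitted exposure probabilities fall
#'   below this (default 0.01).
#' @return A data frame of class \code{risk_curves} (columns
#'   \code{method}, \code{estimator}, \code{group}, \code{time} in years
#'   from the method's time zero, \code{risk}), with attribute
#'   \code{weight_diagnostics}: per-group mean and max stabilised weight.
#' @export
ipw_weighted_km <- function(cohort, spec, positivity_floor = 0.01) {
  stopifnot(inherits(cohort, "tte_cohort"), inherits(spec, "method_spec"))
  s <- cohort$subjects
  cat_f <- factor(s$change_category, levels = EXPOSURE_LEVELS)
  form <- stats::as.formula(paste("cat_f ~",
                                  paste(spec$covariate_set, collapse = " + ")))
  dat <- s[, spec$covariate_set, drop = FALSE]
  dat$cat_f <- stats::relevel(cat_f, ref = "maintain")
  mfit <- nnet::multinom(form, data = dat, trace = FALSE, maxit = 200)
  probs <- stats::fitted(mfit)
  if (is.null(dim(probs))) probs <- cbind(probs, 1 - probs)  # not expected
  p_obs <- probs[cbind(seq_len(nrow(s)), match(as.character(dat$cat_f),
                                               colnames(probs)))]
  n_low <- sum(p_obs < positivity_floor)
  if (n_low > 0)
    warning(n_low, " subject(s) with fitted exposure probability below ",
            positivity_floor, " (positivity concern)")
  marg <- as.numeric(table(dat$cat_f)[as.character(dat$cat_f)]) / nrow(s)
  w <- marg / p_obs

  diag_tab <- do.call(rbind, lapply(EXPOSURE_LEVELS, function(g) {
    wi <- w[s$change_category == g]
    data.frame(group = g, mean_weight = mean(wi), max_weight = max(wi))
  }))

  tt <- curve_times(spec)
  ev <- s$event_interval
  curves <- do.call(rbind, lapply(EXPOSURE_LEVELS, function(g) {
    in_g <- s$change_category == g
    wi <- w[in_g]
    evi <- ev[in_g]
    surv <- 1
    risk <- numeric(length(spec$modelled_intervals))
    for (k in seq_along(spec$modelled_intervals)) {
      t <- spec$modelled_intervals[k]
      at_risk <- is.na(evi) | evi >= t
      d <- sum(wi[!is.na(evi) & evi == t])
      nrisk <- sum(wi[at_risk])
      surv <- surv * (1 - if (nrisk > 0) d / nrisk else 0)
      risk[k] <- 1 - surv
    }
    curve_frame(spec$name, "ipw_km", g,
                c(tt$lead_t, tt$times), c(tt$lead_r, risk))
  }))
  structure(curves, class = c("risk_curves", "data.frame"),
            weight_diagnostics = diag_tab)
}

#' G-formula standardised incidence curves
#'
#' Standardisation via the outcome model: for each exposure level, the
#' fitted pooled-logistic hazards are evaluated for every retained subject
#' with exposure set to that level and covariates at their observed
#' values, converted to cumulative risk by the product of interval
#' survivals, and averaged over subjects.  The default fit carries a
#' single (proportional) exposure effect; refit with exposure-by-interval
#' interactions if a time-varying effect curve is wanted.
#'
#' @param fit A converged \code{pooled_logit_fit}.
#' @param subjects Data frame of retained subjects (the \code{subjects}
#'   element of the excluded cohort the fit was built from).
#' @return A \code{risk_curves} data frame, one curve per exposure level.
#' @export
gformula_incidence <- function(fit, subjects) {
  stopifnot(inherits(fit, "pooled_logit_fit"))
  if (!fit$converged) stop("pooled logistic fit did not converge")
  spec <- fit$spec
  tt <- curve_times(spec)
  curves <- do.call(rbind, lapply(EXPOSURE_LEVELS, function(g) {
    haz <- predict(fit, subjects, exposure = g)
    cumsurv <- t(apply(1 - haz, 1L, cumprod))
    risk <- colMeans(1 - cumsurv)
    curve_frame(spec$name, "gformula", g,
                c(tt$lead_t, tt$times), c(tt$lead_r, unname(risk)))
  }))
  structure(curves, class = c("risk_curves", "data.frame"),
            weight_diagnostics = NULL)
}

#' Unweighted Kaplan-Meier risk curves by exposure group
#'
#' The crude (confounded) analogue of [ipw_weighted_km()], mainly useful
#' as a comparator.
#'
#' @inheritParams ipw_weighted_km
#' @return A \code{risk_curves} data frame.
#' @export
unweighted_km <- function(cohort, spec) {
  stopifnot(inherits(cohort, "tte_cohort"), inherits(spec, "method_spec"))
  s <- cohort$subjects
  tt <- curve_times(spec)
  ev <- s$event_interval
  curves <- do.call(rbind, lapply(EXPOSURE_LEVELS, function(g) {
    evi <- ev[s$change_category == g]
    surv <- 1
    risk <- numeric(length(spec$modelled_intervals))
    for (k in seq_along(spec$modelled_intervals)) {
      t <- spec$modelled_intervals[k]
      d <- sum(!is.na(evi) & evi == t)
      nrisk <- sum(is.na(evi) | evi >= t)
      surv <- surv * (1 - if (nrisk > 0) d / nrisk else 0)
      risk[k] <- 1 - surv
    }
    curve_frame(spec$name, "km", g, c(tt$lead_t, tt$times),
                c(tt$lead_r, risk))
  }))
  structure(curves, class = c("risk_curves", "data.frame"))
}

#' @export
print.risk_curves <- function(x, ...) {
  est <- unique(x$estimator)
  cat(sprintf("Risk curves (%s, %s): %d group(s), %d time points\n",
              unique(x$method), paste(est, collapse = "/"),
              length(unique(x$group)), length(unique(x$time))))
  last <- x[x$time == max(x$time), ]
  for (i in seq_len(nrow(last)))
    cat(sprintf("  %s at %g years: %.1f%%\n", last$group[i], last$time[i],
                100 * last$risk[i]))
  invisible(x)
}

#' @export
plot.risk_curves <- function(x, col = c(loss = "#D55E00",
                                        maintain = "#0072B2",
                                        gain = "#009E73"),
                             main = NULL, ...) {
  if (is.null(main))
    main <- sprintf("%s cumulative incidence (%s)", unique(x$method)[1],
                    paste(unique(x$estimator), collapse = ", "))
  graphics::plot(range(x$time), c(0, max(x$risk) * 1.05), type = "n",
                 xlab = sprintf("years since time zero"),
                 ylab = "cumulative risk", main = main, ...)
  for (g in unique(x$group)) {
    sub <- x[x$group == g, ]
    graphics::lines(sub$time, sub$risk, type = "s", col = col[[g]], lwd = 2)
  }
  graphics::legend("topleft", legend = unique(x$group),
                   col = col[unique(x$group)], lwd = 2, bty = "n")
  invisible(x)
}
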