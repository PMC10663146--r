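# Parameterisation of the synthetic overweight cohort.
#
# The causal structure: baseline confounders C0 (smoking, diuretic use at
# enrolment) and first-follow-up confounders C1 (same, re-measured at year
# 2) each affect both the weight-change category formed over the first
# 2-year interval and the discrete-time CVD hazard thereafter; an incident
# chronic disease in the first interval pushes subjects towards weight
# loss and sharply raises first-interval CVD risk (reverse causation).
# Fixed covariates (age, sex, family history, baseline weight) affect both
# exposure and hazard and are adjusted by every method.

# kg used to centre baseline weight in linear predictors; roughly the
# population mean weight implied by BMI 25-29.9 and the height model.
WEIGHT0_CENTER <- 80
AGE_CENTER <- 52.5

#' Parameters of the synthetic cohort data-generating process
#'
#' Builds the full parameterisation of the simulated observational study:
#' overweight adults (BMI 25-29.9 kg/m2) aged 45-60, followed for 20 years
#' with visits every 2 years (10 intervals), a three-level weight-change
#' exposure formed over the first interval at +/-5\% of baseline weight,
#' and a CVD outcome generated from a discrete-time logistic hazard.  The
#' true conditional effects are injected on the logit scale of the
#' per-interval hazard from the second interval onwards, so with the rare
#' per-interval events used here the injected values are also the log
#' hazard ratios to reporting precision.
#'
#' Default confounder coefficients are the package's own choices (the
#' generating values used in the original study are not published); they
#' are set so that every backdoor path in the design is open: smoking and
#' diuretic use at both measurement times raise the hazard, make loss more
#' likely and gain less likely, and an interval-1 chronic disease strongly
#' promotes loss while raising interval-1 CVD risk only (an acute
#' reverse-causation channel that the first-interval-CVD exclusion of
#' methods 2 and 3 removes).
#'
#' @param n_subjects Number of subjects per cohort (default 10000).
#' @param n_intervals Number of 2-year intervals (default 10, i.e. 20
#'   years); must be at least 2 since interval 1 is the exposure-formation
#'   window.
#' @param change_threshold Relative weight change defining loss/gain
#'   (default 0.05): loss if change <= -threshold, gain if >= +threshold,
#'   maintenance otherwise.
#' @param true_loss_effect,true_gain_effect True conditional effects of
#'   loss and gain vs maintenance on the hazard logit (defaults 0 and 0.3).
#' @param baseline_hazard_logits Numeric vector, one logit per interval.
#'   The default rises from about 0.3\% to 2.8\% per 2-year interval,
#'   mimicking the steep age gradient of CVD incidence in middle age; the
#'   implied 20-year risk is roughly 15-20\%.
#' @param confounder_effects List with named numeric vectors
#'   \code{exposure_loss}, \code{exposure_gain} (multinomial logit
#'   coefficients, maintenance as reference) and \code{hazard} (hazard
#'   logit coefficients).  Names: \code{smoking0}, \code{diuretics0},
#'   \code{smoking1}, \code{diuretics1}, \code{age0}, \code{sex},
#'   \code{famhist}, \code{weight0}.  Continuous terms are centred (age at
#'   52.5 years, weight at 80 kg).  Measurement-1 covariates and exposure
#'   affect the hazard only from interval 2 onwards.
#' @param exposure_intercepts Named vector \code{c(loss=, gain=)} of
#'   multinomial intercepts; defaults give roughly 23\% loss, 51\%
#'   maintenance, 26\% gain.
#' @param chronic_disease_params List: \code{incidence} (interval-1 chronic
#'   disease probability), \code{on_loss} / \code{on_gain} (additions to
#'   the exposure logits), \code{on_hazard} (addition to the interval-1
#'   hazard logit only).
#' @param covariate_params List of baseline covariate and transition rates:
#'   \code{p_sex}, \code{p_famhist}, \code{p_smoking0}, \code{p_diuretics0},
#'   \code{smoke_cessation}, \code{smoke_initiation}, and the diuretics
#'   transition model \code{diur1_intercept}, \code{diur1_on_diuretics0},
#'   \code{diur1_on_age} (logit scale).
#' @param master_seed Default seed used when none is given to
#'   [simulate_cohort()].
#' @return An object of class \code{sim_params} (a validated list).
#' @seealso [simulate_cohort()], [zero_confounding()]
#' @examples
#' p <- sim_params(n_subjects = 500)
#' p$true_gain_effect
#' @export
sim_params <- function(n_subjects = 10000,
                       n_intervals = 10,
                       change_threshold = 0.05,
                       true_loss_effect = 0,
                       true_gain_effect = 0.3,
                       baseline_hazard_logits =
                         stats::qlogis(seq(0.003, 0.028,
                                           length.out = n_intervals)),
                       confounder_effects = default_confounder_effects(),
                       exposure_intercepts = c(loss = -0.8, gain = -0.7),
                       chronic_disease_params = list(
                         incidence = 0.06, on_loss = 2.5, on_gain = 0,
                         on_hazard = 2.0),
                       covariate_params = default_covariate_params(),
                       master_seed = 20231026) {
  params <- structure(list(
    n_subjects = as.integer(n_subjects),
    n_intervals = as.integer(n_intervals),
    interval_years = 2,
    change_threshold = change_threshold,
    true_loss_effect = true_loss_effect,
    true_gain_effect = true_gain_effect,
    baseline_hazard_logits = baseline_hazard_logits,
    confounder_effects = confounder_effects,
    exposure_intercepts = exposure_intercepts,
    chronic_disease_params = chronic_disease_params,
    covariate_params = covariate_params,
    master_seed = as.integer(master_seed)), class = "sim_params")
  validate_params(params)
  params
}

confounder_names <- function() {
  c("smoking0", "diuretics0", "smoking1", "diuretics1",
    "age0", "sex", "famhist", "weight0")
}

default_confounder_effects <- function() {
  list(
    exposure_loss = c(smoking0 = 0.3, diuretics0 = 0.2,
                      smoking1 = 0.55, diuretics1 = 0.45,
                      age0 = 0.02, sex = 0.1, famhist = 0.1, weight0 = 0.01),
    exposure_gain = c(smoking0 = -0.3, diuretics0 = -0.2,
                      smoking1 = -0.55, diuretics1 = -0.45,
                      age0 = -0.02, sex = 0.1, famhist = 0.1,
                      weight0 = -0.01),
    hazard = c(smoking0 = 0.35, diuretics0 = 0.25,
               smoking1 = 0.55, diuretics1 = 0.45,
               age0 = 0.04, sex = 0.3, famhist = 0.3, weight0 = 0.01))
}

default_covariate_params <- function() {
  list(p_sex = 0.5, p_famhist = 0.2, p_smoking0 = 0.25, p_diuretics0 = 0.12,
       smoke_cessation = 0.15, smoke_initiation = 0.05,
       diur1_intercept = -2.2, diur1_on_diuretics0 = 4.0,
       diur1_on_age = 0.04)
}

validate_params <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  if (p$n_subjects < 1L) stop("n_subjects must be positive")
  if (p$n_intervals < 2L)
    stop("n_intervals must be >= 2: interval 1 is the exposure-formation ",
         "window")
  if (p$change_threshold <= 0 || p$change_threshold >= 0.5)
    stop("change_threshold must lie in (0, 0.5)")
  if (length(p$baseline_hazard_logits) != p$n_intervals)
    stop("baseline_hazard_logits must have length n_intervals (",
         p$n_intervals, "), got ", length(p$baseline_hazard_logits))
  for (part in c("exposure_loss", "exposure_gain", "hazard")) {
    v <- p$confounder_effects[[part]]
    if (is.null(v) || !all(confounder_names() %in% names(v)))
      stop("confounder_effects$", part, " must name all of: ",
           paste(confounder_names(), collapse = ", "))
  }
  if (!all(c("loss", "gain") %in% names(p$exposure_intercepts)))
    stop("exposure_intercepts must name 'loss' and 'gain'")
  cd <- p$chronic_disease_params
  if (cd$incidence < 0 || cd$incidence > 0.5)
    stop("chronic disease incidence must lie in [0, 0.5]")
  # rare-event regime: per-interval event probability at covariate means
  # must stay small enough that logit effects read as log hazard ratios
  means <- c(smoking0 = p$covariate_params$p_smoking0,
             diuretics0 = p$covariate_params$p_diuretics0,
             smoking1 = p$covariate_params$p_smoking0,
             diuretics1 = p$covariate_params$p_diuretics0,
             age0 = 0, sex = p$covariate_params$p_sex,
             famhist = p$covariate_params$p_famhist, weight0 = 0)
  shift <- sum(p$confounder_effects$hazard[confounder_names()] * means)
  pmax_at_means <- max(stats::plogis(p$baseline_hazard_logits + shift))
  if (pmax_at_means > 0.05)
    stop("baseline_hazard_logits imply a per-interval event probability ",
         "of ", signif(pmax_at_means, 3),
         " at covariate means; must be <= 0.05 (rare-event regime)")
  invisible(params)
}

#' Switch off all confounding in a parameter set
#'
#' Returns a copy of \code{params} with every confounder coefficient on
#' the exposure and on the hazard set to zero, and the chronic-disease
#' effects zeroed.  Exposure is then randomised, so all three emulation
#' methods are valid (up to the structural misalignment of method 1) --
#' the limiting case used for calibration checks.
#'
#' @param params A [sim_params()] object.
#' @return A \code{sim_params} object.
#' @export
zero_confounding <- function(params = sim_params()) {
  zero <- function(v) { v[] <- 0; v }
  params$confounder_effects <- lapply(params$confounder_effects, zero)
  params$chronic_disease_params$on_loss <- 0
  params$chronic_disease_params$on_gain <- 0
  params$chronic_disease_params$on_hazard <- 0
  validate_params(params)
  params
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic cohort parameters\n")
  cat(sprintf("  %d subjects, %d intervals of %g years (%g years total)\n",
              x$n_subjects, x$n_intervals, x$interval_years,
              x$n_intervals * x$interval_years))
  cat(sprintf("  weight-change threshold: +/-%g%% of baseline weight\n",
              100 * x$change_threshold))
  cat(sprintf("  true conditional effects (logit scale): loss %g, gain %g\n",
              x$true_loss_effect, x$true_gain_effect))
  cat(sprintf("  per-interval baseline hazards: %s\n",
              paste(sprintf("%.3f", stats::plogis(x$baseline_hazard_logits)),
                    collapse = " ")))
  cat(sprintf("  chronic disease: incidence %g, on loss logit +%g, ",
              x$chronic_disease_params$incidence,
              x$chronic_disease_params$on_loss))
  cat(sprintf("on interval-1 hazard +%g\n", x$chronic_disease_params$on_hazard))
  invisible(x)
}
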