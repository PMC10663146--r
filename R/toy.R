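#' The 40-subject hypothetical weight-change trial
#'
#' Loads the worked example of a two-arm randomised trial in overweight
#' adults (BMI 25-29.9 kg/m2, ages 45-60).  Arm \code{a_low_caloric}
#' combines high physical activity with low caloric intake (the weight-loss
#' arm); arm \code{b_standard_caloric} keeps caloric intake standard (the
#' maintenance arm).  Interventions run for 2 years; cardiovascular disease
#' (CVD) is ascertained over 20 years of total follow-up.  Four subjects
#' develop a chronic disease during the 2-year intervention window that
#' itself induces weight loss -- the reverse-causation channel that the
#' emulation methods handle differently.
#'
#' @return A data frame with 40 rows and columns \code{id}, \code{arm},
#'   \code{weight_change} (\code{"loss"} or \code{"maintain"}),
#'   \code{chronic_first2y} (chronic disease with onset in the 2-year
#'   window, including early CVD), and \code{cvd} (CVD by year 20).
#' @examples
#' toy <- toy_trial()
#' table(toy$arm, toy$cvd)
#' @export
toy_trial <- function() {
  path <- system.file("extdata", "toy_trial.csv", package = "wtchange",
                      mustWork = TRUE)
  toy <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_toy(toy)
  toy
}

validate_toy <- function(toy) {
  need <- c("id", "arm", "weight_change", "chronic_first2y", "cvd")
  missing <- setdiff(need, names(toy))
  if (length(missing))
    stop("toy trial data lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(toy) != 40L)
    stop("toy trial must have exactly 40 subjects, got ", nrow(toy))
  arms <- table(toy$arm)
  if (!identical(sort(names(arms)), c("a_low_caloric", "b_standard_caloric")) ||
      any(arms != 20L))
    stop("toy trial must have 20 subjects in each of the two arms")
  if (!all(toy$weight_change %in% c("loss", "maintain")))
    stop("weight_change must be 'loss' or 'maintain'")
  invisible(toy)
}

group_risk <- function(label, numerator, denominator) {
  if (denominator <= 0L)
    stop("group '", label, "' has no members")
  structure(list(group = label, numerator = as.integer(numerator),
                 denominator = as.integer(denominator),
                 risk = numerator / denominator),
            class = "group_risk")
}

#' @export
print.group_risk <- function(x, ...) {
  cat(sprintf("%s: %d/%d = %s\n", x$group, x$numerator, x$denominator,
              format_pct(x$risk)))
  invisible(x)
}

format_pct <- function(p) sprintf("%.1f%%", 100 * p)

#' Per-arm CVD risk in the hypothetical trial
#'
#' Computes the 20-year CVD risk by randomised arm with no exclusions, the
#' intention-to-treat analysis of the trial.  Both arms carry a risk of
#' 3/20 = 15\%: randomisation makes the arms exchangeable, so the trial
#' shows no effect of the caloric-intake intervention.
#'
#' @param subjects Data frame as returned by [toy_trial()].
#' @return Named list of \code{group_risk} objects, one per arm.
#' @export
trial_risk_by_arm <- function(subjects = toy_trial()) {
  validate_toy(subjects)
  arms <- c("a_low_caloric", "b_standard_caloric")
  out <- lapply(arms, function(a) {
    sub <- subjects[subjects$arm == a, ]
    if (nrow(sub) == 0L) stop("arm '", a, "' is empty: malformed fixture")
    group_risk(a, sum(sub$cvd), nrow(sub))
  })
  names(out) <- arms
  out
}

#' Observational analyses of the toy trial under methods 1-3
#'
#' Re-analyses the 40 subjects as if drawn from a healthcare database in
#' which the dietary intervention is unrecorded, so the exposure is the
#' observed weight change.  Method 1 groups subjects by observed weight
#' change with no exclusions (time zero at enrolment, confounders at
#' enrolment only).  Methods 2 and 3 first exclude the four subjects whose
#' weight change was affected by a chronic disease in the 2-year window,
#' then group by weight change; on these data, where the chronic-disease
#' exclusion is the only confounder handling required, the two methods
#' coincide exactly.
#'
#' @param subjects Data frame as returned by [toy_trial()].
#' @param method Method name: \code{"method1"}, \code{"method2"} or
#'   \code{"method3"} (or a [method_spec()] object).
#' @return A list of class \code{toy_emulation} with elements \code{method},
#'   \code{groups} (named list of \code{group_risk} for \code{loss} and
#'   \code{maintain}), \code{risk_difference} (loss minus maintain, a
#'   proportion) and \code{excluded} (ids dropped).
#' @examples
#' emulate_toy(method = "method1")$risk_difference  # 4/22 - 2/18
#' @export
emulate_toy <- function(subjects = toy_trial(), method = "method1") {
  validate_toy(subjects)
  if (inherits(method, "method_spec")) method <- method$name
  method <- match.arg(method, c("method1", "method2", "method3"))
  excluded <- integer(0)
  kept <- subjects
  if (method != "method1") {
    excluded <- subjects$id[subjects$chronic_first2y]
    kept <- subjects[!subjects$chronic_first2y, ]
  }
  groups <- lapply(c(loss = "loss", maintain = "maintain"), function(g) {
    sub <- kept[kept$weight_change == g, ]
    if (nrow(sub) == 0L)
      stop("group '", g, "' is empty after exclusions")
    group_risk(g, sum(sub$cvd), nrow(sub))
  })
  structure(list(method = method, groups = groups,
                 risk_difference = groups$loss$risk - groups$maintain$risk,
                 excluded = excluded),
            class = "toy_emulation")
}

#' @export
print.toy_emulation <- function(x, ...) {
  cat(sprintf("Toy trial emulated with %s (%d subject(s) excluded)\n",
              x$method, length(x$excluded)))
  for (g in x$groups) print(g)
  cat(sprintf("risk difference (loss - maintain): %.1f%%\n",
              100 * x$risk_difference))
  invisible(x)
}

#' Toy example summary across all three methods
#'
#' @param subjects Data frame as returned by [toy_trial()].
#' @return Data frame with one row per method: risks per group and risk
#'   difference, as proportions.
#' @export
toy_summary <- function(subjects = toy_trial()) {
  rows <- lapply(c("method1", "method2", "method3"), function(m) {
    e <- emulate_toy(subjects, m)
    data.frame(method = m,
               loss_events = e$groups$loss$numerator,
               loss_n = e$groups$loss$denominator,
               loss_risk = e$groups$loss$risk,
               maintain_events = e$groups$maintain$numerator,
               maintain_n = e$groups$maintain$denominator,
               maintain_risk = e$groups$maintain$risk,
               risk_difference = e$risk_difference)
  })
  do.call(rbind, rows)
}
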