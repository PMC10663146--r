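#' Monte Carlo replication of the method comparison
#'
#' Repeatedly simulates cohorts and, for each emulation method, applies
#' its exclusions, expands to person-periods and fits the pooled logistic
#' model; then summarises, per method and contrast (loss vs maintenance,
#' gain vs maintenance): mean estimate, bias against the injected truth,
#' empirical SD of the estimates, coverage of the 95\% Wald interval, and
#' Monte-Carlo standard errors of bias and coverage.  Replicates that fail
#' to converge or show separation are dropped from the summaries and
#' counted.  The master seed deterministically spawns one sub-seed per
#' replicate, so any subset of replicates can be re-run (serially or in
#' parallel) with identical results.
#'
#' @param params A [sim_params()] object.
#' @param n_reps Number of replicates (>= 2; default 500).
#' @param methods Character vector of method names (default all three).
#' @param master_seed Integer master seed (default
#'   \code{params$master_seed}).
#' @return An object of class \code{replication_report}: list with
#'   \code{summary} (data frame: method, contrast, truth, mean_estimate,
#'   bias, empirical_sd, coverage, mcse_bias, mcse_coverage, n_effective),
#'   \code{failures} (named counts per method), \code{mean_n_subjects},
#'   \code{estimates} (array of per-replicate estimates), \code{n_reps},
#'   \code{master_seed} and \code{params}.
#' @examples
#' rep <- run_replications(sim_params(n_subjects = 300), n_reps = 5,
#'                         methods = "method3", master_seed = 1)
#' rep$summary
#' @export
run_replications <- function(params = sim_params(), n_reps = 500,
                             methods = c("method1", "method2", "method3"),
                             master_seed = params$master_seed) {
  validate_params(params)
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (length(methods) == 0) stop("methods must name at least one method")
  methods <- match.arg(methods, c("method1", "method2", "method3"),
                       several.ok = TRUE)
  specs <- lapply(methods, method_spec, n_intervals = params$n_intervals)
  names(specs) <- methods
  rep_seeds <- spawn_seeds(master_seed, n_reps)

  contrasts <- c("loss_vs_maint", "gain_vs_maint")
  est <- array(NA_real_, c(n_reps, length(methods), 2),
               dimnames = list(NULL, methods, contrasts))
  se <- est
  ok <- matrix(FALSE, n_reps, length(methods),
               dimnames = list(NULL, methods))
  n_kept <- matrix(NA_real_, n_reps, length(methods),
                   dimnames = list(NULL, methods))

  for (r in seq_len(n_reps)) {
    cohort <- simulate_cohort(params, seed = rep_seeds[r])
    for (m in methods) {
      fit <- tryCatch(suppressWarnings({
        ex <- apply_exclusions(cohort, specs[[m]])
        pp <- expand_person_periods(ex, specs[[m]])
        fit_pooled_logistic(pp, specs[[m]])
      }), error = function(e) NULL)
      if (is.null(fit)) next
      n_kept[r, m] <- fit$n_subjects
      if (fit$converged && !fit$separation_flag) {
        ok[r, m] <- TRUE
        est[r, m, ] <- c(fit$coef_loss, fit$coef_gain)
        se[r, m, ] <- c(fit$se_loss, fit$se_gain)
      }
    }
  }

  failed_methods <- methods[colSums(ok) == 0]
  if (length(failed_methods))
    stop("all replicates failed for method(s): ",
         paste(failed_methods, collapse = ", "))

  truth <- c(loss_vs_maint = params$true_loss_effect,
             gain_vs_maint = params$true_gain_effect)
  z <- stats::qnorm(0.975)
  rows <- list()
  for (m in methods) {
    keep <- ok[, m]
    for (ctr in contrasts) {
      e <- est[keep, m, ctr]
      s <- se[keep, m, ctr]
      nr <- length(e)
      covered <- abs(e - truth[[ctr]]) <= z * s
      cov <- mean(covered)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, contrast = ctr, truth = truth[[ctr]],
        mean_estimate = mean(e), bias = mean(e) - truth[[ctr]],
        empirical_sd = stats::sd(e), coverage = cov,
        mcse_bias = stats::sd(e) / sqrt(nr),
        mcse_coverage = sqrt(cov * (1 - cov) / nr),
        n_effective = nr)
    }
  }
  structure(list(summary = do.call(rbind, rows),
                 failures = n_reps - colSums(ok),
                 mean_n_subjects = colMeans(n_kept, na.rm = TRUE),
                 estimates = est, ses = se, ok = ok,
                 n_reps = n_reps, master_seed = as.integer(master_seed),
                 params = params),
            class = "replication_report")
}

# one sub-seed per replicate, reproducible from the master seed and
# independent of how many replicates are consumed by each worker
spawn_seeds <- function(master_seed, n) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("Replication report: %d replicates, master seed %d\n",
              x$n_reps, x$master_seed))
  if (any(x$failures > 0))
    cat("  failed replicates:",
        paste(sprintf("%s=%d", names(x$failures), x$failures),
              collapse = ", "), "\n")
  print(summarize_report(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Render a replication report as a method-by-contrast grid
#'
#' One row per contrast; per method, the mean estimate, bias and 95\% CI
#' coverage -- the layout of a simulation-study results table.
#'
#' @param report A \code{replication_report}.
#' @return A data frame (also usable for JSON export via
#'   \code{jsonlite::toJSON}).
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "replication_report"))
  s <- report$summary
  methods <- unique(s$method)
  if (length(methods) == 0) stop("report contains no methods")
  out <- NULL
  for (ctr in unique(s$contrast)) {
    row <- data.frame(contrast = ctr,
                      truth = s$truth[s$contrast == ctr][1])
    for (m in methods) {
      cell <- s[s$method == m & s$contrast == ctr, ]
      if (nrow(cell) == 1L) {
        row[[paste0(m, "_estimate")]] <- cell$mean_estimate
        row[[paste0(m, "_bias")]] <- cell$bias
        row[[paste0(m, "_coverage")]] <- cell$coverage
      } else {
        row[[paste0(m, "_estimate")]] <- NA_real_
        row[[paste0(m, "_bias")]] <- NA_real_
        row[[paste0(m, "_coverage")]] <- NA_real_
      }
    }
    out <- rbind(out, row)
  }
  out
}
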