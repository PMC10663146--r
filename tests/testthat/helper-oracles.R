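# Independent oracles used across tests.

# From-scratch Newton-Raphson maximiser of the binomial log-likelihood
# sum(y*eta - log(1+exp(eta))), eta = X beta, with explicit score and
# observed information.  Deliberately independent of stats::glm.fit.
oracle_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    score <- drop(crossprod(X, y - p))
    info <- crossprod(X * (p * (1 - p)), X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  names(beta) <- colnames(X)
  beta
}

# Hand-built design matrix for the pooled logistic model, mirroring the
# declared model (interval indicators, exposure indicators, covariates
# with age0/weight0 mean-centred) without calling package internals.
oracle_design <- function(records, covariate_set) {
  f <- factor(records$interval)
  D <- stats::model.matrix(~ f - 1)
  colnames(D) <- paste0("interval", levels(f))
  covs <- sapply(covariate_set, function(v) {
    x <- records[[v]]
    if (v %in% c("age0", "weight0")) x <- x - mean(x)
    x
  })
  cbind(D, exposure_loss = records$exposure_loss,
        exposure_gain = records$exposure_gain, covs)
}

# Brute-force per-subject loop counting person-period records for a
# method: one record per modelled interval up to and including the event.
oracle_pp_count <- function(subjects, spec) {
  total <- 0L
  for (i in seq_len(nrow(subjects))) {
    ev <- subjects$event_interval[i]
    for (t in spec$modelled_intervals) {
      if (!is.na(ev) && t > ev) break
      total <- total + 1L
    }
  }
  total
}

# Small cohort for cheap unit tests.
small_cohort <- function(n = 400, seed = 11, params = sim_params(n_subjects = n)) {
  simulate_cohort(params, seed = seed)
}

# Hand-built cohort wrapper around an explicit subject table.
manual_cohort <- function(subjects, params = sim_params(n_subjects = nrow(subjects))) {
  structure(list(subjects = subjects, params = params, seed_used = 0L),
            class = "tte_cohort")
}

# Minimal subject table with sensible covariates.
manual_subjects <- function(event_interval) {
  n <- length(event_interval)
  data.frame(id = seq_len(n), age0 = 50 + seq_len(n), sex = rep_len(0:1, n),
             famhist = 0L, height = 1.7, weight0 = 80, bmi0 = 27.7,
             smoking0 = rep_len(c(0L, 1L), n), diuretics0 = 0L,
             smoking1 = rep_len(c(0L, 1L), n), diuretics1 = 0L,
             chronic1 = 0L, weight1 = 80,
             change_category = "maintain",
             event_interval = as.integer(event_interval))
}
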