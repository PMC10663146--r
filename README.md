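# wtchange

Target trial emulation for weight-change exposures.

## The problem

Estimating the effect of weight change on a health outcome from
observational data raises two design questions that randomised trials never
face: *when is time zero?* and *which confounder measurements should be
adjusted for — those at enrolment, or those at the first follow-up visit,
when the weight change can finally be measured?* Different answers, all in
active use in the applied literature, carry different biases and produce
different numbers from the same data.

`wtchange` is a study-design laboratory for this question, aimed at
epidemiologists and biostatisticians. It implements three emulation
strategies for the target trial of a weight-change intervention in
overweight adults (BMI 25–29.9 kg/m², ages 45–60, 20-year follow-up with
visits every 2 years, CVD as the outcome):

* **Method 1** — time zero at enrolment, confounders at enrolment only,
  no exclusions. Subjects whose first-interval disease caused both their
  weight loss and their early CVD stay in the loss group, and the exposure
  indicators are attached to person-time that precedes the exposure.
* **Method 2** — time zero at the first follow-up (so 18 modelled years),
  first-interval CVD cases excluded, confounders at the first follow-up
  only. The backdoor path through the enrolment confounders stays open.
* **Method 3** (recommended) — time zero at enrolment, first-interval CVD
  cases excluded, confounders at *both* measurement times; the first
  2 years form a structural zero-risk baseline period (2 + 18 = 20 years).

## The model

All estimation is discrete-time survival analysis on person-period data.
With intervals *t* = 1, …, 10 of 2 years, exposure *A* ∈ {loss, maintain,
gain} formed over interval 1 at ±5 % of baseline weight, and covariates
*X*, the outcome model is the pooled logistic regression

logit Pr(Y<sub>t</sub> = 1 | Y<sub>t−1</sub> = 0, A, X) =
α<sub>t</sub> + β<sub>loss</sub>·1[A = loss] + β<sub>gain</sub>·1[A = gain] + γ′X

with one intercept α<sub>t</sub> per interval (a saturated baseline
hazard). Because per-interval events are rare, β ≈ the log hazard ratio.
The simulator injects true conditional effects β<sub>loss</sub> = 0 and
β<sub>gain</sub> = 0.3 and opens every backdoor path of the design, so the
bias and 95 % CI coverage of each method are measurable by Monte Carlo.
Cumulative-incidence curves come from stabilised IPW-weighted Kaplan–Meier
and from g-formula standardisation of the fitted model.

## Worked example

The package ships the 40-subject hypothetical trial (20 per arm) in which
the randomised comparison is exactly null:

```r
library(wtchange)
toy_summary()
#>    method loss_events loss_n loss_risk maintain_events maintain_n maintain_risk
#> 1 method1           4     22 0.1818182               2         18     0.1111111
#> 2 method2           2     18 0.1111111               2         18     0.1111111
#> 3 method3           2     18 0.1111111               2         18     0.1111111
#>   risk_difference
#> 1      0.07070707
#> 2      0.00000000
#> 3      0.00000000
```

Both trial arms have risk 3/20 = 15 %, yet method 1 reports a risk
difference of 4/22 − 2/18 ≈ 7.1 % for weight loss vs maintenance — pure
reverse causation through the four subjects whose chronic disease caused
their weight loss. Methods 2 and 3 exclude them and recover the null
(2/18 = 11.1 % in both groups).

The simulated cohort shows the same ordering when modelling is required:

```r
rep <- run_replications(sim_params(), n_reps = 500, master_seed = 20231026)
rep$summary[, c("method", "contrast", "bias", "coverage")]
#>    method      contrast       bias coverage
#> 1 method1 loss_vs_maint  0.0560929    0.766
#> 2 method1 gain_vs_maint -0.0468787    0.870
#> 3 method2 loss_vs_maint  0.0122265    0.944
#> 4 method2 gain_vs_maint -0.0122270    0.936
#> 5 method3 loss_vs_maint -0.0000993    0.956
#> 6 method3 gain_vs_maint -0.0022987    0.942
```

Method 3 is unbiased for both contrasts with nominal coverage; method 2 is
mildly biased (enrolment confounders unadjusted); method 1 is the most
biased, upward for loss (reverse causation inflates the apparent risk of
weight loss) and downward for gain. The magnitudes are specific to this
package's generating parameters; the ordering and signs are structural.

A single cohort analysis end to end:

```r
co  <- simulate_cohort(sim_params(), seed = 1)
sp  <- method_spec("method3")
ex  <- apply_exclusions(co, sp)
fit <- fit_pooled_logistic(expand_person_periods(ex, sp), sp)
fit
#> Pooled logistic fit (method3): 9940 subjects, 2556 events, 81347 records
#>   loss vs maintenance:  0.037 (SE 0.046, 95% CI -0.053 to 0.127)
#>   gain vs maintenance:  0.227 (SE 0.057, 95% CI 0.114 to 0.339)
plot(ipw_weighted_km(ex, sp))          # weighted KM curves per group
plot(gformula_incidence(fit, ex$subjects))
```

A thin command-line wrapper with subcommands `toy`, `simulate`,
`estimate`, `curves` and `replicate` lives at
`inst/cli/wtchange-cli.R` (installed under `system.file("cli", ...)`).

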