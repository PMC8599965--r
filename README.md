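# dynconn

Dynamic brain-state, signal-complexity and connectome-topology analysis of
component timecourses, with permutation-based group statistics and a
synthetic cohort generator for end-to-end validation.

## The scientific problem

Resting-state fMRI studies of neurodegenerative disease ask whether the
*dynamics* of large-scale brain networks differ between patients and
controls. Three measure families are standard:

* **Latent brain states** — a hidden Markov model on component timecourses
  yields recurring activation patterns; per subject one summarizes
  *fractional occupancy* (share of scan time per state), *switching rate*
  and state *lifetimes*.
* **Complexity** — multiscale sample entropy of each component timecourse.
* **Connectome topology** — wavelet-correlation matrices thresholded to a
  fixed edge density; clustering coefficient and characteristic path length
  normalized against degree-preserving random graphs (small-worldness).

Group differences are tested with Freedman–Lane permutation GLMs under
max-statistic family-wise error (FWE) correction, and dynamic measures are
correlated with clinical severity within patients, adjusting for age, sex
and head motion.

## The core model

`fit_hmm()` estimates a shared-covariance multivariate Gaussian HMM on
temporally concatenated, per-subject standardized timecourses
$x_t \in \mathbb{R}^C$:

$$ z_{t+1} \mid z_t \sim \mathrm{Cat}(A_{z_t,\cdot}), \qquad
   x_t \mid z_t = k \sim \mathcal{N}(\mu_k, \Sigma), $$

so states are distinguished purely by their mean activation pattern. Fitting
is maximum-likelihood EM (Baum–Welch) with a C++ scaled forward–backward and
Viterbi core, k-means initialization and random restarts. The chain restarts
at subject boundaries. The returned `"ghmm"` object follows the classic R
modelling idiom: `print`, `summary`, `coef`, `logLik`, `predict` (posterior
probabilities or Viterbi path), `simulate` and `plot` methods.

See the methods vignette (`vignettes/brain-state-dynamics.Rmd`) for the full
model description, parameter rationale and generator design.

## Worked example

Simulate a two-group cohort with a planted occupancy shift (cases spend 10%
more scan time in "executive" states, severity correlates with the shift),
fit the HMM, and test the group difference on occupancy components:

```r
library(dynconn)

co  <- simulate_cohort(cohort_spec(seed = 1))   # 22 controls + 24 cases, K = 8
co
#> Synthetic cohort: 22 controls + 24 cases, C=30, T=305, K=8 states
#>   occupancy shift 0.1 (executive: 1,4,6; subcortical: 5,7), severity loading 0.6

fit <- fit_hmm(co$timeseries, K = 8, seed = 1)
fit
#> Gaussian HMM (shared covariance): 8 states, 30 channels
#>   46 subjects, 14030 concatenated volumes
#>   log-likelihood -583998.26 after 15 EM iterations (converged)

sm <- state_metrics(fit)
round(head(sm$fo, 3), 3)
#>      state1 state2 state3 state4 state5 state6 state7 state8
#> [1,]  0.122  0.082  0.151  0.083  0.121  0.084  0.171  0.186
#> [2,]  0.139  0.131  0.125  0.103  0.050  0.202  0.044  0.205
#> [3,]  0.140  0.124  0.137  0.080  0.087  0.112  0.205  0.115

covs <- co$covariates
covs$motion <- motion_covariate(co$qc$metrics[, -1])
res <- fo_group_analysis(sm$fo, covs, n_perm = 1000, seed = 1)
sprintf("component %d: t = %.2f, FWE p = %.4g", res$component, res$t, res$p_fwe)
#> [1] "component 1: t = -3.69, FWE p = 0.001998"
sprintf("within-case severity r = %.2f (p = %.3g)", res$severity_r, res$severity_p)
#> [1] "within-case severity r = -0.45 (p = 0.0415)"
```

The separating component is oriented so cases score lower; with severity
planted to rise with the occupancy disturbance, the within-case correlation
is negative — the pipeline recovers both the group effect and the
severity sign from a single synthetic cohort.

The same analysis runs end to end from one configuration, writing result
tables and a checksummed manifest:

```r
res <- run_pipeline(default_config(seed = 1, outdir = "run1"))
```

or from the shell via the bundled runner:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dynconn.R", package = "dynconn"))')" \
  --config config.json --outdir run1
```

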