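# dvmix — model-based clustering for differential variability

Differential *variability* (DV) analysis asks a different question than
differential expression: which probes (miRNAs, methylation marks, genes)
have a different expression **variance** in cases than in controls?
Variance shifts carry biological signal — disease groups are often *more*
variable — but probe-wise equal-variance tests (F, Levene,
Brown–Forsythe) look at one probe at a time and leave power on the table.

dvmix clusters whole expression vectors instead. Each probe's vector
across $m = m_c + m_n$ subjects is one draw from a three-component mixture
of multivariate normals with exchangeable (compound-symmetry) within-group
covariance:

- **OV** cluster: $\sigma^2_c > \sigma^2_n$ (over-variable in cases),
- **EV** cluster: $\sigma^2_c = \sigma^2_n$ (equal variance),
- **UV** cluster: $\sigma^2_c < \sigma^2_n$ (under-variable in cases),

each with free group means $\mu_c, \mu_n$ and marginal between-subject
correlations $\rho_c, \rho_n$. Parameters are estimated by a constrained
EM algorithm (closed-form M steps from the two-eigenvalue decomposition of
the compound-symmetry covariance; the EV equality enforced by profiled
bounded optimization; OV/UV order restored by an end-of-run relabeling
repair), and each probe is assigned to the cluster with the largest
posterior probability $p_{gk} = \pi_k f_k(x_g) / \sum_j \pi_j f_j(x_g)$.
OV and UV probes are the DV calls.

The package also provides:

- probe-wise baselines (two-sided F test; Levene with mean, median, or
  10%-trimmed-mean centers) with Benjamini–Hochberg FDR adjustment;
- simulation generators for four scenarios — a normal mixture at published
  generating parameters, a heavy-tailed multivariate-t variant (df = 3),
  and both with correlations zeroed — with exact fixed cluster counts and
  ground-truth labels;
- evaluation metrics: pair-counting Jaccard index between partitions, FPR,
  FNR, and a paired Wilcoxon signed-rank comparison;
- a discovery → validation workflow: Box-Cox + per-probe standardization,
  sign-consistent validation rate pValid = n12/n1, and a within-group
  subject bootstrap of validation rates;
- a thin command-line front end (`inst/cli/dvmix`) with `simulate`,
  `detect`, `baseline`, `evaluate`, and `validate` subcommands.

## Worked example

Simulate the study design (1000 probes, 50 cases / 50 controls, true
mixing proportions 0.31 / 0.58 / 0.11), fit the mixture, and compare
against the truth:

```r
library(dvmix)
sim <- simulate_dataset(scenario_config("SimI", G = 1000, seed = 3))
fit <- fit_mixture(sim$data, fit_config(seed = 3))
fit
#> dvmix EM fit: 1000 probes; loglik -134024.1 (converged in 5 iterations)
#>
#>  OV  EV  UV
#> 309 581 110
fit$model
#> MixtureModel (OV/EV/UV), m_c = 50 , m_n = 50
#>   OV: pi=0.309  case(mu=-0.167, s2=1.506, rho=0.085)  control(mu=0.115, s2=0.454, rho=0.306)
#>   EV: pi=0.581  case(mu=0.048, s2=1.014, rho=0.040)  control(mu=-0.034, s2=1.014, rho=0.109)
#>   UV: pi=0.110  case(mu=0.131, s2=0.279, rho=0.039)  control(mu=-0.119, s2=1.688, rho=-0.010)
str(evaluate_calls(sim$truth, fit$assignments))
#> List of 3
#>  $ jaccard: num 0.996
#>  $ fpr    : num 0
#>  $ fnr    : num 0.00238
```

The truth here has exactly 310 OV / 580 EV / 110 UV probes; the fit
recovers 309 / 581 / 110 with near-perfect pair-counting agreement
(Jaccard 0.996), and the estimated mixture sits on top of the generating
values (e.g., OV variances 1.506 vs 1.49 in cases, 0.454 vs 0.45 in
controls). The probe-wise F test on the same data scores visibly lower on
the same index — borrowing strength across probes is the point of the
model. See `vignettes/differential-variability.Rmd` for the model,
estimation details, and design choices.

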