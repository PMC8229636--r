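# pcgeom

Information geometry and Bayesian prediction for exponential-family
lifetime models under **progressive Type-II censoring**.

In a progressive Type-II censored life test, $n$ items go on test, $m$
failures are observed, and at the $r$-th failure $R_r$ surviving items are
withdrawn ($\sum_r R_r = n - m$). For lifetime laws whose density and
reliability are both of exponential-family (log-linear) form, the joint
censored log-likelihood is again of natural form,

$$\ell(\theta) = \log c(R) + \sum_{r=1}^m \sum_i \theta_i\,
  e_i(x_{r:m:n}, R_r) \;-\; m\,\varphi(\theta),$$

and every information-geometric quantity of the model manifold is a
derivative of the censored cumulant $\varphi$:
the Fisher metric $g_{ij} = m\,\partial_i\partial_j\varphi$, the skewness
tensor $T_{ijk} = m\,\partial_i\partial_j\partial_k\varphi$, and the
$\alpha$-connections $\Gamma^{\alpha}_{ijk} = \frac{1-\alpha}{2} T_{ijk}$
(torsion-free, dually flat at $\alpha = \pm 1$). These tensors drive
Laplace-type asymptotic expansions of the Bayesian posterior and of the
predictive density
$\hat f_\pi(x) = \int f(x;\theta)\,\pi(\theta \mid \text{data})\,d\theta$,
which the package validates against exact quadrature and, for the Rayleigh
model with the Jeffreys prior, against conjugate closed forms
($\mathrm{Gamma}(m, S)$ posterior, $2mxS^m/(S+x^2)^{m+1}$ predictive,
$S = \sum_r (1+R_r) x_r^2$).

The package is aimed at reliability and survival statisticians who need:

* **scheme algebra** — validation, risk-set sizes $\gamma_s$, the marginal
  mixture coefficients $c_{r-1}, a_{s,r}$, and exact identity checks
  (`censoring_scheme()`, `gamma_values()`, `marginal_coefficients()`,
  `collapse_double_sum()`);
* **exact censored-sample simulation** and likelihood/score evaluation
  (`draw_progressive_sample()`, `joint_log_likelihood()`, `fit_mle()`);
* **marginal laws** of individual censored order statistics and their
  moments (`marginal_pdf_rth()`, `rayleigh_marginal_moment()`);
* **geometry tensors** at a parameter point, in both the joint-likelihood
  and the marginal-informed construction — the latter collapses to the
  former by a score identity, and the package computes the collapse
  residual rather than hiding it (`metric_tensor()`, `alpha_connection()`,
  `rc_curvature()`, `marginal_informed_connection()`);
* **Bayesian prediction** by exact quadrature, conjugate closed forms, and
  asymptotic expansion, with a validated corrected expansion mode and a
  regression-locked fidelity mode (`posterior_exact()`,
  `predictive_exact()`, `posterior_expansion()`, `predictive_expansion()`);
* a **simulation harness** comparing plug-in and Bayesian prediction with a
  semi-analytic error oracle (`run_prediction_study()`,
  `rayleigh_pivot_error()`, `estimate_kl_risk()`).

## Worked example: insulating-fluid breakdown data

The packaged data set is a progressively censored sample (n = 19, m = 8,
R = (0,0,3,0,3,0,0,5)) of times to breakdown of an insulating fluid tested
at 34 kV, analysed under a Rayleigh lifetime law.

```r
library(pcgeom)

smp <- table2_fixture()
smp
#> Progressively Type-II censored sample (n = 19, m = 8)
#>   x = 0.19, 0.78, 0.96, 1.31, 2.78, 4.85, 6.5, 7.35
#>   R = 0,0,3,0,3,0,0,5

mod <- rayleigh_model()
lam_hat <- fit_mle(smp, mod)          # closed form m / sum((1+R) x^2)
as.numeric(lam_hat)
#> [1] 0.0187412
```

The MLE $\hat\lambda = 8/426.8681 = 0.0187412$ says the fitted density has
scale $\sigma = 1/\sqrt{2\hat\lambda} \approx 5.2$ minutes. Predicting the
density at $x = 2.8$ minutes:

```r
pr <- jeffreys_prior(mod, smp$scheme)
plug_in_density(smp, mod, 2.8)                       # f(x; lam_hat)
#> [1] 0.090609
predictive_exact(smp, mod, pr, 2.8)                  # Bayes, Jeffreys
#> [1] 0.089094
predictive_expansion(smp, mod, pr, 2.8)$value        # corrected expansion
#> [1] 0.089067
predictive_exact(smp, mod, uniform_prior(0, 3), 2.8) # Bayes, uniform prior
#> [1] 0.098423
```

The exact Jeffreys-prior predictive (0.089094) shades the plug-in value
(0.090609) downward, and the corrected asymptotic expansion (0.089067)
reproduces the exact value to three decimals at m = 8 — the $O(m^{-2})$
error the expansion theory promises. The geometry at the fitted point:

```r
geometry_tensors(mod, as.numeric(lam_hat), smp$scheme,
                 alpha = -1, marginal = TRUE)
#> Geometry of model "rayleigh" at theta = (0.0187412), alpha = -1
#> g =
#>          [,1]
#> [1,] 22777.05
#> T[,,1] =
#> [1] -2430699
#> collapse residual h - m*dphi = -3.865e-12
```

$g_{11} = m/\hat\lambda^2$ is the censored Fisher information; the
collapse residual being numerically zero is the score identity that makes
the marginal-informed connection coincide with the joint-likelihood one.

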