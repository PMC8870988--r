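# potbayes

Bayesian peaks-over-threshold (POT) estimation of Generalized Pareto
Distribution (GPD) tail parameters that uses the **whole** series, not just
the exceedances.

## The problem

In extreme value analysis the exceedances $x_u = x - u$ above a high
threshold $u$ (the $p$-quantile of the series) approximately follow a GPD

$$G(x \mid \xi, \sigma) = 1 - (1 + \xi x/\sigma)^{-1/\xi},$$

with shape $\xi$ (heavy tail $\xi>0$, exponential $\xi=0$, bounded
$\xi<0$) and scale $\sigma > 0$. Fitting only the exceedances discards most
of the data. When the baseline distribution generating the series is a
stable law — Lévy ($\alpha=1/2$), Cauchy ($\alpha=1$) or Normal
($\alpha=2$) — the GPD parameters of the standardised family are known
functions of the tail level $p$, and the observed scale enters only through
$\xi = \xi_Z$, $\sigma = a\,\sigma_Z$. For $\alpha < 2$ the closed form is

$$\hat\xi_Z = 1/\alpha, \qquad
\hat\sigma_Z = \frac{1}{\alpha}\left[\frac{C_\alpha(1+\beta)}{1-p}\right]^{1/\alpha},
\qquad C_\alpha = \frac{\Gamma(\alpha)\sin(\alpha\pi/2)}{\pi}.$$

`potbayes` implements three estimators around this structure:

* **`fit_mh_light()` / `fit_mh_heavy()`** — classical random-walk
  Metropolis–Hastings on the exceedances (Gamma priors on
  $(k, \delta) = (-\xi, -\sigma/\xi)$ for light tails; Pareto-I and
  Inverse-Gamma priors on $(\xi, \sigma)$ for heavy tails);
* **`fit_bmh()`** — Baseline MH: a one-parameter MCMC for the baseline
  scale $a$ on the full series, mapped through the family relation;
* **`fit_ipbmh()`** — Informative-Priors Baseline MH: MH on the
  exceedances under Normal priors centred at the BMH mapping with narrow
  tabulated widths.

Plus the supporting pieces: GPD distribution functions
(`dgpd`/`pgpd`/`qgpd`/`rgpd`), exceedance extraction, stable/mixture/Gamma
synthetic generators, simulation calibration of tail relations for new
baselines (`calibrate_relation()`), an MAE simulation-study harness
(`run_mae_study()`, `run_mixture_study()`), a Gamma-baseline application
pipeline (`run_application()`), broom-style `tidy()`/`glance()` methods and
`autoplot()` diagnostics, and a thin CLI (`inst/cli/potbayes.R`).

## Worked example

Cauchy series with scale $a = 2$; tail level $p = 0.9$, so the true tail
parameters are $\xi = 1$, $\sigma = 2/(\pi \cdot 0.1) \approx 6.37$:

```r
library(potbayes)
x <- stable_sample(512, stable_spec("cauchy", a = 2), seed = 15)
fit <- fit_bmh(x, "cauchy", p = 0.9, config = mh_config(preset = "desk", seed = 16))
tidy(fit)
#> # A tibble: 3 × 4
#>   term  estimate conf.low conf.high
#>   <chr>    <dbl>    <dbl>     <dbl>
#> 1 xi        1        1         1
#> 2 sigma     6.59     5.85      7.47
#> 3 a         2.07     1.84      2.35
```

The shape is pinned at the family value $\xi_Z = 1$ (it is data-independent
under BMH) and the scale estimate $6.59$ sits within the credible interval
of the truth, driven by $\hat a = 2.07$ estimated from all 512 points. The
classical fit on the 51 exceedances alone is visibly noisier:

```r
glance(fit_mh_heavy(extract_exceedances(x, 0.9),
                    config = mh_config(preset = "desk", seed = 17)))
#> # A tibble: 1 × 5
#>   method      xi sigma  nobs min_acceptance
#>   <chr>    <dbl> <dbl> <int>          <dbl>
#> 1 mh_heavy 0.746  5.90    51          0.245
```

`run_mae_study(study_config())` quantifies this gap over the full design
grid, and `autoplot()` on the returned table draws the comparison.

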