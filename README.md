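# perfdens

Conditional probability densities for human performance outcomes —
simple reaction time, executive-function error rate and perceptuo-motor
error rate — given three wearable-derived physiological states: stress,
sleep duration and physical exertion.

Teams planning demanding operations (military force management, shift
scheduling, human-factors research) increasingly have live physiological
feeds but no principled way to turn them into *distributions* over
expected performance.  perfdens reimplements a computational pipeline
that does exactly that: it estimates marginal densities for each
variable from pooled heterogeneous data sources, fuses incompatible
stress instruments onto one latent scale, constructs a sparse
four-dimensional joint density constrained by literature effect sizes,
and answers queries with complete conditional densities — so every
prediction comes with its mode, percentiles, central interval, skew and
kurtosis, not just a point estimate.

## The model in brief

For each outcome $y$ the package builds the joint density with the
predictors $\mathbf{x} = (x_1, x_2, x_3)$ as a sparse convex combination
of isotropic Gaussian basis functions on a lattice over $[-1,1]^4$:

$$p(y, \mathbf{x}) = \sum_i \alpha_i f_i(y, \mathbf{x}), \qquad
  f_i(z) = \frac{1}{(2\pi)^2 \sigma_i^4}
  \exp\!\Big(-\tfrac{1}{2\sigma_i^2}\lVert z - \mu_i\rVert^2\Big),
  \qquad \alpha \ge 0,\ \textstyle\sum_i \alpha_i = 1 .$$

The coefficients minimize a weighted least-squares misfit to (a) the
supplied marginals evaluated at $K$ points per axis and (b) the
predictor–outcome correlations
$r_{x_j y} = (E[x_j y] - m_{x_j} m_y)/(s_{x_j} s_y)$, under an
iteratively reweighted adaptive LASSO with probability-simplex
constraints — convex at every step, hence deterministic and
initialization-free.  Conditioning is closed-form: $p(y \mid \mathbf{x})$
is again a univariate Gaussian mixture.  Stress, observed through
cortisol, alpha amylase, heart rate and subjective ratings, is fused by
maximum likelihood over per-source affine maps $d_i = a_i s + b_i$ into
a shared latent Gaussian mixture $p_S(s)$.

See `vignette("performance-densities")` for the full model description,
numerical conventions and verification strategy.

## Worked example

Fit the reaction-time joint density on the packaged synthetic marginal
suite with the default literature effect sizes, then query it at a
physical predictor point (latent stress 2.4, 5.5 h sleep, Borg 15):

```r
library(perfdens)

suite <- gen_marginal_suite(seed = 1)
fit <- fit_joint_density(
  c(suite$marginals["reaction_time"],
    suite$marginals[c("stress", "sleep", "exertion")]),
  default_effect_sizes(), outcome = "reaction_time", n_per_axis = 9)

print(fit)
#> joint_density [reaction_time]: N = 9 per axis, M = 7 widths, N_B = 45927
#>   270 nonzero coefficients (target <= 400), sum = 1.000000

recovered_stats(fit)
#> Supplied vs recovered effect sizes (r):
#>          supplied recovered abs_error
#> stress      0.220    0.2219    0.0019
#> sleep      -0.278   -0.2733    0.0047
#> exertion   -0.053   -0.0580    0.0050
#>
#> Marginal L1 discrepancies (supplied vs recovered):
#> reaction_time        stress         sleep      exertion
#>        0.0213        0.0286        0.0105        0.0084

predict(fit, newdata = c(2.4, 5.5, 15), units = "physical")
#>      mean     sd    mode  median      lo      hi   skew excess_kurtosis
#> 1 384.422 33.025 386.346 385.414 315.354 446.198 -0.303           0.629
```

The fit keeps 270 of 45,927 candidate components; the recovered
correlations sit within ±0.005 of the supplied literature values and the
recovered marginals within L1 ≤ 0.03 of the supplied ones.  The query
says that under short sleep, raised stress and hard exertion the model
expects a reaction time of ~384 ms with a 95% predictive interval of
roughly 315–446 ms; the negative skew and positive excess kurtosis
quantify the asymmetry of that prediction.

`run_pipeline(run_config(), out_dir = "model_dir")` runs the whole chain
(marginals → stress fusion → three joint fits → fidelity report) and
writes a self-describing model directory.  A thin command-line wrapper
with `simulate`, `fit-fusion`, `build-joint`, `recover-stats`, `query`
and `run-all` subcommands ships at `inst/cli/perfdens.R`.

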