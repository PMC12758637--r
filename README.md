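# gskmr — kernel machine regression with categorical effect modification

`gskmr` is an R package for estimating the health effects of environmental
mixtures when those effects may differ across subgroups. It targets the
common epidemiological setting of a continuous outcome (say, a
neurodevelopment score), a handful of correlated continuous exposures
(say, lead, manganese and arsenic in cord blood), adjustment covariates,
and one categorical effect modifier (say, child sex).

## The model

The backbone is Bayesian kernel machine regression (BKMR):

    y_i = h(z_i) + x_i' beta + eps_i,     eps_i ~ N(0, sigma^2)
    h ~ GP(0, tau * K),  K(z_i, z_j; rho) = exp[ -sum_m (z_im - z_jm)^2 / rho_m ]

The surface `h` captures nonlinearities and interactions among the
exposures. Effect modification by a categorical variable `w` with P levels
is handled three ways:

* **stratified** — an independent BKMR per subgroup (nothing shared);
* **modifier-in-kernel** — indicator-coded `w` appended to the kernel
  inputs of a single BKMR (everything shared; group surfaces penalized
  toward each other);
* **group-separable** — a block-diagonal kernel
  `K_gs(i, j) = tau_{w_i} * K(z_i, z_j; rho)` if `w_i = w_j`, else `0`,
  sharing `beta`, `sigma^2` and the bandwidths `rho` across groups while
  giving each group its own surface variance `tau_g` and an unpenalized
  surface shape.

The group-separable variant is the recommended middle ground: it keeps the
variance advantages of a pooled analysis without forcing the group
surfaces to look alike. Fitting marginalizes `h` and runs MCMC on
(`beta`, `sigma^2`, `lambda = tau/sigma^2`, `r = 1/rho`); group-separable
linear algebra works block-by-block, so only subgroup-sized matrices are
factorized.

Posterior summaries follow mixture-analysis convention: total-mixture
effects (all exposures at quantile q2 versus q1), single-exposure
interquartile effects with the other exposures at their medians,
exposure-response curves along quantile grids, and between-group
differences of any of these, all with 95% credible intervals obtained by
sampling the surface from its conditional distribution per retained draw.

## Worked example

```r
library(gskmr)

# a synthetic two-group study: 77 + 73 children, three correlated
# lognormal exposures, a nonlinear-with-interaction effect at full
# strength in group 1 and half strength in group 2
spec <- builtin_scenario("two_level_A", seed = 42)
spec$group_sizes <- c(77L, 73L)
gen <- generate_dataset(spec)

fit <- kmr(gen$dataset, variant = "group_separable",
           control = kmr_control(iter = 2000, burnin = 1000, thin = 2,
                                 seed = 1))
fit

e1 <- total_mixture_effect(fit, q1 = 0.5, q2 = 0.75, group = 1)
e2 <- total_mixture_effect(fit, q1 = 0.5, q2 = 0.75, group = 2)
e1; e2
between_group_difference(e1, e2)
```

```
Bayesian kernel machine regression fit
  variant:   group_separable 
  n = 150 , M = 3 exposures, P = 2 group(s)
  draws:     500 retained ( 2000 iterations, 1000 burn-in, thin 2 )
  acceptance: lambda 0.41 0.48 | r 0.43 0.49 0.38 
total_mixture effect [g1]: 1.0923 (95% CrI 0.6209, 1.5269)
total_mixture effect [g2]: 0.6007 (95% CrI 0.1382, 1.0365)
diff_total_mixture effect [g1 - g2]: 0.4916 (95% CrI -0.0953, 1.1030)
```

The total-mixture effect is the expected-outcome change when all three
exposures move from their median to their third quartile. The generating
truth for this dataset is 1.06 for group 1 and 0.53 for group 2 (half
strength), so both group-specific intervals cover their truths, and the
between-group difference — the quantity a stratified analysis struggles to
pin down — is estimated at 0.49 against a true 0.53.

Convergence is checked the usual way:

```r
diagnostics_report(fit)   # ESS and Geweke z per scalar parameter
plot(fit)                 # trace plots
```

A command-line wrapper over the same functions lives at
`inst/cli/gskmr.R` (subcommands `fit`, `summarize`, `simulate`,
`diagnose`, configured by YAML/JSON).

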