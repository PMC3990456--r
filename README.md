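# carloglin

Bayesian log-linear modelling of contingency tables whose factor levels are
*dependent* — most commonly geographical regions — with a default prior that
carries that dependence into the regression parameters, and a
reversible-jump MCMC sampler for model-averaged inference on complete and
incomplete (multi-list capture–recapture) tables.

## The model

Cell counts are independent Poisson,

    y_i | phi, beta ~ Poisson(lambda_i),   log lambda_i = phi + x_i' beta,

with a flat prior on the intercept `phi`.  For each log-linear term `t`
(main effect or interaction) the *constrained* parameters `theta_t` relate
to the free ones by `theta_t = A_t beta_t`, where under sum-to-zero
constraints `A_t = P_t [I_{p_t}; C_t]`.  The prior is built by starting
from an unconstrained scale,

    theta_t | sigma_t^2, D_t ~ N(0, sigma_t^2 D_t),

and conditioning on the constraints, which gives

    beta_t | sigma_t^2, D_t ~ N(0, sigma_t^2 Sigma_t),
    Sigma_t = (A_t' D_t^{-1} A_t)^{-1}.

The scale matrix `D_t` encodes the dependence structure of the term's
factor levels:

* **identity** — independent levels; with `sigma_t^2 = g q_t / n` the joint
  prior collapses to the generalised hyper-g form
  `beta | g ~ N(0, g (X'X)^{-1})`;
* **CAR** — `D_t = (I - tau G)^{-1}` for a region adjacency matrix `G`,
  positive-definite for `tau` between the reciprocals of `G`'s extreme
  eigenvalues;
* **distance** — `D_t,ij = exp(-d_ij^2 / (2 tau^2))` for pairwise
  distances `d_ij`;
* **interactions** — the Kronecker product of the constituents' scale
  matrices, so two interaction levels correlate like the main effect
  exactly when all other constituent levels coincide.

`g` gets an inverse-gamma hyperprior `IG(a/2, b n/2)` (default
`a = b = 1e-3`) or can be fixed; `tau` gets a uniform prior on its
permissible interval.  Inference uses data-augmentation MCMC: structurally
missing cells (the capture–recapture cells seen by no source) are imputed
from their Poisson full conditionals, `(phi, beta)` moves by an
iteratively-weighted-least-squares Metropolis–Hastings step, `g` by
conjugate Gibbs, `tau` by a reflected random walk, and the model moves by
reversible jump over the hierarchical space of interactions.  Posterior
summaries include the total-population posterior with highest-posterior-
density intervals (optionally stratified by factors), posterior model
probabilities, the posterior-odds/prior-odds Bayes factor for `tau > 0`,
and a posterior predictive (Freeman–Tukey) p-value for model adequacy.

## Worked example

A synthetic three-list capture–recapture study over eleven regions on a
built-in (synthetic) adjacency map, with regionally varying catchability
and a known truth:

```r
library(carloglin)

fx <- scotland_like_fixture(seed = 7)
fx$masked
#> Contingency table: 352 cells (44 missing), observed total 12267

prior <- prior_spec(fx$layout,
                    list(region = dependence_structure("car", G = fx$G)))
space <- model_space(fx$layout, models = list(fx$spec$interactions))
draws <- run_chain(fx$masked, prior, space,
                   sampler_config(iterations = 5000, burnin = 500,
                                  thin = 2, seed = 1),
                   start_interactions = fx$spec$interactions)
summarize_draws(draws, tau_interval = unname(fx$tau_bounds))
#> Posterior summary
#> Posterior for N: mean 13071.0 (rounded 13 100), 95% HPDI (12992.0, 13145.0)
#> tau: mean 0.286, 95% HPDI (0.217, 0.329), P(tau>0) = 1.000
#> Top models:
#>                                                                  model
#>  source1:region+source2:region+source3:region+age:region+gender:region
#>  probability
#>            1

fx$truth$N       # 13089 — inside the interval
fx$tau_true      # 0.263 — the generating spatial dependence
```

The population total `N` sums the observed counts and the imputed
all-unobserved cells; `P(tau > 0)` near one says the data support positive
spatial association between neighbouring regions, and
`bayes_factor_tau_positive()` converts such a probability into a Bayes
factor against the uniform prior odds.

A thin command-line wrapper over the same functions is installed at
`inst/cli/carloglin` (subcommands `fit`, `simulate`, `prior-report`,
`summarize`, driven by YAML configs).

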