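---
title: "Dependence-structured default priors for log-linear models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dependence-structured default priors for log-linear models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carloglin)
```

# The model

A population cross-classified by `c` factors with `l_1, ..., l_c` levels
yields a contingency table of `n = prod(l_k)` cells.  Cell counts are
modelled as independent Poisson variables whose log means are linear in
the log-linear terms,

$$y_i \mid \phi, \beta \sim \mathrm{Poisson}(\lambda_i), \qquad
  \log \lambda_i = \phi + x_i^{\top}\beta,$$

with an (improper) flat prior on the intercept $\phi$; the posterior is
still proper, and because $\phi$ appears in every model it does not
distort model comparison.  In multi-list (capture--recapture) studies some
factors are *sources* — each records whether an individual appeared on one
list — and the cells unobserved by every source are structurally missing,
so the population total $N$ is unknown.  `carloglin` represents those
cells with an explicit mask (never a sentinel count): imputation has to
distinguish an observed zero from an unobserved cell.

## Constraints

Each term $t$ has $q_t = \prod_{j \in R_t} l_j$ constrained parameters
$\theta_t$ but only $p_t = \prod_{j \in R_t}(l_j - 1)$ free ones,
$\theta_t = A_t \beta_t$, where $R_t$ is the set of the term's constituent
factors.  Under sum-to-zero constraints $A_t$ factorises as
$P_t[I_{p_t}; C_t]$.  Two conventions are fixed package-wide:

* **Cell and row order.**  Cells are linearised with the *last* listed
  factor varying fastest, and every Kronecker composition (of constraint
  matrices and of scale matrices) uses the same order, so rows of $A_t$
  align with the term's level combinations.
* **The permutation $P_t$.**  The redundant rows of $\theta_t$ are those
  in which *any* constituent factor sits at its last level.  Among the
  redundant rows, the ordering is recursive: rows with the slowest
  constituent at its last level come first (in $\theta$ order), then the
  rule recurses over the remaining factors.  Several permutations are
  consistent with the factorisation and all give the same conditioned
  covariance; this one is pinned so that the worked 2x3 example
  reproduces a fixed, documented matrix triple in the regression tests.

Corner-point (reference level 1) and Helmert systems are supported through
the same Kronecker construction with `stats::contr.treatment` and
`stats::contr.helmert` as the per-factor contrast; Helmert matrices contain
no identity sub-block, so no $P_t[I; C_t]$ factorisation is reported for
them.  Exact transforms between systems use
$\beta_A = R_A X \beta$ with
$R_A = (X_A^{\top} M X_A)^{-1} X_A^{\top} M$ and $M = I - J_n/n$.  The
centering projection matters: the intercept is carried separately, so only
the *centered* column span of a design is shared across constraint
systems.  On that span the hat matrix is system-invariant, and under the
identity structure the transformed prior covariance equals
$g\,(X_A^{\top} M X_A)^{-1}$ exactly — with raw (uncentered) corner-point
indicator columns the identity is provably false, which is why
`hat_matrix()` and `constraint_transform()` center first.

## The conditioned prior

The prior treats the constrained parameters as exchangeable draws from a
scale structure and then conditions on identifiability:
$\theta_t \sim N(0, \sigma_t^2 D_t)$ restricted to the constraint surface
gives

$$\beta_t \mid \sigma_t^2, D_t \sim N(0, \sigma_t^2 \Sigma_t), \qquad
  \Sigma_t = (A_t^{\top} D_t^{-1} A_t)^{-1}.$$

`term_prior_covariance()` evaluates this through the Cholesky factor of
$D_t$ (never an explicit inverse), which stays stable near the ends of the
permissible dependence interval.  Supported structures:

* **identity**: $D_t = I$, recovering $\Sigma_t = (A_t^\top A_t)^{-1}$ and —
  with $\sigma_t^2 = g q_t / n$ — the generalised hyper-g prior
  $\beta \mid g \sim N(0, g (X^\top X)^{-1})$ on complete balanced tables.
* **CAR**: $D_t = (I - \tau G)^{-1}$ for a binary symmetric adjacency $G$.
  Positive definiteness holds exactly for
  $\tau \in (1/e_{\min}, 1/e_{\max})$, the reciprocals of $G$'s extreme
  eigenvalues, and `tau_bounds()` computes the interval that way.  For the
  three-region path graph the extreme eigenvalues are $\pm\sqrt{2}$, so
  the interval is $(-1/\sqrt2, 1/\sqrt2)$ — consistent with the closed
  form of the path-graph $D$, whose common denominator $1 - 2\tau^2$
  vanishes precisely at those endpoints.
* **distance**: the Gaussian correlation
  $D_{t,ij} = \exp(-d_{ij}^2 / 2\tau^2)$, $\tau > 0$.
* **interaction terms**: $D_t = \bigotimes_{r \in R_t} D_r$ in layout
  order.  This composition is chosen for its consistency: the correlation
  between two interaction levels equals the main-effect correlation if and
  only if all other constituent levels agree.  It also means every model
  in a hierarchical space shares the same small set of hyperparameters —
  one $\tau$ per correlated factor, reused by every term containing it.

Hyperparameters and defaults: $g \sim IG(a/2,\, b n/2)$ with
$a = b = 10^{-3}$ (a heavy-tailed, effectively scale-free default), or a
fixed $g = kn$ ("$k$ units of prior information"; $k = 1$ gives the
unit-information special case).  $\tau$ takes a uniform prior over its
permissible CAR interval by default; a distance structure has no natural
bounded support, so its uniform prior interval must be supplied in the
configuration — an application-specific choice the package deliberately
does not guess.

# The sampler

`run_chain()` performs, per sweep and in this order: missing-cell
imputation, the within-model $(\phi, \beta)$ update, the Gibbs update of
$g$, the reflected random-walk update of $\tau$, and one reversible-jump
move.  The sweep order is an implementation decision (nothing in the
posterior requires a particular order); it places the cheap conjugate
updates between the two expensive likelihood-driven ones.

* **Within-model update.**  One Metropolis--Hastings step proposing
  $(\phi, \beta)$ jointly from the normal approximation obtained by a
  single iteratively-weighted-least-squares step at the current state,
  with the exact Poisson-posterior ratio (including the reverse-move IWLS
  approximation) in the acceptance probability.  If the weighted system is
  numerically singular the kernel falls back to a symmetric random walk;
  fallbacks are counted in the diagnostics.
* **Initialisation.**  The chain starts $(\phi, \beta)$ at the conditional
  posterior mode (a few deterministic IWLS iterations) and sizes $g$ from
  that $\beta$.  This is not cosmetic: starting at $\beta = 0$ in hyper-g
  mode collapses the conjugate $g$ draw to roughly $bn/(a + p)$, which in
  turn pins $\beta$ at zero — a self-locking state the chain escapes only
  with enormous luck.
* **$g$ update.**  Conjugate Gibbs:
  $g \mid \beta \sim IG\!\big((a + p)/2,\ (bn + \beta^{\top}\Psi_0^{-1}\beta)/2\big)$
  with $\Psi_0 = \mathrm{blockdiag}((q_t/n)\Sigma_t)$.  No tuning.
* **$\tau$ update.**  Random-walk Metropolis reflected at the interval
  ends (the reflected kernel is symmetric).  The proposal scale defaults
  to a tenth of the interval width and adapts towards a 20--50%
  acceptance rate during burn-in only, so the post-burn-in kernel is
  fixed and ergodicity is untouched.  One $\tau$ is shared by all terms
  whose constituents include the correlated factor.
* **Reversible jump.**  A move adds or deletes one interaction chosen
  uniformly among the hierarchy-preserving single-term changes (model
  prior: discrete uniform).  New-term coefficients are drawn from the
  conditional IWLS normal approximation at the current state; the
  acceptance ratio includes that proposal density and the move-count
  asymmetry, so the joint posterior over $(m, \phi, \beta)$ is preserved.
* **Imputation.**  Given $(\phi, \beta)$ the cells are conditionally
  independent, so missing counts are drawn directly from
  $\mathrm{Poisson}(\lambda_i)$.  The linear predictor is capped at 50 (and
  the Poisson mean at $10^8$) purely as an overflow guard; trips are
  counted and reported.

All randomness flows from the single seed in `sampler_config()`; two runs
with the same configuration are bitwise identical.

# The synthetic-data generator

`generator_spec()`/`generate_table()` draw tables from a known log-linear
truth — fixed coefficients, or coefficients drawn from the package's own
conditioned prior at a stated scale and $\tau$ — and optionally mask the
source-unobserved cells.  Two fixtures are bundled:

* `pedagogic_fixture()`: the 2x2x3 hospital-patient table (age,
  hypertension, region A/B/C on a path graph) with its documented
  constraint matrices; used for exact regression tests.
* `scotland_like_fixture()`: a six-factor incomplete table — three binary
  sources, age, gender, and eleven regions — with 352 cells of which the
  44 unobserved-by-all-sources cells are masked.  The adjacency is a
  *synthetic*, documented eleven-node planar-ish graph; it is an invented
  map and no claim is made that it reproduces any real health-board
  geography or its eigenvalue interval.

The fixture's generating model holds the three sources mutually
independent (the classical identifying assumption for three-list
abundance estimation), fixes per-list catchability near 0.55--0.65 so a
few percent of the population lands in the masked cells, and draws the
region main effect plus all five region-involving two-way interactions
(regionally varying catchability, age and gender composition) from the
conditioned CAR prior at a common scale $g_{\mathrm{true}} = 4$
($\sigma_t = \sqrt{g q_t / n}$) and $\tau = 0.8\,\tau_{\max}$.  Those
defaults were chosen once, on information-theoretic grounds: with three or
fewer region-informative coefficient blocks the average attainable
posterior probability of positive dependence tops out near 0.88 even for
an oracle that knows the true coefficients, while six blocks support
decisive recovery; and a large structurally-missing fraction makes
short-chain data-augmentation mixing, not the science, the binding
constraint.  What the generator does **not** emulate: realistic prevalence
magnitudes of any real injecting-drug-user study, real list-overlap
behaviour (source dependence), overdispersion, or real geography.  Passing
tests therefore demonstrate internal calibration of the method under its
own assumptions — not performance on any particular real dataset.

# Numerical choices and degenerate inputs

* $\Sigma_t$ via Cholesky of $D_t$; prior precisions are assembled from
  small per-factor pieces ($A_r^{\top}A_r$ and $A_r^{\top} G A_r$, linear
  in $\tau$ for CAR factors), so a $\tau$ proposal never inverts anything
  larger than a term block.
* The Poisson log-likelihood uses `lgamma(y + 1)`; MH ratios drop the
  $y!$ terms, which cancel at fixed data.
* A complete table makes the $N$ posterior a point mass; summaries report
  the constant rather than failing.  A model space of size one turns the
  reversible jump into a counted no-op.  Zero-iteration configurations
  return empty draw sets.
* HPDIs are shortest sorted windows on the draws (no density smoothing):
  reproducible, equivariant under monotone affine maps, and requiring at
  least 100 draws.
* The Bayes factor for $\tau > 0$ is posterior odds over prior odds with
  the uniform-prior probability $\tau_{\max}/(\tau_{\max} - \tau_{\min})$;
  this is the definition under which a posterior probability and a
  uniform interval jointly determine the factor.
* The posterior predictive p-value uses the Freeman--Tukey discrepancy
  $\sum(\sqrt{y} - \sqrt{\lambda})^2$ by default (robust for small
  counts); a chi-square discrepancy is available.

# Scope decisions

* All non-masked cells are treated as observed counts; the package does
  not attempt to distinguish sampling zeros from undeclared structural
  zeros outside the source-unobserved mask.
* Only the Poisson parameterisation is implemented (no multinomial or
  hypergeometric variants), and only hierarchical model spaces.
* The $\sigma_t^2 = g q_t / n$ scaling is applied to every term,
  including those with non-identity scale structures, keeping a single
  $g$ interpretable across the whole model space.
* Row-standardised (proper-CAR) neighbourhood variants and non-Gaussian
  distance kernels are out of scope; the structure interface is the
  extension point.

# Problem sizes used by the test suite

The correctness arguments lean on small exactly-solvable problems
(two-cell quadrature, 2x2 brute-force evidence integration, conditioning
oracles on terms with $q_t \le 6$) and on scaled-down calibration studies:
100 replicates of the six-factor test bed with chains of 5000 sweeps
(burn-in 500, thinning 2) and the model space held at the generating
model, plus a 20-replicate coverage check on a smaller 40-cell three-list
fixture.  These sizes are the package's own choice of a study that a
reviewer can re-run on a laptop in minutes; they are deliberately far
smaller than a production analysis, which would run the full
reversible-jump space for millions of sweeps.

# Known limitations

* The one-block IWLS proposal loses efficiency as $p$ grows into the
  hundreds; blocked or gradient-based updates would be the next step.
* Posterior model probabilities come from reversible-jump visit
  frequencies only; no marginal-likelihood estimator is provided.
* Short chains slightly understate HPDI widths for the population total
  in hard capture-recapture designs (large missing fractions); the
  calibration study documents the regime in which the intervals are
  trustworthy.
* Convergence diagnostics are limited to acceptance rates and the
  summaries; draws are written as plain tables precisely so external
  diagnostic tooling can consume them.
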