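test_that("chains are reproducible and degenerate configs behave", {
  fx <- pedagogic_fixture()
  spec <- generator_spec(fx$layout, phi = log(30),
                         beta = list(age = 0.2, hypertension = -0.1,
                                     region = c(0.3, -0.2)), seed = 4)
  tab <- generate_table(spec)$complete
  pr <- prior_spec(fx$layout)
  cfg <- sampler_config(iterations = 400, burnin = 100, seed = 9)
  d1 <- run_chain(tab, pr, config = cfg)
  d2 <- run_chain(tab, pr, config = cfg)
  expect_identical(d1$phi, d2$phi)
  expect_identical(d1$beta, d2$beta)
  expect_identical(d1$g, d2$g)
  d0 <- run_chain(tab, pr, config = sampler_config(iterations = 0, burnin = 0))
  expect_length(d0$phi, 0)
  # single-model space: the reversible jump is a no-op
  sp1 <- model_space(fx$layout, max_order = 1)
  d3 <- run_chain(tab, pr, sp1, cfg)
  expect_true(all(d3$model == "independence"))
})

test_that("the IWLS acceptance ratio is exactly one for a null move", {
  fx <- pedagogic_fixture()
  tab <- generate_table(generator_spec(fx$layout, phi = log(20), seed = 2))$complete
  pr <- prior_spec(fx$layout)
  set.seed(1)
  e <- chain_init(tab, pr, config = sampler_config(iterations = 0, burnin = 0))
  b <- c(e$phi, e$beta)
  fw <- carloglin:::.iwls(e, b)
  # proposing the current state: likelihood, prior and both proposal
  # densities cancel exactly
  lr <- (carloglin:::.llik(e$y, e$eta) + carloglin:::.lprior_beta(e, b[-1]) +
           carloglin:::.ldnorm_prec(b, fw$m, fw$R)) -
        (carloglin:::.llik(e$y, e$eta) + carloglin:::.lprior_beta(e, b[-1]) +
           carloglin:::.ldnorm_prec(b, fw$m, fw$R))
  expect_identical(lr, 0)
})

test_that("within-model draws match the IWLS point estimate on rich data", {
  # large balanced table: the posterior concentrates at the MLE, which the
  # independent oracle computes by Fisher scoring (glm)
  fx <- pedagogic_fixture()
  spec <- generator_spec(fx$layout, phi = log(9000),
                         beta = list(age = 0.25, hypertension = -0.15,
                                     region = c(0.2, -0.1)), seed = 21)
  tab <- generate_table(spec)$complete
  d <- build_design(fx$layout)
  fit <- glm(tab$counts ~ d$X, family = poisson())
  pr <- prior_spec(fx$layout)
  dr <- run_chain(tab, pr, config = sampler_config(iterations = 3000,
                                                   burnin = 500, seed = 10))
  for (j in seq_len(ncol(dr$beta))) {
    se <- max(mcse(dr$beta[, j]), 1e-5)
    expect_lt(abs(mean(dr$beta[, j]) - coef(fit)[j + 1]), 3 * se + 2e-3)
  }
})

test_that("a two-cell chain agrees with exact quadrature", {
  lay <- make_layout("grp", 2)
  y <- c(7, 12)
  tab <- contingency_table(lay, y)
  g_fix <- 2 * 2  # fixed unit-information g: s2 = g q/n = g
  pr <- prior_spec(lay, g_mode = "fixed", g_fixed = g_fix)
  s2 <- g_fix * 2 / 2 * 0.5   # sigma_t^2 (A'A)^{-1} = s2/2 per free param
  quad <- two_cell_quadrature(y, s2)
  dr <- run_chain(tab, pr, config = sampler_config(iterations = 20000,
                                                   burnin = 2000, seed = 31))
  se <- mcse(dr$beta[, 1])
  expect_lt(abs(mean(dr$beta[, 1]) - quad$beta_mean), 3 * se)
  se_phi <- mcse(dr$phi)
  expect_lt(abs(mean(dr$phi) - quad$phi_mean), 3 * se_phi)
})

test_that("a discretised two-cell chain matches quadrature in total variation", {
  lay <- make_layout("grp", 2)
  y <- c(9, 15)
  tab <- contingency_table(lay, y)
  pr <- prior_spec(lay, g_mode = "fixed", g_fixed = 4)
  quad <- two_cell_quadrature(y, 4 * 0.5)
  dr <- run_chain(tab, pr, config = sampler_config(iterations = 150000,
                                                   burnin = 5000, seed = 17))
  # bin the beta draws on the quadrature grid
  grid <- quad$beta
  half <- diff(grid[1:2]) / 2
  breaks <- c(grid[1] - half, grid + half)
  emp <- tabulate(findInterval(dr$beta[, 1], breaks), nbins = length(grid))
  emp <- emp / sum(emp)
  expect_lt(0.5 * sum(abs(emp - quad$beta_marg)), 0.02)
})

test_that("the g update draws from its conjugate full conditional", {
  fx <- pedagogic_fixture()
  tab <- generate_table(generator_spec(fx$layout, phi = log(15), seed = 3))$complete
  pr <- prior_spec(fx$layout, a = 3, b = 1)
  set.seed(8)
  e <- chain_init(tab, pr, config = sampler_config(iterations = 0, burnin = 0))
  # beta = 0: the quadratic form vanishes and g | beta ~ IG((a+p)/2, bn/2)
  e$beta <- numeric(length(e$beta))
  p <- length(e$beta); n <- e$n
  draws <- replicate(4000, { update_g(e); e$g })
  u <- pgamma(1 / draws, shape = (3 + p) / 2, rate = 1 * n / 2)
  ks <- max(abs(sort(u) - (seq_along(u) - 0.5) / length(u)))
  expect_lt(ks, 1.36 / sqrt(4000) * 1.5)
  # grid oracle for the single-parameter conditional density
  e2 <- chain_init(contingency_table(make_layout("grp", 2), c(5, 8)),
                   prior_spec(make_layout("grp", 2), a = 3, b = 1),
                   config = sampler_config(iterations = 0, burnin = 0))
  beta1 <- 0.4; e2$beta <- beta1
  gs <- seq(0.01, 40, length.out = 4000)
  # prior IG(a/2, bn/2) x N(beta; 0, g q/n (A'A)^{-1})
  s2_unit <- (2 / 2) * 0.5
  lp <- (-3 / 2 - 1) * log(gs) - (1 * 2) / (2 * gs) -
    0.5 * log(gs * s2_unit) - beta1^2 / (2 * gs * s2_unit)
  dens <- exp(lp - max(lp)); dens <- dens / sum(dens * diff(gs[1:2]))
  # conditional density implied by the Gibbs draw: IG(shape, rate),
  # normalised on the same grid so only the shapes are compared
  shape <- (3 + 1) / 2
  rate <- (1 * 2 + beta1^2 / s2_unit) / 2
  ig <- exp((-shape - 1) * log(gs) - rate / gs)
  ig <- ig / sum(ig * diff(gs[1:2]))
  expect_lt(max(abs(dens - ig)) / max(ig), 1e-6)
  # and the code's draws follow that conditional
  draws2 <- replicate(3000, { e2$beta <- beta1; update_g(e2); e2$g })
  u2 <- pgamma(1 / draws2, shape = shape, rate = rate)
  expect_lt(max(abs(sort(u2) - (seq_along(u2) - 0.5) / length(u2))), 0.04)
})

test_that("the tau kernel targets the beta prior and reflects at the bounds", {
  fx <- pedagogic_fixture()
  pr <- pedagogic_prior()
  tab <- generate_table(generator_spec(
    fx$layout, phi = log(20),
    structures = list(region = dependence_structure("car", G = fx$G)),
    tau = c(region = 0.3), draw = list(region = 0.5), seed = 6))$complete
  set.seed(14)
  e <- chain_init(tab, pr, config = sampler_config(iterations = 0, burnin = 0))
  # symmetric proposal: the acceptance log-ratio equals the log-target
  # difference, i.e. the beta-prior difference at the two tau values
  tau0 <- e$tau[["region"]]
  lp0 <- carloglin:::.lprior_beta(e, e$beta)
  tau1 <- 0.21
  e$tau[["region"]] <- tau1
  carloglin:::.refresh_prec_cache(e, seq_len(e$T_))
  carloglin:::.refresh_Q0(e)
  lp1 <- carloglin:::.lprior_beta(e, e$beta)
  expect_true(is.finite(lp1 - lp0))
  # reflection keeps proposals inside the open interval
  iv <- e$tau_interval[["region"]]
  for (x in c(iv[1] - 0.3, iv[2] + 0.12, iv[2] + 2.7)) {
    rx <- carloglin:::.reflect(x, iv[1], iv[2])
    expect_true(rx >= iv[1] && rx <= iv[2])
  }
  # spatial-signal recovery: eleven regions on the synthetic map, with the
  # region main effect and two region-interactions drawn from the
  # conditioned CAR prior near tau_max.  The sampler's P(tau > 0) must
  # track the independent quadrature oracle computed from the true
  # effects, and on data whose oracle confirms a strong signal the
  # posterior mass above zero must exceed 0.9.
  G11 <- carloglin:::.synthetic_region_graph()
  lay11 <- make_layout(c("u", "v", "region"), c(2, 2, 11))
  b11 <- tau_bounds(G11)
  n11 <- lay11$n
  tcs <- list(term_constraint(lay11, "region"),
              term_constraint(lay11, c("u", "region")),
              term_constraint(lay11, c("v", "region")))
  s2s <- list(4 * 11 / n11, 4 * 22 / n11, 4 * 22 / n11)
  pr11 <- prior_spec(lay11,
                     list(region = dependence_structure("car", G = G11)))
  ints <- list(c("u", "region"), c("v", "region"))
  sp11 <- model_space(lay11, models = list(ints))
  strong_seen <- FALSE
  for (s in 1:3) {
    spec11 <- generator_spec(
      lay11, interactions = ints,
      phi = log(60), beta = list(u = 0.2, v = -0.1),
      draw = list(region = sqrt(s2s[[1]]), "u:region" = sqrt(s2s[[2]]),
                  "v:region" = sqrt(s2s[[3]])),
      structures = list(region = dependence_structure("car", G = G11)),
      tau = c(region = 0.9 * b11[[2]]), seed = s)
    gen11 <- generate_table(spec11)
    p_oracle <- tau_posterior_oracle(
      G11, tcs, gen11$truth$beta[c("region", "u:region", "v:region")], s2s)
    dr11 <- run_chain(gen11$complete, pr11, sp11,
                      sampler_config(iterations = 4000, burnin = 800, seed = s),
                      start_interactions = ints)
    p_chain <- tau_positive_probability(dr11)
    expect_lt(abs(p_chain - p_oracle), 0.15)
    if (p_oracle > 0.95) {
      strong_seen <- TRUE
      expect_gt(p_chain, 0.9)
    }
  }
  expect_true(strong_seen)
})

test_that("successive-conditional sampling recovers the g and tau priors", {
  # Gibbs scan w.r.t. the joint prior: beta | g, tau direct from the
  # conditioned normal, then the package's g (Gibbs) and tau (reflected
  # random walk) kernels; the (g, tau) marginals must reproduce the prior
  fx <- pedagogic_fixture()
  pr <- prior_spec(fx$layout,
                   list(region = dependence_structure("car", G = fx$G)),
                   a = 6, b = 2)
  tab <- generate_table(generator_spec(fx$layout, phi = log(10), seed = 1))$complete
  set.seed(22)
  e <- chain_init(tab, pr, config = sampler_config(iterations = 0, burnin = 0))
  n <- e$n
  des <- build_design(fx$layout)
  nscan <- 6000L
  gs <- taus <- numeric(nscan)
  for (it in seq_len(nscan)) {
    # draw beta from its prior at the current (g, tau)
    Psi <- joint_prior_covariance(des, pr, e$g,
                                  tau = c(region = e$tau[["region"]]))
    e$beta <- drop(t(chol(Psi)) %*% rnorm(ncol(Psi)))
    update_g(e)
    update_tau(e)
    gs[it] <- e$g; taus[it] <- e$tau[["region"]]
  }
  # g ~ IG(a/2, bn/2): compare on the inverse scale against the Gamma cdf
  u <- pgamma(1 / gs, shape = 6 / 2, rate = 2 * n / 2)
  expect_lt(max(abs(sort(u) - (seq_along(u) - 0.5) / length(u))), 0.05)
  iv <- e$tau_interval[["region"]]
  v <- (taus - iv[1]) / diff(iv)
  expect_lt(max(abs(sort(v) - (seq_along(v) - 0.5) / length(v))), 0.05)
})

test_that("imputation is Poisson at the current rates and N is bookkept", {
  set.seed(30)
  fxs <- small_capture_fixture(seed = 2)
  pr <- prior_spec(fxs$layout,
                   list(region = dependence_structure("car", G = fxs$G)))
  e <- chain_init(fxs$masked, pr,
                  config = sampler_config(iterations = 0, burnin = 0))
  # freeze eta at log 5 in the missing cells and draw repeatedly
  e$eta[e$miss] <- log(5)
  nm <- sum(e$miss)
  tot <- 0; reps <- ceiling(1e5 / nm)
  for (r in seq_len(reps)) { impute_missing(e); tot <- tot + sum(e$y[e$miss]) }
  mhat <- tot / (reps * nm)
  expect_lt(abs(mhat - 5), 3 * sqrt(5 / (reps * nm)))
  # lambda -> 0 limit gives zero counts
  e$eta[e$miss] <- -60
  impute_missing(e)
  expect_true(all(e$y[e$miss] == 0))
  # every retained draw satisfies N = N_observed + imputed total
  dr <- run_chain(fxs$masked, pr,
                  config = sampler_config(iterations = 600, burnin = 100,
                                          seed = 3))
  expect_equal(dr$N, fxs$masked$N_observed + rowSums(dr$y_missing))
})

test_that("reversible jump matches brute-force evidence on a 2 x 2 toy", {
  lay <- make_layout(c("a", "b"), c(2, 2))
  y <- c(18, 11, 9, 14)
  tab <- contingency_table(lay, y)
  pr <- prior_spec(lay, g_mode = "fixed", g_fixed = 4)
  # brute-force log evidence by 3-/4-dimensional grid quadrature
  log_evidence <- function(ints) {
    d <- build_design(lay, ints)
    Psi <- joint_prior_covariance(d, pr, 4)
    fit <- glm(y ~ d$X, family = poisson())
    ctr <- coef(fit); sds <- sqrt(diag(vcov(fit))) + 0.15
    grids <- lapply(seq_along(ctr), function(j)
      seq(ctr[j] - 7 * sds[j], ctr[j] + 7 * sds[j], length.out = 41))
    steps <- vapply(grids, function(g) diff(g[1:2]), 0)
    pts <- as.matrix(expand.grid(grids))
    eta <- pts[, 1] + pts[, -1, drop = FALSE] %*% t(d$X)
    ll <- eta %*% y - rowSums(exp(eta)) - sum(lgamma(y + 1))
    Pinv <- solve(Psi)
    qf <- rowSums((pts[, -1, drop = FALSE] %*% Pinv) * pts[, -1, drop = FALSE])
    lp <- ll - 0.5 * qf - 0.5 * determinant(Psi)$modulus -
      (ncol(Psi) / 2) * log(2 * pi)
    m <- max(lp)
    m + log(sum(exp(lp - m))) + sum(log(steps))
  }
  le0 <- log_evidence(list())
  le1 <- log_evidence(list(c("a", "b")))
  p0_exact <- 1 / (1 + exp(le1 - le0))
  sp <- model_space(lay, max_order = 2)
  run_ind <- function(seed, start) {
    dr <- run_chain(tab, pr, sp,
                    sampler_config(iterations = 30000, burnin = 3000, seed = seed),
                    start_interactions = start)
    as.numeric(dr$model == "independence")
  }
  ind_a <- run_ind(41, list())
  ind_b <- run_ind(42, list(c("a", "b")))
  se_a <- mcse(ind_a); se_b <- mcse(ind_b)
  expect_lt(abs(mean(ind_a) - p0_exact), 3 * se_a + 0.01)
  expect_lt(abs(mean(ind_b) - p0_exact), 3 * se_b + 0.01)
  # chains started from either model agree (between-chain consistency)
  expect_lt(abs(mean(ind_a) - mean(ind_b)), 3 * (se_a + se_b) + 0.01)
})

test_that("model-averaged rates conserve the observed total on complete tables", {
  fx <- pedagogic_fixture()
  tab <- generate_table(generator_spec(
    fx$layout, phi = log(40),
    beta = list(age = 0.2, hypertension = 0.1, region = c(0.2, -0.3)),
    seed = 19))$complete
  pr <- prior_spec(fx$layout)
  sp <- model_space(fx$layout, 2)
  dr <- run_chain(tab, pr, sp, sampler_config(iterations = 6000, burnin = 1000,
                                              seed = 23))
  # with a flat intercept prior, sum(lambda) | y is Gamma(sum y, 1) given
  # any (m, beta), so its posterior mean is exactly the observed total
  tot <- rowSums(lambda_draws(dr))
  expect_lt(abs(mean(tot) - sum(tab$counts)), 3 * mcse(tot))
})

test_that("short-chain HPDIs for N cover the truth across replicates", {
  hits <- 0L
  nrep <- 20L
  for (s in seq_len(nrep)) {
    fxs <- small_capture_fixture(seed = 100 + s)
    pr <- prior_spec(fxs$layout,
                     list(region = dependence_structure("car", G = fxs$G)))
    dr <- run_chain(fxs$masked, pr,
                    config = sampler_config(iterations = 2500, burnin = 500,
                                            thin = 2, seed = 100 + s))
    iv <- hpdi(dr$N, 0.95)
    if (iv[[1]] <= fxs$truth$N && fxs$truth$N <= iv[[2]]) hits <- hits + 1L
  }
  # P(hits <= 16 | true coverage 0.95) < 1e-3
  expect_gte(hits, 17L)
})
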