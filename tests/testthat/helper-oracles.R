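# Shared fixtures and independent oracles used across the test files.

path_graph <- function(q) {
  G <- matrix(0, q, q)
  for (i in seq_len(q - 1L)) G[i, i + 1L] <- G[i + 1L, i] <- 1
  G
}

random_graph <- function(q, p_edge = 0.5) {
  G <- matrix(0, q, q)
  G[upper.tri(G)] <- stats::rbinom(q * (q - 1) / 2, 1, p_edge)
  G <- G + t(G)
  if (sum(G) == 0) G[1, 2] <- G[2, 1] <- 1
  G
}

# marginal sums of the constrained parameters theta_t = A_t beta_t over one
# constituent factor's levels, at every combination of the other
# constituents' levels; all must vanish under sum-to-zero constraints
marginal_sums <- function(theta, level_counts, over) {
  sub <- make_layout(paste0("f", seq_along(level_counts)), level_counts)
  tup <- cell_tuples(sub)
  others <- setdiff(seq_along(level_counts), over)
  key <- if (length(others))
    apply(tup[, others, drop = FALSE], 1L, paste, collapse = "|")
  else rep("all", nrow(tup))
  tapply(theta, key, sum)
}

# linear-Gaussian conditioning oracle for the conditioned prior covariance:
# gamma = P' theta with theta ~ N(0, D); condition gamma^(1) on the event
# gamma^(2) - C gamma^(1) = 0 via the standard conditional covariance
conditional_cov_oracle <- function(P, C, D) {
  p <- ncol(C)
  V <- t(P) %*% D %*% P
  i1 <- seq_len(p); i2 <- (p + 1L):nrow(V)
  # U = gamma^(2) - C gamma^(1)
  S11 <- V[i1, i1, drop = FALSE]
  S1U <- V[i1, i2, drop = FALSE] - S11 %*% t(C)
  SUU <- V[i2, i2, drop = FALSE] - C %*% V[i1, i2, drop = FALSE] -
    V[i2, i1, drop = FALSE] %*% t(C) + C %*% S11 %*% t(C)
  S11 - S1U %*% solve(SUU, t(S1U))
}

# two-cell Poisson model with a single 2-level factor: exact posterior of
# (phi, beta) on a grid, flat prior on phi and N(0, s2) prior on beta
two_cell_quadrature <- function(y, s2, half = 4, nn = 401) {
  fit <- stats::glm(y ~ c(1, -1), family = stats::poisson())
  ctr <- stats::coef(fit)
  phis <- seq(ctr[1] - half, ctr[1] + half, length.out = nn)
  betas <- seq(ctr[2] - half, ctr[2] + half, length.out = nn)
  lp <- outer(phis, betas, function(ph, be) {
    e1 <- ph + be; e2 <- ph - be
    y[1] * e1 + y[2] * e2 - exp(e1) - exp(e2) - be^2 / (2 * s2)
  })
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  list(phi = phis, beta = betas, w = w,
       beta_marg = colSums(w), phi_marg = rowSums(w),
       beta_mean = sum(colSums(w) * betas),
       phi_mean = sum(rowSums(w) * phis))
}

# Monte-Carlo standard error with a crude autocorrelation correction
# (batch means over 25 batches)
mcse <- function(x, nbatch = 25L) {
  nb <- min(nbatch, floor(length(x) / 4))
  bm <- tapply(x, cut(seq_along(x), nb), mean)
  stats::sd(bm) / sqrt(nb)
}

# independent oracle for the posterior probability that tau is positive,
# given the true term effects: grid quadrature of the conditioned-normal
# density of the region-involving blocks over tau (g held at its known
# generating value)
tau_posterior_oracle <- function(G, constraints, beta_list, s2_list,
                                 npts = 161) {
  b <- tau_bounds(G)
  grid <- seq(b[[1]] + 1e-4, b[[2]] - 1e-4, length.out = npts)
  lp <- vapply(grid, function(t) {
    Dreg <- car_scale(G, t)
    tot <- 0
    for (k in seq_along(constraints)) {
      tc <- constraints[[k]]
      nrep <- tc$q / nrow(G)       # identity factors ahead of region
      D <- if (nrep > 1) compose_interaction_scale(list(diag(nrep), Dreg))
           else Dreg
      P <- term_prior_precision(tc, D)
      bt <- beta_list[[k]]
      tot <- tot + 0.5 * determinant(P)$modulus -
        0.5 * sum(bt * (P %*% bt)) / s2_list[[k]]
    }
    as.numeric(tot)
  }, 0)
  w <- exp(lp - max(lp))
  sum(w[grid > 0]) / sum(w)
}

pedagogic_prior <- function() {
  fx <- pedagogic_fixture()
  prior_spec(fx$layout,
             list(region = dependence_structure("car", G = fx$G)))
}

# small capture-recapture test bed: three binary sources and five regions
# on a path, region effect drawn from the conditioned CAR prior
small_capture_fixture <- function(seed, tau_frac = 0.8) {
  lay <- make_layout(c("s1", "s2", "s3", "region"), c(2, 2, 2, 5))
  G <- path_graph(5)
  b <- tau_bounds(G)
  spec <- generator_spec(
    lay, interactions = list(),
    phi = log(60),
    beta = list(s1 = 0.3, s2 = 0.2, s3 = 0.25),
    draw = list(region = 0.4),
    structures = list(region = dependence_structure("car", G = G)),
    tau = c(region = tau_frac * b[[2L]]),
    source_factors = c("s1", "s2", "s3"), seed = seed)
  gen <- generate_table(spec)
  list(layout = lay, G = G, spec = spec, masked = gen$masked,
       complete = gen$complete, truth = gen$truth)
}
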