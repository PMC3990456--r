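test_that("CAR tau bounds are the reciprocal extreme eigenvalues", {
  # single edge: eigenvalues +-1
  expect_equal(unname(tau_bounds(path_graph(2))), c(-1, 1))
  # 3-node path: eigenvalues (-sqrt2, 0, sqrt2); the closed form
  # 1/(1 - 2 tau^2) for D is singular exactly at the bounds
  b <- tau_bounds(path_graph(3))
  expect_equal(unname(b), c(-1, 1) / sqrt(2))
  expect_equal(1 - 2 * b[[2]]^2, 0)
  # random graphs: I - tau G is PD strictly inside, singular at the bounds
  set.seed(7)
  for (r in 1:5) {
    G <- random_graph(6)
    b <- tau_bounds(G)
    for (tau in c(b[[1]] + 1e-9, b[[2]] - 1e-9))
      expect_gt(min(eigen(diag(6) - tau * G, symmetric = TRUE)$values), 0)
    expect_lt(min(eigen(diag(6) - (b[[2]] + 1e-9) * G,
                        symmetric = TRUE)$values), 0)
    expect_equal(det(diag(6) - b[[2]] * G), 0, tolerance = 1e-8)
  }
  expect_error(tau_bounds(matrix(0, 3, 3)), "no edges")
  expect_error(tau_bounds(matrix(1, 3, 3)), "zero diagonal")
})

test_that("the CAR scale matrix matches its printed closed form", {
  G <- path_graph(3)
  for (tau in c(-0.4, 0.3)) {
    D <- car_scale(G, tau)
    D_ref <- (1 / (1 - 2 * tau^2)) *
      rbind(c(1 - tau^2, tau, tau^2),
            c(tau, 1, tau),
            c(tau^2, tau, 1 - tau^2))
    expect_equal(D, D_ref, tolerance = 1e-12)
  }
  expect_equal(car_scale(G, 0), diag(3))
  # multiply-back oracle on random graphs
  set.seed(11)
  for (r in 1:5) {
    G <- random_graph(5)
    b <- tau_bounds(G)
    tau <- runif(1, 0.9 * b[[1]], 0.9 * b[[2]])
    expect_equal((diag(5) - tau * G) %*% car_scale(G, tau), diag(5),
                 tolerance = 1e-10)
  }
  expect_error(car_scale(G, 0.9), "outside the permissible")
})

test_that("the distance structure is the Gaussian correlation of distances", {
  d <- as.matrix(dist(c(0, 1, 2)))
  D <- distance_scale(d, 1)
  expect_equal(unname(diag(D)), rep(1, 3))
  expect_equal(D[1, 2], exp(-1 / 2))
  expect_equal(D[1, 3], exp(-2))
  expect_equal(unname(distance_scale(d, 1e6)), matrix(1, 3, 3),
               tolerance = 1e-10)
  expect_error(distance_scale(d, 0), "positive")
  expect_error(distance_scale(d - 1, 1), "symmetric non-negative")
})

test_that("interaction scale matrices are Kronecker compositions", {
  G <- path_graph(3)
  tau <- 0.3
  D <- compose_interaction_scale(list(diag(2), car_scale(G, tau)))
  blk <- (1 / (1 - 2 * tau^2)) *
    rbind(c(1 - tau^2, tau, tau^2), c(tau, 1, tau), c(tau^2, tau, 1 - tau^2))
  expect_equal(D, rbind(cbind(blk, matrix(0, 3, 3)),
                        cbind(matrix(0, 3, 3), blk)), tolerance = 1e-12)
  expect_equal(compose_interaction_scale(list(diag(2), diag(3))), diag(6))
  # brute-force elementwise oracle
  set.seed(2)
  Da <- crossprod(matrix(rnorm(4), 2)); Db <- crossprod(matrix(rnorm(9), 3))
  Dab <- compose_interaction_scale(list(Da, Db))
  for (i in 1:2) for (j in 1:3) for (k in 1:2) for (l in 1:3)
    expect_equal(Dab[(i - 1) * 3 + j, (k - 1) * 3 + l], Da[i, k] * Db[j, l])
  # consistency: interaction-level correlation equals the main-effect one
  # iff the other constituent's levels agree
  corr <- induced_correlation(D)
  main_corr <- tau / sqrt(1 - tau^2)
  expect_equal(corr[1, 2], main_corr)          # same age, regions A-B
  expect_equal(corr[4, 5], main_corr)
  expect_equal(corr[1, 5], 0)                  # different age levels
})

test_that("conditioning on the constraints gives the published covariance", {
  fx <- pedagogic_fixture()
  tc <- fx$age_region
  for (tau in c(-0.4, 0, 0.3)) {
    D <- compose_interaction_scale(list(diag(2), car_scale(fx$G, tau)))
    S <- term_prior_covariance(tc, D)
    S_ref <- (1 / (3 + 4 * tau)) * rbind(c(1 + tau, -1/2), c(-1/2, 1))
    expect_equal(S, S_ref, tolerance = 1e-10)
  }
  # identity scale reduces to (A'A)^{-1}
  expect_equal(term_prior_covariance(tc, diag(6)), solve(crossprod(tc$A)),
               tolerance = 1e-12)
  # linear-Gaussian conditioning oracle on random small terms
  lay <- make_layout(c("u", "v"), c(2, 2))
  tcs <- list(term_constraint(lay, c("u", "v")),
              term_constraint(make_layout("w", 4), "w"))
  set.seed(5)
  for (tc2 in tcs) for (r in 1:10) {
    D <- crossprod(matrix(rnorm(tc2$q^2), tc2$q)) + diag(tc2$q)
    expect_equal(term_prior_covariance(tc2, D),
                 conditional_cov_oracle(tc2$P, tc2$C, D), tolerance = 1e-10)
  }
})

test_that("the induced correlation of the worked example behaves as stated", {
  fx <- pedagogic_fixture()
  tc <- fx$age_region
  S0 <- term_prior_covariance(tc, compose_interaction_scale(
    list(diag(2), car_scale(fx$G, 0))))
  expect_equal(induced_correlation(S0)[1, 2], -1/2)
  taus <- seq(-0.45, 0.45, by = 0.05)
  cors <- vapply(taus, function(tau) {
    S <- term_prior_covariance(tc, compose_interaction_scale(
      list(diag(2), car_scale(fx$G, tau))))
    induced_correlation(S)[1, 2]
  }, 0)
  expect_equal(cors, -1 / (2 * sqrt(1 + taus)), tolerance = 1e-10)
  expect_true(all(diff(cors) > 0))   # increasing in tau
  expect_true(all(cors < 0))         # but always negative
  expect_equal(induced_correlation(diag(3)), diag(3))
})

test_that("the joint prior reduces to the hyper-g form and composes blocks", {
  fx <- pedagogic_fixture()
  pr_id <- prior_spec(fx$layout)
  g <- 2.2
  for (m in enumerate_models(fx$layout, 2)) {
    d <- build_design(fx$layout, m)
    expect_equal(joint_prior_covariance(d, pr_id, g),
                 g * solve(crossprod(d$X)), tolerance = 1e-10)
  }
  # CAR region block equals the conditioned covariance scaled by g q_t / n
  pr <- pedagogic_prior()
  d <- build_design(fx$layout, list(c("age", "region")))
  tau <- 0.25
  Psi <- joint_prior_covariance(d, pr, g, tau = c(region = tau))
  k <- match("age:region", d$labels)
  idx <- which(rep(seq_along(d$terms), vapply(d$constraints, `[[`, 1L, "p")) == k)
  S <- term_prior_covariance(d$constraints[[k]],
                             compose_interaction_scale(
                               list(diag(2), car_scale(fx$G, tau))))
  expect_equal(Psi[idx, idx], (g * 6 / 12) * S, tolerance = 1e-12)
  # tau = 0 collapses every CAR structure to the identity prior
  Psi0 <- joint_prior_covariance(d, pr, g, tau = c(region = 0))
  expect_equal(Psi0, joint_prior_covariance(d, pr_id, g), tolerance = 1e-10)
})

test_that("conditioned covariances stay positive-definite across the interval", {
  set.seed(9)
  lay <- make_layout(c("u", "region"), c(2, 5))
  for (r in 1:200) {
    G <- random_graph(5)
    b <- tau_bounds(G)
    tau <- runif(1, b[[1]] + 0.02 * diff(b), b[[2]] - 0.02 * diff(b))
    D <- car_scale(G, tau)
    expect_no_error(chol(D))
    tc <- term_constraint(lay, c("u", "region"))
    expect_no_error(chol(term_prior_covariance(
      tc, compose_interaction_scale(list(diag(2), D)))))
  }
})

test_that("prior covariances round-trip through the constraint transform", {
  fx <- pedagogic_fixture()
  ints <- list(c("age", "region"))
  d_sz <- build_design(fx$layout, ints)
  d_cp <- build_design(fx$layout, ints, system = "corner_point")
  pr <- pedagogic_prior()
  Psi <- joint_prior_covariance(d_sz, pr, g = 1.5, tau = c(region = 0.2))
  tr <- constraint_transform(d_cp, d_sz)
  PsiA <- transform_prior_covariance(tr, Psi)
  B <- tr$M_X
  expect_equal(solve(B) %*% PsiA %*% t(solve(B)), Psi, tolerance = 1e-8)
})
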