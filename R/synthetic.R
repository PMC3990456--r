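#' Specification for the synthetic-table generator
#'
#' Describes a generating log-linear model: the layout, the true
#' interactions, fixed coefficients and/or coefficients drawn from the
#' package's own conditioned prior at a given scale and dependence
#' parameter, the intercept, and (for capture-recapture emulation) the
#' source factors whose all-unobserved cells are masked.
#'
#' @param layout a [make_layout()] object.
#' @param interactions list of true interaction terms (hierarchical).
#' @param phi intercept of the log rate.
#' @param beta named list: term label -> fixed coefficient vector (length
#'   `p_t`).
#' @param draw named list: term label -> standard deviation `sigma`; the
#'   term's coefficients are drawn `beta_t ~ N(0, sigma^2 Sigma_t)` with
#'   `Sigma_t` the conditioned covariance at `tau`.
#' @param structures named list of [dependence_structure()]s (identity for
#'   unnamed factors).
#' @param tau named vector of dependence parameters for correlated factors
#'   (must lie inside their permissible intervals).
#' @param source_factors,unobserved_levels source factors and their
#'   "unobserved" level, as in [missing_cell_mask()]; `NULL` for a
#'   complete table.
#' @param seed integer seed; the generator is bitwise-reproducible.
#' @return object of class `"generator_spec"`.
#' @export
generator_spec <- function(layout, interactions = list(), phi = log(10),
                           beta = list(), draw = list(), structures = list(),
                           tau = NULL, source_factors = NULL,
                           unobserved_levels = NULL, seed = 1L) {
  stopifnot(inherits(layout, "table_layout"))
  design <- build_design(layout, interactions)  # validates hierarchy
  labs <- design$labels
  bad <- setdiff(c(names(beta), names(draw)), labs)
  if (length(bad))
    stop("coefficients given for term(s) not in the model: ",
         paste(bad, collapse = ", "))
  prior <- prior_spec(layout, structures)
  if (length(prior$correlated)) {
    tau <- normalize_tau(prior, tau)
    for (f in names(tau)) {
      s <- prior$structures[[f]]
      if (s$kind == "car") {
        b <- s$bounds
        if (tau[[f]] <= b[1L] || tau[[f]] >= b[2L])
          stop(sprintf("tau for '%s' outside the permissible interval (%.4g, %.4g)",
                       f, b[1L], b[2L]))
      } else if (tau[[f]] <= 0) stop("distance tau must be positive")
    }
  }
  structure(list(layout = layout, interactions = interactions,
                 design = design, phi = phi, beta = beta, draw = draw,
                 prior = prior, tau = tau,
                 source_factors = source_factors,
                 unobserved_levels = unobserved_levels,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a synthetic contingency table
#'
#' Draws `y_i ~ Poisson(exp(phi + x_i' beta))` under the specification's
#' model, returning the complete table, the masked capture-recapture
#' version (when source factors are declared) and the truth bundle.
#'
#' @param spec a [generator_spec()].
#' @return list with elements `complete` and `masked`
#'   ([contingency_table()]s; `masked` is `NULL` without sources) and
#'   `truth` (`phi`, `beta` by term, `tau`, `N`, `lambda`, the term
#'   labels, and the seed).
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  design <- spec$design
  n <- design$layout$n
  beta <- numeric(0)
  beta_by_term <- list()
  for (k in seq_along(design$terms)) {
    lab <- design$labels[k]
    tc <- design$constraints[[k]]
    bt <- rep(0, tc$p)
    if (!is.null(spec$beta[[lab]])) {
      bt <- as.numeric(spec$beta[[lab]])
      if (length(bt) != tc$p)
        stop("term ", lab, " needs ", tc$p, " coefficients")
    } else if (!is.null(spec$draw[[lab]])) {
      sd_t <- as.numeric(spec$draw[[lab]])
      D <- term_scale_matrix(spec$prior, tc$term, spec$tau)
      S <- term_prior_covariance(tc, D)
      bt <- sd_t * drop(t(chol(S)) %*% stats::rnorm(tc$p))
    }
    beta_by_term[[lab]] <- bt
    beta <- c(beta, bt)
  }
  lambda <- exp(spec$phi + drop(design$X %*% beta))
  if (any(!is.finite(lambda)) || any(lambda > 1e9))
    stop("cell rates overflow; reduce 'phi' or the effect sizes")
  y <- stats::rpois(n, lambda)
  complete <- contingency_table(design$layout, y)
  masked <- NULL
  if (!is.null(spec$source_factors)) {
    mask <- missing_cell_mask(design$layout, spec$source_factors,
                              spec$unobserved_levels)
    ym <- y; ym[mask] <- NA
    masked <- contingency_table(design$layout, ym, mask)
  }
  list(complete = complete, masked = masked,
       truth = list(phi = spec$phi, beta = beta_by_term, tau = spec$tau,
                    N = sum(y), lambda = lambda, terms = design$labels,
                    seed = spec$seed))
}

#' The worked 2 x 2 x 3 example
#'
#' The small hospital-patient table used throughout the documentation:
#' age (young/old), hypertension (no/yes) and region (A/B/C), with A-B and
#' B-C neighbours but not A-C.  Returns the layout, the path adjacency,
#' the permissible CAR interval computed from it, and the age:region
#' constraint matrices for regression tests.
#'
#' @return list with `layout`, `G`, `tau_bounds`, and `age_region`
#'   (a [term_constraint()]).
#' @export
pedagogic_fixture <- function() {
  layout <- make_layout(c("age", "hypertension", "region"), c(2, 2, 3),
                        list(age = c("young", "old"),
                             hypertension = c("no", "yes"),
                             region = c("A", "B", "C")))
  G <- matrix(c(0, 1, 0,
                1, 0, 1,
                0, 1, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  list(layout = layout, G = G, tau_bounds = tau_bounds(G),
       age_region = term_constraint(layout, c("age", "region")))
}

# deterministic synthetic 11-region adjacency: a planar-ish thickened path,
# connected, with both positive and negative adjacency eigenvalues.  This is
# an invented map: it does not reproduce any real health-board geography.
.synthetic_region_graph <- function() {
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 7),
                 c(7, 8), c(8, 9), c(9, 10), c(10, 11),
                 c(1, 3), c(2, 4), c(3, 5), c(6, 8), c(7, 9))
  G <- matrix(0, 11, 11)
  G[edges] <- 1
  G <- G + t(G)
  dimnames(G) <- list(paste0("R", 1:11), paste0("R", 1:11))
  G
}

#' A six-factor capture-recapture test bed
#'
#' A synthetic incomplete table with the structure of a three-list
#' multi-region capture-recapture study: three binary source factors
#' (observed/unobserved), age (2), gender (2) and region (11 levels with a
#' *synthetic* adjacency graph - an invented map, not any real geography).
#' The 44 cells unobserved by all three sources are masked.  The
#' generating model holds the sources mutually independent with each
#' list's catchability above one half (a well-covered multi-list design:
#' a few percent of the population falls in the masked cells), lets
#' catchability, age and gender effects vary by region, and draws every
#' region-involving term from the package's own conditioned CAR prior at
#' `tau = tau_frac * tau_max` with a common scale `g_true` (i.e.
#' `sigma_t = sqrt(g_true q_t / n)`), so the data carry a coherent
#' positive spatial signal.
#'
#' @param seed integer seed for the counts (the adjacency and layout are
#'   fixed).
#' @param tau_frac position of the generating `tau` inside `(0, tau_max)`
#'   (default 0.8).
#' @param phi baseline log cell rate (default `log(20)`).
#' @param g_true common prior scale of the drawn effects (default 4).
#' @return list with `layout`, `G`, `tau_bounds`, `tau_true`, `spec` (the
#'   [generator_spec()]), `complete`, `masked`, and `truth`.
#' @export
scotland_like_fixture <- function(seed = 1L, tau_frac = 0.8, phi = log(20),
                                  g_true = 4) {
  layout <- make_layout(
    c("source1", "source2", "source3", "age", "gender", "region"),
    c(2L, 2L, 2L, 2L, 2L, 11L),
    list(source1 = c("obs", "unobs"), source2 = c("obs", "unobs"),
         source3 = c("obs", "unobs"), age = c("young", "old"),
         gender = c("male", "female"),
         region = paste0("R", 1:11)))
  G <- .synthetic_region_graph()
  b <- tau_bounds(G)
  tau_true <- tau_frac * b[[2L]]
  n <- layout$n
  sd_main <- sqrt(g_true * 11 / n)
  sd_int <- sqrt(g_true * 22 / n)
  interactions <- list(c("source1", "region"), c("source2", "region"),
                       c("source3", "region"), c("age", "region"),
                       c("gender", "region"))
  draw <- stats::setNames(as.list(rep(sd_int, 5L)),
                          vapply(interactions, term_label, ""))
  draw$region <- sd_main
  spec <- generator_spec(
    layout,
    interactions = interactions,
    phi = phi,
    beta = list(source1 = 0.30, source2 = 0.20, source3 = 0.25,
                age = 0.15, gender = 0.20),
    draw = draw,
    structures = list(region = dependence_structure("car", G = G)),
    tau = c(region = tau_true),
    source_factors = c("source1", "source2", "source3"),
    seed = seed)
  gen <- generate_table(spec)
  list(layout = layout, G = G, tau_bounds = b, tau_true = tau_true,
       spec = spec, complete = gen$complete, masked = gen$masked,
       truth = gen$truth)
}
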