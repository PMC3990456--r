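#' Permissible interval for the CAR dependence parameter
#'
#' The conditional autoregressive scale matrix `D = (I - tau G)^{-1}` is
#' positive-definite exactly when `tau` lies strictly between the
#' reciprocals of the extreme eigenvalues of the neighbourhood matrix `G`:
#' `(tau_min, tau_max) = (1/e_min, 1/e_max)` with `e_min < 0 < e_max`.
#'
#' @param G binary symmetric neighbourhood matrix with zero diagonal and at
#'   least one edge.
#' @return numeric vector `c(tau_min, tau_max)`.
#' @examples
#' G <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))  # path A - B - C
#' tau_bounds(G)  # -1/2, 1/2
#' @export
tau_bounds <- function(G) {
  check_adjacency(G)
  e <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  c(tau_min = 1 / min(e), tau_max = 1 / max(e))
}

check_adjacency <- function(G) {
  if (!is.matrix(G) || nrow(G) != ncol(G))
    stop("'G' must be a square matrix")
  if (any(G != 0 & G != 1))
    stop("'G' must be binary (0/1)")
  if (any(diag(G) != 0))
    stop("'G' must have a zero diagonal")
  if (any(G != t(G)))
    stop("'G' must be symmetric")
  if (sum(G) == 0)
    stop("'G' has no edges; the CAR interval is undefined")
  invisible(G)
}

#' CAR scale matrix
#'
#' `D = (I - tau G)^{-1}`, the conditional autoregressive scale structure
#' for factor levels that are geographical neighbours.
#'
#' @param G neighbourhood matrix (see [tau_bounds()]).
#' @param tau dependence parameter, strictly inside [tau_bounds()].
#' @return symmetric positive-definite matrix.
#' @export
car_scale <- function(G, tau) {
  b <- tau_bounds(G)
  if (!is.finite(tau) || tau <= b[1L] || tau >= b[2L])
    stop(sprintf("tau = %g outside the permissible interval (%.6g, %.6g)",
                 tau, b[1L], b[2L]))
  D <- solve(diag(nrow(G)) - tau * G)
  (D + t(D)) / 2
}

#' Distance-based scale matrix
#'
#' Gaussian correlation function of pairwise distances:
#' `D_ij = exp(-d_ij^2 / (2 tau^2))`, with unit diagonal.
#'
#' @param d symmetric matrix of non-negative distances with zero diagonal.
#' @param tau range parameter, `tau > 0`.
#' @return unit-diagonal scale matrix.
#' @export
distance_scale <- function(d, tau) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || any(d != t(d)) ||
      any(d < 0) || any(diag(d) != 0))
    stop("'d' must be a symmetric non-negative matrix with zero diagonal")
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be positive")
  exp(-d^2 / (2 * tau^2))
}

#' Declare the dependence structure of one factor
#'
#' @param kind `"identity"` (independent levels, the default for every
#'   factor), `"car"` (requires `G`) or `"distance"` (requires `d` and a
#'   finite `tau_interval` on which the uniform prior for `tau` is placed).
#' @param G neighbourhood matrix for `"car"`.
#' @param d distance matrix for `"distance"`.
#' @param tau_interval prior support for `tau`.  For `"car"` it defaults to
#'   the full permissible interval [tau_bounds()]; for `"distance"` it must
#'   be supplied, since a uniform prior has no canonical support on an
#'   unbounded range.
#' @return object of class `"dependence_structure"`.
#' @export
dependence_structure <- function(kind = c("identity", "car", "distance"),
                                 G = NULL, d = NULL, tau_interval = NULL) {
  kind <- match.arg(kind)
  if (kind == "identity")
    return(structure(list(kind = kind), class = "dependence_structure"))
  if (kind == "car") {
    b <- tau_bounds(G)
    if (is.null(tau_interval)) tau_interval <- unname(b)
    if (tau_interval[1L] < b[1L] || tau_interval[2L] > b[2L])
      stop("'tau_interval' must lie within the permissible CAR interval")
    return(structure(list(kind = kind, G = G, q = nrow(G),
                          bounds = unname(b),
                          tau_interval = tau_interval),
                     class = "dependence_structure"))
  }
  if (is.null(tau_interval))
    stop("a finite 'tau_interval' is required for the distance structure")
  if (tau_interval[1L] <= 0) stop("distance 'tau' must be positive")
  structure(list(kind = kind, d = d, q = nrow(d),
                 tau_interval = tau_interval),
            class = "dependence_structure")
}

#' @export
print.dependence_structure <- function(x, ...) {
  cat("Dependence structure:", x$kind, "\n")
  if (!is.null(x$tau_interval))
    cat(sprintf("  tau in (%.4g, %.4g)\n", x$tau_interval[1L],
                x$tau_interval[2L]))
  invisible(x)
}

#' Scale matrix of one factor at a given tau
#'
#' @param struct a [dependence_structure()].
#' @param q number of levels (used for the identity kind).
#' @param tau dependence parameter (ignored for identity).
#' @return `q` by `q` scale matrix `D_r`.
#' @export
scale_matrix <- function(struct, q, tau = NULL) {
  stopifnot(inherits(struct, "dependence_structure"))
  switch(struct$kind,
    identity = diag(q),
    car = {
      if (struct$q != q) stop("CAR structure dimension mismatch")
      car_scale(struct$G, tau)
    },
    distance = {
      if (struct$q != q) stop("distance structure dimension mismatch")
      distance_scale(struct$d, tau)
    })
}

#' Kronecker composition of constituent scale matrices
#'
#' The scale matrix of an interaction is the Kronecker product of its
#' constituents' scale matrices, taken in layout order (first factor
#' slowest), matching the ordering of the constrained parameters.  With
#' this composition the correlation between two interaction levels equals
#' the main-effect correlation precisely when all other constituent levels
#' coincide.
#'
#' @param D_list list of constituent scale matrices in layout order.
#' @return the composite scale matrix.
#' @export
compose_interaction_scale <- function(D_list) {
  stopifnot(length(D_list) >= 1L)
  Reduce(kronecker, D_list)
}

#' Prior covariance of a term's free parameters
#'
#' Conditioning the unconstrained `theta_t ~ N(0, sigma^2 D_t)` on the
#' identifiability constraints yields `beta_t ~ N(0, sigma^2 Sigma_t)` with
#' `Sigma_t = (A_t' D_t^{-1} A_t)^{-1}`.  Computed through the Cholesky
#' factor of `D_t` for stability near the ends of the CAR interval.
#'
#' @param constraint a [term_constraint()].
#' @param D the term's scale matrix (see [compose_interaction_scale()]).
#' @return symmetric positive-definite `p_t` by `p_t` matrix.
#' @export
term_prior_covariance <- function(constraint, D) {
  P <- term_prior_precision(constraint, D)
  S <- chol2inv(chol(P))
  (S + t(S)) / 2
}

#' @rdname term_prior_covariance
#' @return `term_prior_precision()` returns the inverse,
#'   `A_t' D_t^{-1} A_t`, without forming `Sigma_t`.
#' @export
term_prior_precision <- function(constraint, D) {
  stopifnot(inherits(constraint, "term_constraint"))
  if (nrow(D) != constraint$q)
    stop("scale matrix dimension must equal the term's q")
  R <- chol(D)
  W <- forwardsolve(t(R), constraint$A)
  crossprod(W)
}

#' Correlation matrix induced by a covariance
#'
#' @param Sigma positive-definite covariance matrix.
#' @return correlation matrix.
#' @export
induced_correlation <- function(Sigma) {
  v <- diag(as.matrix(Sigma))
  if (any(v <= 0)) stop("zero or negative variance entry")
  stats::cov2cor(as.matrix(Sigma))
}

#' Prior specification for a log-linear analysis
#'
#' Collects the per-factor dependence structures and the hyperparameters of
#' the scale hierarchy.  Each term's variance factor is
#' `sigma_t^2 = g q_t / n`; with all-identity structures the implied joint
#' prior is exactly `beta | g ~ N(0, g (X'X)^{-1})`, the generalised
#' hyper-g prior, and `g` either receives an inverse-gamma hyperprior
#' `IG(a/2, b n / 2)` or is held fixed (`g = k n` gives the
#' unit-information default prior at `k = 1`).
#'
#' @param layout a [make_layout()] object.
#' @param structures named list of [dependence_structure()]s; factors not
#'   named get the identity structure.
#' @param a,b inverse-gamma hyperparameters (defaults `1e-3`).
#' @param g_mode `"hyper"` (default) or `"fixed"`.
#' @param g_fixed value of `g` in fixed mode (default `n`, one unit of
#'   prior information).
#' @return object of class `"prior_spec"`.
#' @export
prior_spec <- function(layout, structures = list(), a = 1e-3, b = 1e-3,
                       g_mode = c("hyper", "fixed"), g_fixed = NULL) {
  stopifnot(inherits(layout, "table_layout"))
  g_mode <- match.arg(g_mode)
  if (length(structures)) {
    bad <- setdiff(names(structures), layout$factor_names)
    if (length(bad))
      stop("structures named for unknown factor(s): ",
           paste(bad, collapse = ", "))
    for (f in names(structures)) {
      s <- structures[[f]]
      stopifnot(inherits(s, "dependence_structure"))
      lf <- layout$level_counts[match(f, layout$factor_names)]
      if (s$kind != "identity" && s$q != lf)
        stop("structure for '", f, "' has dimension ", s$q,
             " but the factor has ", lf, " levels")
    }
  }
  all_structs <- stats::setNames(
    lapply(layout$factor_names, function(f)
      if (f %in% names(structures)) structures[[f]]
      else dependence_structure("identity")),
    layout$factor_names)
  correlated <- names(all_structs)[vapply(all_structs, function(s)
    s$kind != "identity", TRUE)]
  if (is.null(g_fixed)) g_fixed <- layout$n
  if (a <= 0 || b <= 0) stop("'a' and 'b' must be positive")
  structure(list(layout = layout, structures = all_structs,
                 correlated = correlated, a = a, b = b,
                 g_mode = g_mode, g_fixed = g_fixed),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Prior specification on", length(x$structures), "factors\n")
  for (f in names(x$structures))
    cat("  ", f, ": ", x$structures[[f]]$kind, "\n", sep = "")
  if (x$g_mode == "hyper")
    cat(sprintf("  g ~ IG(a/2 = %g, b n/2 = %g)\n", x$a / 2,
                x$b * x$layout$n / 2))
  else cat("  g fixed at", x$g_fixed, "\n")
  invisible(x)
}

# tau as a named vector over correlated factors; accept scalar when there
# is exactly one correlated factor
normalize_tau <- function(prior, tau) {
  cf <- prior$correlated
  if (length(cf) == 0L) return(numeric(0))
  if (is.null(tau)) stop("'tau' required for correlated factor(s): ",
                         paste(cf, collapse = ", "))
  if (is.null(names(tau))) {
    if (length(tau) != length(cf))
      stop("'tau' must be named or have one entry per correlated factor")
    names(tau) <- cf
  }
  miss <- setdiff(cf, names(tau))
  if (length(miss)) stop("missing tau for factor(s): ",
                         paste(miss, collapse = ", "))
  tau[cf]
}

#' Scale matrix of a model term under a prior specification
#'
#' @param prior a [prior_spec()].
#' @param term character vector of constituent factors.
#' @param tau named vector of dependence parameters for the correlated
#'   factors (scalar accepted when only one factor is correlated).
#' @return the composite `q_t` by `q_t` scale matrix `D_t`.
#' @export
term_scale_matrix <- function(prior, term, tau = NULL) {
  stopifnot(inherits(prior, "prior_spec"))
  tau <- normalize_tau(prior, tau)
  lay <- prior$layout
  term <- lay$factor_names[lay$factor_names %in% term]
  D_list <- lapply(term, function(f)
    scale_matrix(prior$structures[[f]],
                 q = lay$level_counts[match(f, lay$factor_names)],
                 tau = if (f %in% names(tau)) tau[[f]] else NULL))
  compose_interaction_scale(D_list)
}

#' Joint prior covariance of the regression parameters
#'
#' Block-diagonal over terms: `Psi = diag{sigma_1^2 Sigma_1, ...,
#' sigma_T^2 Sigma_T}` with `sigma_t^2 = g q_t / n`.  With all-identity
#' structures this equals `g (X'X)^{-1}` on a complete balanced table.
#'
#' @param design a [build_design()] under sum-to-zero constraints.
#' @param prior a [prior_spec()].
#' @param g positive scale hyperparameter.
#' @param tau dependence parameter(s), see [term_scale_matrix()].
#' @return `p` by `p` positive-definite matrix.
#' @export
joint_prior_covariance <- function(design, prior, g, tau = NULL) {
  stopifnot(inherits(design, "model_design"), inherits(prior, "prior_spec"))
  if (!is.finite(g) || g <= 0) stop("'g' must be positive")
  n <- design$layout$n
  blocks <- lapply(design$constraints, function(tc) {
    D <- term_scale_matrix(prior, tc$term, tau)
    (g * tc$q / n) * term_prior_covariance(tc, D)
  })
  block_diag(blocks)
}

block_diag <- function(blocks) {
  p <- vapply(blocks, nrow, 1L)
  out <- matrix(0, sum(p), sum(p))
  at <- 0L
  for (B in blocks) {
    idx <- at + seq_len(nrow(B))
    out[idx, idx] <- B
    at <- at + nrow(B)
  }
  out
}
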