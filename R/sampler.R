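#' Sampler configuration
#'
#' @param iterations total MCMC sweeps.
#' @param burnin burn-in, either a fraction of `iterations` (default 0.1)
#'   or an absolute count; must be smaller than `iterations`.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed; every source of randomness in the chain flows
#'   from it.
#' @param tau_scale random-walk standard deviation for the dependence
#'   parameter(s); default one tenth of the prior interval width.
#' @param adapt_tau adapt `tau_scale` towards a 20-50% acceptance rate
#'   during burn-in only (the kernel is fixed afterwards, preserving
#'   ergodicity).
#' @param g_init,tau_init optional starting values.
#' @param eta_cap cap on the linear predictor used when imputing missing
#'   cells (overflow guard for the Poisson sampler; trips are counted).
#' @return object of class `"sampler_config"`.
#' @export
sampler_config <- function(iterations = 10000L, burnin = 0.1, thin = 1L,
                           seed = 1L, tau_scale = NULL, adapt_tau = TRUE,
                           g_init = NULL, tau_init = NULL, eta_cap = 50) {
  iterations <- as.integer(iterations)
  if (iterations < 0L) stop("'iterations' must be non-negative")
  if (burnin < 1) burnin <- floor(burnin * iterations)
  burnin <- as.integer(burnin)
  if (iterations > 0L && burnin >= iterations)
    stop("burn-in must be smaller than 'iterations'")
  thin <- max(1L, as.integer(thin))
  structure(list(iterations = iterations, burnin = burnin, thin = thin,
                 seed = as.integer(seed), tau_scale = tau_scale,
                 adapt_tau = isTRUE(adapt_tau), g_init = g_init,
                 tau_init = tau_init, eta_cap = eta_cap),
            class = "sampler_config")
}

#' Model space for reversible-jump moves
#'
#' Either the free hierarchical space (all downward-closed interaction sets
#' up to `max_order`, every main effect always present) or an explicit list
#' of models.
#'
#' @param layout a [make_layout()] object.
#' @param max_order highest interaction order (free space).
#' @param models explicit list of models (each a list of interaction
#'   terms); overrides `max_order`.
#' @return object of class `"rj_model_space"`.
#' @export
model_space <- function(layout, max_order = 2L, models = NULL) {
  stopifnot(inherits(layout, "table_layout"))
  if (is.null(models)) {
    fac <- layout$factor_names
    max_order <- min(as.integer(max_order), length(fac))
    allowed <- list()
    if (max_order >= 2L)
      for (ord in 2:max_order)
        allowed <- c(allowed, utils::combn(fac, ord, simplify = FALSE))
    return(structure(list(kind = "free", layout = layout,
                          max_order = max_order, allowed = allowed),
                     class = "rj_model_space"))
  }
  models <- lapply(models, function(m) lapply(m, as.character))
  allowed <- list()
  seen <- character(0)
  for (m in models) for (tm in m) {
    lab <- term_label(layout$factor_names[layout$factor_names %in% tm])
    if (!lab %in% seen) {
      seen <- c(seen, lab)
      allowed <- c(allowed, list(layout$factor_names[layout$factor_names %in% tm]))
    }
  }
  incl <- do.call(rbind, lapply(models, function(m) {
    labs <- vapply(m, function(tm)
      term_label(layout$factor_names[layout$factor_names %in% tm]), "")
    seen %in% labs
  }))
  if (length(seen) == 0L) incl <- matrix(FALSE, length(models), 0L)
  structure(list(kind = "explicit", layout = layout, allowed = allowed,
                 allowed_labels = seen, incl = incl),
            class = "rj_model_space")
}

#' @export
print.rj_model_space <- function(x, ...) {
  if (x$kind == "free")
    cat("Free hierarchical model space, interactions up to order",
        x$max_order, "(", length(x$allowed), "candidate terms )\n")
  else cat("Explicit model space of", nrow(x$incl), "models\n")
  invisible(x)
}

# ---- chain state ----------------------------------------------------------

# The chain state is an environment mutated in place by the update kernels.
# Layout of the parameter vector: main effects in canonical order, then the
# *included* interactions in canonical order.

#' Initialise a chain state
#'
#' Builds the caches (full design over the model space, per-term prior
#' precision pieces) and the starting state used by [run_chain()] and the
#' individual update kernels.
#'
#' @param table a [contingency_table()].
#' @param prior a [prior_spec()] on the same layout.
#' @param space a [model_space()]; `NULL` gives the independence-model-only
#'   space.
#' @param config a [sampler_config()].
#' @param start_interactions interactions included at the start (default
#'   none: the independence model).
#' @return an environment of class `"chain_state"`.
#' @export
chain_init <- function(table, prior, space = NULL, config = sampler_config(),
                       start_interactions = list()) {
  stopifnot(inherits(table, "contingency_table"),
            inherits(prior, "prior_spec"))
  lay <- table$layout
  if (!identical(lay$factor_names, prior$layout$factor_names))
    stop("table and prior layouts disagree")
  if (is.null(space)) space <- model_space(lay, max_order = 1L)
  stopifnot(inherits(space, "rj_model_space"))

  full <- build_design(lay, space$allowed, system = "sum_to_zero")
  n_main <- length(lay$factor_names)
  terms <- full$terms
  labels <- full$labels
  cons <- full$constraints
  p_t <- vapply(cons, `[[`, 1L, "p")
  q_t <- vapply(cons, `[[`, 1L, "q")
  T_ <- length(terms)
  Xblocks <- lapply(seq_len(T_), function(k)
    full$X[, full$col_term == k, drop = FALSE])

  # per-term constituent pieces for the prior precision
  # Sigma_t^{-1}(tau) = kron_r M_r with M_r = A'A (identity),
  # A'A - tau A'GA (CAR) or A' D(tau)^{-1} A (distance)
  pieces <- lapply(seq_len(T_), function(k) {
    lapply(cons[[k]]$term, function(f) {
      l <- lay$level_counts[match(f, lay$factor_names)]
      A <- factor_contrast(l, "sum_to_zero")
      s <- prior$structures[[f]]
      pc <- list(factor = f, kind = s$kind, S0 = crossprod(A), A = A,
                 struct = s)
      if (s$kind == "car") pc$K <- crossprod(A, s$G %*% A)
      pc
    })
  })
  term_factors <- lapply(cons, `[[`, "term")

  e <- new.env(parent = emptyenv())
  class(e) <- "chain_state"
  e$layout <- lay; e$prior <- prior; e$space <- space; e$config <- config
  e$miss <- table$missing; e$obs <- !table$missing
  e$y <- table$counts
  e$N_observed <- table$N_observed
  e$n <- lay$n
  e$terms <- terms; e$labels <- labels; e$cons <- cons
  e$p_t <- p_t; e$q_t <- q_t; e$n_main <- n_main; e$T_ <- T_
  e$Xblocks <- Xblocks
  e$pieces <- pieces; e$term_factors <- term_factors
  e$is_inter <- seq_len(T_) > n_main

  # tau: one shared value per correlated factor
  cf <- prior$correlated
  e$tau_interval <- lapply(cf, function(f) prior$structures[[f]]$tau_interval)
  names(e$tau_interval) <- cf
  tau0 <- vapply(cf, function(f) {
    iv <- prior$structures[[f]]$tau_interval
    if (!is.null(config$tau_init) && f %in% names(config$tau_init))
      config$tau_init[[f]] else mean(iv)
  }, 0)
  names(tau0) <- cf
  e$tau <- tau0
  e$tau_scale <- vapply(cf, function(f) {
    iv <- prior$structures[[f]]$tau_interval
    if (is.null(config$tau_scale)) 0.1 * diff(iv) else config$tau_scale
  }, 0)
  names(e$tau_scale) <- cf

  # starting model
  incl <- rep(FALSE, T_); incl[seq_len(n_main)] <- TRUE
  for (tm in start_interactions) {
    lab <- term_label(lay$factor_names[lay$factor_names %in% tm])
    k <- match(lab, labels)
    if (is.na(k)) stop("start interaction ", lab, " not in the model space")
    incl[k] <- TRUE
  }
  if (space$kind == "explicit") {
    e$model_idx <- .match_model(space, incl[e$is_inter])
    if (is.na(e$model_idx)) stop("starting model not in the explicit space")
  }
  e$incl <- incl

  # starting values
  ybar <- mean(e$y[e$obs])
  e$y[e$miss] <- round(ybar)
  e$phi <- log(max(ybar, 0.5))
  e$g <- if (prior$g_mode == "fixed") prior$g_fixed
         else if (!is.null(config$g_init)) config$g_init else e$n
  e$beta <- numeric(sum(p_t[incl]))
  .refresh_prec_cache(e, seq_len(T_))
  .refresh_model(e)
  e$eta <- rep(e$phi, e$n)
  # start (phi, beta) at the conditional posterior mode (a few deterministic
  # IWLS iterations) so that the scale hyperparameter, whose full
  # conditional is sized by beta, opens up immediately; starting at beta = 0
  # in hyper-g mode would collapse g and freeze the chain near the origin
  b <- c(e$phi, e$beta)
  for (i in seq_len(25L)) {
    fw <- tryCatch(.iwls(e, b), error = function(err) NULL)
    if (is.null(fw)) break
    if (max(abs(fw$m - b)) < 1e-8) { b <- fw$m; break }
    b <- fw$m
  }
  e$phi <- b[1L]; e$beta <- b[-1L]
  e$eta <- drop(e$Xa %*% b)
  if (prior$g_mode == "hyper" && is.null(config$g_init) && length(e$beta)) {
    quad <- sum(e$beta * (e$Q0 %*% e$beta))
    e$g <- max((prior$b * e$n + quad) / (prior$a + length(e$beta)), 1e-3)
  }
  e$acc <- c(within = 0, within_n = 0, rj = 0, rj_n = 0,
             tau = 0, tau_n = 0, iwls_fallback = 0, eta_capped = 0)
  e
}

#' @export
print.chain_state <- function(x, ...) {
  cat("Chain state: model", .model_label(x), "| p =", length(x$beta), "\n")
  invisible(x)
}

.match_model <- function(space, inter_incl) {
  hits <- which(apply(space$incl, 1L, function(r) all(r == inter_incl)))
  if (length(hits)) hits[1L] else NA_integer_
}

.model_label <- function(e) {
  labs <- e$labels[e$incl & e$is_inter]
  if (length(labs) == 0L) "independence" else paste(labs, collapse = "+")
}

# recompute Sigma_t^{-1} and its log-determinant for the given terms at the
# current tau
.refresh_prec_cache <- function(e, which_terms) {
  if (is.null(e$Sinv)) { e$Sinv <- vector("list", e$T_); e$logdetS <- numeric(e$T_) }
  for (k in which_terms) {
    M <- NULL
    for (pc in e$pieces[[k]]) {
      Mr <- switch(pc$kind,
        identity = pc$S0,
        car = pc$S0 - e$tau[[pc$factor]] * pc$K,
        distance = {
          D <- distance_scale(pc$struct$d, e$tau[[pc$factor]])
          R <- chol(D)
          crossprod(forwardsolve(t(R), pc$A))
        })
      M <- if (is.null(M)) Mr
           else if (nrow(M) == 1L) M[1L, 1L] * Mr
           else if (nrow(Mr) == 1L) Mr[1L, 1L] * M
           else kronecker(M, Mr)
    }
    e$Sinv[[k]] <- M
    e$logdetS[k] <- 2 * sum(log(diag(chol(M))))
  }
  invisible(e)
}

# rebuild the active design and prior precision after a model change
.refresh_model <- function(e) {
  act <- which(e$incl)
  e$active <- act
  e$Xa <- cbind(1, do.call(cbind, e$Xblocks[act]))
  e$beta_term <- rep(act, e$p_t[act])   # term id of each beta entry
  .refresh_Q0(e)
}

# prior precision of the active beta (up to 1/g) and the scalars entering
# its log density; cheap enough to rebuild whenever tau or the model moves
.refresh_Q0 <- function(e) {
  act <- e$active
  # Q0 = n * blockdiag(Sinv_t / q_t); prior precision of beta is Q0 / g
  e$Q0 <- block_diag(lapply(act, function(k) (e$n / e$q_t[k]) * e$Sinv[[k]]))
  e$p_active <- sum(e$p_t[act])
  e$ld_sum <- sum(e$logdetS[act]) - sum(e$p_t[act] * log(e$q_t[act] / e$n))
  invisible(e)
}

.lam <- function(eta) exp(pmin(eta, 30))

# Poisson log-likelihood up to the lgamma(y+1) constant (cancels in ratios
# taken at fixed y)
.llik <- function(y, eta) sum(y * eta) - sum(.lam(eta))

# N(0, sigma_t^2 Sigma_t) log-density of one term block, constants included
.lprior_term <- function(e, k, bt) {
  s2 <- e$g * e$q_t[k] / e$n
  0.5 * (e$logdetS[k] - e$p_t[k] * log(s2) - e$p_t[k] * log(2 * pi)) -
    0.5 * sum(bt * (e$Sinv[[k]] %*% bt)) / s2
}

# joint N(0, Psi) log density of the active beta via the cached precision:
# sum_t log N(beta_t; 0, sigma_t^2 Sigma_t) with sigma_t^2 = g q_t / n
.lprior_beta <- function(e, beta) {
  if (!length(beta)) return(0)
  0.5 * (e$ld_sum - e$p_active * (log(e$g) + log(2 * pi))) -
    0.5 * sum(beta * (e$Q0 %*% beta)) / e$g
}

# one IWLS step towards the mode of the conditional posterior of (phi, beta)
.iwls <- function(e, b) {
  eta <- drop(e$Xa %*% b)
  lam <- .lam(eta)
  P <- crossprod(e$Xa * sqrt(lam))
  P[-1L, -1L] <- P[-1L, -1L] + e$Q0 / e$g
  R <- chol(P)
  rhs <- crossprod(e$Xa, lam * eta + e$y - lam)
  list(m = drop(backsolve(R, forwardsolve(t(R), rhs))), R = R)
}

# log N(x; m, P^{-1}) with P = R'R
.ldnorm_prec <- function(x, m, R) {
  sum(log(diag(R))) - 0.5 * length(x) * log(2 * pi) -
    0.5 * sum((R %*% (x - m))^2)
}

# ---- update kernels -------------------------------------------------------

#' Within-model update of the intercept and regression parameters
#'
#' One Metropolis-Hastings step updating `(phi, beta)` jointly.  The
#' proposal is the normal approximation to the full conditional obtained
#' from a single iteratively-weighted-least-squares step at the current
#' state (and, for the reverse density, at the proposed state); the
#' accept/reject uses the exact Poisson likelihood with the `N(0, Psi)`
#' prior on `beta` and a flat prior on `phi`.  If the weighted least
#' squares system is numerically singular the kernel falls back to a
#' symmetric random-walk proposal (counted in the diagnostics).
#'
#' @param e a [chain_init()] state.
#' @return the state, invisibly (mutated in place).
#' @export
within_model_update <- function(e) {
  b <- c(e$phi, e$beta)
  fw <- tryCatch(.iwls(e, b), error = function(err) NULL)
  if (is.null(fw)) {
    e$acc[["iwls_fallback"]] <- e$acc[["iwls_fallback"]] + 1
    bp <- b + stats::rnorm(length(b), 0, 0.02)
    eta_p <- drop(e$Xa %*% bp)
    lr <- (.llik(e$y, eta_p) + .lprior_beta(e, bp[-1L])) -
          (.llik(e$y, e$eta) + .lprior_beta(e, b[-1L]))
    if (log(stats::runif(1)) < lr) {
      e$phi <- bp[1L]; e$beta <- bp[-1L]; e$eta <- eta_p
      e$acc[["within"]] <- e$acc[["within"]] + 1
    }
    e$acc[["within_n"]] <- e$acc[["within_n"]] + 1
    return(invisible(e))
  }
  bp <- fw$m + backsolve(fw$R, stats::rnorm(length(b)))
  rv <- tryCatch(.iwls(e, bp), error = function(err) NULL)
  if (is.null(rv)) { e$acc[["within_n"]] <- e$acc[["within_n"]] + 1; return(invisible(e)) }
  eta_p <- drop(e$Xa %*% bp)
  lr <- (.llik(e$y, eta_p) + .lprior_beta(e, bp[-1L]) +
           .ldnorm_prec(b, rv$m, rv$R)) -
        (.llik(e$y, e$eta) + .lprior_beta(e, b[-1L]) +
           .ldnorm_prec(bp, fw$m, fw$R))
  if (is.finite(lr) && log(stats::runif(1)) < lr) {
    e$phi <- bp[1L]; e$beta <- bp[-1L]; e$eta <- eta_p
    e$acc[["within"]] <- e$acc[["within"]] + 1
  }
  e$acc[["within_n"]] <- e$acc[["within_n"]] + 1
  invisible(e)
}

#' Gibbs update of the scale hyperparameter g
#'
#' With `beta | g ~ N(0, g Psi0)`, `Psi0 = blockdiag((q_t/n) Sigma_t)`, and
#' `g ~ IG(a/2, b n/2)`, the full conditional is conjugate:
#' `g | beta ~ IG((a + p)/2, (b n + beta' Psi0^{-1} beta)/2)`.
#'
#' @param e a [chain_init()] state (hyper-g mode).
#' @return the state, invisibly.
#' @export
update_g <- function(e) {
  if (e$prior$g_mode != "hyper") return(invisible(e))
  p <- length(e$beta)
  quad <- if (p) sum(e$beta * (e$Q0 %*% e$beta)) else 0
  shape <- (e$prior$a + p) / 2
  rate <- (e$prior$b * e$n + quad) / 2
  e$g <- rate / stats::rgamma(1L, shape)
  invisible(e)
}

.reflect <- function(x, lo, hi) {
  while (x < lo || x > hi) {
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
  }
  x
}

#' Random-walk update of the dependence parameter(s)
#'
#' For each correlated factor, a Metropolis step with a normal random walk
#' reflected at the ends of the prior interval (the reflected kernel is
#' symmetric, so the acceptance ratio is the ratio of `N(beta; 0, Psi(tau))`
#' prior densities; the uniform prior on `tau` cancels).
#'
#' @param e a [chain_init()] state.
#' @return the state, invisibly.
#' @export
update_tau <- function(e) {
  for (f in names(e$tau)) {
    iv <- e$tau_interval[[f]]
    prop <- .reflect(e$tau[[f]] + stats::rnorm(1L, 0, e$tau_scale[[f]]), iv[1L], iv[2L])
    touched <- which(vapply(e$term_factors, function(tf) f %in% tf, TRUE))
    act <- intersect(touched, e$active)
    old <- list(tau = e$tau[[f]], Sinv = e$Sinv[touched],
                logdet = e$logdetS[touched])
    lp0 <- sum(vapply(act, function(k)
      .lprior_term(e, k, e$beta[e$beta_term == k]), 0))
    e$tau[[f]] <- prop
    .refresh_prec_cache(e, touched)
    lp1 <- sum(vapply(act, function(k)
      .lprior_term(e, k, e$beta[e$beta_term == k]), 0))
    if (log(stats::runif(1)) < lp1 - lp0) {
      e$acc[["tau"]] <- e$acc[["tau"]] + 1
      .refresh_Q0(e)             # Q0 depends on Sinv
    } else {
      e$tau[[f]] <- old$tau
      e$Sinv[touched] <- old$Sinv
      e$logdetS[touched] <- old$logdet
    }
    e$acc[["tau_n"]] <- e$acc[["tau_n"]] + 1
  }
  invisible(e)
}

#' Impute the structurally missing cell counts
#'
#' Given `(phi, beta)` the Poisson cells are conditionally independent, so
#' each missing count is drawn from `Poisson(lambda_i)` at the current
#' linear predictor (capped for overflow safety; trips are counted in the
#' diagnostics).
#'
#' @param e a [chain_init()] state with a non-empty missing mask.
#' @return the state, invisibly.
#' @export
impute_missing <- function(e) {
  if (!any(e$miss)) return(invisible(e))
  eta_m <- e$eta[e$miss]
  capped <- eta_m > e$config$eta_cap
  if (any(capped)) {
    e$acc[["eta_capped"]] <- e$acc[["eta_capped"]] + sum(capped)
    eta_m <- pmin(eta_m, e$config$eta_cap)
  }
  lam <- pmin(exp(eta_m), 1e8)
  e$y[e$miss] <- stats::rpois(sum(e$miss), lam)
  invisible(e)
}

# eligible single-term moves preserving hierarchy; returns list of
# (type, term index)
.eligible_moves <- function(e) {
  if (e$space$kind == "explicit") {
    cur <- e$incl[e$is_inter]
    nb <- which(apply(e$space$incl, 1L, function(r) sum(r != cur) == 1L))
    return(lapply(nb, function(i) {
      d <- which(e$space$incl[i, ] != cur)
      k <- match(e$space$allowed_labels[d], e$labels)
      list(type = if (cur[d]) "delete" else "add", term = k, model = i)
    }))
  }
  moves <- list()
  for (k in which(e$is_inter)) {
    tm <- e$terms[[k]]
    if (e$incl[k]) {
      # deletable iff no included superset
      sup <- any(vapply(which(e$incl & e$is_inter), function(j)
        j != k && all(tm %in% e$terms[[j]]), TRUE))
      if (!sup) moves <- c(moves, list(list(type = "delete", term = k)))
    } else {
      # addable iff all sub-terms of order >= 2 are included
      ok <- TRUE
      if (length(tm) > 2L) {
        subs <- utils::combn(tm, length(tm) - 1L, simplify = FALSE)
        ok <- all(vapply(subs, function(s)
          any(vapply(which(e$incl & e$is_inter), function(j)
            setequal(e$terms[[j]], s), TRUE)), TRUE))
      }
      if (ok) moves <- c(moves, list(list(type = "add", term = k)))
    }
  }
  moves
}

#' Reversible-jump move between log-linear models
#'
#' Proposes adding or deleting one interaction term, chosen uniformly among
#' the hierarchy-preserving single-term changes within the model space.
#' Parameters of an added term are drawn from a normal proposal centred on
#' the conditional IWLS approximation to their full conditional; the
#' acceptance ratio preserves the joint posterior over `(m, phi, beta)`
#' under the discrete uniform model prior.
#'
#' @param e a [chain_init()] state.
#' @return the state, invisibly.
#' @export
reversible_jump_update <- function(e) {
  moves <- .eligible_moves(e)
  K <- length(moves)
  if (K == 0L) return(invisible(e))
  mv <- moves[[sample.int(K, 1L)]]
  k <- mv$term
  Xt <- e$Xblocks[[k]]
  s2 <- e$g * e$q_t[k] / e$n
  Pt <- e$Sinv[[k]] / s2

  if (mv$type == "add") {
    lam <- .lam(e$eta)
    Vinv <- crossprod(Xt * sqrt(lam)) + Pt
    R <- tryCatch(chol(Vinv), error = function(err) NULL)
    if (is.null(R)) return(invisible(e))
    mu <- drop(backsolve(R, forwardsolve(t(R), crossprod(Xt, e$y - lam))))
    bt <- mu + backsolve(R, stats::rnorm(e$p_t[k]))
    eta_p <- e$eta + drop(Xt %*% bt)
    incl_p <- e$incl; incl_p[k] <- TRUE
    Kp <- .n_moves_if(e, incl_p)
    lr <- .llik(e$y, eta_p) - .llik(e$y, e$eta) +
      .lprior_term(e, k, bt) - .ldnorm_prec(bt, mu, R) + log(K) - log(Kp)
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      e$incl[k] <- TRUE
      if (e$space$kind == "explicit") e$model_idx <- mv$model
      # splice the new block into canonical position
      pos <- sum(e$p_t[e$active[e$active < k]])
      e$beta <- append(e$beta, bt, after = pos)
      .refresh_model(e)
      e$eta <- eta_p
      e$acc[["rj"]] <- e$acc[["rj"]] + 1
    }
  } else {
    sel <- e$beta_term == k
    bt <- e$beta[sel]
    eta_p <- e$eta - drop(Xt %*% bt)
    lam_p <- .lam(eta_p)
    Vinv <- crossprod(Xt * sqrt(lam_p)) + Pt
    R <- tryCatch(chol(Vinv), error = function(err) NULL)
    if (is.null(R)) return(invisible(e))
    mu <- drop(backsolve(R, forwardsolve(t(R), crossprod(Xt, e$y - lam_p))))
    incl_p <- e$incl; incl_p[k] <- FALSE
    Kp <- .n_moves_if(e, incl_p)
    lr <- .llik(e$y, eta_p) - .llik(e$y, e$eta) -
      .lprior_term(e, k, bt) + .ldnorm_prec(bt, mu, R) + log(K) - log(Kp)
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      e$incl[k] <- FALSE
      if (e$space$kind == "explicit") e$model_idx <- mv$model
      e$beta <- e$beta[!sel]
      .refresh_model(e)
      e$eta <- eta_p
      e$acc[["rj"]] <- e$acc[["rj"]] + 1
    }
  }
  e$acc[["rj_n"]] <- e$acc[["rj_n"]] + 1
  invisible(e)
}

# number of eligible moves from a hypothetical inclusion vector
.n_moves_if <- function(e, incl) {
  old <- e$incl
  e$incl <- incl
  on.exit(e$incl <- old)
  length(.eligible_moves(e))
}

# ---- driver ---------------------------------------------------------------

#' Run the data-augmentation reversible-jump MCMC
#'
#' Each sweep performs, in order: imputation of missing cells, the
#' within-model `(phi, beta)` update, the Gibbs update of `g`, the
#' reflected random-walk update of `tau`, and one reversible-jump move.
#' Post-burn-in, thinned states are retained.  The whole chain is
#' reproducible from `config$seed`.
#'
#' @param table a [contingency_table()]; missing cells are imputed.
#' @param prior a [prior_spec()].
#' @param space a [model_space()] (default: independence model only).
#' @param config a [sampler_config()].
#' @param start_interactions interactions of the starting model.
#' @return An object of class `"posterior_draws"`: a list with `model`
#'   (character), `phi`, `g`, `N` (numeric vectors), `tau` (matrix, one
#'   column per correlated factor), `beta` (matrix over the union of model
#'   terms, `NA` where a term is excluded), `y_missing` (matrix of imputed
#'   counts), `accept` (rates per move type), plus the design/bookkeeping
#'   needed by the summary functions.
#' @export
run_chain <- function(table, prior, space = NULL, config = sampler_config(),
                      start_interactions = list()) {
  stopifnot(inherits(config, "sampler_config"))
  set.seed(config$seed)
  e <- chain_init(table, prior, space, config, start_interactions)
  n_iter <- config$iterations
  keep <- if (n_iter > 0L)
    seq_len(n_iter) > config$burnin &
      (seq_len(n_iter) - config$burnin) %% config$thin == 0L
  else logical(0)
  n_keep <- sum(keep)
  p_full <- sum(e$p_t)
  n_miss <- sum(e$miss)
  draws <- list(
    model = character(n_keep),
    phi = numeric(n_keep), g = numeric(n_keep), N = numeric(n_keep),
    tau = matrix(NA_real_, n_keep, length(e$tau),
                 dimnames = list(NULL, names(e$tau))),
    beta = matrix(NA_real_, n_keep, p_full,
                  dimnames = list(NULL, rep(e$labels, e$p_t))),
    y_missing = matrix(NA_real_, n_keep, n_miss))
  beta_col <- rep(seq_len(e$T_), e$p_t)   # full-vector column of each term
  has_space <- length(.eligible_moves(e)) > 0L || e$space$kind == "explicit"
  r <- 0L
  tau_acc_win <- c(0L, 0L)
  for (it in seq_len(n_iter)) {
    if (n_miss) impute_missing(e)
    within_model_update(e)
    update_g(e)
    if (length(e$tau)) {
      a0 <- e$acc[["tau"]]
      update_tau(e)
      tau_acc_win <- tau_acc_win + c(e$acc[["tau"]] - a0, length(e$tau))
    }
    if (has_space) reversible_jump_update(e)
    # tau proposal-scale adaptation, burn-in only
    if (config$adapt_tau && it <= config$burnin && length(e$tau) &&
        it %% 100L == 0L && tau_acc_win[2L] > 0L) {
      rate <- tau_acc_win[1L] / tau_acc_win[2L]
      if (rate < 0.2) e$tau_scale <- e$tau_scale / 1.5
      if (rate > 0.5) e$tau_scale <- e$tau_scale * 1.5
      tau_acc_win <- c(0L, 0L)
    }
    if (n_iter > 0L && keep[it]) {
      r <- r + 1L
      draws$model[r] <- .model_label(e)
      draws$phi[r] <- e$phi
      draws$g[r] <- e$g
      draws$N[r] <- sum(e$y)
      if (length(e$tau)) draws$tau[r, ] <- e$tau
      if (n_miss) draws$y_missing[r, ] <- e$y[e$miss]
      cols <- beta_col %in% e$active
      draws$beta[r, ] <- NA_real_
      draws$beta[r, cols] <- e$beta
    }
  }
  acc <- e$acc
  rates <- c(within = unname(acc[["within"]] / max(1, acc[["within_n"]])),
             rj = unname(acc[["rj"]] / max(1, acc[["rj_n"]])),
             tau = unname(acc[["tau"]] / max(1, acc[["tau_n"]])))
  structure(
    list(model = draws$model, phi = draws$phi, g = draws$g, N = draws$N,
         tau = draws$tau, beta = draws$beta, y_missing = draws$y_missing,
         accept = rates, diagnostics = acc,
         labels = e$labels, p_t = e$p_t, beta_col = beta_col,
         X_full = do.call(cbind, e$Xblocks), layout = e$layout,
         miss = e$miss, y_obs = table$counts, N_observed = e$N_observed,
         config = config),
    class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws:", length(x$phi), "retained iterations\n")
  if (length(x$N) && any(x$miss))
    cat(sprintf("  N: mean %.1f\n", mean(x$N)))
  cat(sprintf("  acceptance: within %.2f, rj %.2f, tau %.2f\n",
              x$accept[["within"]], x$accept[["rj"]], x$accept[["tau"]]))
  invisible(x)
}

#' Cell means of each retained draw
#'
#' Reconstructs `lambda_i = exp(phi + x_i' beta)` for every retained
#' iteration from the stored parameters.
#'
#' @param draws a [run_chain()] result.
#' @return matrix with one row per draw and one column per cell.
#' @export
lambda_draws <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  B <- draws$beta
  B[is.na(B)] <- 0
  exp(sweep(B %*% t(draws$X_full), 1L, draws$phi, `+`))
}
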