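#' Highest posterior density interval
#'
#' Shortest contiguous window of the sorted draws containing a fraction
#' `level` of them.  Sample-based (no density smoothing), so the result is
#' reproducible and equivariant under monotone affine transforms.
#'
#' @param x numeric draws (at least 100).
#' @param level coverage level in (0, 1); default 0.95.
#' @return numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(x, level = 0.95) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 100L) stop("too few draws for an HPDI (need >= 100)")
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  m <- ceiling(level * n)
  if (m >= n) return(c(lower = x[1L], upper = x[n]))
  i <- which.min(x[m:n] - x[1:(n - m + 1L)])
  c(lower = x[i], upper = x[i + m - 1L])
}

#' Bayes factor for positive spatial dependence
#'
#' Posterior odds over prior odds for the hypothesis `tau > 0`, with the
#' uniform prior on `(tau_min, tau_max)` giving prior probability
#' `tau_max / (tau_max - tau_min)`.
#'
#' @param p_posterior posterior probability that `tau > 0`, strictly in
#'   (0, 1).
#' @param tau_min,tau_max prior interval with `tau_min < 0 < tau_max`.
#' @return the Bayes factor (positive scalar).
#' @examples
#' bayes_factor_tau_positive(0.816, -0.457, 0.247)  # ~8.205
#' @export
bayes_factor_tau_positive <- function(p_posterior, tau_min, tau_max) {
  if (p_posterior <= 0 || p_posterior >= 1)
    stop("'p_posterior' must be strictly between 0 and 1")
  if (!(tau_min < 0 && tau_max > 0))
    stop("the prior interval must contain 0")
  p0 <- tau_max / (tau_max - tau_min)
  (p_posterior / (1 - p_posterior)) / (p0 / (1 - p0))
}

#' Kass-Raftery verbal label for a Bayes factor
#' @param bf Bayes factor.
#' @return character label.
#' @export
evidence_label <- function(bf) {
  if (bf < 1) "evidence against"
  else if (bf < 3) "barely worth mentioning"
  else if (bf < 20) "positive evidence"
  else if (bf < 150) "strong evidence"
  else "very strong evidence"
}

#' Posterior model probabilities
#'
#' Relative frequencies of the visited models among the retained
#' reversible-jump draws.
#'
#' @param draws a [run_chain()] result.
#' @return data frame with columns `model` and `probability`, sorted by
#'   decreasing probability.
#' @export
model_probabilities <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  tab <- sort(table(draws$model), decreasing = TRUE)
  data.frame(model = names(tab),
             probability = as.numeric(tab) / length(draws$model),
             row.names = NULL)
}

#' Posterior summary of the total population size
#'
#' Mean and HPDI for `N`, optionally broken down by the levels of retained
#' factors (for an incomplete capture-recapture table, each stratum's `N`
#' sums its observed counts and the imputed counts of its missing cells;
#' the strata sum exactly to the total in every draw).
#'
#' @param draws a [run_chain()] result.
#' @param level HPDI level.
#' @param by optional character vector of factor names to stratify by.
#' @return object of class `"population_posterior"`: `mean`, `hpdi`,
#'   `draws` (the per-iteration `N`), `degenerate` (complete table), and —
#'   when `by` is given — a data frame `strata`.
#' @export
population_posterior <- function(draws, level = 0.95, by = NULL) {
  stopifnot(inherits(draws, "posterior_draws"))
  degenerate <- !any(draws$miss)
  Nd <- draws$N
  out <- list(mean = mean(Nd),
              hpdi = if (degenerate) c(lower = Nd[1L], upper = Nd[1L])
                     else hpdi(Nd, level),
              level = level, draws = Nd, degenerate = degenerate)
  if (!is.null(by)) {
    lay <- draws$layout
    bad <- setdiff(by, lay$factor_names)
    if (length(bad)) stop("unknown factor(s): ", paste(bad, collapse = ", "))
    tup <- cell_tuples(lay)
    key <- apply(tup[, by, drop = FALSE], 1L, paste, collapse = "|")
    lev <- unique(key)
    obs_y <- draws$y_obs
    obs_y[draws$miss] <- 0
    miss_idx <- which(draws$miss)
    strata <- lapply(lev, function(s) {
      cells <- key == s
      base <- sum(obs_y[cells])
      add <- if (length(miss_idx))
        rowSums(draws$y_missing[, cells[miss_idx], drop = FALSE]) else 0
      Ns <- base + add
      iv <- if (degenerate) c(Ns[1L], Ns[1L]) else hpdi(Ns, level)
      data.frame(stratum = s, mean = mean(Ns),
                 lower = iv[[1L]], upper = iv[[2L]])
    })
    out$strata <- do.call(rbind, strata)
    out$strata_key <- key
  }
  structure(out, class = "population_posterior")
}

#' @export
print.population_posterior <- function(x, ...) {
  rounded <- if (x$mean >= 1000)
    sprintf(" (rounded %s)", format(round(x$mean, -2), big.mark = " ")) else ""
  cat(sprintf("Posterior for N: mean %.1f%s, %g%% HPDI (%.1f, %.1f)\n",
              x$mean, rounded, 100 * x$level, x$hpdi[[1L]], x$hpdi[[2L]]))
  if (!is.null(x$strata)) {
    cat("By stratum:\n")
    print(x$strata, row.names = FALSE)
  }
  invisible(x)
}

#' Posterior predictive p-value for model adequacy
#'
#' For every retained draw, replicate observed cells are simulated from
#' `Poisson(lambda)` and the discrepancy of the replicate is compared with
#' that of the data; the p-value is the fraction of draws in which the
#' replicate discrepancy is at least as large.  The default discrepancy is
#' the Freeman-Tukey statistic `sum (sqrt(y) - sqrt(lambda))^2`, robust
#' for small counts; a chi-square discrepancy is available.
#'
#' @param draws a [run_chain()] result.
#' @param table the observed [contingency_table()] (missing cells are
#'   excluded from the discrepancy).
#' @param statistic `"freeman_tukey"` (default) or `"chi_square"`.
#' @return scalar p-value in `[0, 1]`.
#' @export
bayesian_p_value <- function(draws, table,
                             statistic = c("freeman_tukey", "chi_square")) {
  stopifnot(inherits(draws, "posterior_draws"),
            inherits(table, "contingency_table"))
  statistic <- match.arg(statistic)
  obs <- !table$missing
  y <- table$counts[obs]
  lam <- lambda_draws(draws)[, obs, drop = FALSE]
  disc <- function(yy, ll)
    if (statistic == "freeman_tukey") rowSums((sqrt(yy) - sqrt(ll))^2)
    else rowSums((yy - ll)^2 / ll)
  D_obs <- disc(matrix(y, nrow(lam), length(y), byrow = TRUE), lam)
  yrep <- matrix(stats::rpois(length(lam), lam), nrow(lam))
  D_rep <- disc(yrep, lam)
  mean(D_rep >= D_obs)
}

#' Posterior probability that tau is positive
#'
#' @param draws a [run_chain()] result.
#' @param factor correlated factor name (defaults to the only one).
#' @return scalar probability.
#' @export
tau_positive_probability <- function(draws, factor = NULL) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (ncol(draws$tau) == 0L) stop("no correlated factor in the chain")
  if (is.null(factor)) factor <- colnames(draws$tau)[1L]
  mean(draws$tau[, factor] > 0)
}

#' Full posterior summary
#'
#' Posterior means, the population-size summary, the model-probability
#' table, and — when a correlated factor is present — `P(tau > 0)` with
#' the corresponding posterior-odds/prior-odds Bayes factor and its
#' Kass-Raftery evidence label.
#'
#' @param draws a [run_chain()] result.
#' @param level HPDI level.
#' @param tau_interval prior interval used for the Bayes factor (defaults
#'   to the one stored in the chain's prior is not carried; supply it when
#'   it differs from the observed support).
#' @param table optional [contingency_table()]; when given, a posterior
#'   predictive p-value is included.
#' @return object of class `"posterior_summary"`.
#' @export
summarize_draws <- function(draws, level = 0.95, tau_interval = NULL,
                            table = NULL) {
  stopifnot(inherits(draws, "posterior_draws"))
  out <- list(level = level,
              phi_mean = mean(draws$phi), g_mean = mean(draws$g),
              population = population_posterior(draws, level),
              models = model_probabilities(draws))
  if (ncol(draws$tau) > 0L) {
    f <- colnames(draws$tau)[1L]
    p_pos <- tau_positive_probability(draws, f)
    out$tau_mean <- mean(draws$tau[, f])
    out$tau_hpdi <- hpdi(draws$tau[, f], level)
    out$p_tau_positive <- p_pos
    if (is.null(tau_interval))
      tau_interval <- range(draws$tau[, f])
    if (p_pos > 0 && p_pos < 1 && tau_interval[1L] < 0 && tau_interval[2L] > 0) {
      out$bayes_factor <- bayes_factor_tau_positive(p_pos, tau_interval[1L],
                                                    tau_interval[2L])
      out$evidence <- evidence_label(out$bayes_factor)
    }
  }
  if (!is.null(table)) out$p_value <- bayesian_p_value(draws, table)
  structure(out, class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary\n")
  print(x$population)
  if (!is.null(x$p_tau_positive)) {
    cat(sprintf("tau: mean %.3f, %g%% HPDI (%.3f, %.3f), P(tau>0) = %.3f\n",
                x$tau_mean, 100 * x$level, x$tau_hpdi[[1L]], x$tau_hpdi[[2L]],
                x$p_tau_positive))
    if (!is.null(x$bayes_factor))
      cat(sprintf("Bayes factor for tau > 0: %.3f (%s)\n",
                  x$bayes_factor, x$evidence))
  }
  if (!is.null(x$p_value))
    cat(sprintf("Posterior predictive p-value: %.3f\n", x$p_value))
  cat("Top models:\n")
  print(utils::head(x$models, 5L), row.names = FALSE)
  invisible(x)
}
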