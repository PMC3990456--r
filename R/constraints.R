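#' @keywords internal
#' Per-factor contrast (constraint) matrix for one factor with l levels.
#' Rows are indexed by factor level, columns by the l - 1 free parameters.
factor_contrast <- function(l, system) {
  switch(system,
    sum_to_zero  = rbind(diag(l - 1L), -1),           # last level redundant
    corner_point = stats::contr.treatment(l),         # level 1 is reference
    helmert      = stats::contr.helmert(l),
    stop("unsupported constraint system: ", system))
}

normalize_system <- function(system) {
  system <- gsub("-", "_", tolower(system))
  ok <- c("sum_to_zero", "corner_point", "helmert")
  if (length(system) != 1L || !system %in% ok)
    stop("unsupported constraint system: ", paste(system, collapse = ", "))
  system
}

#' Label of a model term
#'
#' Interaction terms are written as their constituent factor names joined by
#' colons, e.g. `"age:region"`.
#' @param term character vector of constituent factor names.
#' @return single string.
#' @export
term_label <- function(term) paste(term, collapse = ":")

# order constrained theta rows: block with the slowest constituent factor at
# its flagged level first (theta order within the block), then recurse on the
# remaining rows over the remaining factors.  Reproduces the printed
# permutation for the two-way pedagogic example.
.constrained_order <- function(rows, flagged, col) {
  if (length(rows) == 0L || col > ncol(flagged)) return(rows)
  hit <- flagged[rows, col]
  c(rows[hit], .constrained_order(rows[!hit], flagged, col + 1L))
}

#' Constraint matrices of a log-linear term
#'
#' For a main effect or interaction term `t` the `q_t` constrained
#' parameters `theta_t` are generated from the `p_t` free parameters
#' `beta_t` by `theta_t = A_t beta_t`.  Under sum-to-zero (and
#' corner-point) constraints `A_t` factorises as `P_t [I_{p_t}; C_t]` with
#' `P_t` a permutation separating the free from the redundant rows.  For an
#' interaction, `A_t` is the Kronecker product of the constituent
#' main-effect matrices taken in layout order, so the *last* constituent's
#' levels vary fastest along the rows of `A_t` — the same convention as the
#' cell ordering.
#'
#' @param layout a [make_layout()] object.
#' @param term character vector of constituent factor names (subset of the
#'   layout's factors; a single name gives a main effect).
#' @param system `"sum_to_zero"` (default), `"corner_point"` or
#'   `"helmert"`.
#' @return An object of class `"term_constraint"`: `term`, `label`, `q`,
#'   `p`, `A` (`q` by `p`), and — where the `P [I; C]` factorisation exists
#'   (sum-to-zero and corner-point) — the permutation matrix `P` and the
#'   `(q - p)` by `p` matrix `C`; for the Helmert system `P` and `C` are
#'   `NULL` since no subset of Helmert rows forms an identity block.
#' @examples
#' lay <- make_layout(c("age", "hypertension", "region"), c(2, 2, 3))
#' tc <- term_constraint(lay, c("age", "region"))
#' tc$q; tc$p   # 6, 2
#' @export
term_constraint <- function(layout, term, system = "sum_to_zero") {
  stopifnot(inherits(layout, "table_layout"))
  system <- normalize_system(system)
  term <- as.character(term)
  bad <- setdiff(term, layout$factor_names)
  if (length(bad))
    stop("unknown factor(s) in term: ", paste(bad, collapse = ", "))
  # keep constituents in layout order
  term <- layout$factor_names[layout$factor_names %in% term]
  ls_ <- layout$level_counts[match(term, layout$factor_names)]
  q <- prod(ls_)
  p <- prod(ls_ - 1L)
  A <- matrix(1, 1L, 1L)
  for (l in ls_) A <- kronecker(A, factor_contrast(l, system))
  P <- C <- NULL
  if (system != "helmert") {
    # sub-tuples over the constituent factors, last fastest
    sub <- cell_tuples(make_layout(term, ls_))
    redundant_level <- if (system == "sum_to_zero") ls_ else rep(1L, length(ls_))
    flagged <- sub == matrix(redundant_level, q, length(ls_), byrow = TRUE)
    free <- rowSums(flagged) == 0L
    ord <- c(which(free), .constrained_order(which(!free), flagged, 1L))
    # theta row ord[k] occupies position k of gamma = P^T theta
    P <- matrix(0, q, q)
    P[cbind(ord, seq_len(q))] <- 1
    C <- A[ord[-seq_len(p)], , drop = FALSE]
    stopifnot(max(abs(A - P %*% rbind(diag(p), C))) == 0)
  }
  structure(list(term = term, label = term_label(term),
                 q = as.integer(q), p = as.integer(p),
                 A = A, P = P, C = C, system = system),
            class = "term_constraint")
}

#' @export
print.term_constraint <- function(x, ...) {
  cat("Term ", x$label, " (", x$system, "): q = ", x$q, ", p = ", x$p, "\n",
      sep = "")
  invisible(x)
}

# canonical ordering of a model's terms: main effects in layout order, then
# interactions by order and by position of their constituents
canonical_terms <- function(layout, interactions) {
  mains <- as.list(layout$factor_names)
  if (length(interactions) == 0L) return(mains)
  interactions <- lapply(interactions, function(tm)
    layout$factor_names[layout$factor_names %in% tm])
  key <- vapply(interactions, function(tm)
    sprintf("%02d_%s", length(tm),
            paste(sprintf("%02d", match(tm, layout$factor_names)),
                  collapse = "_")), "")
  c(mains, interactions[order(key)])
}

#' Model matrix of a hierarchical log-linear model
#'
#' Builds the `n` by `p` model matrix `X` whose column blocks `X_t` carry
#' the free parameters of each term: the row of `X_t` for cell `i` is the
#' row of `A_t` indexed by the cell's levels on the term's constituent
#' factors.  On a complete balanced table each `X_t` is therefore a
#' row-replicated stacking of `A_t`, so `X_t' X_t = (n / q_t) A_t' A_t`,
#' and under sum-to-zero constraints distinct term blocks are orthogonal.
#'
#' All main effects are always included; `interactions` lists the
#' higher-order terms, which must be hierarchical (every lower-order
#' interaction among an included term's constituents must also be
#' included).
#'
#' @param layout a [make_layout()] object.
#' @param interactions list of character vectors (interaction terms); may
#'   be empty for the independence model.  Main effects are implicit and
#'   need not be listed.
#' @param system constraint system, as in [term_constraint()].
#' @return An object of class `"model_design"`: `layout`, `terms` (list of
#'   all terms in canonical order), `labels`, `constraints` (list of
#'   [term_constraint()]s), `X`, `p`, `q`, `col_term` (integer map from
#'   column to term), and `system`.
#' @export
build_design <- function(layout, interactions = list(), system = "sum_to_zero") {
  stopifnot(inherits(layout, "table_layout"))
  system <- normalize_system(system)
  if (length(interactions) && is.character(interactions) &&
      !is.list(interactions))
    interactions <- strsplit(interactions, ":", fixed = TRUE)
  interactions <- lapply(interactions, as.character)
  if (any(vapply(interactions, length, 1L) < 2L))
    stop("'interactions' must contain terms of order >= 2 (main effects are implicit)")
  labs <- vapply(interactions, term_label, "")
  if (anyDuplicated(labs)) stop("duplicate interaction terms")
  # hierarchy: all proper sub-terms of order >= 2 must be present
  for (tm in interactions) {
    tm <- layout$factor_names[layout$factor_names %in% tm]
    if (length(tm) > 2L) {
      subs <- utils::combn(tm, length(tm) - 1L, simplify = FALSE)
      have <- vapply(subs, function(s) term_label(s) %in% labs ||
                       .sub_present(s, interactions), TRUE)
      if (!all(have))
        stop("non-hierarchical model: term ", term_label(tm),
             " lacks lower-order term(s)")
    }
  }
  terms <- canonical_terms(layout, interactions)
  cons <- lapply(terms, term_constraint, layout = layout, system = system)
  tup <- cell_tuples(layout)
  blocks <- vector("list", length(terms))
  for (k in seq_along(terms)) {
    tm <- cons[[k]]$term
    ls_ <- layout$level_counts[match(tm, layout$factor_names)]
    sub_layout <- make_layout(tm, ls_)
    ridx <- cell_index(sub_layout, tup[, tm, drop = FALSE])
    blocks[[k]] <- cons[[k]]$A[ridx, , drop = FALSE]
  }
  X <- do.call(cbind, blocks)
  p_t <- vapply(cons, `[[`, 1L, "p")
  structure(list(layout = layout, terms = terms,
                 labels = vapply(terms, term_label, ""),
                 constraints = cons, X = X,
                 p = sum(p_t), q = sum(vapply(cons, `[[`, 1L, "q")),
                 col_term = rep(seq_along(terms), p_t),
                 system = system),
            class = "model_design")
}

.sub_present <- function(s, interactions)
  any(vapply(interactions, function(tm) setequal(tm, s), TRUE))

#' @export
print.model_design <- function(x, ...) {
  cat("Log-linear model design (", x$system, "): ",
      paste(x$labels, collapse = " + "), "\n", "  n = ", nrow(x$X),
      ", p = ", x$p, ", q = ", x$q, "\n", sep = "")
  invisible(x)
}

#' Enumerate the hierarchical model space
#'
#' All hierarchical log-linear models that contain every main effect and
#' any downward-closed subset of the interactions up to `max_order`.  With
#' `max_order = 2` and `c` factors this is `2^(c(c-1)/2)` models.
#'
#' @param layout a [make_layout()] object.
#' @param max_order highest interaction order considered (1 gives the
#'   independence model only).
#' @return list of models; each model is a list of interaction terms
#'   (character vectors), empty for the independence model.
#' @export
enumerate_models <- function(layout, max_order = 2L) {
  stopifnot(inherits(layout, "table_layout"))
  max_order <- as.integer(max_order)
  if (max_order < 1L) stop("'max_order' must be >= 1")
  fac <- layout$factor_names
  max_order <- min(max_order, length(fac))
  if (max_order == 1L) return(list(list()))
  cand <- list()
  for (ord in 2:max_order)
    cand <- c(cand, utils::combn(fac, ord, simplify = FALSE))
  models <- list(list())
  # grow downward-closed subsets order by order
  for (ord in 2:max_order) {
    this_ord <- Filter(function(tm) length(tm) == ord, cand)
    grown <- list()
    for (m in models) {
      labs <- vapply(m, term_label, "")
      # interactions of this order whose sub-terms are all in m
      ok <- Filter(function(tm) {
        if (ord == 2L) return(TRUE)
        subs <- utils::combn(tm, ord - 1L, simplify = FALSE)
        all(vapply(subs, function(s) term_label(s) %in% labs, TRUE))
      }, this_ord)
      nk <- length(ok)
      if (nk == 0L) { grown <- c(grown, list(m)); next }
      for (bits in 0:(2^nk - 1L)) {
        sel <- ok[bitwAnd(bits, 2^(seq_len(nk) - 1L)) > 0L]
        grown <- c(grown, list(c(m, sel)))
      }
    }
    models <- grown
  }
  models
}

#' Transform between constraint systems
#'
#' Regression parameters under an alternative constraint system are an
#' exact linear transform of the sum-to-zero parameters:
#' `beta_A = R_A X beta` with
#' `R_A = (X_A' M X_A)^{-1} X_A' M`, `M = I - J/n` the centering
#' projection (the intercept is carried separately, so only the centered
#' column spans matter).  The induced prior covariance under the
#' alternative system is `Psi_A = R_A X Psi X' R_A'`.
#'
#' @param design_alt [build_design()] under the alternative system.
#' @param design_sz [build_design()] of the same terms under sum-to-zero.
#' @return An object of class `"constraint_transform"` with `R_A`, the two
#'   designs, and `M_X` (`R_A %*% X`, the `p` by `p` parameter map).
#' @export
constraint_transform <- function(design_alt, design_sz) {
  stopifnot(inherits(design_alt, "model_design"),
            inherits(design_sz, "model_design"))
  if (!identical(design_alt$labels, design_sz$labels))
    stop("designs must encode the same terms")
  if (design_sz$system != "sum_to_zero")
    stop("'design_sz' must use sum-to-zero constraints")
  XA <- design_alt$X
  n <- nrow(XA)
  XAc <- sweep(XA, 2L, colMeans(XA))          # M %*% XA without forming M
  G <- crossprod(XAc, XA)
  if (rcond(G) < 1e-12) stop("rank-deficient centered design in the alternative system")
  R_A <- solve(G, t(XAc))
  structure(list(R_A = R_A, design_alt = design_alt, design_sz = design_sz,
                 M_X = R_A %*% design_sz$X),
            class = "constraint_transform")
}

#' Prior covariance under an alternative constraint system
#'
#' @param transform a [constraint_transform()].
#' @param Psi prior covariance of the sum-to-zero parameters (see
#'   [joint_prior_covariance()]).
#' @return `Psi_A = R_A X Psi X' R_A'`, generally no longer block-diagonal.
#' @export
transform_prior_covariance <- function(transform, Psi) {
  stopifnot(inherits(transform, "constraint_transform"))
  B <- transform$M_X
  B %*% Psi %*% t(B)
}

#' Hat matrix of a model design
#'
#' Projection onto the centered column span of the model matrix.  The
#' centered span — and hence the hat matrix — is identical across
#' constraint systems encoding the same terms, which is what makes the
#' induced prior covariance system-independent under the identity
#' structure.
#'
#' @param design a [build_design()] object.
#' @return `n` by `n` projection matrix.
#' @export
hat_matrix <- function(design) {
  Xc <- sweep(design$X, 2L, colMeans(design$X))
  Xc %*% solve(crossprod(Xc), t(Xc))
}
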