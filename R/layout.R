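#' Define the layout of a contingency table
#'
#' A layout records the classifying factors of a contingency table, their
#' level counts, and a fixed linearisation of the cells.  Cells are ordered
#' so that the level of the *last* listed factor varies fastest (row-major
#' over the factor list), and all design, constraint and scale matrices in
#' the package follow the same convention.
#'
#' @param factor_names character vector of factor labels (at least one).
#' @param level_counts integer vector of the same length; every factor must
#'   have at least two levels.
#' @param level_labels optional named list giving the level labels of each
#'   factor; defaults to `"1"`, `"2"`, ... per factor.
#'
#' @return An object of class `"table_layout"` with elements
#'   `factor_names`, `level_counts`, `level_labels` and `n` (the total
#'   number of cells, the product of the level counts).
#'
#' @examples
#' lay <- make_layout(c("age", "hypertension", "region"), c(2, 2, 3))
#' lay$n  # 12
#' @export
make_layout <- function(factor_names, level_counts, level_labels = NULL) {
  factor_names <- as.character(factor_names)
  if (length(factor_names) < 1L)
    stop("at least one factor is required")
  if (anyDuplicated(factor_names))
    stop("factor names must be unique")
  level_counts <- as.integer(level_counts)
  if (length(level_counts) != length(factor_names))
    stop("'factor_names' and 'level_counts' must have the same length")
  if (any(is.na(level_counts)) || any(level_counts < 2L))
    stop("every factor must have at least 2 levels")
  if (is.null(level_labels)) {
    level_labels <- lapply(level_counts, function(l) as.character(seq_len(l)))
    names(level_labels) <- factor_names
  } else {
    if (!setequal(names(level_labels), factor_names))
      stop("'level_labels' must be named by the factor names")
    level_labels <- level_labels[factor_names]
    ok <- mapply(function(lab, l) length(lab) == l, level_labels, level_counts)
    if (!all(ok))
      stop("level label lengths must match 'level_counts'")
    level_labels <- lapply(level_labels, as.character)
  }
  structure(
    list(factor_names = factor_names,
         level_counts = level_counts,
         level_labels = level_labels,
         n = prod(level_counts)),
    class = "table_layout")
}

#' @export
print.table_layout <- function(x, ...) {
  cat("Contingency-table layout: ", x$n, " cells\n", sep = "")
  cat(paste0("  ", x$factor_names, " (", x$level_counts, " levels)",
             collapse = "\n"), "\n")
  invisible(x)
}

#' Cross-classifications of every cell
#'
#' Returns the full `n` by `c` matrix of factor levels, one row per cell, in
#' the layout's linear cell order (last factor fastest).
#'
#' @param layout a [make_layout()] object.
#' @return integer matrix with one column per factor.
#' @export
cell_tuples <- function(layout) {
  stopifnot(inherits(layout, "table_layout"))
  l <- layout$level_counts
  c_ <- length(l)
  # strides: last factor has stride 1
  stride <- rev(cumprod(rev(c(l[-1L], 1L))))
  k <- seq_len(layout$n) - 1L
  out <- matrix(0L, layout$n, c_, dimnames = list(NULL, layout$factor_names))
  for (j in seq_len(c_))
    out[, j] <- (k %/% stride[j]) %% l[j] + 1L
  out
}

#' Linear index of a cross-classification
#'
#' Inverse of [cell_tuples()]: maps one or more level tuples to linear cell
#' indices under the last-factor-fastest ordering.
#'
#' @param layout a [make_layout()] object.
#' @param tuple integer vector of length `c`, or a matrix with `c` columns.
#' @return integer vector of cell indices in `1..n`.
#' @export
cell_index <- function(layout, tuple) {
  stopifnot(inherits(layout, "table_layout"))
  l <- layout$level_counts
  if (is.null(dim(tuple))) tuple <- matrix(as.integer(tuple), nrow = 1L)
  if (ncol(tuple) != length(l))
    stop("tuple width must equal the number of factors")
  if (any(tuple < 1L) || any(tuple > rep(l, each = nrow(tuple))))
    stop("level out of range")
  stride <- rev(cumprod(rev(c(l[-1L], 1L))))
  as.integer(drop((tuple - 1L) %*% stride) + 1L)
}

#' Mask the cells unobserved by every source
#'
#' In multi-list (capture-recapture) tables some factors are *sources*: each
#' records whether an individual was observed by that list.  Cells in which
#' every source factor sits at its "unobserved" level contain individuals
#' seen by no list, so their counts are structurally missing.  This function
#' marks exactly those cells.
#'
#' @param layout a [make_layout()] object.
#' @param source_factors character vector of source factor names (non-empty
#'   subset of the layout's factors).
#' @param unobserved_levels integer or character vector, one entry per
#'   source, giving the level that means "not observed" (integer position or
#'   level label).  Defaults to level 2 of every source.
#' @return logical vector of length `n`; `TRUE` marks a missing cell.
#' @examples
#' lay <- make_layout(paste0("f", 1:6), c(2, 2, 2, 2, 2, 11))
#' sum(missing_cell_mask(lay, paste0("f", 1:3)))  # 44
#' @export
missing_cell_mask <- function(layout, source_factors,
                              unobserved_levels = NULL) {
  stopifnot(inherits(layout, "table_layout"))
  source_factors <- as.character(source_factors)
  if (length(source_factors) < 1L)
    stop("at least one source factor is required")
  miss <- !source_factors %in% layout$factor_names
  if (any(miss))
    stop("unknown factor(s): ", paste(source_factors[miss], collapse = ", "))
  if (is.null(unobserved_levels))
    unobserved_levels <- rep(2L, length(source_factors))
  if (length(unobserved_levels) != length(source_factors))
    stop("one unobserved level per source factor is required")
  lev <- integer(length(source_factors))
  for (s in seq_along(source_factors)) {
    labs <- layout$level_labels[[source_factors[s]]]
    if (is.character(unobserved_levels)) {
      m <- match(unobserved_levels[s], labs)
      if (is.na(m)) stop("unknown level '", unobserved_levels[s],
                         "' for factor '", source_factors[s], "'")
      lev[s] <- m
    } else {
      lev[s] <- as.integer(unobserved_levels[s])
      if (lev[s] < 1L || lev[s] > length(labs))
        stop("unknown level ", lev[s], " for factor '", source_factors[s], "'")
    }
  }
  tup <- cell_tuples(layout)
  mask <- rep(TRUE, layout$n)
  for (s in seq_along(source_factors))
    mask <- mask & tup[, source_factors[s]] == lev[s]
  mask
}

#' Construct a contingency table
#'
#' Binds a vector of cell counts to a layout.  Missing (structurally
#' unobserved) cells are flagged by an explicit logical mask rather than a
#' sentinel count, so that a zero count and an unobserved cell remain
#' distinguishable during imputation.
#'
#' @param layout a [make_layout()] object.
#' @param counts numeric vector of length `n`; non-negative integers where
#'   observed.  Entries under the mask may be `NA`.
#' @param missing logical mask of length `n` (default: `is.na(counts)`).
#' @return An object of class `"contingency_table"` with elements `layout`,
#'   `counts` (`NA` in masked cells), `missing`, and `N_observed`, the sum
#'   of the observed counts.
#' @export
contingency_table <- function(layout, counts, missing = NULL) {
  stopifnot(inherits(layout, "table_layout"))
  counts <- as.numeric(counts)
  if (length(counts) != layout$n)
    stop("'counts' must have length n = ", layout$n)
  if (is.null(missing)) missing <- is.na(counts)
  missing <- as.logical(missing)
  if (length(missing) != layout$n)
    stop("'missing' must have length n")
  obs <- counts[!missing]
  if (any(is.na(obs)))
    stop("observed cells must have counts (NA found outside the mask)")
  if (any(obs < 0) || any(obs != round(obs)))
    stop("counts must be non-negative integers")
  counts[missing] <- NA_real_
  structure(
    list(layout = layout, counts = counts, missing = missing,
         N_observed = sum(obs)),
    class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Contingency table: ", x$layout$n, " cells (",
      sum(x$missing), " missing), observed total ", x$N_observed, "\n",
      sep = "")
  invisible(x)
}

#' Linear predictor of a log-linear model
#'
#' Bundles the intercept `phi`, the cell-wise linear predictor
#' `eta = phi + X beta` and the Poisson means `lambda = exp(eta)`.
#'
#' @param phi scalar intercept.
#' @param X the `n` by `p` model matrix (see [build_design()]); may have
#'   zero columns for the intercept-only model.
#' @param beta coefficient vector of length `ncol(X)`.
#' @return list with class `"linear_predictor"`: `phi`, `eta`, `lambda`.
#' @export
linear_predictor <- function(phi, X, beta) {
  stopifnot(is.numeric(phi), length(phi) == 1L, is.finite(phi))
  if (length(beta) != ncol(X))
    stop("length(beta) must equal ncol(X)")
  eta <- as.numeric(phi + X %*% beta)
  structure(list(phi = phi, eta = eta, lambda = exp(eta)),
            class = "linear_predictor")
}

#' Poisson log-likelihood of a complete table
#'
#' Computes `sum_i [ y_i * eta_i - lambda_i - log(y_i!) ]`, the joint
#' log-probability of independent Poisson cell counts with means
#' `lambda_i = exp(eta_i)`.  The table must be complete: structurally
#' missing cells have to be imputed before the likelihood is defined.
#'
#' @param table a [contingency_table()] with no missing cells.
#' @param predictor a [linear_predictor()] (or any list with an `eta`
#'   element of length `n`).
#' @return scalar log-likelihood.  `log(y!)` uses `lgamma(y + 1)`.
#' @export
log_likelihood <- function(table, predictor) {
  stopifnot(inherits(table, "contingency_table"))
  if (any(table$missing))
    stop("table has missing cells; impute them before evaluating the likelihood")
  eta <- predictor$eta
  if (length(eta) != table$layout$n)
    stop("predictor length must equal the number of cells")
  if (any(!is.finite(eta)))
    stop("non-finite linear predictor")
  y <- table$counts
  sum(y * eta - exp(eta) - lgamma(y + 1))
}

#' Read a contingency table from a long-format delimited file
#'
#' One row per cell: the factor columns followed by a count column.  An
#' empty count field marks a structurally missing cell.  The factor level
#' order is taken from the supplied layout, never from file order, so the
#' file may list cells in any order.
#'
#' @param path file path; tab- or comma-delimited with a header row.
#' @param layout a [make_layout()] whose factor names match the file's
#'   factor columns.
#' @param count_col name of the count column (default `"count"`).
#' @param sep field separator; `""` auto-detects tab vs comma.
#' @return a [contingency_table()].
#' @export
read_table_long <- function(path, layout, count_col = "count", sep = "") {
  stopifnot(inherits(layout, "table_layout"))
  if (identical(sep, "")) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = "")
  need <- c(layout$factor_names, count_col)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in table file: ", paste(miss, collapse = ", "))
  if (nrow(df) != layout$n)
    stop("table file has ", nrow(df), " rows; layout expects ", layout$n)
  tup <- matrix(0L, nrow(df), length(layout$factor_names))
  for (j in seq_along(layout$factor_names)) {
    f <- layout$factor_names[j]
    m <- match(df[[f]], layout$level_labels[[f]])
    if (any(is.na(m)))
      stop("unknown level(s) for factor '", f, "'")
    tup[, j] <- m
  }
  idx <- cell_index(layout, tup)
  if (anyDuplicated(idx))
    stop("duplicate cells in table file")
  counts <- rep(NA_real_, layout$n)
  counts[idx] <- suppressWarnings(as.numeric(df[[count_col]]))
  contingency_table(layout, counts)
}

#' Write a contingency table in long format
#'
#' Inverse of [read_table_long()]: one row per cell in the layout's order,
#' missing cells written with an empty count field.
#'
#' @param table a [contingency_table()].
#' @param path output path (tab-delimited).
#' @export
write_table_long <- function(table, path) {
  stopifnot(inherits(table, "contingency_table"))
  lay <- table$layout
  tup <- cell_tuples(lay)
  df <- as.data.frame(lapply(seq_along(lay$factor_names), function(j)
    lay$level_labels[[j]][tup[, j]]))
  names(df) <- lay$factor_names
  df$count <- ifelse(table$missing, "",
                     format(table$counts, trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
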