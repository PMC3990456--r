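#' Read a region adjacency from file
#'
#' Accepts either a labelled square 0/1 matrix (header row of region
#' labels, first column of labels) or a two-column edge list of label
#' pairs; both tab-delimited.
#'
#' @param path file path.
#' @param labels optional character vector fixing the region order (needed
#'   for edge lists; for matrices it must match the file's labels).
#' @return binary symmetric adjacency matrix with dimnames.
#' @export
read_adjacency <- function(path, labels = NULL) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(first) <= 2L) {      # edge list
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    if (ncol(df) < 2L) stop("edge list needs two columns")
    if (is.null(labels)) labels <- sort(unique(c(df[[1L]], df[[2L]])))
    bad <- setdiff(c(df[[1L]], df[[2L]]), labels)
    if (length(bad)) stop("unknown region label(s): ",
                          paste(unique(bad), collapse = ", "))
    G <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
    G[cbind(df[[1L]], df[[2L]])] <- 1
    G <- pmax(G, t(G))
    diag(G) <- 0
    return(check_adjacency(G))
  }
  M <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1L, check.names = FALSE))
  if (!is.null(labels)) {
    if (!setequal(labels, rownames(M)))
      stop("adjacency labels do not match the factor's levels")
    M <- M[labels, labels]
  }
  storage.mode(M) <- "double"
  check_adjacency(M)
}

#' Write an adjacency matrix
#' @param G labelled adjacency matrix.
#' @param path output path (tab-delimited, labelled).
#' @export
write_adjacency <- function(G, path) {
  df <- data.frame(region = rownames(G), G, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled symmetric distance matrix
#' @param path file path (tab-delimited, header row and label column).
#' @param labels optional label order to enforce.
#' @return numeric matrix.
#' @export
read_distance_matrix <- function(path, labels = NULL) {
  M <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1L, check.names = FALSE))
  if (!is.null(labels)) M <- M[labels, labels]
  storage.mode(M) <- "double"
  M
}

#' Write posterior draws as delimited text
#'
#' One row per retained iteration: iteration number, model label, `phi`,
#' `g`, `tau` columns, `N`, then the per-term coefficient columns (blank
#' where the term is excluded from that iteration's model) and the imputed
#' missing counts.
#'
#' @param draws a [run_chain()] result.
#' @param path output path.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  bl <- draws$labels[draws$beta_col]
  reps <- stats::ave(seq_along(bl), bl, FUN = seq_along)
  beta_names <- paste0("beta.", bl, ".", reps)
  df <- data.frame(iteration = seq_along(draws$phi), model = draws$model,
                   phi = draws$phi, g = draws$g, check.names = FALSE)
  if (ncol(draws$tau))
    for (f in colnames(draws$tau)) df[[paste0("tau.", f)]] <- draws$tau[, f]
  df$N <- draws$N
  B <- draws$beta
  colnames(B) <- beta_names
  df <- cbind(df, B)
  if (ncol(draws$y_missing)) {
    Y <- draws$y_missing
    colnames(Y) <- paste0("ymiss.", which(draws$miss))
    df <- cbind(df, Y)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a draws file written by [write_draws()]
#' @param path file path.
#' @return data frame, one row per retained iteration.
#' @export
read_draws <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = "")
}

# ---- run configuration ----------------------------------------------------

.cfg_path <- function(p, base) if (file.exists(p)) p else file.path(base, p)

.layout_from_config <- function(cfg) {
  if (is.null(cfg$factors)) stop("config needs a 'factors' list")
  nm <- vapply(cfg$factors, `[[`, "", "name")
  levs <- lapply(cfg$factors, `[[`, "levels")
  names(levs) <- nm
  make_layout(nm, vapply(levs, length, 1L), levs)
}

.structures_from_config <- function(cfg, layout, base) {
  out <- list()
  for (f in names(cfg$structures)) {
    sc <- cfg$structures[[f]]
    kind <- tolower(sc$kind %||% "identity")
    if (kind == "identity") next
    if (kind == "car") {
      if (is.null(sc$adjacency))
        stop("CAR structure for factor '", f,
             "' requires an 'adjacency' file in the config")
      G <- read_adjacency(.cfg_path(sc$adjacency, base),
                          labels = layout$level_labels[[f]])
      out[[f]] <- dependence_structure("car", G = G,
                                       tau_interval = sc$tau_interval)
    } else if (kind == "distance") {
      if (is.null(sc$distances))
        stop("distance structure for factor '", f,
             "' requires a 'distances' file in the config")
      d <- read_distance_matrix(.cfg_path(sc$distances, base),
                                labels = layout$level_labels[[f]])
      if (is.null(sc$tau_interval))
        stop("distance structure for factor '", f,
             "' requires a 'tau_interval' in the config")
      out[[f]] <- dependence_structure("distance", d = d,
                                       tau_interval = as.numeric(sc$tau_interval))
    } else stop("unknown structure kind '", sc$kind, "' for factor '", f, "'")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a run configuration
#'
#' The configuration is a YAML file declaring the table path, the factors
#' and their level order, optional source factors, per-factor dependence
#' structures, prior hyperparameters, the model space and the sampler
#' settings.  Relative paths resolve against the config file's directory.
#'
#' @param path YAML config path.
#' @return list with resolved `layout`, `table`, `prior`, `space`,
#'   `sampler` ([sampler_config()]), `output` directory, and the raw
#'   config.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  layout <- .layout_from_config(cfg)
  if (is.null(cfg$table)) stop("config needs a 'table' path")
  tpath <- .cfg_path(cfg$table, base)
  if (!file.exists(tpath)) stop("table file not found: ", tpath)
  tab <- read_table_long(tpath, layout)
  if (!is.null(cfg$sources)) {
    mask <- missing_cell_mask(layout, cfg$sources$factors,
                              unlist(cfg$sources$unobserved))
    if (!all(tab$missing == mask)) {
      if (any(tab$missing & !mask))
        stop("table has empty counts outside the source-unobserved cells")
      cnt <- tab$counts; cnt[mask] <- NA
      tab <- contingency_table(layout, cnt, mask)
    }
  }
  structures <- .structures_from_config(cfg, layout, base)
  pc <- cfg$prior %||% list()
  prior <- prior_spec(layout, structures,
                      a = pc$a %||% 1e-3, b = pc$b %||% 1e-3,
                      g_mode = pc$g_mode %||% "hyper",
                      g_fixed = pc$g_fixed)
  mc <- cfg$model %||% list()
  space <- if (!is.null(mc$models))
    model_space(layout, models = lapply(mc$models, function(m)
      lapply(as.list(m), function(s) strsplit(s, ":", fixed = TRUE)[[1L]])))
  else model_space(layout, max_order = mc$max_order %||% 2L)
  sc <- cfg$sampler %||% list()
  sampler <- sampler_config(iterations = sc$iterations %||% 10000L,
                            burnin = sc$burnin %||% 0.1,
                            thin = sc$thin %||% 1L,
                            seed = sc$seed %||% 1L,
                            tau_scale = sc$tau_scale,
                            adapt_tau = sc$adapt_tau %||% TRUE)
  list(layout = layout, table = tab, prior = prior, space = space,
       sampler = sampler, output = .cfg_path(cfg$output %||% "output", base),
       raw = cfg)
}

#' Fit a configured analysis end to end
#'
#' Runs [run_chain()] under the configuration, then writes four outputs to
#' the output directory: `draws.tsv`, `summary.txt`, a
#' `model_probabilities.tsv` table, and `provenance.yaml` (config, seed
#' and package version — enough to re-run bit-identically).
#'
#' @param config path to a YAML config, or the result of
#'   [read_run_config()].
#' @return the [summarize_draws()] summary, invisibly.
#' @export
run_fit <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  draws <- run_chain(config$table, config$prior, config$space,
                     config$sampler)
  tau_iv <- NULL
  if (length(config$prior$correlated))
    tau_iv <- config$prior$structures[[config$prior$correlated[1L]]]$tau_interval
  summ <- summarize_draws(draws, tau_interval = tau_iv,
                          table = config$table)
  write_draws(draws, file.path(config$output, "draws.tsv"))
  utils::write.table(model_probabilities(draws),
                     file.path(config$output, "model_probabilities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(file.path(config$output, "summary.txt"), "w")
  sink(con); print(summ); sink(); close(con)
  yaml::write_yaml(list(package = "carloglin",
                        version = as.character(utils::packageVersion("carloglin")),
                        seed = config$sampler$seed, config = config$raw),
                   file.path(config$output, "provenance.yaml"))
  invisible(summ)
}

#' Generate synthetic data from a YAML specification
#'
#' Supports the two built-in presets (`preset: pedagogic`, a complete
#' 2x2x3 table with a CAR region effect, and `preset: scotland`, the
#' six-factor incomplete capture-recapture test bed) with optional
#' overrides (`seed`, `tau`, `tau_frac`, `phi`).  Writes `table.tsv`, a
#' `truth.yaml` bundle, and `adjacency.tsv` when a CAR factor is present.
#'
#' @param spec_file YAML path, or an equivalent list.
#' @param output optional output directory (overrides the config).
#' @return invisible list of written paths plus the truth bundle.
#' @export
run_simulate <- function(spec_file, output = NULL) {
  cfg <- if (is.character(spec_file)) yaml::read_yaml(spec_file) else spec_file
  base <- if (is.character(spec_file)) dirname(normalizePath(spec_file)) else "."
  seed <- as.integer(cfg$seed %||% 1L)
  preset <- tolower(cfg$preset %||% "pedagogic")
  if (preset == "pedagogic") {
    fx <- pedagogic_fixture()
    tau <- cfg$tau %||% 0.3
    b <- fx$tau_bounds
    if (tau <= b[[1L]] || tau >= b[[2L]])
      stop(sprintf("tau = %g outside the permissible interval (%.4g, %.4g)",
                   tau, b[[1L]], b[[2L]]))
    spec <- generator_spec(
      fx$layout, interactions = list(),
      phi = cfg$phi %||% log(20),
      beta = list(age = 0.1, hypertension = 0.1),
      draw = list(region = 0.5),
      structures = list(region = dependence_structure("car", G = fx$G)),
      tau = c(region = tau), seed = seed)
    gen <- generate_table(spec)
    table <- gen$complete
    G <- fx$G
  } else if (preset %in% c("scotland", "scotland_like")) {
    fx <- scotland_like_fixture(seed = seed,
                                tau_frac = cfg$tau_frac %||% 0.8,
                                phi = cfg$phi %||% log(25))
    gen <- list(truth = fx$truth)
    table <- fx$masked
    G <- fx$G
  } else stop("unknown preset '", cfg$preset, "'")
  out <- if (!is.null(output)) output else .cfg_path(cfg$output %||% "simulated", base)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- list(table = file.path(out, "table.tsv"),
                truth = file.path(out, "truth.yaml"),
                adjacency = file.path(out, "adjacency.tsv"))
  write_table_long(table, paths$table)
  write_adjacency(G, paths$adjacency)
  tr <- gen$truth
  yaml::write_yaml(list(phi = tr$phi, beta = tr$beta,
                        tau = as.list(tr$tau), N = tr$N, seed = tr$seed),
                   paths$truth)
  invisible(c(paths, list(truth_bundle = gen$truth)))
}

#' Audit the prior before fitting
#'
#' For every term of the model (main effects and interactions up to
#' `max_order`) reports `q_t`, `p_t`, the permissible `tau` interval of
#' any correlated constituent, and the conditioned covariance `Sigma_t`
#' evaluated at a supplied `tau`.  With all-identity structures the
#' report notes that the joint prior reduces to `g (X'X)^{-1}`.
#'
#' @param layout a [make_layout()] object.
#' @param structures named list of [dependence_structure()]s.
#' @param tau value(s) of the dependence parameter at which `Sigma_t` is
#'   evaluated (named, or scalar for a single correlated factor); ignored
#'   with all-identity structures.
#' @param max_order highest interaction order to report.
#' @return object of class `"prior_report"` (a list of per-term entries),
#'   printed as structured text.
#' @export
prior_report <- function(layout, structures = list(), tau = NULL,
                         max_order = 2L) {
  prior <- prior_spec(layout, structures)
  fac <- layout$factor_names
  terms <- as.list(fac)
  if (max_order >= 2L)
    for (ord in 2:min(max_order, length(fac)))
      terms <- c(terms, utils::combn(fac, ord, simplify = FALSE))
  entries <- lapply(terms, function(tm) {
    tc <- term_constraint(layout, tm)
    ent <- list(label = tc$label, q = tc$q, p = tc$p)
    cf <- intersect(tm, prior$correlated)
    if (length(cf)) {
      ent$tau_bounds <- lapply(cf, function(f) {
        s <- prior$structures[[f]]
        if (s$kind == "car") s$bounds else s$tau_interval
      })
      names(ent$tau_bounds) <- cf
    }
    D <- term_scale_matrix(prior, tm, tau)
    ent$Sigma <- term_prior_covariance(tc, D)
    ent
  })
  structure(list(entries = entries, tau = tau,
                 identity_only = length(prior$correlated) == 0L),
            class = "prior_report")
}

#' @export
print.prior_report <- function(x, ...) {
  cat("Prior report\n")
  if (x$identity_only)
    cat("All structures are identity: the joint prior is the generalised",
        "hyper-g form beta | g ~ N(0, g (X'X)^-1)\n")
  else if (!is.null(x$tau))
    cat("Sigma_t evaluated at tau =",
        paste(format(x$tau), collapse = ", "), "\n")
  for (ent in x$entries) {
    cat(sprintf("\nterm %s: q = %d, p = %d\n", ent$label, ent$q, ent$p))
    if (!is.null(ent$tau_bounds))
      for (f in names(ent$tau_bounds))
        cat(sprintf("  tau bounds for %s: (%.6g, %.6g)\n", f,
                    ent$tau_bounds[[f]][1L], ent$tau_bounds[[f]][2L]))
    cat("  Sigma_t:\n")
    mat <- format(round(ent$Sigma, 6), trim = TRUE)
    for (i in seq_len(nrow(mat)))
      cat("    ", paste(mat[i, ], collapse = "  "), "\n")
  }
  invisible(x)
}
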