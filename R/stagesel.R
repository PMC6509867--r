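#' Configuration for elastic-net stability selection
#'
#' The per-stage regression minimizes
#' \deqn{(1/m)\|y - X\beta\|_2^2 + \lambda\,(a\|\beta\|_1 + (1-a)\|\beta\|_2^2)}
#' along a decreasing grid of overall penalty strengths \eqn{\lambda}. The
#' mixing fraction `alpha_mix` \eqn{= a} balances the lasso and ridge parts;
#' at the default 0.5 the two penalty coefficients are equal at every grid
#' point. A gene counts as selected in a model when any of its feature
#' columns (expression or methylation) has `|beta| > coef_threshold`; genes
#' selected in at least `cutoff` of the `n_models` models form the
#' stage-specific gene set.
#'
#' @param alpha_mix lasso/ridge mixing fraction in (0, 1].
#' @param n_models number of penalty-grid points (models) per stage.
#' @param coef_threshold minimum absolute coefficient for a selection.
#' @param cutoff minimum number of models a gene must be selected in.
#' @param lambda_min_ratio smallest penalty as a fraction of the smallest
#'   all-zero penalty `lambda_max`.
#' @param max_iter coordinate-descent sweep cap per grid point.
#' @param tol convergence tolerance on the maximum coefficient change per
#'   sweep.
#' @return An object of class `enet_config`.
#' @export
enet_config <- function(alpha_mix = 0.5, n_models = 50L,
                        coef_threshold = 1e-8, cutoff = 20L,
                        lambda_min_ratio = 1e-2, max_iter = 10000L,
                        tol = 1e-7) {
  cfg <- list(alpha_mix = as.numeric(alpha_mix),
              n_models = as.integer(n_models),
              coef_threshold = as.numeric(coef_threshold),
              cutoff = as.integer(cutoff),
              lambda_min_ratio = as.numeric(lambda_min_ratio),
              max_iter = as.integer(max_iter), tol = as.numeric(tol))
  if (cfg$alpha_mix <= 0 || cfg$alpha_mix > 1)
    stop("'alpha_mix' must be in (0, 1]")
  if (cfg$n_models < 1L) stop("'n_models' must be >= 1")
  if (cfg$cutoff > cfg$n_models) stop("'cutoff' must be <= n_models")
  if (cfg$tol <= 0) stop("'tol' must be > 0")
  if (cfg$lambda_min_ratio <= 0 || cfg$lambda_min_ratio > 1)
    stop("'lambda_min_ratio' must be in (0, 1]")
  class(cfg) <- "enet_config"
  cfg
}

# Penalized objective evaluated at one coefficient vector.
enet_objective <- function(X, y, beta, lambda, alpha_mix) {
  r <- y - X %*% beta
  sum(r^2) / length(y) +
    lambda * (alpha_mix * sum(abs(beta)) + (1 - alpha_mix) * sum(beta^2))
}

as_label_vector <- function(y) {
  if (inherits(y, "stage_label")) y <- y$y
  y <- as.numeric(y)
  if (any(!y %in% c(0, 1))) stop("label vector must be binary 0/1")
  y
}

as_design <- function(X) {
  if (inherits(X, "feature_matrix")) X$X else as.matrix(X)
}

#' Fit the elastic-net regularization path for one stage
#'
#' Solves the penalized least-squares problem by cyclic coordinate descent
#' with warm starts along a log-spaced grid of `n_models` penalty strengths,
#' from `lambda_max` (the smallest penalty at which all coefficients are
#' exactly zero, by the subgradient condition
#' `max_j |(2/m) x_j' y| <= lambda * alpha_mix`) down to
#' `lambda_max * lambda_min_ratio`.
#'
#' @param X a `feature_matrix` or a numeric matrix with standardized columns.
#' @param y a `stage_label` or binary 0/1 vector.
#' @param config an [enet_config()].
#' @return An `enet_path`: `lambdas` (decreasing), `beta`
#'   (`n_models` x `n` coefficient matrix), `objective` per grid point,
#'   convergence diagnostics, and the configuration.
#' @export
fit_enet_path <- function(X, y, config = enet_config()) {
  Xm <- as_design(X)
  yv <- as_label_vector(y)
  if (length(yv) != nrow(Xm)) stop("length(y) must equal nrow(X)")
  if (length(unique(yv)) < 2L) stop("degenerate label: y is constant")
  m <- nrow(Xm)
  score <- abs(crossprod(Xm, yv)) * 2 / m
  # a hair above the subgradient bound so the first grid point is exactly
  # all-zero despite rounding
  lambda_max <- max(score) / config$alpha_mix * (1 + 1e-9)
  if (lambda_max <= 0) lambda_max <- .Machine$double.eps
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * config$lambda_min_ratio),
                     length.out = config$n_models))
  fit <- .enet_path_cd(Xm, yv, lambdas, config$alpha_mix, config$tol,
                       config$max_iter)
  beta <- fit$beta
  colnames(beta) <- colnames(Xm)
  if (!all(fit$converged))
    warning(sprintf(
      "coordinate descent hit max_iter at %d grid point(s); final max coefficient change %.3g",
      sum(!fit$converged), max(fit$final_delta[!fit$converged])))
  objective <- vapply(seq_along(lambdas), function(l)
    enet_objective(Xm, yv, beta[l, ], lambdas[l], config$alpha_mix),
    numeric(1))
  structure(list(lambdas = lambdas, beta = beta, objective = objective,
                 iters = fit$iters, converged = fit$converged,
                 config = config),
            class = "enet_path")
}

#' @export
print.enet_path <- function(x, ...) {
  nz <- rowSums(abs(x$beta) > x$config$coef_threshold)
  cat(sprintf("Elastic-net path: %d models over lambda [%.3g, %.3g]\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas)))
  cat(sprintf("  active features: %d (first model) to %d (last model)\n",
              nz[1L], nz[length(nz)]))
  invisible(x)
}

#' @export
coef.enet_path <- function(object, model = length(object$lambdas), ...) {
  setNames(object$beta[model, ], colnames(object$beta))
}

#' Count per-gene selections along a coefficient path
#'
#' A gene is selected in a model when any of its feature columns has
#' `|beta| > coef_threshold`; expression and methylation columns of the same
#' gene count once per model (union, not sum). Genes with a count of at
#' least `cutoff` form the selected set.
#'
#' @param path an `enet_path`.
#' @param column_gene named character vector mapping every column of the
#'   path's coefficient matrix to a gene symbol.
#' @param config an [enet_config()] (defaults to the path's own).
#' @return A `selection_profile`: `counts` (named integer vector over
#'   genes), `selected` (character vector of genes with
#'   `count >= cutoff`), and the counting parameters.
#' @export
count_selections <- function(path, column_gene, config = path$config) {
  cols <- colnames(path$beta)
  if (is.null(names(column_gene))) {
    if (length(column_gene) != ncol(path$beta))
      stop("column_gene must cover every path column")
    names(column_gene) <- cols
  }
  missing <- setdiff(cols, names(column_gene))
  if (length(missing))
    stop(sprintf("column_gene is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  active <- abs(path$beta) > config$coef_threshold  # models x columns
  genes <- unique(unname(column_gene[cols]))
  counts <- vapply(genes, function(g) {
    gc <- cols[column_gene[cols] == g]
    sum(rowSums(active[, gc, drop = FALSE]) > 0L)
  }, integer(1))
  structure(list(counts = counts,
                 selected = names(counts)[counts >= config$cutoff],
                 cutoff = config$cutoff,
                 coef_threshold = config$coef_threshold,
                 n_models = nrow(path$beta)),
            class = "selection_profile")
}

#' @export
print.selection_profile <- function(x, ...) {
  cat(sprintf("Selection profile: %d genes counted over %d models; %d at cutoff >= %d\n",
              length(x$counts), x$n_models, length(x$selected), x$cutoff))
  invisible(x)
}

#' Stage-specific gene selection across all one-vs-rest contrasts
#'
#' Fits one elastic-net regularization path per stage label vector and
#' applies the selection-count rule, yielding the stage-specific gene sets
#' and a per-stage run summary (number of models, the largest number of
#' genes active in any single model, and the number of genes at the
#' selection cutoff).
#'
#' @param X a `feature_matrix` (or matrix plus `column_gene`).
#' @param labels named list of `stage_label` vectors (see
#'   [binarize_stages()]).
#' @param config an [enet_config()].
#' @param column_gene column-to-gene map; taken from `X` when it is a
#'   `feature_matrix`.
#' @return A `stage_select` object: per-stage `profiles` and `paths`, the
#'   `summary` data.frame, and the configuration.
#' @export
select_stage_genes <- function(X, labels, config = enet_config(),
                               column_gene = NULL) {
  if (inherits(X, "feature_matrix")) {
    column_gene <- X$column_gene
    Xm <- X$X
  } else Xm <- as_design(X)
  if (is.null(column_gene)) stop("column_gene required for a plain matrix")
  paths <- lapply(labels, function(lab) fit_enet_path(Xm, lab, config))
  profiles <- lapply(paths, count_selections, column_gene = column_gene,
                     config = config)
  summary <- data.frame(
    stage = names(labels),
    models = vapply(paths, function(p) length(p$lambdas), integer(1)),
    detected_genes = vapply(seq_along(paths), function(i) {
      active <- abs(paths[[i]]$beta) > config$coef_threshold
      genes <- unname(column_gene[colnames(paths[[i]]$beta)])
      max(vapply(seq_len(nrow(active)), function(l)
        length(unique(genes[active[l, ]])), integer(1)))
    }, integer(1)),
    genes_at_cutoff = vapply(profiles, function(p) length(p$selected),
                             integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(profiles = profiles, paths = paths, summary = summary,
                 config = config),
            class = "stage_select")
}

#' @export
print.stage_select <- function(x, ...) {
  cat("Stage-specific elastic-net stability selection\n")
  cat(sprintf("  alpha_mix %.2f, %d models, cutoff %d\n",
              x$config$alpha_mix, x$config$n_models, x$config$cutoff))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
summary.stage_select <- function(object, ...) object$summary

#' Selected gene sets of a fitted stage selection
#' @param x a `stage_select`.
#' @return Named list of character vectors (selected genes per stage).
#' @export
selected_genes <- function(x) {
  stopifnot(inherits(x, "stage_select"))
  lapply(x$profiles, `[[`, "selected")
}

#' Write per-stage selection profiles and the run summary as TSV
#' @param x a `stage_select`.
#' @param dir output directory.
#' @export
write_selection_tsv <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (st in names(x$profiles)) {
    p <- x$profiles[[st]]
    df <- data.frame(gene = names(p$counts), count = unname(p$counts),
                     selected = names(p$counts) %in% p$selected)
    df <- df[order(-df$count, df$gene), ]
    write.table(df, file.path(dir, sprintf("selection_profile_%s.tsv", st)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(x$summary, file.path(dir, "run_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(x)
}
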