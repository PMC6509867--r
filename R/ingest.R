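#' Read an omics layer from a TSV matrix
#'
#' Expects rows = features and columns = samples, with feature identifiers in
#' the first column and sample identifiers in the header. Features with any
#' missing value (`NA`, `"NA"`, `"NULL"`, empty cell) are removed. For
#' methylation data measured at CpG loci, `locus_map` maps each locus to the
#' gene(s) it annotates: a locus value is divided equally among its genes,
#' and a gene's value is the mean of the contributions it receives from its
#' loci, so the result is one feature per gene on the original scale.
#'
#' @param path TSV file (optionally gzipped).
#' @param layer `"expression"` or `"methylation"`.
#' @param locus_map optional named list: locus id -> character vector of gene
#'   symbols.
#' @return An `omics_layer`: list with `values` (samples x features matrix),
#'   `feature_ids`, `gene_of_feature` (named character vector) and `layer`.
#' @export
read_omics <- function(path, layer = c("expression", "methylation"),
                       locus_map = NULL) {
  layer <- match.arg(layer)
  con <- open_text(path)
  on.exit(close(con))
  raw <- read.table(con, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character",
                    quote = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop(sprintf("empty or malformed omics file: %s", path))
  feature_ids <- raw[[1L]]
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup))
    stop(sprintf("duplicate feature IDs in %s: %s", path,
                 paste(unique(dup), collapse = ", ")))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  missing_mask <- is.na(cells) | cells %in% c("NA", "NULL", "")
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad_cell <- is.na(vals) & !missing_mask
  if (any(bad_cell)) {
    row <- feature_ids[which(rowSums(bad_cell) > 0)[1L]]
    stop(sprintf("non-numeric value in %s at feature '%s'", path, row))
  }
  keep <- rowSums(missing_mask) == 0L
  vals <- vals[keep, , drop = FALSE]
  feature_ids <- feature_ids[keep]
  if (sum(!keep) > 0L)
    message(sprintf("read_omics: dropped %d feature(s) with missing values",
                    sum(!keep)))
  values <- t(vals)  # samples x features
  rownames(values) <- colnames(raw)[-1L]
  colnames(values) <- feature_ids
  if (!is.null(locus_map)) {
    values <- share_loci(values, locus_map)
    feature_ids <- colnames(values)
  }
  structure(list(values = values, feature_ids = feature_ids,
                 gene_of_feature = setNames(feature_ids, feature_ids),
                 layer = layer),
            class = "omics_layer")
}

# Equal-sharing of multi-gene loci followed by per-gene mean aggregation:
# each locus contributes value / (number of its genes) to every mapped gene,
# and a gene's value is the mean of its received contributions.
share_loci <- function(values, locus_map) {
  loci <- intersect(colnames(values), names(locus_map))
  if (length(loci) == 0L) stop("locus_map matches no feature")
  gene_of <- locus_map[loci]
  pairs <- data.frame(locus = rep(loci, lengths(gene_of)),
                      gene = unlist(gene_of, use.names = FALSE),
                      stringsAsFactors = FALSE)
  pairs$weight <- 1 / lengths(gene_of)[match(pairs$locus, loci)]
  genes <- sort(unique(pairs$gene))
  out <- matrix(0, nrow = nrow(values), ncol = length(genes),
                dimnames = list(rownames(values), genes))
  n_contrib <- setNames(numeric(length(genes)), genes)
  for (k in seq_len(nrow(pairs))) {
    g <- pairs$gene[k]
    out[, g] <- out[, g] + values[, pairs$locus[k]] * pairs$weight[k]
    n_contrib[g] <- n_contrib[g] + 1
  }
  sweep(out, 2L, n_contrib, "/")
}

#' Restrict two omics layers to their shared genes
#'
#' @param expr,meth `omics_layer` objects.
#' @return List of the two layers restricted to the gene intersection, in the
#'   same (sorted) gene order.
#' @export
intersect_layers <- function(expr, meth) {
  shared <- sort(intersect(unname(expr$gene_of_feature),
                           unname(meth$gene_of_feature)))
  if (length(shared) == 0L) stop("no shared genes between layers")
  restrict <- function(layer) {
    keep <- layer$feature_ids[unname(layer$gene_of_feature) %in% shared]
    keep <- keep[order(layer$gene_of_feature[keep])]
    layer$values <- layer$values[, keep, drop = FALSE]
    layer$feature_ids <- keep
    layer$gene_of_feature <- layer$gene_of_feature[keep]
    layer
  }
  list(expression = restrict(expr), methylation = restrict(meth))
}

#' Build one-vs-rest binary stage label vectors from a clinical table
#'
#' Samples without a usable `pathology_t_stage` entry are dropped; substage
#' suffixes are normalized (e.g. `"T2b"` -> `"t2"`). Each returned vector is
#' 1 for samples of its stage and 0 otherwise, so across the stages every
#' retained sample carries exactly one 1.
#'
#' @param clinical data.frame with `sample_id` and `pathology_t_stage`.
#' @param stages stage tags to build vectors for.
#' @return Named list of `stage_label` objects (`stage`, `y` named 0/1
#'   vector).
#' @export
binarize_stages <- function(clinical, stages = paste0("t", 1:4)) {
  stopifnot(all(c("sample_id", "pathology_t_stage") %in% names(clinical)))
  raw <- trimws(as.character(clinical$pathology_t_stage))
  usable <- !is.na(raw) & raw != "" & toupper(raw) != "NA"
  norm <- sub("^(t[0-9]+).*$", "\\1", tolower(raw))
  bad <- usable & !(norm %in% stages)
  if (any(bad))
    stop(sprintf("stage values outside %s for sample(s): %s",
                 paste(stages, collapse = "/"),
                 paste(clinical$sample_id[bad], collapse = ", ")))
  ids <- clinical$sample_id[usable]
  norm <- norm[usable]
  if (length(ids) == 0L) stop("no sample with a usable pathology_t_stage")
  lapply(setNames(stages, stages), function(st) {
    structure(list(stage = st,
                   y = setNames(as.integer(norm == st), ids)),
              class = "stage_label")
  })
}

#' Assemble the standardized multi-omics feature matrix
#'
#' Concatenates the expression features followed by the methylation features
#' of the gene-intersected layers, restricted to `sample_ids`, and z-score
#' standardizes every column. Constant columns cannot be standardized and are
#' dropped with a warning.
#'
#' @param expr,meth gene-intersected `omics_layer` objects.
#' @param sample_ids samples to keep (must exist in both layers).
#' @return A `feature_matrix`: list with `X` (samples x features, each
#'   column mean 0 / sd 1), `sample_ids`, `column_gene` and `column_layer`.
#' @export
assemble_features <- function(expr, meth, sample_ids) {
  for (layer in list(expr, meth)) {
    missing <- setdiff(sample_ids, rownames(layer$values))
    if (length(missing))
      stop(sprintf("sample(s) missing from %s layer: %s", layer$layer,
                   paste(missing, collapse = ", ")))
  }
  blocks <- list(expr, meth)
  X <- do.call(cbind, lapply(blocks, function(l)
    l$values[sample_ids, , drop = FALSE]))
  column_gene <- unlist(lapply(blocks, function(l)
    unname(l$gene_of_feature[colnames(l$values)])))
  column_layer <- rep(c("expression", "methylation"),
                      vapply(blocks, function(l) ncol(l$values), integer(1)))
  colnames(X) <- paste(column_gene, substr(column_layer, 1L, 4L), sep = "|")
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  const <- sdv == 0 | !is.finite(sdv)
  if (any(const)) {
    warning(sprintf("dropping %d constant feature column(s)", sum(const)))
    X <- X[, !const, drop = FALSE]
    column_gene <- column_gene[!const]
    column_layer <- column_layer[!const]
    mu <- mu[!const]; sdv <- sdv[!const]
  }
  if (ncol(X) == 0L) stop("no non-constant feature columns")
  X <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  structure(list(X = X, sample_ids = sample_ids,
                 column_gene = setNames(column_gene, colnames(X)),
                 column_layer = setNames(column_layer, colnames(X))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d samples x %d standardized columns (%d genes)\n",
              nrow(x$X), ncol(x$X), length(unique(x$column_gene))))
  invisible(x)
}

#' Construct a protein-protein interaction network
#'
#' @param edges two-column character matrix of gene pairs; self-loops and
#'   duplicate pairs are removed.
#' @param nodes optional node universe (defaults to the edge endpoints).
#' @return A `ppi_network` with `nodes` and canonical `edges` (u < v).
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- canonical_edges(edges[, 1L], edges[, 2L])
  nodes <- sort(unique(c(nodes, as.vector(edges))))
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a PPI edge list from a two-column TSV
#'
#' Duplicate edges (in either orientation) and self-loops are dropped and
#' counted in a message.
#'
#' @param path TSV file (optionally gzipped), two gene symbols per line.
#' @return A [ppi_network].
#' @export
read_ppi <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop(sprintf("malformed PPI line %d in %s", bad[1L], path))
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  edges <- canonical_edges(from, to)
  n_dropped <- length(from) - nrow(edges)
  if (n_dropped > 0L)
    message(sprintf("read_ppi: dropped %d self-loop/duplicate edge(s)",
                    n_dropped))
  ppi_network(edges)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Duplicate members within a set are removed.
#'
#' @param path GMT file (optionally gzipped).
#' @return Named list of character vectors; descriptions kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d in %s (need name, description, members)",
                 bad[1L], path))
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate gene-set names in %s", path))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <- setNames(
    vapply(parts, `[[`, character(1), 2L), ids)
  sets
}
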