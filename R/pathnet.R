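#' Hypergeometric pathway enrichment with Benjamini-Hochberg correction
#'
#' Tests each pathway gene set for over-representation of the query (module)
#' genes by the upper-tail hypergeometric probability
#' \eqn{P(K \ge k)} with universe size \eqn{N}, pathway size \eqn{K},
#' query size \eqn{n} and overlap \eqn{k}. Pathways with no overlapping
#' gene are not reported. q-values are Benjamini-Hochberg adjusted across
#' the reported pathways of the one query (stage).
#'
#' @param module_genes query gene set (the stage module members).
#' @param gene_sets named list of pathway gene sets.
#' @param universe background gene universe; pathways and query are
#'   intersected with it.
#' @param fdr significance threshold on the q-value.
#' @param stage optional stage tag carried into the result.
#' @return data.frame with one row per overlapping pathway: `pathway`,
#'   `stage`, `k_overlap`, `pathway_size`, `query_size`, `universe_size`,
#'   `p_value`, `q_value`, `significant`; ordered by p-value.
#' @export
enrich <- function(module_genes, gene_sets, universe, fdr = 0.05,
                   stage = NA_character_) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- intersect(unique(module_genes), universe)
  if (length(query) == 0L) stop("empty query after universe intersection")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(gene_sets[[id]], universe)
    k <- length(intersect(set, query))
    if (k == 0L) return(NULL)
    K <- length(set)
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = id, stage = stage, k_overlap = k,
               pathway_size = K, query_size = n, universe_size = N,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- data.frame(pathway = character(0), stage = character(0),
                      k_overlap = integer(0), pathway_size = integer(0),
                      query_size = integer(0), universe_size = integer(0),
                      p_value = numeric(0), q_value = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    return(out)
  }
  res <- do.call(rbind, rows)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value <= fdr
  res[order(res$p_value, res$pathway), , drop = FALSE]
}

#' Squared-overlap score between two pathways
#'
#' \eqn{W = k^2 / (p q)} where `k` is the number of shared genes and `p`,
#' `q` are the total gene counts of the two pathways. Symmetric, in
#' \eqn{[0, 1]}, equal to 1 exactly for identical sets and 0 for disjoint
#' sets.
#'
#' @param set_i,set_j nonempty gene sets (character vectors; duplicates
#'   ignored).
#' @return The overlap score.
#' @export
overlap_score <- function(set_i, set_j) {
  set_i <- unique(set_i); set_j <- unique(set_j)
  if (length(set_i) == 0L || length(set_j) == 0L)
    stop("overlap_score requires nonempty sets")
  k <- length(intersect(set_i, set_j))
  k^2 / (length(set_i) * length(set_j))
}

#' Build the stage-evolution pathway network
#'
#' Nodes are the pathways significant in at least one stage, each carrying
#' the set of stages where it is significant (multi-stage pathways stay one
#' node). Edges connect every pathway pair sharing at least one annotated
#' gene, weighted by the squared-overlap score; `min_w` filters edges for
#' display.
#'
#' @param results named list (stage -> [enrich()] data.frame).
#' @param gene_sets the pathway collection (full annotated gene sets; edge
#'   weights use the full sets, not the enriched overlaps).
#' @param min_w minimum overlap score for an edge (default 0: any shared
#'   gene).
#' @return A `pathway_network`: `nodes` data.frame (`pathway`, `stages`
#'   semicolon-joined, `n_genes`), `edges` data.frame (`from`, `to`, `k`,
#'   `w`), and `stage_sets` (named list pathway -> stage vector).
#' @export
build_pathway_network <- function(results, gene_sets, min_w = 0) {
  sig <- lapply(results, function(r) r$pathway[r$significant])
  pathways <- sort(unique(unlist(sig)))
  stage_sets <- lapply(setNames(pathways, pathways), function(p)
    names(sig)[vapply(sig, function(s) p %in% s, logical(1))])
  if (length(pathways) == 0L)
    warning("no significant pathway in any stage: empty network")
  nodes <- data.frame(
    pathway = pathways,
    stages = vapply(stage_sets, paste, character(1), collapse = ";"),
    n_genes = vapply(pathways, function(p)
      length(unique(gene_sets[[p]])), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      k = integer(0), w = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(pathways) > 1L) {
    pairs <- combn(pathways, 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      k <- length(intersect(unique(gene_sets[[a]]), unique(gene_sets[[b]])))
      if (k < 1L) return(NULL)
      w <- overlap_score(gene_sets[[a]], gene_sets[[b]])
      if (w < min_w) return(NULL)
      data.frame(from = a, to = b, k = k, w = w, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) edges <- do.call(rbind, rows)
  }
  structure(list(nodes = nodes, edges = edges, stage_sets = stage_sets),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  multi <- sum(lengths(x$stage_sets) > 1L)
  cat(sprintf("Pathway evolution network: %d pathways (%d multi-stage), %d overlap edges\n",
              nrow(x$nodes), multi, nrow(x$edges)))
  invisible(x)
}

#' Group the pathway network into connected components
#'
#' Components are the operational reading of the visually separable pathway
#' groups: each group collects pathways linked by shared genes, and its
#' stage composition summarizes which disease stages the group spans.
#'
#' @param network a `pathway_network`.
#' @return data.frame with `group` (1-based, ordered by size descending
#'   then lexicographically by first member), `pathway`, `stages`.
#' @export
group_components <- function(network) {
  if (nrow(network$nodes) == 0L)
    return(data.frame(group = integer(0), pathway = character(0),
                      stages = character(0), stringsAsFactors = FALSE))
  g <- as_igraph(network$nodes$pathway,
                 as.matrix(network$edges[, c("from", "to"), drop = FALSE]))
  comp <- igraph::components(g)
  members <- split(igraph::V(g)$name, comp$membership)
  members <- lapply(members, sort)
  ord <- order(-lengths(members),
               vapply(members, `[[`, character(1), 1L))
  members <- members[ord]
  do.call(rbind, lapply(seq_along(members), function(i) {
    data.frame(group = i, pathway = members[[i]],
               stages = network$nodes$stages[
                 match(members[[i]], network$nodes$pathway)],
               stringsAsFactors = FALSE)
  }))
}

#' Export the pathway network as GraphML (plus TSV tables)
#'
#' Node attributes: `stages`, `n_genes`; edge attributes: `k` (shared
#' genes) and `w` (overlap score, the display edge width).
#'
#' @param network a `pathway_network`.
#' @param dir output directory.
#' @export
write_pathway_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(network$nodes, file.path(dir, "pathway_nodes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(network$edges, file.path(dir, "pathway_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  groups <- group_components(network)
  write.table(groups, file.path(dir, "groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  g <- as_igraph(network$nodes$pathway,
                 as.matrix(network$edges[, c("from", "to"), drop = FALSE]))
  if (nrow(network$nodes)) {
    igraph::V(g)$stages <- network$nodes$stages[
      match(igraph::V(g)$name, network$nodes$pathway)]
    igraph::V(g)$n_genes <- network$nodes$n_genes[
      match(igraph::V(g)$name, network$nodes$pathway)]
  }
  if (nrow(network$edges)) {
    igraph::E(g)$k <- network$edges$k
    igraph::E(g)$w <- network$edges$w
  }
  igraph::write_graph(g, file.path(dir, "pathway_network.graphml"),
                      format = "graphml")
  invisible(network)
}
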