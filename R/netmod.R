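as_igraph <- function(nodes, edges) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, rbind(edges[, 1L], edges[, 2L]))
  g
}

#' Expand seed genes with their direct PPI neighbours
#'
#' Builds the subnetwork the giant-component step operates on: the seeds
#' present in the PPI network plus all of their first-hop neighbours, with
#' every background edge between the kept nodes (full induced subgraph).
#' Seeds absent from the network contribute nothing and are reported in a
#' message.
#'
#' @param seeds character vector of seed genes.
#' @param ppi a [ppi_network].
#' @return List with `nodes` (sorted character vector) and `edges`
#'   (canonical two-column matrix).
#' @export
expand_with_neighbors <- function(seeds, ppi) {
  seeds <- unique(seeds)
  present <- intersect(seeds, ppi$nodes)
  absent <- setdiff(seeds, ppi$nodes)
  if (length(absent))
    message(sprintf("expand_with_neighbors: %d seed(s) absent from the PPI network",
                    length(absent)))
  if (length(present) == 0L)
    return(list(nodes = character(0),
                edges = canonical_edges(character(0), character(0))))
  touches <- ppi$edges[, 1L] %in% present | ppi$edges[, 2L] %in% present
  nb <- unique(as.vector(ppi$edges[touches, , drop = FALSE]))
  nodes <- sort(unique(c(present, nb)))
  keep <- ppi$edges[, 1L] %in% nodes & ppi$edges[, 2L] %in% nodes
  list(nodes = nodes, edges = ppi$edges[keep, , drop = FALSE])
}

#' Extract the giant connected component as a stage module
#'
#' Returns the largest connected component of the seed-plus-neighbour
#' subnetwork. Ties on size are broken by (i) the component containing the
#' most seed (detected) genes, then (ii) the lexicographically smallest
#' sorted node list. Node roles record whether a member was a detected seed
#' or a recruited neighbour.
#'
#' @param subnet list with `nodes` and `edges` (see
#'   [expand_with_neighbors()]).
#' @param seeds the stage's detected seed genes.
#' @param stage stage tag stored on the module.
#' @return A `stage_module`: `stage`, `nodes`, `edges`, `role` (named
#'   vector, `"detected"` or `"neighbor"`), `cross_tags` (empty until
#'   [annotate_cross_stage()]).
#' @export
giant_component <- function(subnet, seeds = character(0), stage = NA_character_) {
  if (length(subnet$nodes) == 0L) {
    warning("empty subnetwork: returning an empty module")
    return(structure(list(stage = stage, nodes = character(0),
                          edges = subnet$edges,
                          role = setNames(character(0), character(0)),
                          cross_tags = list()),
                     class = "stage_module"))
  }
  g <- as_igraph(subnet$nodes, subnet$edges)
  comp <- igraph::components(g)
  members <- split(igraph::V(g)$name, comp$membership)
  sizes <- lengths(members)
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    n_seed <- vapply(members[cand], function(ns) sum(ns %in% seeds),
                     integer(1))
    cand <- cand[n_seed == max(n_seed)]
    if (length(cand) > 1L) {
      keys <- vapply(members[cand],
                     function(ns) paste(sort(ns), collapse = "\r"),
                     character(1))
      cand <- cand[order(keys)[1L]]
    }
  }
  nodes <- sort(members[[cand[1L]]])
  keep <- subnet$edges[, 1L] %in% nodes & subnet$edges[, 2L] %in% nodes
  role <- setNames(ifelse(nodes %in% seeds, "detected", "neighbor"), nodes)
  structure(list(stage = stage, nodes = nodes,
                 edges = subnet$edges[keep, , drop = FALSE],
                 role = role,
                 cross_tags = setNames(vector("list", length(nodes)), nodes)),
            class = "stage_module")
}

#' @export
print.stage_module <- function(x, ...) {
  cat(sprintf("Stage module [%s]: %d nodes (%d detected, %d neighbors), %d edges\n",
              x$stage, length(x$nodes), sum(x$role == "detected"),
              sum(x$role == "neighbor"), nrow(x$edges)))
  invisible(x)
}

#' Build the giant-component module for every stage
#'
#' Convenience wrapper: for each stage's selected genes, expand with direct
#' neighbours, induce the subnetwork, keep the giant connected component and
#' annotate cross-stage overlaps.
#'
#' @param selected named list: stage -> selected (seed) gene vector.
#' @param ppi a [ppi_network].
#' @return Named list of `stage_module` objects with cross-stage tags.
#' @export
build_stage_modules <- function(selected, ppi) {
  modules <- lapply(names(selected), function(st) {
    sub <- expand_with_neighbors(selected[[st]], ppi)
    if (length(sub$nodes) == 0L) {
      suppressWarnings(giant_component(sub, selected[[st]], st))
    } else giant_component(sub, selected[[st]], st)
  })
  names(modules) <- names(selected)
  annotate_cross_stage(modules)
}

stage_num <- function(stage) sub("^t", "", stage)

#' Annotate cross-stage overlap tags on stage modules
#'
#' For every stage pair (s < t) and every role combination, genes occurring
#' in both modules are tagged with the pair label: detected-detected
#' `"s-t"`, detected-neighbour `"s-tN"`, neighbour-detected `"sN-t"`,
#' neighbour-neighbour `"sN-tN"` (stage numbers, lower stage first; `N`
#' marks the neighbour role on that side).
#'
#' @param modules named list of `stage_module` objects.
#' @return The modules with `cross_tags` filled in.
#' @export
annotate_cross_stage <- function(modules) {
  sts <- names(modules)
  for (m in seq_along(modules))
    modules[[m]]$cross_tags <- setNames(
      vector("list", length(modules[[m]]$nodes)), modules[[m]]$nodes)
  if (length(sts) < 2L) return(modules)
  combos <- combn(seq_along(sts), 2L)
  for (k in seq_len(ncol(combos))) {
    a <- combos[1L, k]; b <- combos[2L, k]
    for (role_a in c("detected", "neighbor")) {
      for (role_b in c("detected", "neighbor")) {
        ga <- names(modules[[a]]$role)[modules[[a]]$role == role_a]
        gb <- names(modules[[b]]$role)[modules[[b]]$role == role_b]
        shared <- intersect(ga, gb)
        if (length(shared) == 0L) next
        tag <- paste0(stage_num(sts[a]),
                      if (role_a == "neighbor") "N" else "", "-",
                      stage_num(sts[b]),
                      if (role_b == "neighbor") "N" else "")
        for (g in shared) {
          modules[[a]]$cross_tags[[g]] <- c(modules[[a]]$cross_tags[[g]], tag)
          modules[[b]]$cross_tags[[g]] <- c(modules[[b]]$cross_tags[[g]], tag)
        }
      }
    }
  }
  modules
}

#' Export a stage module as GraphML plus node/edge TSV tables
#'
#' GraphML carries `role`, `cross_tags` (semicolon-joined) and `stage` node
#' attributes for Cytoscape import.
#'
#' @param module a `stage_module`.
#' @param dir output directory.
#' @export
write_module <- function(module, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tags <- vapply(module$cross_tags[module$nodes], function(tg)
    paste(sort(unique(tg)), collapse = ";"), character(1))
  nodes_df <- data.frame(gene = module$nodes,
                         role = unname(module$role[module$nodes]),
                         cross_tags = unname(tags),
                         stringsAsFactors = FALSE)
  edges_df <- as.data.frame(module$edges, stringsAsFactors = FALSE)
  base <- sprintf("module_%s", module$stage)
  write.table(nodes_df, file.path(dir, paste0(base, "_nodes.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(edges_df, file.path(dir, paste0(base, "_edges.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  g <- as_igraph(module$nodes, module$edges)
  if (length(module$nodes)) {
    igraph::V(g)$role <- unname(module$role[igraph::V(g)$name])
    igraph::V(g)$cross_tags <- unname(tags[igraph::V(g)$name])
    igraph::V(g)$stage <- module$stage
  }
  igraph::write_graph(g, file.path(dir, paste0(base, ".graphml")),
                      format = "graphml")
  invisible(module)
}
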