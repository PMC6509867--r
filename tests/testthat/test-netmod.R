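edge_mat <- function(...) {
  v <- c(..., character(0))
  m <- matrix(v, ncol = 2L, byrow = TRUE)
  colnames(m) <- c("from", "to")
  m
}

test_that("neighbor expansion induces the full one-hop subnetwork", {
  # star graph: center C with leaves L1..L4, plus a detached edge
  ppi <- ppi_network(edge_mat("C", "L1", "C", "L2", "C", "L3", "C", "L4",
                              "X", "Y"))
  sub <- expand_with_neighbors("C", ppi)
  expect_setequal(sub$nodes, c("C", paste0("L", 1:4)))
  expect_equal(nrow(sub$edges), 4L)

  # edges between two recruited neighbours are kept (full induced subgraph)
  ppi2 <- ppi_network(edge_mat("S", "A", "S", "B", "A", "B"))
  sub2 <- expand_with_neighbors("S", ppi2)
  expect_equal(nrow(sub2$edges), 3L)

  empty <- expand_with_neighbors(character(0), ppi)
  expect_length(empty$nodes, 0L)
  # seeds absent from the network contribute nothing
  expect_message(gone <- expand_with_neighbors("ZZZ", ppi), "absent")
  expect_length(gone$nodes, 0L)
})

test_that("giant component selection matches brute-force enumeration", {
  # explicit 5-node vs 3-node components
  sub <- list(nodes = c(paste0("a", 1:5), paste0("b", 1:3)),
              edges = edge_mat("a1", "a2", "a2", "a3", "a3", "a4",
                               "a4", "a5", "b1", "b2", "b2", "b3"))
  mod <- giant_component(sub, seeds = "b1", stage = "t1")
  expect_setequal(mod$nodes, paste0("a", 1:5))

  # connected graph is returned unchanged
  conn <- list(nodes = c("u", "v", "w"),
               edges = edge_mat("u", "v", "v", "w"))
  expect_setequal(giant_component(conn)$nodes, c("u", "v", "w"))

  # randomized agreement with the BFS oracle
  set.seed(20)
  for (i in 1:25) {
    g <- random_edge_set(sample(5:40, 1L), runif(1, 0.02, 0.1))
    mod <- giant_component(list(nodes = g$nodes, edges = g$edges))
    comps <- brute_components(g$nodes, g$edges)
    expect_equal(length(mod$nodes), max(lengths(comps)))
    # tie-free case: the component itself must match
    if (sum(lengths(comps) == max(lengths(comps))) == 1L)
      expect_setequal(mod$nodes,
                      comps[[which.max(lengths(comps))]])
  }

  expect_warning(empty <- giant_component(list(nodes = character(0),
                                               edges = edge_mat())),
                 "empty")
  expect_length(empty$nodes, 0L)
})

test_that("size ties break by seed count, then lexicographic order", {
  sub <- list(nodes = c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4"),
              edges = edge_mat("a1", "a2", "a2", "a3", "a3", "a4",
                               "b1", "b2", "b2", "b3", "b3", "b4"))
  # component b holds two seeds, component a one
  mod <- giant_component(sub, seeds = c("a1", "b1", "b2"), stage = "t1")
  expect_setequal(mod$nodes, paste0("b", 1:4))
  expect_equal(unname(mod$role[c("b1", "b2", "b3")]),
               c("detected", "detected", "neighbor"))
  # equal seed counts: lexicographically smallest node list wins
  mod2 <- giant_component(sub, seeds = c("a1", "b1"))
  expect_setequal(mod2$nodes, paste0("a", 1:4))
})

test_that("module edges are always a subset of the background PPI", {
  set.seed(21)
  for (i in 1:5) {
    g <- random_edge_set(30, 0.08)
    ppi <- ppi_network(g$edges, nodes = g$nodes)
    seeds <- sample(g$nodes, 4L)
    sub <- suppressMessages(expand_with_neighbors(seeds, ppi))
    if (length(sub$nodes) == 0L) next
    mod <- giant_component(sub, seeds)
    ppi_keys <- paste(ppi$edges[, 1], ppi$edges[, 2])
    mod_keys <- paste(mod$edges[, 1], mod$edges[, 2])
    expect_true(all(mod_keys %in% ppi_keys))
    expect_true(all(as.vector(mod$edges) %in% mod$nodes))
    expect_true(all(names(mod$role[mod$role == "detected"]) %in% seeds))
  }
})

test_that("cross-stage tags follow the pairwise role labeling scheme", {
  mk_module <- function(stage, detected, neighbors) {
    nodes <- sort(c(detected, neighbors))
    structure(list(stage = stage, nodes = nodes,
                   edges = edge_mat()[0, , drop = FALSE],
                   role = setNames(ifelse(nodes %in% detected, "detected",
                                          "neighbor"), nodes),
                   cross_tags = setNames(vector("list", length(nodes)),
                                         nodes)),
              class = "stage_module")
  }
  mods <- annotate_cross_stage(list(
    t3 = mk_module("t3", detected = c("A", "B"), neighbors = c("N1", "N2")),
    t4 = mk_module("t4", detected = c("A", "N1"), neighbors = c("B", "Q"))))
  # detected in both stages -> plain pair tag on both modules
  expect_equal(mods$t3$cross_tags[["A"]], "3-4")
  expect_equal(mods$t4$cross_tags[["A"]], "3-4")
  # detected in 3, neighbor in 4
  expect_equal(mods$t3$cross_tags[["B"]], "3-4N")
  # neighbor in 3, detected in 4
  expect_equal(mods$t3$cross_tags[["N1"]], "3N-4")
  # unique gene carries no tag
  expect_null(mods$t4$cross_tags[["Q"]])

  # brute-force triple loop over (pair, roleA, roleB) on random modules
  set.seed(22)
  for (rep in 1:5) {
    genes <- sprintf("G%02d", 1:20)
    mods_in <- lapply(setNames(paste0("t", 1:3), paste0("t", 1:3)),
                      function(st) {
      nodes <- sample(genes, sample(5:12, 1L))
      det <- sample(nodes, sample(seq_len(length(nodes) - 1L), 1L))
      mk_module(st, det, setdiff(nodes, det))
    })
    out <- annotate_cross_stage(mods_in)
    sts <- names(mods_in)
    expected <- lapply(out, function(m)
      setNames(vector("list", length(m$nodes)), m$nodes))
    for (a in seq_along(sts)) for (b in seq_along(sts)) {
      if (a >= b) next
      for (ra in c("detected", "neighbor")) for (rb in c("detected", "neighbor")) {
        tag <- paste0(sub("t", "", sts[a]), if (ra == "neighbor") "N" else "",
                      "-", sub("t", "", sts[b]), if (rb == "neighbor") "N" else "")
        ga <- names(mods_in[[a]]$role)[mods_in[[a]]$role == ra]
        gb <- names(mods_in[[b]]$role)[mods_in[[b]]$role == rb]
        for (g in intersect(ga, gb)) {
          expected[[a]][[g]] <- c(expected[[a]][[g]], tag)
          expected[[b]][[g]] <- c(expected[[b]][[g]], tag)
        }
      }
    }
    for (st in sts)
      for (g in names(expected[[st]]))
        expect_setequal(out[[st]]$cross_tags[[g]] %||% character(0),
                        expected[[st]][[g]] %||% character(0))
  }
})

test_that("module export writes GraphML plus node/edge tables", {
  ppi <- ppi_network(edge_mat("C", "L1", "C", "L2", "L1", "L2"))
  mod <- giant_component(expand_with_neighbors("C", ppi), "C", stage = "t2")
  dir <- tempfile("mod_")
  write_module(mod, dir)
  nodes <- read.table(file.path(dir, "module_t2_nodes.tsv"), header = TRUE,
                      sep = "\t")
  expect_setequal(nodes$gene, c("C", "L1", "L2"))
  expect_true(file.exists(file.path(dir, "module_t2.graphml")))
  g <- igraph::read_graph(file.path(dir, "module_t2.graphml"),
                          format = "graphml")
  expect_equal(igraph::gorder(g), 3L)
  expect_equal(igraph::gsize(g), 3L)
})
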