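# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths (and igraph) so that agreement is
# informative.

# Objective of the penalized least-squares problem.
obj_enet <- function(X, y, beta, lambda, alpha) {
  sum((y - X %*% beta)^2) / length(y) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) * sum(beta^2))
}

# Accelerated proximal-gradient (FISTA) reference minimizer of the same
# objective; independent of the coordinate-descent solver under test.
ref_enet_fista <- function(X, y, lambda, alpha, iters = 20000L) {
  m <- nrow(X); n <- ncol(X)
  L <- 2 * max(eigen(crossprod(X), symmetric = TRUE,
                     only.values = TRUE)$values) / m +
    2 * lambda * (1 - alpha)
  step <- 1 / L
  b <- numeric(n); z <- b; tk <- 1
  for (it in seq_len(iters)) {
    grad <- -2 * crossprod(X, y - X %*% z) / m + 2 * lambda * (1 - alpha) * z
    u <- z - step * grad
    thr <- step * lambda * alpha
    b_new <- sign(u) * pmax(abs(u) - thr, 0)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- b_new + ((tk - 1) / t_new) * (b_new - b)
    b <- b_new; tk <- t_new
  }
  b
}

# Brute-force connected components by BFS over an adjacency list.
brute_components <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  if (NROW(edges) > 0) for (r in seq_len(nrow(edges))) {
    u <- edges[r, 1]; v <- edges[r, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (s in nodes) {
    if (seen[[s]]) next
    queue <- s; seen[[s]] <- TRUE; comp <- character(0)
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      comp <- c(comp, u)
      for (v in adj[[u]]) if (!seen[[v]]) { seen[[v]] <- TRUE; queue <- c(queue, v) }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Exact upper-tail hypergeometric probability by direct enumeration of the
# probability mass.
hyper_upper_exact <- function(k, K, N, n) {
  i <- seq(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# A random simple undirected graph as a canonical edge matrix.
random_edge_set <- function(n_nodes, p) {
  nodes <- sprintf("v%03d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2L))
  keep <- runif(nrow(pairs)) < p
  list(nodes = nodes, edges = pairs[keep, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small, fast generator configuration for structural tests.
tiny_cfg <- function(seed = 1L, ...) {
  args <- list(n_samples = 40L, n_genes = 60L, n_stages = 2L,
               signal_genes_per_stage = 4L, n_pathways = 10L,
               pathway_size_range = c(6L, 12L), seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(synth_config, args)
}

# Write a samples-x-genes matrix in the on-disk omics layout
# (rows = features) and return the path.
write_omics_fixture <- function(mat, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(feature_id = colnames(mat), t(mat), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
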