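#' @useDynLib stagewise, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats phyper p.adjust rnorm rbinom runif setNames sd
#' @importFrom utils read.table write.table combn
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Open a text connection; transparently handles .gz paths.
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical undirected edge matrix: two character columns, u < v, unique rows.
canonical_edges <- function(from, to) {
  if (length(from) == 0L) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  }
  u <- pmin(from, to)
  v <- pmax(from, to)
  keep <- u != v
  m <- unique(cbind(from = u[keep], to = v[keep]))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}
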