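#' Configuration for the synthetic multi-omics generator
#'
#' Defines the study conditions emulated by the generator: paired
#' expression/methylation matrices with stage-specific planted signal genes,
#' a sparse protein-protein interaction (PPI) graph in which each stage's
#' planted genes form a connected neighbourhood, and a GMT pathway collection
#' in which some pathways are enriched for planted genes and consecutive-stage
#' pathways share members.
#'
#' @param n_samples number of samples (patients).
#' @param n_genes size of the gene universe.
#' @param n_stages number of tumour stages (one-vs-rest contrasts), labelled
#'   `t1..t<n_stages>`.
#' @param signal_genes_per_stage number of planted signal genes per stage.
#' @param effect_size standardized mean shift (in units of `noise_sd`) of a
#'   planted gene in samples of its stage: `+effect_size` in expression,
#'   `-effect_size` in methylation (promoter hypomethylation convention).
#' @param noise_sd standard deviation of the Gaussian background.
#' @param ppi_mean_degree expected degree of the Erdos-Renyi background PPI.
#' @param n_pathways number of pathway gene sets in the GMT collection.
#' @param pathway_size_range integer vector `c(min, max)` of pathway sizes.
#' @param stage_props per-stage sample proportions (default uniform); must
#'   sum to 1.
#' @param signal_pathways_per_stage number of pathways per stage seeded with
#'   at least 50 percent planted genes of that stage.
#' @param shared_chain_genes number of genes shared between the lead signal
#'   pathways of consecutive stages (creates pathway-network edges).
#' @param seed integer RNG seed; all generator outputs are deterministic
#'   functions of the configuration including this seed.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_samples = 200L, n_genes = 500L, n_stages = 4L,
                         signal_genes_per_stage = 10L, effect_size = 2,
                         noise_sd = 1, ppi_mean_degree = 4,
                         n_pathways = 40L, pathway_size_range = c(10L, 20L),
                         stage_props = NULL,
                         signal_pathways_per_stage = 2L,
                         shared_chain_genes = 3L, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes),
              n_stages = as.integer(n_stages),
              signal_genes_per_stage = as.integer(signal_genes_per_stage),
              effect_size = as.numeric(effect_size),
              noise_sd = as.numeric(noise_sd),
              ppi_mean_degree = as.numeric(ppi_mean_degree),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              stage_props = stage_props %||% rep(1 / n_stages, n_stages),
              signal_pathways_per_stage = as.integer(signal_pathways_per_stage),
              shared_chain_genes = as.integer(shared_chain_genes),
              seed = as.integer(seed))
  counts <- c("n_samples", "n_genes", "n_stages", "signal_genes_per_stage")
  for (f in counts) {
    if (cfg[[f]] < 1L) stop(sprintf("'%s' must be >= 1", f))
  }
  if (cfg$effect_size < 0) stop("'effect_size' must be >= 0")
  if (cfg$noise_sd <= 0) stop("'noise_sd' must be > 0")
  if (cfg$ppi_mean_degree < 0) stop("'ppi_mean_degree' must be >= 0")
  if (cfg$n_pathways < 0L) stop("'n_pathways' must be >= 0")
  if (length(cfg$pathway_size_range) != 2L ||
      cfg$pathway_size_range[1L] > cfg$pathway_size_range[2L] ||
      cfg$pathway_size_range[2L] > cfg$n_genes)
    stop("'pathway_size_range' must satisfy min <= max <= n_genes")
  if (length(cfg$stage_props) != cfg$n_stages ||
      abs(sum(cfg$stage_props) - 1) > 1e-8 || any(cfg$stage_props <= 0))
    stop("'stage_props' must be positive and sum to 1")
  if (cfg$signal_genes_per_stage * cfg$n_stages > cfg$n_genes)
    stop("gene universe too small")
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d samples, %d genes, %d stages (%d planted genes/stage)\n",
              x$n_samples, x$n_genes, x$n_stages, x$signal_genes_per_stage))
  cat(sprintf("  effect size %.2g, noise sd %.2g, PPI mean degree %.2g\n",
              x$effect_size, x$noise_sd, x$ppi_mean_degree))
  cat(sprintf("  %d pathways (sizes %d-%d), seed %d\n", x$n_pathways,
              x$pathway_size_range[1L], x$pathway_size_range[2L], x$seed))
  invisible(x)
}

stage_names <- function(n) paste0("t", seq_len(n))

# Deterministic per-stage sample counts: floor shares, remainder to the
# largest fractional parts.
stage_counts <- function(cfg) {
  raw <- cfg$stage_props * cfg$n_samples
  cnt <- floor(raw)
  rem <- cfg$n_samples - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  as.integer(cnt)
}

#' Generate paired expression/methylation matrices with planted stage signal
#'
#' Background entries are i.i.d. Normal(0, `noise_sd^2`). For each stage,
#' its planted genes are mean-shifted by `+effect_size * noise_sd` in
#' expression and `-effect_size * noise_sd` in methylation for the samples of
#' that stage, so the two omics layers carry anti-correlated signal for the
#' same genes.
#'
#' @param cfg a [synth_config()].
#' @return A list with `expression` and `methylation` (samples x genes
#'   matrices with dimnames), `clinical` (data.frame with `sample_id`,
#'   `pathology_t_stage`), and `truth` (planted gene sets per stage and the
#'   stage of every sample).
#' @export
gen_omics <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  samples <- sprintf("s%03d", seq_len(cfg$n_samples))
  stages <- stage_names(cfg$n_stages)
  with_seed(cfg$seed, {
    cnt <- stage_counts(cfg)
    stage_of_sample <- sample(rep(stages, cnt))
    names(stage_of_sample) <- samples
    planted_pool <- sample(genes, cfg$signal_genes_per_stage * cfg$n_stages)
    planted <- split(planted_pool,
                     rep(stages, each = cfg$signal_genes_per_stage))
    shift <- cfg$effect_size * cfg$noise_sd
    expr <- matrix(rnorm(cfg$n_samples * cfg$n_genes, 0, cfg$noise_sd),
                   nrow = cfg$n_samples, dimnames = list(samples, genes))
    meth <- matrix(rnorm(cfg$n_samples * cfg$n_genes, 0, cfg$noise_sd),
                   nrow = cfg$n_samples, dimnames = list(samples, genes))
    for (st in stages) {
      rows <- stage_of_sample == st
      expr[rows, planted[[st]]] <- expr[rows, planted[[st]]] + shift
      meth[rows, planted[[st]]] <- meth[rows, planted[[st]]] - shift
    }
    clinical <- data.frame(sample_id = samples,
                           pathology_t_stage = unname(stage_of_sample),
                           stringsAsFactors = FALSE)
    truth <- list(planted_genes = planted,
                  stage_of_sample = stage_of_sample)
    list(expression = expr, methylation = meth, clinical = clinical,
         truth = truth)
  })
}

# Map pair indices 1..n(n-1)/2 (ordered by first then second endpoint) to
# (i, j) with i < j; vectorized.
pair_index_to_edge <- function(t, n) {
  cs <- cumsum(seq(n - 1L, 1L))
  i <- findInterval(t, c(0, cs), left.open = TRUE)
  j <- i + (t - c(0, cs)[i])
  cbind(i, j)
}

#' Generate a synthetic PPI network with planted stage neighbourhoods
#'
#' Background edges follow an Erdos-Renyi model with expected degree
#' `ppi_mean_degree`. On top of it, each stage's planted genes are wired as a
#' star (first planted gene as hub), which makes all planted genes of a stage
#' mutually reachable within two hops -- the structure the giant-component
#' module step is designed to exploit.
#'
#' @param cfg a [synth_config()].
#' @param truth the `truth` element returned by [gen_omics()].
#' @return A [ppi_network] over the full gene universe: simple, undirected,
#'   no self-loops.
#' @export
gen_ppi <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$ppi_mean_degree >= cfg$n_genes)
    stop("'ppi_mean_degree' must be smaller than n_genes")
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  with_seed(cfg$seed + 1L, {
    n <- cfg$n_genes
    from <- character(0); to <- character(0)
    if (n >= 2L && cfg$ppi_mean_degree > 0) {
      n_pairs <- n * (n - 1) / 2
      p <- cfg$ppi_mean_degree / (n - 1)
      n_edges <- rbinom(1L, n_pairs, p)
      if (n_edges > 0L) {
        idx <- sample.int(n_pairs, n_edges)
        ij <- pair_index_to_edge(sort(idx), n)
        from <- genes[ij[, 1L]]
        to <- genes[ij[, 2L]]
      }
    }
    for (st in names(truth$planted_genes)) {
      pg <- truth$planted_genes[[st]]
      if (length(pg) >= 2L) {
        from <- c(from, rep(pg[1L], length(pg) - 1L))
        to <- c(to, pg[-1L])
      }
    }
    ppi_network(canonical_edges(from, to), nodes = genes)
  })
}

#' Generate a synthetic GMT pathway collection with planted enrichment
#'
#' Produces `n_pathways` gene sets with sizes uniform in
#' `pathway_size_range`. For each stage, `signal_pathways_per_stage` sets are
#' seeded so that at least half of their members are that stage's planted
#' genes; the lead signal pathways of consecutive stages share
#' `shared_chain_genes` members, planting a cross-stage chain in the pathway
#' overlap network. Each signal pathway gets a size-matched random decoy;
#' remaining pathways are random gene sets.
#'
#' @param cfg a [synth_config()].
#' @param truth the `truth` element returned by [gen_omics()].
#' @return A named list of character vectors (the gene sets), with attributes
#'   `signal_stage` (named vector pathway -> stage), `decoy_of` (named vector
#'   decoy -> signal pathway) and `chain` (character vector of the
#'   consecutive-stage chain pathways, in stage order).
#' @export
gen_pathways <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"))
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  if (cfg$n_pathways == 0L) {
    out <- structure(list(), signal_stage = character(0),
                     decoy_of = character(0), chain = character(0))
    return(out)
  }
  with_seed(cfg$seed + 2L, {
    stages <- names(truth$planted_genes)
    background <- setdiff(genes, unlist(truth$planted_genes))
    lo <- cfg$pathway_size_range[1L]; hi <- cfg$pathway_size_range[2L]
    rsize <- function() sample(seq(lo, hi), 1L)

    sets <- list(); signal_stage <- character(0); decoy_of <- character(0)
    # chain glue between consecutive stages' lead signal pathways: planted
    # genes drawn from the two flanking stages, so the shared members are
    # disease genes the pipeline can actually see in both stages' modules
    n_glue <- max(0L, cfg$shared_chain_genes)
    glue <- vector("list", max(0L, length(stages) - 1L))
    if (length(stages) > 1L && n_glue > 0L) {
      for (i in seq_len(length(stages) - 1L)) {
        a <- truth$planted_genes[[stages[i]]]
        b <- truth$planted_genes[[stages[i + 1L]]]
        glue[[i]] <- c(sample(a, min(length(a), ceiling(n_glue / 2))),
                       sample(b, min(length(b), floor(n_glue / 2))))
      }
    }
    chain <- character(0)
    for (si in seq_along(stages)) {
      st <- stages[si]
      for (r in seq_len(cfg$signal_pathways_per_stage)) {
        pl <- truth$planted_genes[[st]]
        extra <- character(0)
        if (r == 1L) {  # lead pathway carries the cross-stage glue
          if (si > 1L) extra <- c(extra, glue[[si - 1L]])
          if (si < length(stages)) extra <- c(extra, glue[[si]])
          extra <- unique(extra)
          # keep the glue within the half of the set not reserved for the
          # stage's own planted genes
          extra <- extra[seq_len(min(length(extra), floor(hi / 2)))]
        }
        # lead pathways are drawn large enough to hold glue plus >=50%
        # own-stage planted members
        s_lo <- max(lo, 2L * length(extra))
        s <- if (s_lo >= hi) hi else sample(seq(s_lo, hi), 1L)
        own_pool <- setdiff(pl, extra)
        n_own <- min(length(own_pool),
                     max(ceiling(s / 2) - sum(extra %in% pl), 0L))
        members <- sample(own_pool, n_own)
        n_fill <- s - n_own - length(extra)
        fill <- sample(setdiff(background, extra), max(0L, n_fill))
        id <- sprintf("pw%03d", length(sets) + 1L)
        sets[[id]] <- sort(unique(c(members, extra, fill)))
        signal_stage[id] <- st
        if (r == 1L) chain <- c(chain, id)
        if (length(sets) >= cfg$n_pathways) break
      }
      if (length(sets) >= cfg$n_pathways) break
    }
    # size-matched decoys drawn from background genes only
    for (sig_id in names(signal_stage)) {
      if (length(sets) >= cfg$n_pathways) break
      id <- sprintf("pw%03d", length(sets) + 1L)
      sets[[id]] <- sort(sample(background, length(sets[[sig_id]])))
      decoy_of[id] <- sig_id
    }
    # filler pathways over the whole universe
    while (length(sets) < cfg$n_pathways) {
      id <- sprintf("pw%03d", length(sets) + 1L)
      sets[[id]] <- sort(sample(genes, rsize()))
    }
    structure(sets, signal_stage = signal_stage, decoy_of = decoy_of,
              chain = chain)
  })
}

#' Generate and write a complete synthetic input bundle
#'
#' Runs [gen_omics()], [gen_ppi()] and [gen_pathways()] and writes the five
#' pipeline inputs plus the ground truth to `dir`: `expression.tsv` and
#' `methylation.tsv` (rows = features, columns = samples), `clinical.tsv`
#' (`sample_id`, `pathology_t_stage`), `ppi.tsv` (two tab-separated gene
#' symbols per line), `pathways.gmt`, and `truth.json`.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`omics`, `ppi`,
#'   `pathways`) and the file `paths`.
#' @export
write_synth_inputs <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  omics <- gen_omics(cfg)
  ppi <- gen_ppi(cfg, omics$truth)
  gmt <- gen_pathways(cfg, omics$truth)
  paths <- list(expression = file.path(dir, "expression.tsv"),
                methylation = file.path(dir, "methylation.tsv"),
                clinical = file.path(dir, "clinical.tsv"),
                ppi = file.path(dir, "ppi.tsv"),
                gmt = file.path(dir, "pathways.gmt"),
                truth = file.path(dir, "truth.json"))
  write_omics_tsv(omics$expression, paths$expression)
  write_omics_tsv(omics$methylation, paths$methylation)
  write.table(omics$clinical, paths$clinical, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_ppi_tsv(ppi, paths$ppi)
  write_gmt(gmt, paths$gmt)
  truth_json <- list(
    planted_genes = omics$truth$planted_genes,
    stage_of_sample = as.list(omics$truth$stage_of_sample),
    pathway_membership = unclass(gmt),
    signal_pathways = as.list(attr(gmt, "signal_stage")),
    decoy_of = as.list(attr(gmt, "decoy_of")),
    chain = attr(gmt, "chain"))
  writeLines(jsonlite::toJSON(truth_json, auto_unbox = TRUE, pretty = TRUE),
             paths$truth)
  invisible(list(omics = omics, ppi = ppi, pathways = gmt, paths = paths))
}

# samples x features matrix -> TSV with rows = features, columns = samples
write_omics_tsv <- function(mat, path) {
  df <- data.frame(feature_id = colnames(mat), t(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a PPI network as a two-column TSV edge list
#' @param ppi a [ppi_network].
#' @param path output file.
#' @export
write_ppi_tsv <- function(ppi, path) {
  write.table(ppi$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Write a gene-set collection in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional named descriptions (defaults to "na").
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(id) {
    desc <- descriptions[[id]] %||% "na"
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}
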