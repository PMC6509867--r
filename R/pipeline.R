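#' Configuration for an end-to-end pipeline run
#'
#' Exactly one input mode must be supplied: either the five real-format
#' input paths (`expression`, `methylation`, `clinical`, `ppi`, `gmt`) or a
#' [synth_config()] in `synth`, in which case the synthetic inputs are
#' generated, written under `outdir/inputs` and read back through the same
#' ingestion path as real data.
#'
#' @param expression,methylation,clinical,ppi,gmt input file paths (real
#'   mode).
#' @param synth a [synth_config()] (synthetic mode).
#' @param enet an [enet_config()].
#' @param fdr enrichment significance threshold (BH q-value).
#' @param min_w minimum overlap score for a pathway-network edge.
#' @param outdir output directory.
#' @return A `run_config`.
#' @export
run_config <- function(expression = NULL, methylation = NULL,
                       clinical = NULL, ppi = NULL, gmt = NULL,
                       synth = NULL, enet = enet_config(), fdr = 0.05,
                       min_w = 0, outdir = tempfile("stagewise_run_")) {
  real <- list(expression = expression, methylation = methylation,
               clinical = clinical, ppi = ppi, gmt = gmt)
  have_real <- !vapply(real, is.null, logical(1))
  if (!is.null(synth) && any(have_real))
    stop("supply either the five input paths or 'synth', not both")
  if (is.null(synth)) {
    if (!all(have_real))
      stop(sprintf("missing input path(s): %s",
                   paste(names(real)[!have_real], collapse = ", ")))
  } else stopifnot(inherits(synth, "synth_config"))
  structure(list(inputs = real, synth = synth, enet = enet,
                 fdr = as.numeric(fdr), min_w = as.numeric(min_w),
                 outdir = outdir),
            class = "run_config")
}

label_subset <- function(label, sample_ids) {
  structure(list(stage = label$stage, y = label$y[sample_ids]),
            class = "stage_label")
}

#' Run the full stage-specific gene and pathway-network pipeline
#'
#' Ingests the five inputs, selects stage-specific genes by elastic-net
#' stability selection, builds the giant-component PPI modules, runs
#' hypergeometric enrichment per stage and assembles the overlap-weighted
#' pathway evolution network. All per-stage outputs are written under
#' `cfg$outdir`, together with `manifest.json` recording input hashes, the
#' configuration and the per-stage summary counts. The manifest carries no
#' timestamps, so identical inputs and configuration reproduce it
#' byte-for-byte.
#'
#' @param cfg a [run_config()].
#' @return A `stagewise_run`: `selection` (`stage_select`), `modules`,
#'   `enrichment`, `network`, `groups`, `manifest`, plus the resolved input
#'   `paths`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cfg$synth)) {
    bundle <- write_synth_inputs(cfg$synth, file.path(cfg$outdir, "inputs"))
    paths <- bundle$paths[c("expression", "methylation", "clinical", "ppi",
                            "gmt")]
  } else {
    paths <- cfg$inputs
    missing <- names(paths)[!vapply(paths, file.exists, logical(1))]
    if (length(missing))
      stop(sprintf("input file(s) not found: %s [%s]",
                   paste(missing, collapse = ", "),
                   paste(unlist(paths[missing]), collapse = ", ")))
  }

  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  ing <- step("ingest", {
    expr_layer <- read_omics(paths$expression, "expression")
    meth_layer <- read_omics(paths$methylation, "methylation")
    layers <- intersect_layers(expr_layer, meth_layer)
    clinical <- read.table(paths$clinical, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    labels <- binarize_stages(clinical)
    staged <- names(labels[[1L]]$y)
    samples <- Reduce(intersect, list(staged,
                                      rownames(layers$expression$values),
                                      rownames(layers$methylation$values)))
    if (length(samples) == 0L) stop("no sample shared by all inputs")
    fm <- assemble_features(layers$expression, layers$methylation, samples)
    labels <- lapply(labels, label_subset, sample_ids = samples)
    ppi <- read_ppi(paths$ppi)
    gmt <- read_gmt(paths$gmt)
    list(fm = fm, labels = labels, ppi = ppi, gmt = gmt)
  })

  selection <- step("stage selection",
                    select_stage_genes(ing$fm, ing$labels, cfg$enet))
  sel_dir <- file.path(cfg$outdir, "selection")
  write_selection_tsv(selection, sel_dir)

  modules <- step("module detection",
                  build_stage_modules(selected_genes(selection), ing$ppi))
  mod_dir <- file.path(cfg$outdir, "modules")
  for (m in modules) write_module(m, mod_dir)

  measured <- unique(unname(ing$fm$column_gene))
  universe <- intersect(unique(unlist(ing$gmt)), measured)
  enrichment <- step("enrichment", {
    lapply(setNames(names(modules), names(modules)), function(st) {
      genes <- intersect(modules[[st]]$nodes, universe)
      if (length(genes) == 0L)
        return(enrich(universe[1L], ing$gmt, universe, cfg$fdr, st)[0L, ])
      enrich(genes, ing$gmt, universe, cfg$fdr, st)
    })
  })
  enr_dir <- file.path(cfg$outdir, "enrichment")
  dir.create(enr_dir, recursive = TRUE, showWarnings = FALSE)
  for (st in names(enrichment))
    write.table(enrichment[[st]],
                file.path(enr_dir, sprintf("enrichment_%s.tsv", st)),
                sep = "\t", quote = FALSE, row.names = FALSE)

  network <- step("pathway network", suppressWarnings(
    build_pathway_network(enrichment, ing$gmt, cfg$min_w)))
  net_dir <- file.path(cfg$outdir, "pathway_network")
  write_pathway_network(network, net_dir)
  groups <- group_components(network)

  summary_df <- selection$summary
  summary_df$giant_component_nodes <- vapply(
    summary_df$stage, function(st) length(modules[[st]]$nodes), integer(1))
  summary_df$giant_component_edges <- vapply(
    summary_df$stage, function(st) nrow(modules[[st]]$edges), integer(1))
  summary_df$significant_pathways <- vapply(
    summary_df$stage, function(st) sum(enrichment[[st]]$significant),
    integer(1))

  manifest <- list(
    package_version = as.character(utils::packageVersion("stagewise")),
    inputs = lapply(paths, function(p) list(
      path = basename(p), md5 = unname(tools::md5sum(p)))),
    config = list(
      mode = if (is.null(cfg$synth)) "real" else "synthetic",
      synth = if (is.null(cfg$synth)) NULL else unclass(cfg$synth),
      enet = unclass(cfg$enet), fdr = cfg$fdr, min_w = cfg$min_w),
    n_samples = nrow(ing$fm$X),
    n_features = ncol(ing$fm$X),
    n_genes = length(measured),
    stage_summary = summary_df,
    pathway_network = list(nodes = nrow(network$nodes),
                           edges = nrow(network$edges),
                           groups = length(unique(groups$group))))
  manifest_json <- jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                    pretty = TRUE, digits = NA,
                                    dataframe = "columns")
  writeLines(manifest_json, file.path(cfg$outdir, "manifest.json"))

  structure(list(config = cfg, paths = paths, features = ing$fm,
                 labels = ing$labels, ppi = ing$ppi, gene_sets = ing$gmt,
                 selection = selection, modules = modules,
                 enrichment = enrichment, network = network,
                 groups = groups, manifest = manifest),
            class = "stagewise_run")
}

#' @export
print.stagewise_run <- function(x, ...) {
  cat("stagewise pipeline run\n")
  cat(sprintf("  mode: %s; outputs: %s\n", x$manifest$config$mode,
              x$config$outdir))
  print(x$manifest$stage_summary, row.names = FALSE)
  cat(sprintf("  pathway network: %d nodes, %d edges, %d groups\n",
              x$manifest$pathway_network$nodes,
              x$manifest$pathway_network$edges,
              x$manifest$pathway_network$groups))
  invisible(x)
}
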