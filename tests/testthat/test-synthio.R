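test_that("generator output is deterministic and has the configured shape", {
  cfg <- tiny_cfg(seed = 7L)
  a <- gen_omics(cfg)
  b <- gen_omics(cfg)
  expect_identical(a, b)

  expect_equal(dim(a$expression), c(cfg$n_samples, cfg$n_genes))
  expect_identical(dimnames(a$expression), dimnames(a$methylation))
  expect_equal(nrow(a$clinical), cfg$n_samples)
  # every sample carries exactly one stage
  expect_true(all(a$truth$stage_of_sample %in% paste0("t", 1:2)))
  expect_setequal(names(a$truth$stage_of_sample), a$clinical$sample_id)
  # planted sets are disjoint subsets of the universe, one per stage
  planted <- a$truth$planted_genes
  expect_equal(lengths(planted), setNames(rep(4L, 2), c("t1", "t2")))
  expect_equal(anyDuplicated(unlist(planted)), 0L)
  expect_true(all(unlist(planted) %in% colnames(a$expression)))

  expect_error(synth_config(n_genes = 10, n_stages = 4,
                            signal_genes_per_stage = 5,
                            pathway_size_range = c(2, 5)),
               "gene universe too small")
})

test_that("zero effect size leaves planted genes at background level", {
  pvals <- unlist(lapply(1:3, function(s) {
    cfg <- synth_config(n_samples = 200L, n_genes = 100L, n_stages = 4L,
                        signal_genes_per_stage = 5L, effect_size = 0,
                        pathway_size_range = c(5L, 10L), seed = s)
    om <- gen_omics(cfg)
    unlist(lapply(names(om$truth$planted_genes), function(st) {
      rows <- om$truth$stage_of_sample == st
      vapply(om$truth$planted_genes[[st]], function(g)
        t.test(om$expression[rows, g], om$expression[!rows, g])$p.value,
        numeric(1))
    }))
  }))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("planted genes separate at effect size 2 (direct t-statistic oracle)", {
  cfg <- synth_config(n_samples = 200L, n_genes = 300L,
                      signal_genes_per_stage = 10L, effect_size = 2,
                      noise_sd = 1, seed = 3L)
  om <- gen_omics(cfg)
  tstat <- function(mat, g, rows)
    unname(t.test(mat[rows, g], mat[!rows, g])$statistic)
  t_expr <- t_meth <- numeric(0)
  for (st in names(om$truth$planted_genes)) {
    rows <- om$truth$stage_of_sample == st
    for (g in om$truth$planted_genes[[st]]) {
      t_expr <- c(t_expr, tstat(om$expression, g, rows))
      t_meth <- c(t_meth, tstat(om$methylation, g, rows))
    }
  }
  expect_gte(mean(t_expr > qnorm(0.999)), 0.9)
  # methylation signal is anti-correlated with the expression signal
  expect_gte(mean(t_meth < -qnorm(0.999)), 0.9)
})

test_that("increasing effect size never decreases the mean planted t-statistic", {
  mean_t <- vapply(c(0, 0.5, 1, 2, 4), function(es) {
    cfg <- synth_config(n_samples = 120L, n_genes = 80L,
                        signal_genes_per_stage = 5L, effect_size = es,
                        pathway_size_range = c(5L, 10L), seed = 42L)
    om <- gen_omics(cfg)
    mean(unlist(lapply(names(om$truth$planted_genes), function(st) {
      rows <- om$truth$stage_of_sample == st
      vapply(om$truth$planted_genes[[st]], function(g)
        unname(t.test(om$expression[rows, g],
                      om$expression[!rows, g])$statistic), numeric(1))
    })))
  }, numeric(1))
  expect_true(all(diff(mean_t) >= 0))
})

test_that("synthetic PPI is simple and planted genes are 2-hop connected", {
  for (s in 1:4) {
    cfg <- tiny_cfg(seed = s, ppi_mean_degree = 3)
    om <- gen_omics(cfg)
    ppi <- gen_ppi(cfg, om$truth)
    # simplicity by direct scan of the edge list
    expect_true(all(ppi$edges[, 1L] != ppi$edges[, 2L]))
    keys <- paste(pmin(ppi$edges[, 1], ppi$edges[, 2]),
                  pmax(ppi$edges[, 1], ppi$edges[, 2]))
    expect_equal(anyDuplicated(keys), 0L)
    # planted genes plus their direct neighbours form one component (BFS)
    for (st in names(om$truth$planted_genes)) {
      pg <- om$truth$planted_genes[[st]]
      touch <- ppi$edges[, 1] %in% pg | ppi$edges[, 2] %in% pg
      nodes <- unique(c(pg, as.vector(ppi$edges[touch, , drop = FALSE])))
      sub <- ppi$edges[ppi$edges[, 1] %in% nodes & ppi$edges[, 2] %in% nodes, ,
                       drop = FALSE]
      comps <- brute_components(nodes, sub)
      holds <- vapply(comps, function(cp) all(pg %in% cp), logical(1))
      expect_true(any(holds))
    }
  }
})

test_that("degenerate PPI settings give an empty edge list or an error", {
  cfg <- tiny_cfg(n_stages = 1L, signal_genes_per_stage = 1L,
                  ppi_mean_degree = 0)
  om <- gen_omics(cfg)
  ppi <- gen_ppi(cfg, om$truth)
  expect_equal(nrow(ppi$edges), 0L)
  cfg2 <- tiny_cfg(ppi_mean_degree = 60)
  om2 <- gen_omics(cfg2)
  expect_error(gen_ppi(cfg2, om2$truth), "ppi_mean_degree")
})

test_that("pathway collection plants enrichment signal and cross-stage glue", {
  cfg <- synth_config(seed = 5L)
  om <- gen_omics(cfg)
  gmt <- gen_pathways(cfg, om$truth)
  expect_length(gmt, cfg$n_pathways)
  sizes <- lengths(gmt)
  expect_true(all(sizes >= cfg$pathway_size_range[1L] &
                  sizes <= cfg$pathway_size_range[2L]))
  signal <- attr(gmt, "signal_stage")
  expect_length(signal, cfg$n_stages * cfg$signal_pathways_per_stage)
  for (id in names(signal)) {
    pl <- om$truth$planted_genes[[signal[[id]]]]
    expect_gte(length(intersect(gmt[[id]], pl)) / length(gmt[[id]]), 0.5)
  }
  # consecutive lead pathways share the configured glue genes
  chain <- attr(gmt, "chain")
  expect_length(chain, cfg$n_stages)
  for (i in seq_len(length(chain) - 1L)) {
    shared <- intersect(gmt[[chain[i]]], gmt[[chain[i + 1L]]])
    expect_gte(length(shared), cfg$shared_chain_genes)
  }
  # each signal pathway has a size-matched decoy
  decoy_of <- attr(gmt, "decoy_of")
  expect_length(decoy_of, length(signal))
  for (d in names(decoy_of))
    expect_equal(length(gmt[[d]]), length(gmt[[decoy_of[[d]]]]))

  expect_length(gen_pathways(tiny_cfg(n_pathways = 0L), om$truth), 0L)
})

test_that("planted pathway construction yields the expected downstream quantities", {
  # a signal pathway beats a size-matched random set on the exact
  # hypergeometric tail for a planted-gene query
  cfg <- synth_config(seed = 9L)
  om <- gen_omics(cfg)
  gmt <- gen_pathways(cfg, om$truth)
  signal <- attr(gmt, "signal_stage")
  decoy_of <- attr(gmt, "decoy_of")
  universe <- sprintf("g%04d", seq_len(cfg$n_genes))
  N <- length(universe)
  for (d in names(decoy_of)) {
    sig <- decoy_of[[d]]
    query <- om$truth$planted_genes[[signal[[sig]]]]
    p_sig <- hyper_upper_exact(length(intersect(gmt[[sig]], query)),
                               length(gmt[[sig]]), N, length(query))
    p_dec <- hyper_upper_exact(length(intersect(gmt[[d]], query)),
                               length(gmt[[d]]), N, length(query))
    expect_lt(p_sig, p_dec)
  }
  # two consecutive-stage sets sharing 3 of their 6 members score 9/36
  expect_equal(overlap_score(c("a", "b", "c", "d", "e", "f"),
                             c("a", "b", "c", "x", "y", "z")), 0.25)
})

test_that("a written input bundle round-trips through the readers", {
  cfg <- tiny_cfg(seed = 2L, ppi_mean_degree = 3)
  dir <- tempfile("bundle_")
  bundle <- write_synth_inputs(cfg, dir)
  expect_true(all(file.exists(unlist(bundle$paths))))
  expr <- suppressMessages(read_omics(bundle$paths$expression, "expression"))
  expect_equal(expr$values, bundle$omics$expression, tolerance = 1e-12)
  ppi <- suppressMessages(read_ppi(bundle$paths$ppi))
  expect_identical(ppi$edges, bundle$ppi$edges)
  gmt <- read_gmt(bundle$paths$gmt)
  # [ indexing drops the generator/reader bookkeeping attributes
  expect_identical(gmt[seq_along(gmt)],
                   bundle$pathways[seq_along(bundle$pathways)])
  truth <- jsonlite::read_json(bundle$paths$truth, simplifyVector = TRUE)
  expect_setequal(unname(unlist(truth$planted_genes)),
                  unname(unlist(bundle$omics$truth$planted_genes)))
})
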