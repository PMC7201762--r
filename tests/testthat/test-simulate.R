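test_that("generation is deterministic under a fixed seed", {
  cfg <- tiny_config()
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$expression, b$expression)
  expect_identical(a$ppi_edges, b$ppi_edges)
  expect_identical(a$truth_dcs_pairs, b$truth_dcs_pairs)
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(n_signature = 50, n_probes = 20))
  expect_error(simulation_config(n_dcs_pairs = 30, n_signature = 20))
  expect_error(simulation_config(delta_beta = 1.2), "delta_beta")
  expect_error(simulation_config(r_low = 0.7, r_high = 0.6), "r_low")
  expect_error(simulate_methylation(tiny_config(delta_beta = 0.97)),
               "outside")
})

test_that("betas are bounded and truth sets live in the generated universes", {
  st <- generate_study(tiny_config())
  expect_true(all(st$methylation >= 0 & st$methylation <= 1))
  expect_true(all(st$truth_signature_probes %in% rownames(st$methylation)))
  expect_true(all(st$truth_dcs_pairs$probe_id %in% st$truth_signature_probes))
  expect_true(all(st$truth_dcs_pairs$gene_id %in% rownames(st$expression)))
  prots <- unique(c(st$ppi_edges$protein1, st$ppi_edges$protein2))
  expect_true(all(st$truth_ppi_intermediates %in% prots))
  expect_true(all(st$ppi_edges$combined_score > 0 &
                    st$ppi_edges$combined_score <= 1000))
})

test_that("planted group shift is recovered at the configured effect size", {
  cfg <- simulation_config(n_current = 70, n_never = 30, n_probes = 2000,
                           n_signature = 50, delta_beta = 0.25, rng_seed = 9)
  sim <- simulate_methylation(cfg)
  cur <- sim$groups == "current"
  med_gap <- apply(sim$beta[sim$truth_signature_probes, ], 1, function(b)
    abs(median(b[cur]) - median(b[!cur])))
  expect_lt(abs(mean(med_gap) - 0.25), 0.05)
})

test_that("planted expression coupling hits its target correlations", {
  cfg <- simulation_config(n_current = 100, n_never = 100, n_probes = 500,
                           n_genes = 300, n_signature = 40, n_dcs_pairs = 20,
                           r_high = 0.9, r_low = 0, rng_seed = 5)
  meth <- simulate_methylation(cfg)
  ex <- simulate_expression(cfg, meth)
  r_c <- r_u <- numeric(nrow(ex$truth_dcs_pairs))
  for (i in seq_len(nrow(ex$truth_dcs_pairs))) {
    p <- ex$truth_dcs_pairs$probe_id[i]; g <- ex$truth_dcs_pairs$gene_id[i]
    coupled <- meth$groups == ex$truth_dcs_pairs$coupled_group[i]
    r_c[i] <- abs(spearman_rho(meth$beta[p, coupled], ex$expr[g, coupled]))
    r_u[i] <- abs(spearman_rho(meth$beta[p, !coupled], ex$expr[g, !coupled]))
  }
  expect_gte(mean(r_c >= 0.75 & r_c <= 0.98), 0.9)
  expect_gte(mean(r_u < 0.3), 0.9)
})

test_that("coupling refuses more pairs than planted probes", {
  cfg <- tiny_config()
  meth <- simulate_methylation(cfg)
  cfg2 <- tiny_config()
  cfg2$n_dcs_pairs <- cfg2$n_signature + 5L  # bypass constructor on purpose
  expect_error(simulate_expression(cfg2, meth), "n_dcs_pairs")
})

test_that("a null study yields (near-)empty downstream discoveries", {
  cfg <- simulation_config(n_current = 100, n_never = 100, n_probes = 400,
                           n_genes = 120, n_signature = 10, delta_beta = 0,
                           n_dcs_pairs = 0, rng_seed = 77)
  st <- generate_study(cfg)
  pr <- prescreen_probes(st$methylation, st$metadata)
  expect_lte(sum(pr$selected), 0.01 * nrow(pr))
  ct <- suppressWarnings(correlate_probes_genes(
    st$methylation[1:20, ], st$expression, st$metadata, method = "spearman"))
  expect_lte(nrow(dcs_select(ct)$pairs), 1)
})

test_that("written study files round-trip through the readers", {
  dir <- withr::local_tempdir()
  st <- generate_study(tiny_config())
  write_study(st, dir)
  expect_equal(read_methylation(file.path(dir, "methylation.tsv")),
               st$methylation)
  expect_equal(read_expression(file.path(dir, "expression.tsv")),
               st$expression, tolerance = 1e-12)
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(man$probe_id, st$annotation$probe_id)
  expect_equal(man$feature_type, st$annotation$feature_type)
  expect_equal(man$gene_symbols, st$annotation$gene_symbols)
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$smoking_status, st$metadata$smoking_status)
  g <- load_string_edges(file.path(dir, "ppi_edges.tsv"), score_floor = 0)
  expect_equal(nrow(g$edges), nrow(st$ppi_edges))
  canon <- function(e) paste(pmin(e$protein1, e$protein2),
                             pmax(e$protein1, e$protein2), e$combined_score)
  expect_setequal(canon(g$edges), canon(st$ppi_edges))
})
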