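#' Simulation configuration for a synthetic tobacco-exposure methylation study
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults mirror the structure of the lung-adenocarcinoma discovery cohort
#' the pipeline is designed for: 102 current smokers versus 43 never smokers,
#' 450K-style bimodal beta-values, a planted signature of differentially
#' methylated probes, a subset of probes whose coupling to gene expression
#' differs between smoking groups, and a weighted protein-interaction graph
#' with planted high-betweenness bridge proteins.
#'
#' @param n_current number of current-smoker samples.
#' @param n_never number of never-smoker samples.
#' @param n_probes total number of CpG probes.
#' @param n_genes total number of genes in the expression matrix.
#' @param n_signature number of probes carrying a planted group shift.
#' @param delta_beta planted group difference in mean beta, in beta units.
#'   `0` gives a pure null study.
#' @param beta_precision concentration parameter of the per-probe Beta law;
#'   larger values give tighter beta distributions.
#' @param n_dcs_pairs number of probe-gene pairs with group-specific coupling.
#' @param r_high target within-group correlation magnitude in the coupled
#'   group of a planted pair.
#' @param r_low target correlation magnitude in the uncoupled group.
#' @param ppi_n_proteins number of proteins in the synthetic PPI graph.
#' @param ppi_edges_per_node preferential-attachment parameter of the
#'   background graph.
#' @param rng_seed integer seed; every generator derives its stream from it.
#' @return An object of class `simulation_config` (a validated list).
#' @examples
#' cfg <- simulation_config(n_probes = 200, n_signature = 10, n_genes = 100)
#' cfg$delta_beta
#' @export
simulation_config <- function(n_current = 102L, n_never = 43L,
                              n_probes = 2000L, n_genes = 1500L,
                              n_signature = 50L, delta_beta = 0.25,
                              beta_precision = 30,
                              n_dcs_pairs = 20L,
                              r_high = 0.9, r_low = 0,
                              ppi_n_proteins = 300L, ppi_edges_per_node = 3L,
                              rng_seed = 1L) {
  cfg <- list(
    n_current = as.integer(n_current), n_never = as.integer(n_never),
    n_probes = as.integer(n_probes), n_genes = as.integer(n_genes),
    n_signature = as.integer(n_signature), delta_beta = delta_beta,
    beta_precision = beta_precision, n_dcs_pairs = as.integer(n_dcs_pairs),
    r_high = r_high, r_low = r_low,
    ppi_n_proteins = as.integer(ppi_n_proteins),
    ppi_edges_per_node = as.integer(ppi_edges_per_node),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$n_current >= 2L, cfg$n_never >= 2L,
    cfg$n_probes >= 1L, cfg$n_genes >= 1L,
    cfg$n_signature >= 0L, cfg$n_signature <= cfg$n_probes,
    cfg$n_dcs_pairs >= 0L, cfg$n_dcs_pairs <= max(cfg$n_signature, 0L),
    cfg$beta_precision > 0, cfg$ppi_n_proteins >= 2L,
    cfg$ppi_edges_per_node >= 1L
  )
  if (cfg$delta_beta < 0 || cfg$delta_beta >= 1)
    stop("`delta_beta` must lie in [0, 1)")
  if (cfg$r_low < 0 || cfg$r_low >= cfg$r_high || cfg$r_high > 1)
    stop("need 0 <= r_low < r_high <= 1")
  if (abs(cfg$rng_seed) > 2^31 - 100)
    stop("`rng_seed` out of integer range")
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  samples: %d current / %d never\n", x$n_current, x$n_never))
  cat(sprintf("  probes:  %d (%d signature, delta_beta = %g)\n",
              x$n_probes, x$n_signature, x$delta_beta))
  cat(sprintf("  genes:   %d (%d coupled pairs, r_high %.2f / r_low %.2f)\n",
              x$n_genes, x$n_dcs_pairs, x$r_high, x$r_low))
  cat(sprintf("  PPI:     %d proteins, m = %d\n",
              x$ppi_n_proteins, x$ppi_edges_per_node))
  invisible(x)
}

probe_ids_for <- function(n) sprintf("cg%08d", seq_len(n))
gene_ids_for  <- function(n) sprintf("g%05d", seq_len(n))
sample_ids_for <- function(cfg) sprintf("smp%04d", seq_len(cfg$n_current + cfg$n_never))

sample_groups_for <- function(cfg) {
  rep(c("current", "never"), c(cfg$n_current, cfg$n_never))
}

# Per-probe baseline means: bimodal mixture mimicking the
# methylated/unmethylated modes of 450K arrays.
draw_probe_means <- function(n) {
  comp <- sample.int(3L, n, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  mu <- numeric(n)
  mu[comp == 1L] <- stats::rbeta(sum(comp == 1L), 1.5, 12)  # unmethylated mode
  mu[comp == 2L] <- stats::rbeta(sum(comp == 2L), 12, 1.5)  # methylated mode
  mu[comp == 3L] <- stats::rbeta(sum(comp == 3L), 2, 2)     # intermediate
  pmin(pmax(mu, 0.03), 0.97)
}

#' Simulate a probe-by-sample methylation beta-value matrix
#'
#' Non-signature probes share one Beta law across both smoking groups, with
#' probe-level means drawn from a bimodal mixture. Each signature probe's mean
#' is shifted by `delta_beta` (direction random per probe, flipped when the
#' shift would leave the open unit interval) in the current-smoker group.
#' Values are Beta(mu*kappa, (1-mu)*kappa) draws with kappa =
#' `beta_precision`, so all betas lie in \[0, 1\] by construction.
#'
#' The planted structure (probe means, which probes carry the signature, and
#' shift directions) is a function of `rng_seed` alone, while the sampling
#' noise is governed by `noise_seed`. Re-generating with the same `rng_seed`
#' but a fresh `noise_seed` therefore yields an independent cohort with the
#' SAME underlying biology — the held-out validation design of a two-cohort
#' study.
#'
#' @param config a [simulation_config()].
#' @param noise_seed optional integer; defaults to a seed derived from
#'   `rng_seed`. Change it (keeping `rng_seed`) to draw a validation cohort.
#' @return A list of class `methylation_sim` with elements `beta` (probe x
#'   sample matrix), `groups` (per-sample smoking status),
#'   `truth_signature_probes` (planted probe ids) and `signature_direction`
#'   (+1/-1 shift sign per planted probe).
#' @export
simulate_methylation <- function(config, noise_seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed + 1L)
  n <- config$n_current + config$n_never
  groups <- sample_groups_for(config)
  probes <- probe_ids_for(config$n_probes)
  mu <- draw_probe_means(config$n_probes)

  sig_idx <- sort(sample.int(config$n_probes, config$n_signature))
  # keep planted probes away from the boundaries so the shift stays valid
  mu[sig_idx] <- stats::runif(config$n_signature, 0.20, 0.80)
  dir <- sample(c(-1, 1), config$n_signature, replace = TRUE)
  shifted <- mu[sig_idx] + dir * config$delta_beta
  flip <- shifted <= 0.02 | shifted >= 0.98
  dir[flip] <- -dir[flip]
  shifted <- mu[sig_idx] + dir * config$delta_beta
  if (any(shifted <= 0.02 | shifted >= 0.98))
    stop("`delta_beta` pushes a planted probe mean outside (0, 1)")

  mu_mat <- matrix(mu, config$n_probes, n)
  mu_mat[sig_idx, groups == "current"] <- shifted
  set.seed(noise_seed %||% (config$rng_seed + 10L))
  kappa <- config$beta_precision
  beta <- matrix(
    stats::rbeta(length(mu_mat), mu_mat * kappa, (1 - mu_mat) * kappa),
    nrow = config$n_probes,
    dimnames = list(probes, sample_ids_for(config))
  )
  beta <- pmin(pmax(beta, 0), 1)

  structure(
    list(beta = beta, groups = groups,
         truth_signature_probes = probes[sig_idx],
         signature_direction = stats::setNames(dir, probes[sig_idx]),
         config = config),
    class = "methylation_sim"
  )
}

#' Simulate gene expression with group-specific methylation coupling
#'
#' Background genes are independent Gaussians on the log2 scale. For each of
#' `n_dcs_pairs` planted pairs, a gene's expression is a linear function of a
#' signature probe's beta plus noise in ONE smoking group (so that the
#' within-group correlation magnitude targets `r_high`) and carries only
#' `r_low`-level dependence in the other group. This is the ground truth the
#' differential-correlation stage is expected to recover.
#'
#' @param config a [simulation_config()].
#' @param meth a `methylation_sim` from [simulate_methylation()].
#' @return A list of class `expression_sim` with elements `expr` (gene x
#'   sample log2-scale matrix) and `truth_dcs_pairs` (data frame with
#'   `probe_id`, `gene_id`, `coupled_group`).
#' @export
simulate_expression <- function(config, meth) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(meth, "methylation_sim"))
  if (config$n_dcs_pairs > length(meth$truth_signature_probes))
    stop("`n_dcs_pairs` exceeds the number of planted signature probes")
  set.seed(config$rng_seed + 2L)
  genes <- gene_ids_for(config$n_genes)
  n <- ncol(meth$beta)
  base_mean <- stats::runif(config$n_genes, 3, 11)
  base_sd <- stats::runif(config$n_genes, 0.5, 1.5)
  expr <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n,
                 dimnames = list(genes, colnames(meth$beta)))

  pairs <- NULL
  if (config$n_dcs_pairs > 0L) {
    probe_sel <- sample(meth$truth_signature_probes, config$n_dcs_pairs)
    gene_sel <- sample(genes, config$n_dcs_pairs)
    grp_sel <- sample(c("current", "never"), config$n_dcs_pairs, replace = TRUE)
    for (i in seq_len(config$n_dcs_pairs)) {
      b <- meth$beta[probe_sel[i], ]
      for (g in c("current", "never")) {
        idx <- meth$groups == g
        r <- if (g == grp_sel[i]) config$r_high else config$r_low
        if (r <= 0) next
        z <- as.numeric(scale(b[idx]))
        expr[gene_sel[i], idx] <- r * z + sqrt(1 - r^2) * stats::rnorm(sum(idx))
      }
    }
    pairs <- data.frame(probe_id = probe_sel, gene_id = gene_sel,
                        coupled_group = grp_sel, stringsAsFactors = FALSE)
  }
  expr <- expr * base_sd + base_mean
  structure(list(expr = expr, truth_dcs_pairs = pairs, config = config),
            class = "expression_sim")
}

#' Simulate a weighted protein-interaction graph with planted bridges
#'
#' A preferential-attachment background graph (combined scores 400-800) is
#' overlaid with a small clique of "bridge" proteins; every seed protein gets
#' one high-confidence edge (score 990) to a bridge. Because the
#' score-to-distance map is strictly decreasing, nearly every seed-pair
#' shortest path then runs through the bridges, which are returned as the
#' planted high-betweenness intermediates.
#'
#' @param config a [simulation_config()].
#' @param seed_proteins character vector of proteins that downstream path
#'   tracing will use as seeds. They become part of the protein universe.
#' @param n_bridges number of planted bridge proteins.
#' @return A list of class `ppi_sim` with `edges` (protein1, protein2,
#'   combined_score) and `truth_ppi_intermediates`.
#' @export
simulate_ppi <- function(config, seed_proteins, n_bridges = 3L) {
  stopifnot(inherits(config, "simulation_config"),
            is.character(seed_proteins), !anyDuplicated(seed_proteins))
  set.seed(config$rng_seed + 3L)
  n_bridges <- as.integer(n_bridges)
  n_bg <- config$ppi_n_proteins - length(seed_proteins) - n_bridges
  if (n_bg < 1L)
    stop("`ppi_n_proteins` too small for the requested seeds and bridges")
  bridges <- sprintf("br%03d", seq_len(n_bridges))
  background <- sprintf("pr%04d", seq_len(n_bg))
  universe <- c(seed_proteins, background, bridges)

  g <- igraph::sample_pa(length(universe), m = config$ppi_edges_per_node,
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  # scatter node labels so seeds are not all early attachment targets
  lab <- sample(universe)
  edges <- data.frame(
    protein1 = lab[el[, 1]], protein2 = lab[el[, 2]],
    combined_score = sample(400:800, nrow(el), replace = TRUE),
    stringsAsFactors = FALSE
  )
  link <- data.frame(
    protein1 = seed_proteins,
    protein2 = bridges[(seq_along(seed_proteins) - 1L) %% n_bridges + 1L],
    combined_score = 990L, stringsAsFactors = FALSE
  )
  bclique <- NULL
  if (n_bridges > 1L) {
    cmb <- utils::combn(bridges, 2L)
    bclique <- data.frame(protein1 = cmb[1, ], protein2 = cmb[2, ],
                          combined_score = 990L, stringsAsFactors = FALSE)
  }
  edges <- rbind(edges, link, bclique)
  edges <- edges[edges$protein1 != edges$protein2, ]
  key <- paste(pmin(edges$protein1, edges$protein2),
               pmax(edges$protein1, edges$protein2))
  edges <- edges[order(key, -edges$combined_score), ]
  edges <- edges[!duplicated(paste(pmin(edges$protein1, edges$protein2),
                                   pmax(edges$protein1, edges$protein2))), ]
  rownames(edges) <- NULL
  structure(list(edges = edges, truth_ppi_intermediates = bridges,
                 proteins = universe, config = config),
            class = "ppi_sim")
}

#' Generate a complete synthetic study
#'
#' Orchestrates [simulate_methylation()], [simulate_expression()] and
#' [simulate_ppi()], and adds a probe annotation manifest (feature types drawn
#' with the open-sea/island/shore/shelf proportions observed for the published
#' 105-probe signature: 0.457 / 0.257 / 0.191 / 0.095) plus sample metadata
#' carrying the clinical fields the preprocessing filters check. A small
#' fraction of non-signature probes and background genes is placed on chrX/chrY
#' to exercise the sex-chromosome filter. PPI seeds are the planted
#' differential-correlation genes.
#'
#' @param config a [simulation_config()].
#' @param noise_seed optional integer passed to [simulate_methylation()]:
#'   keeping `config` fixed and varying `noise_seed` draws an independent
#'   validation cohort with the same planted structure.
#' @return An object of class `synthetic_study`: methylation, expression,
#'   annotation, metadata, gene_chromosome map, ppi edges, and the three truth
#'   sets (`truth_signature_probes`, `truth_dcs_pairs`,
#'   `truth_ppi_intermediates`).
#' @examples
#' study <- generate_study(simulation_config(
#'   n_current = 20, n_never = 10, n_probes = 100, n_genes = 50,
#'   n_signature = 5, n_dcs_pairs = 2, ppi_n_proteins = 40))
#' dim(study$methylation)
#' @export
generate_study <- function(config, noise_seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  meth <- simulate_methylation(config, noise_seed = noise_seed)
  expr <- simulate_expression(config, meth)

  set.seed(config$rng_seed + 4L)
  probes <- rownames(meth$beta)
  genes <- rownames(expr$expr)
  planted_probes <- meth$truth_signature_probes
  planted_genes <- if (is.null(expr$truth_dcs_pairs)) character(0) else
    unique(expr$truth_dcs_pairs$gene_id)

  chrom <- sample(paste0("chr", 1:22), config$n_probes, replace = TRUE)
  # a pinch of sex-chromosome probes among the unplanted ones
  free <- setdiff(seq_along(probes), match(planted_probes, probes))
  n_xy <- min(length(free), max(0L, round(0.02 * config$n_probes)))
  if (n_xy > 0)
    chrom[sample(free, n_xy)] <- sample(c("chrX", "chrY"), n_xy, replace = TRUE)

  feats <- c("OpenSea", "Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf")
  fprob <- c(0.457, 0.257, 0.0955, 0.0955, 0.0475, 0.0475)
  feature_type <- sample(feats, config$n_probes, replace = TRUE, prob = fprob)

  n_sym <- sample(0:2, config$n_probes, replace = TRUE, prob = c(0.19, 0.65, 0.16))
  gene_symbols <- vapply(n_sym, function(k)
    paste(sample(genes, k), collapse = ";"), character(1))
  # planted pairs must be discoverable through the manifest's first gene
  if (!is.null(expr$truth_dcs_pairs)) {
    m <- match(expr$truth_dcs_pairs$probe_id, probes)
    gene_symbols[m] <- expr$truth_dcs_pairs$gene_id
  }
  annotation <- data.frame(probe_id = probes, chromosome = chrom,
                           gene_symbols = gene_symbols,
                           feature_type = feature_type,
                           stringsAsFactors = FALSE)

  gene_chr <- sample(paste0("chr", 1:22), config$n_genes, replace = TRUE)
  free_g <- setdiff(seq_along(genes), match(planted_genes, genes))
  n_xy_g <- min(length(free_g), max(0L, round(0.02 * config$n_genes)))
  if (n_xy_g > 0)
    gene_chr[sample(free_g, n_xy_g)] <-
      sample(c("chrX", "chrY"), n_xy_g, replace = TRUE)
  gene_chromosome <- stats::setNames(gene_chr, genes)

  n <- ncol(meth$beta)
  metadata <- data.frame(
    sample_id = colnames(meth$beta),
    smoking_status = meth$groups,
    age = sample(40:90, n, replace = TRUE),
    gender = sample(c("female", "male"), n, replace = TRUE),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.55, 0.2, 0.2, 0.05)),
    vital_status = sample(c("alive", "dead"), n, replace = TRUE),
    survival_days = sample(60:3000, n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  seeds <- if (length(planted_genes) >= 2) planted_genes else
    genes[seq_len(min(10L, length(genes)))]
  ppi <- simulate_ppi(config, seed_proteins = seeds)

  structure(
    list(methylation = meth$beta, expression = expr$expr,
         annotation = annotation, metadata = metadata,
         gene_chromosome = gene_chromosome,
         ppi_edges = ppi$edges, ppi_seeds = seeds,
         truth_signature_probes = planted_probes,
         truth_dcs_pairs = expr$truth_dcs_pairs,
         truth_ppi_intermediates = ppi$truth_ppi_intermediates,
         config = config),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic methylation study\n")
  cat(sprintf("  methylation: %d probes x %d samples\n",
              nrow(x$methylation), ncol(x$methylation)))
  cat(sprintf("  expression:  %d genes x %d samples\n",
              nrow(x$expression), ncol(x$expression)))
  cat(sprintf("  planted: %d signature probes, %d coupled pairs, %d PPI bridges\n",
              length(x$truth_signature_probes),
              if (is.null(x$truth_dcs_pairs)) 0L else nrow(x$truth_dcs_pairs),
              length(x$truth_ppi_intermediates)))
  invisible(x)
}

#' Write a synthetic study to standard flat files
#'
#' Emits `methylation.tsv`, `expression.tsv`, `manifest.tsv`, `metadata.tsv`,
#' `ppi_edges.tsv` and a `truth.json` sidecar into `dir`. Empty gene lists and
#' OpenSea features are written with the em-dash convention used by published
#' probe tables; [read_manifest()] maps them back.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wm(study$methylation, "methylation.tsv")
  wm(study$expression, "expression.tsv")
  man <- study$annotation
  man$gene_symbols[man$gene_symbols == ""] <- "—"
  man$feature_type[man$feature_type == "OpenSea"] <- "—"
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$ppi_edges, file.path(dir, "ppi_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    signature_probes = study$truth_signature_probes,
    dcs_pairs = study$truth_dcs_pairs,
    ppi_intermediates = study$truth_ppi_intermediates,
    ppi_seeds = study$ppi_seeds,
    gene_chromosome = as.list(study$gene_chromosome)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
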