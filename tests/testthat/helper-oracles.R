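# Independent oracles used across the suite. Each is a from-scratch
# implementation kept deliberately separate from the package internals.

# exact two-sided Mann-Whitney p by enumeration of all rank assignments
enum_wilcox_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(length(r), n1), 2,
              function(id) sum(r[id]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# biweight midcorrelation evaluated element by element from its definition
bicor_oracle <- function(x, y) {
  norm_dev <- function(v) {
    med <- median(v)
    mad0 <- median(abs(v - med))
    u <- (v - med) / (9 * mad0)
    a <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    d <- a * (v - med)
    d / sqrt(sum(d^2))
  }
  sum(norm_dev(x) * norm_dev(y))
}

# minimum path cost between two nodes by exhaustive simple-path search
brute_force_min_cost <- function(edges, s, t) {
  nodes <- unique(c(edges$protein1, edges$protein2))
  adj <- lapply(setNames(nodes, nodes), function(u) {
    i <- edges$protein1 == u | edges$protein2 == u
    data.frame(v = ifelse(edges$protein1[i] == u,
                          edges$protein2[i], edges$protein1[i]),
               w = edges$distance[i], stringsAsFactors = FALSE)
  })
  best <- Inf
  walk <- function(u, cost, seen) {
    if (cost >= best) return()
    if (u == t) { best <<- cost; return() }
    a <- adj[[u]]
    for (k in seq_len(nrow(a)))
      if (!(a$v[k] %in% seen)) walk(a$v[k], cost + a$w[k], c(seen, a$v[k]))
  }
  walk(s, 0, s)
  best
}

# small random connected-ish weighted edge table for path property tests
random_edge_table <- function(n_nodes, n_extra = n_nodes) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  spine <- data.frame(protein1 = nodes[-n_nodes], protein2 = nodes[-1])
  extra <- data.frame(protein1 = sample(nodes, n_extra, replace = TRUE),
                      protein2 = sample(nodes, n_extra, replace = TRUE))
  e <- rbind(spine, extra)
  e <- e[e$protein1 != e$protein2, ]
  e$combined_score <- sample(100:1000, nrow(e), replace = TRUE)
  e
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_current = 30L, n_never = 20L, n_probes = 200L, n_genes = 100L,
         n_signature = 10L, n_dcs_pairs = 4L, ppi_n_proteins = 60L,
         rng_seed = 42L),
    list(...))
  do.call(simulation_config, args)
}

table2_manifest <- function() {
  read_manifest(system.file("extdata", "table2_probes.tsv",
                            package = "smokesig"))
}
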