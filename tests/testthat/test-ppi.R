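edge_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(protein1 = m[, 1], protein2 = m[, 2],
             combined_score = as.integer(m[, 3]), stringsAsFactors = FALSE)
}

test_that("score-to-distance transforms are positive and order-preserving", {
  expect_equal(score_to_distance(1000), 1)
  expect_equal(score_to_distance(500), 501)
  expect_error(score_to_distance(0), "\\(0, 1000\\]")
  expect_error(score_to_distance(1500), "\\(0, 1000\\]")
  s <- sample(1:1000)
  for (tr in c("linear", "log")) {
    d <- score_to_distance(s, tr)
    expect_true(all(d > 0))
    expect_true(all(diff(d[order(s)]) < 0))  # strictly decreasing in score
  }
})

test_that("edge loading dedups undirected pairs keeping the max score", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "A\tB\t900", "B\tA\t700", "B\tC\t450"), f)
  g <- load_string_edges(f, score_floor = 400)
  expect_equal(nrow(g$edges), 2)
  ab <- g$edges[g$edges$protein1 == "A", ]
  expect_equal(ab$combined_score, 900L)

  writeLines(c("protein1\tprotein2\tcombined_score", "A\tB\t1200"), f)
  expect_error(load_string_edges(f), "line")
  writeLines("protein1\tprotein2\tcombined_score", f)
  expect_warning(g0 <- load_string_edges(f), "empty")
  expect_equal(length(g0$proteins), 0)
})

test_that("a forced chain topology gives the middle protein betweenness 1", {
  g <- ppi_graph(edge_df("A", "B", 900, "B", "C", 900), score_floor = 0)
  tr <- trace_all_pairs(g, c("A", "C"))
  expect_equal(tr$betweenness, c(B = 1L))
  expect_equal(tr$n_pairs, 1L)
})

test_that("an articulation protein collects the full cross-pair count", {
  for (km in list(c(4, 4), c(3, 5))) {
    a <- sprintf("a%02d", seq_len(km[1]))
    b <- sprintf("b%02d", seq_len(km[2]))
    ca <- utils::combn(a, 2); cb <- utils::combn(b, 2)
    edges <- rbind(
      data.frame(protein1 = ca[1, ], protein2 = ca[2, ], combined_score = 800L),
      data.frame(protein1 = cb[1, ], protein2 = cb[2, ], combined_score = 800L),
      data.frame(protein1 = c(a, b), protein2 = "art", combined_score = 800L))
    g <- ppi_graph(edges, score_floor = 0)
    tr <- trace_all_pairs(g, c(a, b))
    expect_equal(unname(tr$betweenness["art"]), km[1] * km[2])
    expect_equal(sum(tr$betweenness), km[1] * km[2])  # no other intermediates
  }
})

test_that("path costs equal the brute-force minimum on small random graphs", {
  set.seed(61)
  for (rep in 1:40) {
    edges <- random_edge_table(sample(5:12, 1))
    g <- ppi_graph(edges, score_floor = 0)
    seeds <- sample(g$proteins, 2)
    D <- igraph::distances(g$graph, weights = igraph::E(g$graph)$distance)
    bf <- brute_force_min_cost(g$edges, seeds[1], seeds[2])
    expect_equal(D[seeds[1], seeds[2]], bf)
  }
})

test_that("unreachable seed pairs are recorded, not fatal", {
  g <- ppi_graph(edge_df("A", "B", 900, "C", "D", 900), score_floor = 0)
  tr <- trace_all_pairs(g, c("A", "C", "D"))
  expect_equal(tr$n_pairs, 1L)
  expect_equal(nrow(tr$unreachable), 2L)
  expect_warning(trace_all_pairs(g, c("A", "B", "ZZ")), "not in the PPI")
  expect_error(suppressWarnings(trace_all_pairs(g, c("A", "ZZ"))),
               "fewer than 2")
})

test_that("results do not depend on the seed ordering", {
  set.seed(63)
  edges <- random_edge_table(15, 20)
  g <- ppi_graph(edges, score_floor = 0)
  seeds <- sample(g$proteins, 6)
  t1 <- trace_all_pairs(g, seeds)
  t2 <- trace_all_pairs(g, rev(seeds))
  expect_identical(t1$betweenness, t2$betweenness)
})

test_that("tie-broken paths are deterministic and lexicographically minimal", {
  # two equal-cost routes A-B-D and A-C-D: B is chosen over C
  g <- ppi_graph(edge_df("A", "B", 900, "B", "D", 900,
                         "A", "C", 900, "C", "D", 900), score_floor = 0)
  tr <- trace_all_pairs(g, c("A", "D"))
  expect_equal(tr$betweenness, c(B = 1L))
})

test_that("the permutation background flags a star center and is reproducible", {
  n_leaf <- 12
  leaves <- sprintf("L%02d", seq_len(n_leaf))
  g <- ppi_graph(data.frame(protein1 = leaves, protein2 = "hub",
                            combined_score = 900L), score_floor = 0)
  pf <- permutation_background(g, seed_count = 5, n_rounds = 20,
                               betweenness_floor = 1, rng_seed = 71)
  expect_true("hub" %in% pf$removal)
  pf2 <- permutation_background(g, seed_count = 5, n_rounds = 20,
                                betweenness_floor = 1, rng_seed = 71)
  expect_identical(pf$frequency, pf2$frequency)
  expect_error(permutation_background(g, seed_count = 100), "exceeds")

  e <- suppressWarnings(ppi_graph(edge_df("A", "B", 100), score_floor = 900))
  pfe <- permutation_background(e, seed_count = 1, n_rounds = 3)
  expect_equal(pfe$removal, character(0))
})

test_that("related-protein selection honors floor, seeds and removal list", {
  g <- ppi_graph(edge_df("A", "B", 900, "B", "C", 900, "C", "D", 900),
                 score_floor = 0)
  tr <- trace_all_pairs(g, c("A", "D"))
  expect_setequal(names(tr$betweenness), c("B", "C"))
  expect_equal(nrow(select_related(tr, floor = 5)), 0)  # floor above max
  sel <- select_related(tr, floor = 1)
  expect_setequal(sel$protein, c("B", "C"))
  fake_filter <- structure(list(frequency = c(B = 10L, C = 0L),
                                removal = "B", n_rounds = 10,
                                betweenness_floor = 1),
                           class = "perm_filter")
  sel2 <- select_related(tr, fake_filter, floor = 1)
  expect_equal(sel2$protein, "C")
  # gene-symbol mapping travels through
  sel3 <- select_related(tr, floor = 1, id_map = c(B = "GENE_B", C = "GENE_C"))
  expect_equal(sel3$gene[sel3$protein == "B"], "GENE_B")
})
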