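#' Map a STRING combined score to an edge distance
#'
#' Higher-confidence interactions must be shorter. The default linear map
#' `1001 - score` is strictly positive and strictly decreasing on the valid
#' score range (0, 1000]; the alternative `-log(score / 1000)` emphasizes
#' confidence ratios instead (and assigns distance 0 to a perfect score).
#'
#' @param combined_score integer score(s) in (0, 1000].
#' @param transform `"linear"` (default) or `"log"`.
#' @return numeric distance(s).
#' @examples
#' score_to_distance(1000)  # 1
#' score_to_distance(500)   # 501
#' @export
score_to_distance <- function(combined_score, transform = c("linear", "log")) {
  transform <- match.arg(transform)
  if (any(is.na(combined_score)) || any(combined_score <= 0) ||
      any(combined_score > 1000))
    stop("combined scores must lie in (0, 1000]")
  switch(transform,
         linear = 1001 - combined_score,
         # floored so distances stay strictly positive at score 1000
         log = pmax(-log(combined_score / 1000), 1e-9))
}

#' Build a weighted PPI graph from an edge table
#'
#' @param edges data frame with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @param score_floor edges with a lower score are dropped (default 400,
#'   STRING's medium confidence).
#' @param transform distance transform, see [score_to_distance()].
#' @return list of class `ppi_graph`: `edges` (with a `distance` column),
#'   `graph` (an igraph object with `distance` edge attribute), `proteins`.
#' @export
ppi_graph <- function(edges, score_floor = 400, transform = "linear") {
  stopifnot(is.data.frame(edges),
            all(c("protein1", "protein2", "combined_score") %in% names(edges)))
  edges <- edges[edges$protein1 != edges$protein2, , drop = FALSE]
  # undirected dedup keeping the maximum score
  a <- pmin(edges$protein1, edges$protein2)
  b <- pmax(edges$protein1, edges$protein2)
  o <- order(a, b, -edges$combined_score)
  edges <- data.frame(protein1 = a, protein2 = b,
                      combined_score = edges$combined_score,
                      stringsAsFactors = FALSE)[o, , drop = FALSE]
  edges <- edges[!duplicated(edges[, c("protein1", "protein2")]), ,
                 drop = FALSE]
  edges <- edges[edges$combined_score >= score_floor, , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) == 0) {
    warning("no edges at or above the score floor: empty graph")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(edges = edges, graph = g, proteins = character(0),
                          transform = transform),
                     class = "ppi_graph"))
  }
  edges$distance <- score_to_distance(edges$combined_score, transform)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  structure(list(edges = edges, graph = g,
                 proteins = igraph::V(g)$name, transform = transform),
            class = "ppi_graph")
}

#' Load a STRING-style edge list from TSV
#'
#' Validates the rows (reporting line numbers of malformed ones), removes
#' duplicate undirected edges keeping the maximum score, drops edges below
#' the score floor, and attaches distances.
#'
#' @param path TSV with columns `protein1`, `protein2`, `combined_score`.
#' @inheritParams ppi_graph
#' @return a `ppi_graph`.
#' @export
load_string_edges <- function(path, score_floor = 400, transform = "linear") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(df)))
    stop("edge file must have columns: ", paste(need, collapse = ", "))
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(is.na(score) | score != round(score) | score <= 0 |
                 score > 1000 | df$protein1 == "" | df$protein2 == "")
  if (length(bad))
    stop("malformed edge rows at line(s): ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  df$combined_score <- as.integer(score)
  ppi_graph(df, score_floor = score_floor, transform = transform)
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("PPI graph: %d proteins, %d edges (%s distance)\n",
              length(x$proteins), nrow(x$edges), x$transform))
  invisible(x)
}

# neighbor lists with edge distances, for deterministic path reconstruction
adjacency_list <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$distance
  from <- c(el[, 1], el[, 2]); to <- c(el[, 2], el[, 1]); ww <- c(w, w)
  o <- order(from, to)
  from <- from[o]; to <- to[o]; ww <- ww[o]
  nb <- rep(list(matrix(numeric(0), 0, 2)), n)
  idx <- split(seq_along(from), from)
  for (k in names(idx))
    nb[[as.integer(k)]] <- cbind(to[idx[[k]]], ww[idx[[k]]])
  nb
}

#' Trace shortest paths between all seed pairs and count betweenness
#'
#' Runs Dijkstra (via igraph) from every seed and, for each unordered
#' reachable seed pair, reconstructs ONE minimum-distance path — the
#' lexicographically smallest node sequence among ties, so results are
#' deterministic. Every interior node of a returned path has its betweenness
#' incremented by one; a node's betweenness is therefore the number of
#' seed-pair shortest paths across it, bounded by the number of seed pairs.
#' Unreachable pairs are recorded, not errors.
#'
#' @param graph a `ppi_graph`.
#' @param seeds character vector of seed proteins; seeds not present in the
#'   graph are reported with a warning and skipped (at least 2 must map).
#' @return list of class `path_trace`: `betweenness` (named count vector over
#'   proteins with positive betweenness), `seeds` (mapped), `unmapped`,
#'   `unreachable` (two-column data frame), `n_pairs` (reachable pairs).
#' @export
trace_all_pairs <- function(graph, seeds) {
  stopifnot(inherits(graph, "ppi_graph"))
  seeds <- unique(seeds)
  unmapped <- setdiff(seeds, graph$proteins)
  if (length(unmapped))
    warning(length(unmapped), " seed(s) not in the PPI graph: ",
            paste(utils::head(unmapped, 5), collapse = ", "))
  seeds <- sort(intersect(seeds, graph$proteins))
  if (length(seeds) < 2) stop("fewer than 2 seeds map to the graph")

  g <- graph$graph
  nodes <- graph$proteins
  sidx <- match(seeds, nodes)
  D <- igraph::distances(g, v = sidx, weights = igraph::E(g)$distance,
                         algorithm = "dijkstra")
  nb <- adjacency_list(g)
  btw <- integer(length(nodes))
  unreach <- list()
  n_pairs <- 0L
  eps <- 1e-9

  for (i in seq_along(seeds)) {
    for (j in seq_along(seeds)) {
      if (j <= i) next
      s <- sidx[i]; t <- sidx[j]
      dt <- D[j, ]                       # distance from t to every node
      if (!is.finite(dt[s])) {
        unreach[[length(unreach) + 1L]] <- c(seeds[i], seeds[j])
        next
      }
      n_pairs <- n_pairs + 1L
      u <- s
      while (u != t) {
        m <- nb[[u]]
        ok <- abs(dt[m[, 1]] + m[, 2] - dt[u]) <=
          eps * (1 + abs(dt[u]))
        v <- min(m[ok, 1])               # lexicographic tie-break
        if (v != t) btw[v] <- btw[v] + 1L
        u <- v
      }
    }
  }
  pos <- btw > 0
  unreach <- if (length(unreach))
    stats::setNames(as.data.frame(do.call(rbind, unreach),
                                  stringsAsFactors = FALSE),
                    c("seed1", "seed2"))
  else data.frame(seed1 = character(0), seed2 = character(0))
  structure(list(betweenness = stats::setNames(btw[pos], nodes[pos]),
                 seeds = seeds, unmapped = unmapped,
                 unreachable = unreach, n_pairs = n_pairs),
            class = "path_trace")
}

#' @export
print.path_trace <- function(x, ...) {
  cat(sprintf(
    "Shortest-path trace: %d seeds, %d reachable pairs, %d unreachable\n",
    length(x$seeds), x$n_pairs, nrow(x$unreachable)))
  top <- utils::head(sort(x$betweenness, decreasing = TRUE), 5)
  if (length(top))
    cat("  top betweenness:",
        paste(sprintf("%s (%d)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Permutation background for promiscuous shortest-path proteins
#'
#' Ubiquitous hub proteins sit on shortest paths between almost any protein
#' set, so their high betweenness carries no signal. Each round draws
#' `seed_count` proteins uniformly without replacement, traces all their
#' pairs, and records which proteins reach the betweenness floor; proteins
#' doing so in at least `removal_fraction` of rounds form the removal list.
#'
#' @param graph a `ppi_graph`.
#' @param seed_count proteins drawn per round (use the size of the real seed
#'   set).
#' @param n_rounds number of permutation rounds (default 100).
#' @param betweenness_floor betweenness at or above which a protein counts as
#'   hit in a round.
#' @param removal_fraction fraction of rounds (default 0.5) above which a
#'   protein is listed for removal.
#' @param rng_seed optional integer seed.
#' @return list of class `perm_filter`: `frequency` (named hit counts),
#'   `removal` (protein ids), `n_rounds`, `betweenness_floor`.
#' @export
permutation_background <- function(graph, seed_count, n_rounds = 100L,
                                   betweenness_floor = 10,
                                   removal_fraction = 0.5, rng_seed = NULL) {
  stopifnot(inherits(graph, "ppi_graph"), n_rounds >= 1)
  n <- length(graph$proteins)
  if (n == 0) {
    return(structure(list(frequency = integer(0), removal = character(0),
                          n_rounds = n_rounds,
                          betweenness_floor = betweenness_floor),
                     class = "perm_filter"))
  }
  if (seed_count > n) stop("seed_count exceeds the number of proteins")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  freq <- stats::setNames(integer(n), graph$proteins)
  for (r in seq_len(n_rounds)) {
    picks <- sample(graph$proteins, seed_count)
    tr <- tryCatch(suppressWarnings(trace_all_pairs(graph, picks)),
                   error = function(e) NULL)
    if (is.null(tr)) next
    hits <- names(tr$betweenness)[tr$betweenness >= betweenness_floor]
    freq[hits] <- freq[hits] + 1L
  }
  structure(list(frequency = freq,
                 removal = sort(names(freq)[freq >= removal_fraction * n_rounds]),
                 n_rounds = n_rounds, betweenness_floor = betweenness_floor),
            class = "perm_filter")
}

#' @export
print.perm_filter <- function(x, ...) {
  cat(sprintf(
    "Permutation background: %d rounds, floor %g; %d protein(s) to remove\n",
    x$n_rounds, x$betweenness_floor, length(x$removal)))
  if (length(x$removal))
    cat("  removal:", paste(x$removal, collapse = ", "), "\n")
  invisible(x)
}

#' Select related proteins by betweenness, minus the permutation background
#'
#' Proteins whose betweenness reaches `floor` (inclusive), excluding the
#' seeds themselves and any protein on the permutation removal list, ranked
#' by betweenness descending with ties broken by protein id. An id map can
#' translate protein ids back to gene symbols.
#'
#' @param trace a `path_trace`.
#' @param filter optional `perm_filter` computed on the same graph.
#' @param floor minimum betweenness (default 100).
#' @param id_map optional named character vector protein id -> gene symbol.
#' @return data frame `protein`, `gene`, `betweenness`, `background_freq`,
#'   ranked; class `related_proteins`.
#' @export
select_related <- function(trace, filter = NULL, floor = 100, id_map = NULL) {
  stopifnot(inherits(trace, "path_trace"))
  b <- trace$betweenness
  b <- b[!(names(b) %in% trace$seeds)]
  b <- b[b >= floor]
  if (!is.null(filter)) {
    stopifnot(inherits(filter, "perm_filter"))
    b <- b[!(names(b) %in% filter$removal)]
  }
  ord <- order(-b, names(b))
  out <- data.frame(
    protein = names(b)[ord],
    gene = if (is.null(id_map)) names(b)[ord] else
      unname(id_map[names(b)[ord]]),
    betweenness = as.integer(b[ord]),
    background_freq = if (is.null(filter)) rep(NA_integer_, length(ord)) else
      as.integer(filter$frequency[names(b)[ord]]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("related_proteins", "data.frame")
  out
}
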