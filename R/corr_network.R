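#' Biweight midcorrelation
#'
#' Robust correlation built on Tukey biweights around the median:
#' `u_i = (x_i - med(x)) / (9 * MAD(x))` with the unscaled median absolute
#' deviation, weights `a_i = (1 - u_i^2)^2` for `|u_i| < 1` (zero outside),
#' and the correlation is the inner product of the weight-normalized
#' deviations. Far less sensitive to single gross outliers than Pearson's
#' coefficient.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param zero_mad what to do when a MAD is zero: `"pearson"` (default) falls
#'   back to the Pearson correlation with a warning, `"error"` stops.
#' @return correlation in \[-1, 1\].
#' @examples
#' x <- rnorm(50); bicor(x, 2 * x + 1)
#' @export
bicor <- function(x, y, zero_mad = c("pearson", "error")) {
  zero_mad <- match.arg(zero_mad)
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  tx <- bicor_transform(x)
  ty <- bicor_transform(y)
  if (is.null(tx) || is.null(ty)) {
    if (zero_mad == "error") stop("zero MAD: biweight weights undefined")
    warning("zero MAD; falling back to Pearson correlation")
    return(stats::cor(x, y))
  }
  min(1, max(-1, sum(tx * ty)))
}

# weight-normalized deviations; NULL when MAD (or the weighted SS) vanishes
bicor_transform <- function(x) {
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 <= 0) return(NULL)
  u <- (x - med) / (9 * mad0)
  a <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- a * (x - med)
  ss <- sum(xt^2)
  if (ss <= 0) return(NULL)
  xt / sqrt(ss)
}

#' Spearman's rank correlation
#'
#' Pearson correlation of midranks; invariant under strictly monotone
#' transforms of either argument.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rank correlation undefined")
  stats::cor(rank(x), rank(y))
}

# rows of m -> normalized vectors whose cross-products are correlations.
# method "bicor": biweight transform (Pearson fallback on zero MAD);
# method "spearman"/"pearson": standardized (mid)ranks / values.
row_transform <- function(m, method) {
  fallback <- 0L
  out <- t(apply(m, 1, function(v) {
    if (stats::sd(v) == 0) return(rep(NA_real_, length(v)))
    if (method == "bicor") {
      tv <- bicor_transform(v)
      if (!is.null(tv)) return(tv)
      fallback <<- fallback + 1L
    }
    if (method == "spearman") v <- rank(v)
    v <- v - mean(v)
    v / sqrt(sum(v^2))
  }))
  attr(out, "n_fallback") <- fallback
  out
}

#' Within-group probe-gene correlations
#'
#' For every (signature probe, gene) pair computes the correlation between
#' probe methylation and gene expression separately inside the current-smoker
#' and never-smoker groups, with the chosen method. Probes or genes that are
#' constant within a group yield `NA` for that group and a warning.
#'
#' @param methylation signature-probe x sample beta matrix.
#' @param expression gene x sample matrix (shared sample ids).
#' @param metadata data frame with `sample_id` and `smoking_status`.
#' @param method `"bicor"` or `"spearman"`.
#' @return data frame of class `correlation_table` with columns `probe_id`,
#'   `gene_id`, `method`, `r_current`, `r_never`.
#' @export
correlate_probes_genes <- function(methylation, expression, metadata,
                                   method = c("bicor", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(colnames(methylation), colnames(expression))
  if (length(shared) == 0) stop("no shared samples between ME and GE")
  status <- metadata$smoking_status[match(shared, metadata$sample_id)]
  rs <- list()
  for (g in c("current", "never")) {
    ids <- shared[!is.na(status) & status == g]
    if (length(ids) < 4)
      stop("fewer than 4 samples in the ", g, " group")
    tm <- row_transform(methylation[, ids, drop = FALSE], method)
    tg <- row_transform(expression[, ids, drop = FALSE], method)
    nf <- attr(tm, "n_fallback") + attr(tg, "n_fallback")
    if (nf > 0)
      warning(nf, " zero-MAD row(s) in the ", g,
              " group fell back to Pearson")
    if (anyNA(tm) || anyNA(tg))
      warning("constant rows in the ", g, " group: correlations set to NA")
    rs[[g]] <- tcrossprod(tm, tg)  # probes x genes
  }
  out <- data.frame(
    probe_id = rep(rownames(methylation), times = nrow(expression)),
    gene_id = rep(rownames(expression), each = nrow(methylation)),
    method = method,
    r_current = pmin(1, pmax(-1, as.vector(rs$current))),
    r_never = pmin(1, pmax(-1, as.vector(rs$never))),
    stringsAsFactors = FALSE
  )
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Differential correlation selection (two-threshold rule)
#'
#' A probe-gene pair is called differentially correlated when its correlation
#' magnitude is high (>= `ts2`) in one smoking group and low (<= `ts1`) in
#' the other; both thresholds are inclusive. The defaults 0.3 / 0.6 are the
#' optimized operating point of the strategy.
#'
#' @param table a `correlation_table` from [correlate_probes_genes()].
#' @param ts1 low-correlation threshold (default 0.3).
#' @param ts2 high-correlation threshold (default 0.6).
#' @return list of class `dcs_result`: `pairs` (selected rows of `table`),
#'   `genes` (sorted unique genes of the selected pairs), `ts1`, `ts2`.
#' @export
dcs_select <- function(table, ts1 = 0.3, ts2 = 0.6) {
  stopifnot(is.data.frame(table),
            all(c("r_current", "r_never") %in% names(table)))
  if (!(ts1 >= 0 && ts1 < ts2 && ts2 <= 1))
    stop("need 0 <= ts1 < ts2 <= 1")
  rc <- abs(table$r_current); rn <- abs(table$r_never)
  sel <- (rc >= ts2 & rn <= ts1) | (rn >= ts2 & rc <= ts1)
  sel[is.na(sel)] <- FALSE
  pairs <- table[sel, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, genes = sort(unique(pairs$gene_id)),
                 ts1 = ts1, ts2 = ts2),
            class = "dcs_result")
}

#' @export
print.dcs_result <- function(x, ...) {
  cat(sprintf(
    "Differential correlation: %d pairs / %d genes at TS1 = %g, TS2 = %g\n",
    nrow(x$pairs), length(x$genes), x$ts1, x$ts2))
  invisible(x)
}

#' Soft-threshold gene weight network with hub calling
#'
#' Adjacency `a_ij = |cor(GE_i, GE_j)|^beta_soft` between genes (Pearson by
#' default, biweight midcorrelation optionally), zero diagonal; a gene's
#' connectivity is its adjacency row sum and genes above `hub_threshold`
#' (strictly) are flagged as hubs.
#'
#' @param expression gene x sample matrix restricted to the genes of interest
#'   (>= 3 genes). Constant genes are excluded with a warning.
#' @param beta_soft soft-threshold power (default 6).
#' @param hub_threshold connectivity cutoff for hub calling (default 10.75).
#' @param method `"pearson"` or `"bicor"`.
#' @return list of class `gene_network`: `adjacency`, `connectivity`, `hubs`,
#'   `beta_soft`, `hub_threshold`.
#' @export
build_weight_network <- function(expression, beta_soft = 6,
                                 hub_threshold = 10.75,
                                 method = c("pearson", "bicor")) {
  method <- match.arg(method)
  stopifnot(is.matrix(expression))
  const <- apply(expression, 1, stats::sd) == 0
  if (any(const)) {
    warning("excluding ", sum(const), " constant gene(s)")
    expression <- expression[!const, , drop = FALSE]
  }
  if (nrow(expression) < 3) stop("need at least 3 non-constant genes")
  tr <- row_transform(expression, if (method == "bicor") "bicor" else "pearson")
  a <- tcrossprod(tr)
  a[] <- abs(pmin(pmax(a, -1), 1))^beta_soft
  diag(a) <- 0
  k <- rowSums(a)
  structure(list(adjacency = a, connectivity = k,
                 hubs = sort(names(k)[k > hub_threshold]),
                 beta_soft = beta_soft, hub_threshold = hub_threshold),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "Gene weight network: %d genes, soft power %g; %d hub(s) with k > %g\n",
    nrow(x$adjacency), x$beta_soft, length(x$hubs), x$hub_threshold))
  if (length(x$hubs)) cat("  hubs: ", paste(x$hubs, collapse = ", "), "\n")
  invisible(x)
}

#' Intersect the gene sets found by two correlation methods
#'
#' @param bimc_genes,src_genes character vectors of gene ids.
#' @return list of class `related_gene_sets`: `bimc_genes`, `src_genes`,
#'   `common_genes` (sorted intersection).
#' @export
intersect_sets <- function(bimc_genes, src_genes) {
  structure(list(bimc_genes = sort(unique(bimc_genes)),
                 src_genes = sort(unique(src_genes)),
                 common_genes = sort(intersect(bimc_genes, src_genes))),
            class = "related_gene_sets")
}

#' @export
print.related_gene_sets <- function(x, ...) {
  cat(sprintf("Related genes: %d by bicor, %d by Spearman, %d in common\n",
              length(x$bimc_genes), length(x$src_genes),
              length(x$common_genes)))
  invisible(x)
}
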