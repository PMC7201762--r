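VALID_CHROMOSOMES <- c(paste0("chr", 1:22), "chrX", "chrY")
VALID_FEATURES <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
REQUIRED_CLINICAL <- c("age", "gender", "stage", "survival_days", "vital_status")

read_id_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs an id column plus data columns: ", path)
  if (anyDuplicated(df[[1]])) stop("duplicate row ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Read a probe-by-sample methylation matrix from TSV
#'
#' First column is the probe id; remaining columns are samples.
#' @param path path to a tab-separated file.
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
read_methylation <- function(path) {
  m <- read_id_matrix(path)
  rng <- range(m, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    warning("methylation values outside [0, 1] found in ", path)
  m
}

#' Read a gene-by-sample expression matrix from TSV
#' @inheritParams read_methylation
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) read_id_matrix(path)

#' Read a probe annotation manifest
#'
#' Expects columns `probe_id`, `chromosome`, `gene_symbols` (semicolon-joined,
#' ordered most-likely-first) and `feature_type`. Dash cells (`-` or the
#' em-dash used in published probe tables) map to an empty gene list and to
#' `OpenSea` respectively.
#'
#' @param path path to a tab-separated manifest.
#' @return data frame of class `probe_annotation`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("probe_id", "chromosome", "gene_symbols", "feature_type")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  dashes <- c("-", "—", "")
  df$gene_symbols[df$gene_symbols %in% dashes | is.na(df$gene_symbols)] <- ""
  df$gene_symbols <- gsub("[; ]*;[; ]*", ";", trimws(df$gene_symbols))
  df$feature_type[df$feature_type %in% dashes | is.na(df$feature_type)] <- "OpenSea"
  bad <- setdiff(unique(df$feature_type), VALID_FEATURES)
  if (length(bad))
    stop("unknown feature types: ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop("duplicate probe ids in manifest")
  class(df) <- c("probe_annotation", "data.frame")
  df
}

#' Read sample metadata
#'
#' Requires `sample_id` and `smoking_status` (current/never/ever) plus the
#' clinical fields the preprocessing filter checks (age, gender, stage,
#' survival_days, vital_status).
#' @param path path to a tab-separated file.
#' @return data frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "smoking_status", REQUIRED_CLINICAL)
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$smoking_status), c("current", "never", "ever", NA))
  if (length(bad))
    stop("unknown smoking_status values: ", paste(bad, collapse = ", "))
  df
}

#' Apply the standard preprocessing filters
#'
#' Filters, in order: (a) probes and genes whose values are missing in every
#' sample; (b) samples lacking any of age, gender, stage, overall survival or
#' vital status; (c) probes and genes on the X and Y chromosomes. Optionally
#' applies `log2(x + 1)` to the expression matrix for data not already on the
#' log scale. A filter log records the count removed by each rule in order.
#'
#' @param methylation probe x sample beta matrix.
#' @param expression gene x sample matrix.
#' @param annotation a `probe_annotation` (from [read_manifest()] or a
#'   synthetic study); must cover every methylation probe.
#' @param metadata sample metadata data frame.
#' @param gene_chromosome optional named character vector mapping gene ids to
#'   chromosome labels. When `NULL`, a gene is treated as sex-chromosomal only
#'   if every manifest probe listing it sits on chrX/chrY.
#' @param log2_expression apply log2(x+1) to expression (default `FALSE`:
#'   input is assumed already log scale).
#' @return list of class `filtered_study`: filtered `methylation`,
#'   `expression`, `annotation`, `metadata`, and `filter_log` (data frame of
#'   rule, item, n_removed).
#' @export
filter_dataset <- function(methylation, expression, annotation, metadata,
                           gene_chromosome = NULL, log2_expression = FALSE) {
  stopifnot(is.matrix(methylation), is.matrix(expression),
            is.data.frame(annotation), is.data.frame(metadata))
  miss_probe <- setdiff(rownames(methylation), annotation$probe_id)
  if (length(miss_probe))
    stop("probes absent from the manifest: ",
         paste(utils::head(miss_probe, 5), collapse = ", "))
  bad_chr <- setdiff(unique(annotation$chromosome), VALID_CHROMOSOMES)
  if (length(bad_chr))
    stop("unknown chromosome labels in manifest: ",
         paste(bad_chr, collapse = ", "), " (probes ",
         paste(utils::head(
           annotation$probe_id[annotation$chromosome %in% bad_chr], 5),
           collapse = ", "), ")")

  log <- data.frame(rule = character(0), item = character(0),
                    n_removed = integer(0), stringsAsFactors = FALSE)
  add <- function(rule, item, n)
    rbind(log, data.frame(rule = rule, item = item, n_removed = as.integer(n),
                          stringsAsFactors = FALSE))

  all_na_p <- rowSums(!is.na(methylation)) == 0L
  methylation <- methylation[!all_na_p, , drop = FALSE]
  log <- add("all_missing", "probes", sum(all_na_p))
  all_na_g <- rowSums(!is.na(expression)) == 0L
  expression <- expression[!all_na_g, , drop = FALSE]
  log <- add("all_missing", "genes", sum(all_na_g))

  meta <- metadata[match(colnames(methylation), metadata$sample_id), ,
                   drop = FALSE]
  incomplete <- rowSums(is.na(meta[, REQUIRED_CLINICAL, drop = FALSE])) > 0L |
    is.na(meta$sample_id)
  keep_samples <- meta$sample_id[!incomplete]
  log <- add("incomplete_clinical", "samples", sum(incomplete))
  methylation <- methylation[, colnames(methylation) %in% keep_samples,
                             drop = FALSE]
  expression <- expression[, colnames(expression) %in% keep_samples,
                           drop = FALSE]
  metadata <- metadata[metadata$sample_id %in% keep_samples, , drop = FALSE]

  chr <- annotation$chromosome[match(rownames(methylation),
                                     annotation$probe_id)]
  sex_p <- chr %in% c("chrX", "chrY")
  methylation <- methylation[!sex_p, , drop = FALSE]
  log <- add("sex_chromosome", "probes", sum(sex_p))

  if (is.null(gene_chromosome)) {
    first <- first_gene(annotation)
    by_gene <- split(annotation$chromosome[match(names(first),
                                                 annotation$probe_id)], first)
    sexual <- names(by_gene)[vapply(by_gene, function(ch)
      all(ch %in% c("chrX", "chrY")), logical(1))]
    sex_g <- rownames(expression) %in% sexual
  } else {
    sex_g <- gene_chromosome[rownames(expression)] %in% c("chrX", "chrY")
  }
  expression <- expression[!sex_g, , drop = FALSE]
  log <- add("sex_chromosome", "genes", sum(sex_g))

  if (log2_expression) expression <- log2(expression + 1)
  annotation <- annotation[annotation$probe_id %in% rownames(methylation), ,
                           drop = FALSE]
  structure(list(methylation = methylation, expression = expression,
                 annotation = annotation, metadata = metadata,
                 filter_log = log),
            class = "filtered_study")
}

#' @export
print.filtered_study <- function(x, ...) {
  cat("Filtered study: ", nrow(x$methylation), " probes, ",
      nrow(x$expression), " genes, ", ncol(x$methylation), " samples\n",
      sep = "")
  print(x$filter_log)
  invisible(x)
}

#' Jarque-Bera normality test
#'
#' Classical moment-based goodness-of-fit test of normality:
#' `JB = n/6 * (S^2 + (K - 3)^2 / 4)` with skewness `S` and kurtosis `K`
#' computed from biased (1/n) central moments, referred to a chi-squared
#' distribution with 2 degrees of freedom.
#'
#' @param x numeric vector, length >= 8, non-constant.
#' @return an object of class `htest` with `statistic` and `p.value`.
#' @examples
#' jarque_bera_test(rnorm(100))
#' @export
jarque_bera_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("need at least 8 non-missing observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("constant vector: skewness undefined")
  s <- mean((x - m)^3) / m2^1.5
  k <- mean((x - m)^4) / m2^2
  jb <- n / 6 * (s^2 + (k - 3)^2 / 4)
  structure(list(statistic = c(JB = jb), parameter = c(df = 2),
                 p.value = stats::pchisq(jb, 2, lower.tail = FALSE),
                 method = "Jarque-Bera normality test",
                 data.name = deparse(substitute(x))),
            class = "htest")
}

#' Audit per-probe normality across a methylation matrix
#'
#' Applies [jarque_bera_test()] to every probe and reports the fraction whose
#' p-value is at least `alpha` (uncorrected), i.e. the share of probes that
#' look compatible with a normal distribution. On 450K-style bimodal
#' beta-values this fraction is expected to be small, which motivates
#' rank-based downstream testing.
#'
#' @param methylation probe x sample matrix.
#' @param alpha per-probe significance level (default 0.05).
#' @return data frame of class `normality_report` (probe_id, jb, p, normal)
#'   with attributes `fraction_normal` and `alpha`.
#' @export
normality_audit <- function(methylation, alpha = 0.05) {
  stopifnot(is.matrix(methylation), nrow(methylation) >= 1)
  res <- t(apply(methylation, 1, function(x) {
    ht <- jarque_bera_test(x)
    c(ht$statistic[[1]], ht$p.value)
  }))
  out <- data.frame(probe_id = rownames(methylation), jb = res[, 1],
                    p = res[, 2], normal = res[, 2] >= alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fraction_normal") <- mean(out$normal)
  attr(out, "alpha") <- alpha
  class(out) <- c("normality_report", "data.frame")
  out
}

#' @export
print.normality_report <- function(x, ...) {
  cat(sprintf("Normality audit: %.2f%% of %d probes normal at alpha = %g\n",
              100 * attr(x, "fraction_normal"), nrow(x), attr(x, "alpha")))
  NextMethod()
}

first_gene <- function(annotation) {
  has <- annotation$gene_symbols != ""
  g <- sub(";.*$", "", annotation$gene_symbols[has])
  stats::setNames(g, annotation$probe_id[has])
}

# round half away from zero, one decimal
round1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

#' Summarize a probe annotation table
#'
#' Computes the feature-type distribution (both raw Island/N_Shore/... counts
#' and the collapsed open-sea / island / shore / shelf percentages), the
#' number of probes not located in any gene, the genes hit by two or more
#' probes, and the probe-to-first-gene map. When a probe lists several genes
#' the first is taken as the most likely one, so downstream probe-gene
#' analyses use one gene per probe. Percentages are rounded half away from
#' zero to one decimal.
#'
#' @param annotation a `probe_annotation` data frame (e.g. from
#'   [read_manifest()]); must be non-empty.
#' @return list of class `annotation_summary`: `n_probes`, `feature_counts`,
#'   `category_counts`, `category_pct`, `n_probes_without_gene`,
#'   `multi_probe_genes`, `first_gene_map`, `n_mapped_probes`,
#'   `n_distinct_first_genes`.
#' @examples
#' man <- read_manifest(system.file("extdata", "table2_probes.tsv",
#'                                  package = "smokesig"))
#' summarize_annotations(man)
#' @export
summarize_annotations <- function(annotation) {
  stopifnot(is.data.frame(annotation))
  if (nrow(annotation) == 0) stop("empty annotation table")
  n <- nrow(annotation)
  ft <- factor(annotation$feature_type, levels = VALID_FEATURES)
  feature_counts <- table(ft)
  cat_map <- c(Island = "Island", N_Shore = "Shore", S_Shore = "Shore",
               N_Shelf = "Shelf", S_Shelf = "Shelf", OpenSea = "OpenSea")
  categ <- factor(cat_map[as.character(ft)],
                  levels = c("OpenSea", "Island", "Shore", "Shelf"))
  category_counts <- table(categ)
  category_pct <- round1(100 * as.numeric(category_counts) / n)
  names(category_pct) <- names(category_counts)

  fg <- first_gene(annotation)
  tab <- table(fg)
  out <- list(
    n_probes = n,
    feature_counts = feature_counts,
    category_counts = category_counts,
    category_pct = category_pct,
    n_probes_without_gene = n - length(fg),
    multi_probe_genes = sort(names(tab)[tab >= 2]),
    first_gene_map = fg,
    n_mapped_probes = length(fg),
    n_distinct_first_genes = length(tab)
  )
  class(out) <- "annotation_summary"
  out
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat("Annotation summary of", x$n_probes, "probes\n")
  pct <- x$category_pct
  for (k in names(pct))
    cat(sprintf("  %-8s %3d  (%.1f%%)\n", k, x$category_counts[[k]], pct[[k]]))
  cat(sprintf("  probes without gene: %d\n", x$n_probes_without_gene))
  cat(sprintf("  gene-bearing probes: %d mapping to %d distinct first genes\n",
              x$n_mapped_probes, x$n_distinct_first_genes))
  cat(sprintf("  genes with >= 2 probes: %s\n",
              paste(x$multi_probe_genes, collapse = ", ")))
  invisible(x)
}
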