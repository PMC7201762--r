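#' Two-sided Wilcoxon rank-sum test p-value
#'
#' Exact null distribution when the pooled sample size is at most 20 and the
#' data are tie-free; otherwise the normal approximation with midrank tie
#' correction and continuity correction.
#'
#' @param x,y numeric vectors for the two groups (both non-empty).
#' @return the two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(1:4, 5:8)  # exact: 2/70
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                     correct = TRUE)$p.value
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Prescreen probes for smoking-associated methylation differences
#'
#' Tests every probe with the Wilcoxon rank-sum test between current and
#' never smokers and controls the FDR across probes with Benjamini-Hochberg.
#' Samples whose smoking status is `ever` (smoked, not necessarily currently)
#' do not enter the contrast and are dropped with a warning.
#'
#' @param methylation probe x sample beta matrix.
#' @param metadata data frame with `sample_id` and `smoking_status`.
#' @param q FDR level; probes with adjusted p <= q are selected.
#' @return data frame of class `prescreen_result` with columns `probe_id`,
#'   `p`, `p_adj`, `median_current`, `median_never`, `selected`, in the input
#'   probe order; attribute `q`.
#' @export
prescreen_probes <- function(methylation, metadata, q = 0.05) {
  stopifnot(is.matrix(methylation), is.data.frame(metadata))
  status <- metadata$smoking_status[match(colnames(methylation),
                                          metadata$sample_id)]
  if (any(status == "ever", na.rm = TRUE))
    warning("excluding ", sum(status == "ever", na.rm = TRUE),
            " 'ever'-smoker samples from the current-vs-never contrast")
  cur <- which(status == "current")
  nev <- which(status == "never")
  if (length(cur) < 3 || length(nev) < 3)
    stop("need at least 3 samples in each smoking group")
  res <- apply(methylation, 1, function(b)
    c(wilcoxon_rank_sum(b[cur], b[nev]),
      stats::median(b[cur], na.rm = TRUE),
      stats::median(b[nev], na.rm = TRUE)))
  out <- data.frame(probe_id = rownames(methylation),
                    p = res[1, ], p_adj = bh_adjust(res[1, ]),
                    median_current = res[2, ], median_never = res[3, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$selected <- out$p_adj <= q
  attr(out, "q") <- q
  class(out) <- c("prescreen_result", "data.frame")
  out
}

#' @export
print.prescreen_result <- function(x, ...) {
  cat(sprintf("Wilcoxon/BH prescreen: %d of %d probes selected at q = %g\n",
              sum(x$selected), nrow(x), attr(x, "q")))
  NextMethod()
}
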