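#' Classification performance counts and rates
#'
#' Builds sensitivity (SN = TP/(TP+FN)), specificity (SP = TN/(TN+FP)) and
#' accuracy (ACC = (TP+TN)/total) either from explicit confusion counts or
#' from truth/prediction label vectors (+1 positive / -1 negative). A class
#' absent from the truth leaves the corresponding rate `NA` with a warning.
#'
#' @param tp,fp,tn,fn non-negative integer confusion counts; or
#' @param truth,pred label vectors coded +1/-1 (used when counts are missing).
#' @return object of class `classifier_metrics`.
#' @examples
#' classifier_metrics(tp = 100, fn = 2, tn = 43, fp = 0)
#' @export
classifier_metrics <- function(tp = NULL, fp = NULL, tn = NULL, fn = NULL,
                               truth = NULL, pred = NULL) {
  if (is.null(tp)) {
    stopifnot(length(truth) == length(pred))
    truth <- code_labels(truth); pred <- code_labels(pred)
    tp <- sum(truth == 1 & pred == 1); fn <- sum(truth == 1 & pred == -1)
    tn <- sum(truth == -1 & pred == -1); fp <- sum(truth == -1 & pred == 1)
  }
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  sn <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  sp <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  if (is.na(sn) || is.na(sp))
    warning("a class is absent: SN or SP undefined")
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 SN = sn, SP = sp, ACC = (tp + tn) / (tp + fp + tn + fn)),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, digits = 4, ...) {
  cat(sprintf("SN %.*f  SP %.*f  ACC %.*f  (TP %d FP %d TN %d FN %d)\n",
              digits, x$SN, digits, x$SP, digits, x$ACC,
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

stratified_folds <- function(y, k) {
  if (k > min(table(y))) stop("k exceeds the size of the smallest class")
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated PLS-DA performance with component selection
#'
#' Stratified k-fold cross-validation: for each candidate component count the
#' model is refit on the training folds and the held-out samples are
#' classified by the sign of the prediction; pooled out-of-fold confusion
#' counts give SN/SP/ACC. The component count with maximal pooled accuracy is
#' chosen (smallest count on ties). Fold assignment uses the current RNG
#' state, so seed before calling for reproducibility.
#'
#' @param X sample x probe matrix.
#' @param y labels, +1/-1 or two-level factor.
#' @param k number of folds (default 5), at most the smallest class size.
#' @param component_grid candidate component counts.
#' @param scale passed to [fit_plsda()].
#' @return list of class `cv_result`: `n_components`, `metrics` (pooled
#'   [classifier_metrics()] at the chosen count), `acc_by_component`.
#' @export
cross_validate <- function(X, y, k = 5L, component_grid = 1:5, scale = TRUE) {
  X <- as.matrix(X); y <- code_labels(y)
  grid <- unique(pmin(component_grid,
                      min(nrow(X) - ceiling(nrow(X) / k) - 1L, ncol(X))))
  grid <- sort(grid[grid >= 1L])
  if (length(grid) == 0) grid <- 1L
  fold <- stratified_folds(y, k)
  pred <- matrix(NA_real_, length(y), length(grid))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit_max <- suppressWarnings(
      fit_plsda(X[tr, , drop = FALSE], y[tr], n_components = max(grid),
                scale = scale))
    for (j in seq_along(grid)) {
      a <- min(grid[j], fit_max$n_components)
      fit_a <- truncate_components(fit_max, a)
      pred[!tr, j] <- predict(fit_a, X[!tr, , drop = FALSE], type = "class")
    }
  }
  accs <- colMeans(pred == y)
  best <- which.max(accs)   # first max -> smallest component count on ties
  structure(list(
    n_components = grid[best],
    metrics = classifier_metrics(truth = y, pred = pred[, best]),
    acc_by_component = stats::setNames(accs, grid)
  ), class = "cv_result")
}

# restrict a fitted plsda to its first `a` components
truncate_components <- function(fit, a) {
  if (a >= fit$n_components) return(fit)
  fit$W <- fit$W[, seq_len(a), drop = FALSE]
  fit$P <- fit$P[, seq_len(a), drop = FALSE]
  fit$T <- fit$T[, seq_len(a), drop = FALSE]
  fit$q <- fit$q[seq_len(a)]
  fit$coefficients <- drop(fit$W %*% solve(crossprod(fit$P, fit$W), fit$q))
  fit$n_components <- a
  fit
}

#' Deep-selecting signature probe identification
#'
#' Iterative PLS-DA feature elimination: fit a classifier on the active
#' probes, rank probes by their contribution to the model (VIP by default),
#' drop the lowest-ranked fraction, refit, and repeat while recording
#' cross-validated performance. The loop stops once the cross-validated
#' accuracy has not beaten the running best for `patience` consecutive
#' iterations, or when fewer than `min_probes` probes remain; the probe set of
#' the best-accuracy iteration (first occurrence on ties) is returned as the
#' signature.
#'
#' @param X sample x probe matrix (typically the prescreen survivors).
#' @param y labels, +1 smoker / -1 never, or a two-level factor.
#' @param probes probes to start from (default all columns of `X`).
#' @param drop_fraction fraction of active probes removed per iteration
#'   (default 0.1, at least one probe).
#' @param min_probes stop once the active set would fall below this size.
#' @param patience iterations without a new best accuracy before stopping.
#' @param k,component_grid,scale cross-validation settings, see
#'   [cross_validate()].
#' @param importance `"vip"` (default) or `"coef"` (absolute regression
#'   coefficient) as the probe contribution measure.
#' @param seed optional integer seed for the fold assignments.
#' @return object of class `deep_select`: `signature` (character vector),
#'   `trace` (per-iteration data frame), `probe_sets` (list of active sets),
#'   `best_iteration`, `stopping_reason`, and `final_model` (a `plsda` refit
#'   on the signature with the best iteration's component count).
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60 * 20), 60, 20,
#'             dimnames = list(NULL, paste0("p", 1:20)))
#' y <- rep(c(1, -1), each = 30)
#' X[, 1] <- X[, 1] + y          # one informative probe
#' fit <- deep_select(X, y, min_probes = 2, seed = 1)
#' fit$signature
#' @export
deep_select <- function(X, y, probes = colnames(X), drop_fraction = 0.1,
                        min_probes = 10L, patience = 5L, k = 5L,
                        component_grid = 1:5, scale = TRUE,
                        importance = c("vip", "coef"), seed = NULL) {
  importance <- match.arg(importance)
  X <- as.matrix(X); y <- code_labels(y)
  if (is.null(probes)) stop("X must have column names identifying probes")
  if (length(probes) < 2) stop("need at least 2 probes to select from")
  if (!is.null(seed)) set.seed(seed)
  if (all(apply(X[, probes, drop = FALSE], 2, stats::sd) == 0))
    stop("degenerate input: all probes constant")

  active <- probes
  trace <- list(); probe_sets <- list()
  best_acc <- -Inf; best_iter <- 0L; stall <- 0L
  reason <- "min_probes"
  it <- 0L
  while (TRUE) {
    it <- it + 1L
    Xa <- X[, active, drop = FALSE]
    cv <- cross_validate(Xa, y, k = k, component_grid = component_grid,
                         scale = scale)
    trace[[it]] <- data.frame(
      iteration = it, n_probes = length(active),
      n_components = cv$n_components,
      SN = cv$metrics$SN, SP = cv$metrics$SP, ACC = cv$metrics$ACC)
    probe_sets[[it]] <- active
    if (cv$metrics$ACC > best_acc) {
      best_acc <- cv$metrics$ACC; best_iter <- it; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) { reason <- "patience"; break }
    }
    n_drop <- max(1L, floor(drop_fraction * length(active)))
    if (length(active) - n_drop < min_probes) { reason <- "min_probes"; break }
    fit <- suppressWarnings(
      fit_plsda(Xa, y, n_components = cv$n_components, scale = scale))
    imp <- if (importance == "vip") vip(fit) else
      abs(fit$coefficients / fit$x_scale)
    imp <- imp[match(active, names(imp))]
    imp[is.na(imp)] <- -Inf  # columns dropped as constant go first
    active <- active[order(imp, decreasing = TRUE)][
      seq_len(length(active) - n_drop)]
  }
  trace <- do.call(rbind, trace)
  signature <- probe_sets[[best_iter]]
  final <- suppressWarnings(
    fit_plsda(X[, signature, drop = FALSE], y,
              n_components = trace$n_components[best_iter], scale = scale))
  structure(
    list(signature = signature, trace = trace, probe_sets = probe_sets,
         best_iteration = best_iter, stopping_reason = reason,
         final_model = final, importance = importance),
    class = "deep_select"
  )
}

#' @export
print.deep_select <- function(x, ...) {
  b <- x$trace[x$best_iteration, ]
  cat(sprintf(paste0(
    "Deep-selecting signature: %d probes (iteration %d of %d, stopped by %s)\n",
    "  CV at best iteration: SN %.4f  SP %.4f  ACC %.4f  (%d components)\n"),
    length(x$signature), x$best_iteration, nrow(x$trace), x$stopping_reason,
    b$SN, b$SP, b$ACC, b$n_components))
  invisible(x)
}

#' @export
summary.deep_select <- function(object, ...) {
  cat("Deep-select elimination trace:\n")
  print(object$trace, row.names = FALSE)
  invisible(object$trace)
}

#' @export
coef.deep_select <- function(object, ...) coef(object$final_model)

#' @export
predict.deep_select <- function(object, newdata, ...) {
  predict(object$final_model, newdata, ...)
}

#' @export
plot.deep_select <- function(x, ...) {
  graphics::plot(x$trace$n_probes, x$trace$ACC, type = "b", log = "x",
                 xlab = "active probes", ylab = "cross-validated accuracy",
                 main = "Deep-selecting elimination trace", ...)
  graphics::abline(v = length(x$signature), lty = 2)
  invisible(x)
}

#' Evaluate a signature on an external validation cohort
#'
#' Classifies a held-out cohort with the model refit on the full training
#' data restricted to the signature probes, and reports SN/SP/ACC.
#'
#' @param object a `deep_select` fit (its `final_model` is used) or a `plsda`.
#' @param X_val validation sample x probe matrix; must contain every
#'   signature probe (an error lists any that are missing).
#' @param y_val validation labels.
#' @return a [classifier_metrics()] object.
#' @export
evaluate_external <- function(object, X_val, y_val) {
  model <- if (inherits(object, "deep_select")) object$final_model else object
  stopifnot(inherits(model, "plsda"))
  X_val <- as.matrix(X_val)
  miss <- setdiff(model$probes, colnames(X_val))
  if (length(miss))
    stop("validation matrix lacks signature probes: ",
         paste(miss, collapse = ", "))
  pred <- predict(model, X_val, type = "class")
  classifier_metrics(truth = code_labels(y_val), pred = pred)
}
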