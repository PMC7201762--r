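#' Fit a PLS-DA model (PLS1 on a coded class label)
#'
#' NIPALS partial least squares regression of a numeric +1/-1 class code on a
#' sample-by-probe matrix, the workhorse of the deep-selecting signature
#' search. Columns are centered and (optionally) scaled to unit variance;
#' the response is centered. The fit is fully deterministic.
#'
#' @param X numeric sample x probe matrix (complete columns).
#' @param y class labels: +1 for the positive class (smoker), -1 for the
#'   negative class, or a two-level factor (first level coded -1).
#' @param n_components number of latent components, at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param scale scale columns to unit variance (default `TRUE`). Zero-variance
#'   columns are dropped with a warning when scaling.
#' @return object of class `plsda` with x-weights `W`, x-loadings `P`,
#'   y-loadings `q`, scores `T`, the regression coefficients on the
#'   preprocessed scale, and the centering/scaling parameters.
#' @export
fit_plsda <- function(X, y, n_components = 2L, scale = TRUE) {
  X <- as.matrix(X)
  y <- code_labels(y)
  stopifnot(nrow(X) == length(y), !anyNA(X))
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(nrow(X) - 1L, ncol(X)))
    stop("`n_components` must lie in [1, min(n_samples - 1, n_probes)]")

  x_center <- colMeans(X)
  x_scale <- rep(1, ncol(X))
  if (scale) {
    x_scale <- apply(X, 2, stats::sd)
    zero <- x_scale <= .Machine$double.eps
    if (any(zero)) {
      warning("dropping ", sum(zero), " zero-variance column(s)")
      X <- X[, !zero, drop = FALSE]
      x_center <- x_center[!zero]
      x_scale <- x_scale[!zero]
      if (ncol(X) == 0) stop("no non-constant columns left")
      n_components <- min(n_components, ncol(X))
    }
  }
  Xc <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- mean(y)
  yc <- y - y_center

  p <- ncol(Xc)
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(Xc), n_components)
  q <- numeric(n_components)
  Xd <- Xc; yd <- yc
  a <- 0L
  for (comp in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw <= .Machine$double.eps) break  # response variance exhausted
    w <- w / nw
    tt <- drop(Xd %*% w)
    t2 <- sum(tt^2)
    if (t2 <= .Machine$double.eps) break
    pl <- drop(crossprod(Xd, tt)) / t2
    qa <- sum(yd * tt) / t2
    Xd <- Xd - tcrossprod(tt, pl)
    yd <- yd - tt * qa
    a <- comp
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- tt; q[a] <- qa
  }
  if (a == 0L) stop("PLS fit degenerate: X carries no covariance with y")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]; q <- q[seq_len(a)]
  B <- drop(W %*% solve(crossprod(P, W), q))

  structure(
    list(W = W, P = P, q = q, T = Tm, coefficients = B,
         x_center = x_center, x_scale = x_scale, y_center = y_center,
         n_components = a, scaled = scale,
         probes = colnames(X) %||% as.character(seq_len(p))),
    class = "plsda"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

code_labels <- function(y) {
  if (is.factor(y) || is.character(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2) stop("y must have exactly two classes")
    return(ifelse(as.character(y) == lev[2], 1, -1))
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("numeric y must be coded -1 / +1")
  y
}

#' Predict from a PLS-DA model
#'
#' @param object a `plsda` fit.
#' @param newdata sample x probe matrix containing the model's probes.
#' @param type `"response"` for the continuous prediction on the +1/-1 scale,
#'   `"class"` for the sign-thresholded class (+1 on ties).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.plsda <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$probes, colnames(newdata))
  if (length(miss))
    stop("newdata lacks model probes: ",
         paste(utils::head(miss, 5), collapse = ", "))
  Xc <- sweep(sweep(newdata[, object$probes, drop = FALSE], 2,
                    object$x_center), 2, object$x_scale, "/")
  yhat <- drop(Xc %*% object$coefficients) + object$y_center
  if (type == "response") yhat else ifelse(yhat >= 0, 1, -1)
}

#' @export
coef.plsda <- function(object, ...) {
  b <- object$coefficients / object$x_scale
  stats::setNames(c(object$y_center - sum(b * object$x_center), b),
                  c("(Intercept)", object$probes))
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA fit: %d components over %d probes\n",
              x$n_components, length(x$probes)))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' Per-probe PLS importance: `VIP_j = sqrt(p * sum_a SSY_a w_aj^2 / sum_a
#' SSY_a)` with `SSY_a` the response variance explained by component `a` and
#' unit-norm x-weights `w_a`. The squared scores average to 1 over probes, so
#' probes with VIP above 1 contribute more than average to the class
#' separation. For a one-component model the VIP ranking coincides with the
#' `|w|` ranking.
#'
#' @param model a fitted `plsda`.
#' @return named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsda"))
  ssy <- model$q^2 * colSums(model$T^2)           # per-component explained SS
  wn2 <- sweep(model$W^2, 2, colSums(model$W^2), "/")
  p <- nrow(model$W)
  stats::setNames(sqrt(p * drop(wn2 %*% ssy) / sum(ssy)), model$probes)
}
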