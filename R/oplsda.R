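# Orthogonal partial least squares discriminant analysis for a binary
# class, single predictive component plus n_orth orthogonal (class-
# uncorrelated) components removed by orthogonal signal correction, with
# leave-one-out cross-validation. Fitting is deterministic (no randomness).

#' Fit an oPLS-DA model
#'
#' X is autoscaled per feature (mean 0, unit variance; or mean-centered
#' only), y is coded {0, 1} and centered. Each orthogonal component weight
#' is the X-loading of the predictive score minus its projection on the
#' predictive weight (normalized); its systematic variation is deflated
#' from X before the final one-component PLS fit.
#'
#' @param X Samples x features numeric matrix.
#' @param y Binary class labels (factor, character or 0/1).
#' @param n_orth Number of orthogonal components (default 1, giving the
#'   conventional 2-latent-variable model: 1 predictive + 1 orthogonal).
#' @param scale `"auto"` (autoscaling, default) or `"center"`.
#' @param positive_class Label treated as the positive class for
#'   sensitivity (default `"ET"`, early-stage tumor, when present;
#'   otherwise the second factor level).
#' @return Object of class `opls_da`: centering/scaling vectors, predictive
#'   weight/loading/regression scalar (`w_pred`, `p_pred`, `b`), orthogonal
#'   weights/loadings (`w_orth`, `p_orth`; features x n_orth), `n_lv`
#'   (= 1 + n_orth), captured variances `var_x_percent` / `var_y_percent`,
#'   and bookkeeping (`kept` features, class coding).
#' @export
opls_da_fit <- function(X, y, n_orth = 1L, scale = c("auto", "center"),
                        positive_class = NULL) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_("X must be finite")
  cls <- droplevels(as.factor(y))
  if (nlevels(cls) != 2L) stop_("y must contain exactly two classes (got %d)",
                                nlevels(cls))
  if (any(table(cls) < 2L)) stop_("need >= 2 samples per class")
  positive_class <- positive_class %||%
    (if ("ET" %in% levels(cls)) "ET" else levels(cls)[2])
  if (!positive_class %in% levels(cls)) {
    stop_("positive_class '%s' not among labels", positive_class)
  }
  y01 <- as.numeric(cls == positive_class)

  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, sd)
  kept <- which(x_sd > 0)
  if (length(kept) < ncol(X)) {
    warning(sprintf("dropping %d zero-variance feature(s)",
                    ncol(X) - length(kept)))
  }
  if (length(kept) == 0L) stop_("no features with variance left")
  x_scale <- if (scale == "auto") x_sd[kept] else rep(1, length(kept))
  Xs <- sweep(sweep(X[, kept, drop = FALSE], 2, x_mean[kept]), 2, x_scale, `/`)
  y_mean <- mean(y01)
  yc <- y01 - y_mean
  ssx_total <- sum(Xs^2)

  w <- as.numeric(crossprod(Xs, yc))
  w <- w / sqrt(sum(w^2))
  n_orth <- as.integer(n_orth)
  p_feat <- length(kept)
  w_orth <- matrix(0, p_feat, max(n_orth, 0))
  p_orth <- matrix(0, p_feat, max(n_orth, 0))
  t_orth <- matrix(0, nrow(Xs), max(n_orth, 0))
  Xf <- Xs
  for (j in seq_len(n_orth)) {
    t_pred <- as.numeric(Xf %*% w)
    p <- as.numeric(crossprod(Xf, t_pred)) / sum(t_pred^2)
    wo <- p - sum(w * p) * w
    no <- sqrt(sum(wo^2))
    if (no < 1e-12) {
      w_orth <- w_orth[, seq_len(j - 1L), drop = FALSE]
      p_orth <- p_orth[, seq_len(j - 1L), drop = FALSE]
      t_orth <- t_orth[, seq_len(j - 1L), drop = FALSE]
      n_orth <- j - 1L
      break
    }
    wo <- wo / no
    to <- as.numeric(Xf %*% wo)
    po <- as.numeric(crossprod(Xf, to)) / sum(to^2)
    Xf <- Xf - tcrossprod(to, po)
    w_orth[, j] <- wo; p_orth[, j] <- po; t_orth[, j] <- to
  }
  t_pred <- as.numeric(Xf %*% w)
  p_pred <- as.numeric(crossprod(Xf, t_pred)) / sum(t_pred^2)
  b <- sum(t_pred * yc) / sum(t_pred^2)

  ss_pred <- sum(tcrossprod(t_pred, p_pred)^2)
  ss_orth <- if (n_orth > 0) {
    sum(vapply(seq_len(n_orth),
               function(j) sum(tcrossprod(t_orth[, j], p_orth[, j])^2),
               numeric(1)))
  } else 0
  var_x_percent <- 100 * (ss_pred + ss_orth) / ssx_total
  var_y_percent <- 100 * sum((t_pred * b)^2) / sum(yc^2)

  structure(
    list(x_mean = x_mean[kept], x_scale = x_scale, kept = kept,
         w_pred = w, p_pred = p_pred, b = b,
         w_orth = w_orth, p_orth = p_orth, n_orth = n_orth,
         n_lv = 1L + n_orth,
         var_x_percent = var_x_percent, var_y_percent = var_y_percent,
         scores_pred = t_pred, scores_orth = t_orth,
         y_mean = y_mean, levels = levels(cls),
         positive_class = positive_class),
    class = "opls_da")
}

#' @export
print.opls_da <- function(x, ...) {
  cat(sprintf(
    "<opls_da> %d LVs (1 predictive + %d orthogonal), X var %.2f%%, Y var %.2f%%\n",
    x$n_lv, x$n_orth, x$var_x_percent, x$var_y_percent))
  invisible(x)
}

#' Predict class scores and labels
#'
#' New samples are scaled with the training vectors, orthogonal components
#' deflated, and the predictive score thresholded at the midpoint of the
#' {0, 1} class codes (0.5); a score exactly on the threshold is assigned
#' to the negative class.
#'
#' @param object An [opls_da_fit()] model.
#' @param newdata Samples x features matrix (same feature set as training).
#' @param ... Unused.
#' @return data.frame with `score` (predicted class code) and `class`.
#' @export
predict.opls_da <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)[, object$kept, drop = FALSE]
  Xs <- sweep(sweep(Xn, 2, object$x_mean), 2, object$x_scale, `/`)
  for (j in seq_len(object$n_orth)) {
    to <- as.numeric(Xs %*% object$w_orth[, j])
    Xs <- Xs - tcrossprod(to, object$p_orth[, j])
  }
  t_new <- as.numeric(Xs %*% object$w_pred)
  score <- t_new * object$b + object$y_mean
  neg <- setdiff(object$levels, object$positive_class)
  data.frame(score = score,
             class = ifelse(score > 0.5, object$positive_class, neg))
}

#' Leave-one-out cross-validated oPLS-DA classification
#'
#' Fits on N-1 samples and predicts the left-out sample, for every sample;
#' aggregates a confusion table with the positive class (default ET) as
#' "positive".
#'
#' @inheritParams opls_da_fit
#' @return A `classification_report` (see [report_metrics()]) with
#'   additional fields `misclassified_ids` and `scores`.
#' @export
loo_cross_validate <- function(X, y, n_orth = 1L, scale = c("auto", "center"),
                               positive_class = NULL) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  cls <- droplevels(as.factor(y))
  n <- nrow(X)
  if (n < 3L) stop_("need at least 3 samples for LOO")
  pred <- character(n); score <- numeric(n)
  for (i in seq_len(n)) {
    yi <- droplevels(cls[-i])
    if (nlevels(yi) < 2L) {
      stop_("LOO fold %d leaves a single class; cannot fit", i)
    }
    fit <- opls_da_fit(X[-i, , drop = FALSE], yi, n_orth = n_orth,
                       scale = scale, positive_class = positive_class)
    p <- predict(fit, X[i, , drop = FALSE])
    pred[i] <- p$class; score[i] <- p$score
  }
  pos <- positive_class %||% (if ("ET" %in% levels(cls)) "ET" else levels(cls)[2])
  truth <- as.character(cls)
  tp <- sum(truth == pos & pred == pos)
  fn <- sum(truth == pos & pred != pos)
  tn <- sum(truth != pos & pred != pos)
  fp <- sum(truth != pos & pred == pos)
  rep <- report_metrics(tp = tp, fn = fn, tn = tn, fp = fp,
                        positive_class = pos)
  ids <- rownames(X) %||% as.character(seq_len(n))
  rep$misclassified_ids <- ids[pred != truth]
  rep$scores <- data.frame(id = ids, truth = truth, predicted = pred,
                           score = score)
  rep
}

#' Classification metrics from a confusion table
#'
#' accuracy = (TP+TN)/N, sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' as percentages rounded to 1 decimal.
#'
#' @param tp,fn,tn,fp Non-negative confusion counts (positive class = ET
#'   convention: TP = ET classified ET).
#' @param positive_class Label reported as positive.
#' @return Object of class `classification_report`: `accuracy`,
#'   `sensitivity`, `specificity` (%), `n_misclassified`, `confusion`
#'   (2 x 2 matrix), `positive_class`.
#' @export
report_metrics <- function(tp, fn, tn, fp, positive_class = "ET") {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_("confusion counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0L) stop_("empty confusion table")
  div <- function(a, b) if (b == 0) 0 else a / b
  # column-wise fill: [1,1]=TP, [2,1]=FP, [1,2]=FN, [2,2]=TN
  confusion <- matrix(c(tp, fp, fn, tn), 2, 2,
                      dimnames = list(truth = c("positive", "negative"),
                                      predicted = c("positive", "negative")))
  structure(
    list(accuracy = round(100 * div(tp + tn, n), 1),
         sensitivity = round(100 * div(tp, tp + fn), 1),
         specificity = round(100 * div(tn, tn + fp), 1),
         n_misclassified = fn + fp,
         confusion = confusion,
         positive_class = positive_class),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%% (%d misclassified; positive = %s)\n",
    x$accuracy, x$sensitivity, x$specificity, x$n_misclassified,
    x$positive_class))
  invisible(x)
}
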