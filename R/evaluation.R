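#' 4x4 confusion matrix
#'
#' Rows are predicted (output) classes, columns are true (target)
#' classes; entry `[p, t]` counts subjects predicted `p` whose true
#' level is `t`.
#'
#' @param predicted,truth Integer vectors of risk levels in 1..4, equal
#'   length.
#' @return An integer matrix of class `"confusion_matrix4"`.
#' @export
confusion_matrix4 <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop_pstnn("shape", "predicted and truth lengths differ")
  }
  ok <- function(v) !anyNA(v) && all(v == round(v)) && all(v >= 1 & v <= 4)
  if (!ok(predicted) || !ok(truth)) {
    stop_pstnn("invalid_label", "labels must be integers in 1..4")
  }
  cm <- matrix(0L, 4, 4,
               dimnames = list(predicted = paste0("risk", 1:4),
                               truth = paste0("risk", 1:4)))
  for (i in seq_along(predicted)) {
    cm[predicted[i], truth[i]] <- cm[predicted[i], truth[i]] + 1L
  }
  structure(cm, class = c("confusion_matrix4", class(cm)))
}

#' @export
print.confusion_matrix4 <- function(x, ...) {
  m <- unclass(x)
  total <- sum(m)
  cat("Confusion matrix (rows = output class, columns = target class)\n")
  tab <- cbind(m, total = rowSums(m))
  tab <- rbind(tab, total = c(colSums(m), total))
  print(tab)
  cat(sprintf("Overall accuracy: %.1f%%\n", 100 * sum(diag(m)) / total))
  invisible(x)
}

#' Per-class sensitivity, specificity and accuracy
#'
#' One-vs-rest dichotomization of the confusion matrix: for class r,
#' `TP = cm[r, r]`, `FN` is the rest of column r, `FP` the rest of row
#' r, and `TN` everything else; then sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and accuracy `(TP+TN)/total`. Overall
#' accuracy is the trace over the total. A class absent from the truth
#' yields an undefined (NaN) sensitivity with a warning.
#'
#' @param cm A [confusion_matrix4()].
#' @return An object of class `"class_metrics"`: list with `per_class`
#'   (data frame: class, sensitivity, specificity, accuracy) and
#'   `overall_accuracy`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix4"))
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) stop_pstnn("empty_input", "empty confusion matrix")
  sens <- spec <- acc <- numeric(4)
  for (r in 1:4) {
    TP <- m[r, r]
    FN <- sum(m[, r]) - TP
    FP <- sum(m[r, ]) - TP
    TN <- total - TP - FN - FP
    if (TP + FN == 0) {
      warning(sprintf("class %d absent from truth; sensitivity undefined", r))
      sens[r] <- NaN
    } else {
      sens[r] <- TP / (TP + FN)
    }
    spec[r] <- TN / (TN + FP)
    acc[r] <- (TP + TN) / total
  }
  structure(list(per_class = data.frame(class = 1:4, sensitivity = sens,
                                        specificity = spec, accuracy = acc),
                 overall_accuracy = sum(diag(m)) / total),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat("Per-class metrics (one-vs-rest)\n")
  tab <- x$per_class
  tab[, -1] <- round(100 * tab[, -1], 1)
  names(tab) <- c("class", "sensitivity %", "specificity %", "accuracy %")
  print(tab, row.names = FALSE)
  cat(sprintf("Overall accuracy: %.1f%%\n", 100 * x$overall_accuracy))
  invisible(x)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each risk level r, the ROC curve traces true- against
#' false-positive rates as the threshold on the class-r score sweeps
#' from high to low; tied scores collapse into single threshold steps.
#' AUC is computed by the trapezoidal rule, which under this tie
#' handling equals the pairwise-comparison (rank-sum) statistic with
#' ties counted one half.
#'
#' @param scores Numeric matrix, subjects in rows, four class-score
#'   columns (see [class_scores()] / `predict(..., type = "scores")`).
#' @param truth Integer vector of true levels in 1..4.
#' @return An object of class `"roc_result"`: per class, a list with
#'   `points` (data frame `fpr`, `tpr`, monotone from (0,0) to (1,1))
#'   and `auc` (NaN for a class absent from the truth).
#' @export
roc_auc <- function(scores, truth) {
  scores <- as.matrix(scores)
  # -Inf is a legal score (a saturated output infinitely far from a
  # pattern); only NA/NaN are rejected
  if (ncol(scores) != 4 || anyNA(scores)) {
    stop_pstnn("invalid_output", "`scores` must be an n x 4 matrix without NA")
  }
  if (nrow(scores) != length(truth)) {
    stop_pstnn("shape", "scores and truth lengths differ")
  }
  out <- lapply(1:4, function(r) {
    pos <- truth == r
    P <- sum(pos); N <- sum(!pos)
    if (P == 0 || N == 0) {
      if (P == 0) warning(sprintf("class %d absent from truth; AUC undefined", r))
      return(list(points = data.frame(fpr = c(0, 1), tpr = c(0, 1)), auc = NaN))
    }
    s <- scores[, r]
    ord <- order(-s)
    s_ord <- s[ord]; pos_ord <- pos[ord]
    # group tied scores into single steps
    last <- c(s_ord[-1] != s_ord[-length(s_ord)], TRUE)
    tp <- cumsum(pos_ord)[last]
    fp <- cumsum(!pos_ord)[last]
    tpr <- c(0, tp / P); fpr <- c(0, fp / N)
    auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
    list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
  })
  names(out) <- paste0("risk", 1:4)
  structure(out, class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("One-vs-rest ROC\n")
  for (r in 1:4) cat(sprintf("  risk %d: AUC = %.3f\n", r, x[[r]]$auc))
  invisible(x)
}

#' One-way fixed-effects ANOVA on accuracy samples
#'
#' Classical one-way ANOVA `Y_i = mu + T_i + e_i` comparing groups of
#' repeated performance measurements (e.g. per-run accuracies of
#' competing classifiers): `F = MS_between / MS_within` with the p-value
#' from the F distribution. Assumes independence and normality of the
#' samples; these are not checked. Fitted via [stats::aov()].
#'
#' @param groups List of two or more numeric vectors, each with at least
#'   two values.
#' @param alpha Significance level (default 0.005, i.e. a 99.5%
#'   confidence level).
#' @return An object of class `"anova_result"`: list with `F`, `df`
#'   (between, within), `p_value`, `alpha`, `significant`. Identical
#'   constant groups give `F = 0`.
#' @export
anova_one_way <- function(groups, alpha = 0.005) {
  if (!is.list(groups) || length(groups) < 2 ||
      any(vapply(groups, length, integer(1)) < 2)) {
    stop_pstnn("empty_input", "need >= 2 groups with >= 2 values each")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  df1 <- length(groups) - 1L
  df2 <- length(y) - length(groups)
  if (var(y) == 0) {                          # no variance anywhere: F = 0
    Fstat <- 0; p <- 1
  } else {
    tab <- summary(aov(y ~ g))[[1]]
    Fstat <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
    if (!is.finite(Fstat)) {                  # zero within-group variance
      Fstat <- Inf; p <- 0
    }
  }
  structure(list(F = Fstat, df = c(between = df1, within = df2),
                 p_value = p, alpha = alpha, significant = p < alpha),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g (%ssignificant at alpha = %g)\n",
              x$df[1], x$df[2], x$F, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Assemble a full evaluation report
#'
#' Confusion matrix, per-class metrics and per-class AUCs for a set of
#' predictions, in one object serializable to JSON by [write_report()].
#'
#' @param predicted Integer vector of predicted levels.
#' @param truth Integer vector of true levels.
#' @param scores Optional n x 4 score matrix for ROC/AUC.
#' @return An object of class `"evaluation_report"`.
#' @export
evaluation_report <- function(predicted, truth, scores = NULL) {
  cm <- confusion_matrix4(predicted, truth)
  metrics <- per_class_metrics(cm)
  roc <- if (!is.null(scores)) roc_auc(scores, truth)
  structure(list(confusion = cm, metrics = metrics, roc = roc),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  print(x$confusion)
  cat("\n")
  print(x$metrics)
  if (!is.null(x$roc)) { cat("\n"); print(x$roc) }
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param report An [evaluation_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  doc <- list(
    format = "pstnn-report",
    confusion_matrix = unclass(report$confusion),
    per_class = report$metrics$per_class,
    overall_accuracy = report$metrics$overall_accuracy
  )
  if (!is.null(report$roc)) {
    doc$auc <- vapply(report$roc, function(r) r$auc, numeric(1))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
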