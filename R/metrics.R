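#' Compute the metric suite from predictions
#'
#' Classification metrics come from the argmax of the class probabilities:
#' accuracy, macro-averaged precision/recall/F1 and a 3x3 confusion matrix
#' (rows = true class, columns = predicted). One-vs-rest AUC is computed per
#' class on the softmax scores; a class absent from the test set gets
#' \code{NA}, never 0 or 1. Regression metrics: MAE in ppm averaged over
#' both gas targets, and R-squared pooled over both targets
#' (\eqn{1 - \sum SS_{res} / \sum SS_{tot}}, per-target centering) plus
#' per-gas values.
#'
#' @param probs 3 x N matrix of class probabilities (rows in
#'   \code{class_levels()} order).
#' @param conc_pred 2 x N matrix of ppm predictions (rows n-propanol,
#'   ethanol).
#' @param labels Factor of true labels with levels \code{class_levels()}.
#' @param conc_true N x 2 matrix of true ppm (columns propanol, ethanol).
#' @return A \code{metrics_report} list.
#' @export
evaluate_predictions <- function(probs, conc_pred, labels, conc_true) {
  N <- length(labels)
  if (N == 0) stopf("empty test set")
  lev <- class_levels()
  pred <- factor(lev[max.col(t(probs), ties.method = "first")], levels = lev)
  confusion <- table(true = labels, predicted = pred)
  accuracy <- mean(pred == labels)

  per_class <- lapply(lev, function(cl) {
    tp <- sum(pred == cl & labels == cl)
    fp <- sum(pred == cl & labels != cl)
    fn <- sum(pred != cl & labels == cl)
    support <- sum(labels == cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (support > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    auc <- if (support > 0 && support < N) {
      as.numeric(pROC::auc(pROC::roc(
        response = as.integer(labels == cl), predictor = probs[match(cl, lev), ],
        quiet = TRUE, direction = "<", levels = c(0, 1))))
    } else NA_real_
    c(precision = precision, recall = recall, f1 = f1, auc = auc,
      support = support)
  })
  pc <- do.call(rbind, per_class)
  rownames(pc) <- lev
  present <- pc[, "support"] > 0
  macro <- colMeans(pc[present, c("precision", "recall", "f1"), drop = FALSE],
                    na.rm = TRUE)

  truth <- t(conc_true[, c("propanol", "ethanol"), drop = FALSE])
  res <- conc_pred - truth
  mae <- mean(abs(res))
  ss_res <- rowSums(res^2)
  ss_tot <- apply(truth, 1, function(y) sum((y - mean(y))^2))
  r2_per_gas <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
  names(r2_per_gas) <- c("propanol", "ethanol")
  r2 <- 1 - sum(ss_res) / sum(ss_tot)

  structure(list(
    accuracy = accuracy,
    precision = unname(macro["precision"]),
    recall = unname(macro["recall"]),
    f1 = unname(macro["f1"]),
    confusion = confusion,
    per_class = pc,
    auc = stats::setNames(pc[, "auc"], lev),
    mae = mae, r2 = r2, r2_per_gas = r2_per_gas,
    n = N
  ), class = "metrics_report")
}

#' Evaluate a trained model on a test set
#'
#' @param model Trained model list (\code{params}, \code{state},
#'   \code{config}).
#' @param dataset An \code{enose_dataset} of test samples.
#' @return A \code{metrics_report} (see \code{evaluate_predictions}).
#' @export
evaluate_model <- function(model, dataset) {
  if (length(dataset$labels) == 0) stopf("empty test set")
  pr <- predict_mrca(model, dataset$tensors)
  evaluate_predictions(pr$probs, pr$conc, dataset$labels, dataset$conc)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  cat(sprintf("MAE %.2f ppm  R2 %.4f (propanol %.4f, ethanol %.4f)  n=%d\n",
              x$mae, x$r2, x$r2_per_gas["propanol"],
              x$r2_per_gas["ethanol"], x$n))
  invisible(x)
}
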