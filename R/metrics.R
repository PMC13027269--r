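# Evaluation metrics. Each class is scored one-vs-rest from the confusion
# matrix: Accuracy = (TP+TN)/(TP+TN+FP+FN), Precision = TP/(TP+FP),
# Recall = TP/(TP+FN), F1 = 2PR/(P+R). Two aggregation flavors are
# reported: macro (unweighted class means, sensitive to rare classes) and
# overall (sample-level accuracy plus support-weighted P/R/F1).

#' Build an evaluation report from labels and predictions
#'
#' Per-class metrics that are undefined (zero support, or zero predicted
#' positives for precision) are reported as `NA` and excluded from the
#' macro means with a warning, rather than zero-filled.
#'
#' @param truth integer vector of true class ids (1-based).
#' @param pred integer vector of predicted class ids.
#' @param n_classes number of classes.
#' @param class_names optional class names.
#' @return an object of class `"eval_report"`: `confusion` (rows = truth,
#'   columns = prediction), `per_class`, `macro`, `overall`.
#' @export
eval_report <- function(truth, pred, n_classes = max(truth, pred),
                        class_names = NULL) {
  stopifnot(length(truth) == length(pred))
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(n_classes))
  lv <- seq_len(n_classes)
  confusion <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  confusion <- matrix(as.integer(confusion), n_classes, n_classes,
                      dimnames = list(truth = class_names, pred = class_names))
  n <- length(truth)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- n - tp - fp - fn
  support <- rowSums(confusion)
  acc_c <- (tp + tn) / n
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  rec <- ifelse(support > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(is.na(prec) | is.na(rec), NA_real_,
               ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0))
  per_class <- data.frame(class = class_names, support = support,
                          accuracy = acc_c, precision = prec,
                          recall = rec, f1 = f1, row.names = NULL)
  if (anyNA(c(prec, rec))) {
    und <- class_names[is.na(prec) | is.na(rec)]
    warning(sprintf("eval_report(): undefined metrics for class(es) %s; excluded from macro averages",
                    paste(und, collapse = ", ")), call. = FALSE)
  }
  macro <- c(accuracy = mean(acc_c, na.rm = TRUE),
             precision = mean(prec, na.rm = TRUE),
             recall = mean(rec, na.rm = TRUE),
             f1 = mean(f1, na.rm = TRUE))
  wmean <- function(v) {
    ok <- !is.na(v) & support > 0
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * support[ok]) / sum(support[ok])
  }
  overall <- c(accuracy = sum(tp) / n,
               precision = wmean(prec),
               recall = wmean(rec),
               f1 = wmean(f1))
  structure(list(confusion = confusion, per_class = per_class,
                 macro = macro, overall = overall, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("Evaluation report (n = %d)\n", x$n))
  cat(sprintf("  overall: acc %.3f | prec %.3f | rec %.3f | F1 %.3f\n",
              x$overall["accuracy"], x$overall["precision"],
              x$overall["recall"], x$overall["f1"]))
  cat(sprintf("  macro:   acc %.3f | prec %.3f | rec %.3f | F1 %.3f\n",
              x$macro["accuracy"], x$macro["precision"],
              x$macro["recall"], x$macro["f1"]))
  print(round(x$per_class[, -1], digits))
  invisible(x)
}

#' Evaluate a model on labeled aligned samples
#'
#' @param model an `"mvcf_model"` or `"mvcf_fit"`.
#' @param samples an `"aligned_samples"` object with labels.
#' @return an [eval_report()].
#' @export
evaluate_model <- function(model, samples) {
  if (inherits(model, "mvcf_fit")) model <- model$model
  pred <- predict(model, samples, type = "class")
  eval_report(samples$labels, pred, model$n_classes,
              class_names = samples$class_names)
}

#' Density-stratified evaluation
#'
#' Evaluates the model separately on the sparse and dense strata of a test
#' set and reports the metric deltas (sparse minus dense), probing
#' robustness to colony crowding and occlusion. An absent stratum is
#' reported as an empty marker.
#'
#' @param model an `"mvcf_model"` or `"mvcf_fit"`.
#' @param samples labeled `"aligned_samples"` with density tags.
#' @return a list with `sparse`, `dense` (eval reports or `NULL`), and
#'   `delta` (overall-metric drops, sparse minus dense).
#' @export
density_stratified_eval <- function(model, samples) {
  if (!length(samples$density)) stop("density tags missing", call. = FALSE)
  if (all(samples$density == samples$density[1]) &&
      !samples$density[1] %in% c("sparse", "dense")) {
    stop("density tags must be 'sparse'/'dense'", call. = FALSE)
  }
  sub <- function(tag) {
    idx <- which(samples$density == tag)
    if (!length(idx)) return(NULL)
    s <- samples
    s$images <- s$images[idx]
    s$sensor <- s$sensor[idx, , drop = FALSE]
    s$labels <- s$labels[idx]
    s$groups <- s$groups[idx]
    s$density <- s$density[idx]
    evaluate_model(model, s)
  }
  sparse <- sub("sparse")
  dense <- sub("dense")
  delta <- if (is.null(sparse) || is.null(dense)) NULL else
    sparse$overall - dense$overall
  list(sparse = sparse, dense = dense, delta = delta)
}
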