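#' Haemorrhage subtype labels
#'
#' Default reporting order of the five ICH subtypes: intraventricular
#' (IVT), intraparenchymal (IPC), subarachnoid (SAD), epidural (EPI), and
#' subdural (SBD).
#'
#' @export
ich_classes <- c("IVT", "IPC", "SAD", "EPI", "SBD")

#' Confusion matrix
#'
#' @param truth,predicted label vectors of equal length; every value must
#'   appear in `classes`.
#' @param classes class order (default the union of observed labels in
#'   order of first appearance; use [ich_classes] for the subtype order).
#' @return An integer matrix of class `confusion_matrix`, entry
#'   `[a, b]` = number of samples with true class `a` predicted as `b`.
#' @export
confusion <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  if (is.null(classes)) classes <- unique(c(truth, predicted))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad) > 0L) {
    stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  cm <- unclass(table(tf, pf))
  dimnames(cm) <- list(truth = classes, predicted = classes)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Per-class classification metrics
#'
#' One-vs-rest counts per class: `TP` the diagonal entry, `FN` the rest of
#' the row, `FP` the rest of the column, `TN` everything else. Metrics:
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, and per-class accuracy `(TP+TN)/N`. A zero denominator
#' yields metric 0 with `degenerate = TRUE`. Values are kept at full
#' precision; round only at report time (see [metric_report()]).
#'
#' @param cm a [confusion()] matrix.
#' @return A tibble with one row per class.
#' @export
per_class_metrics <- function(cm) {
  cm <- unclass(cm)
  N <- sum(cm)
  if (N == 0L) stop("confusion matrix is empty", call. = FALSE)
  classes <- rownames(cm)
  safe <- function(num, den) if (den == 0) 0 else num / den
  rows <- lapply(seq_along(classes), function(i) {
    TP <- cm[i, i]
    FN <- sum(cm[i, ]) - TP
    FP <- sum(cm[, i]) - TP
    TN <- N - TP - FN - FP
    tibble::tibble(
      class = classes[i],
      sensitivity = safe(TP, TP + FN),
      specificity = safe(TN, TN + FP),
      precision = safe(TP, TP + FP),
      accuracy = (TP + TN) / N,
      degenerate = (TP + FN) == 0 || (TN + FP) == 0 || (TP + FP) == 0
    )
  })
  dplyr::bind_rows(rows)
}

#' Macro (unweighted) average of per-class metrics
#'
#' @param metrics a [per_class_metrics()] tibble (or a confusion matrix,
#'   which is converted first).
#' @return A one-row tibble with the four macro-averaged metrics.
#' @export
macro_average <- function(metrics) {
  if (inherits(metrics, "confusion_matrix")) metrics <- per_class_metrics(metrics)
  tibble::tibble(
    sensitivity = mean(metrics$sensitivity),
    specificity = mean(metrics$specificity),
    precision = mean(metrics$precision),
    accuracy = mean(metrics$accuracy)
  )
}

#' Report table of per-class metrics with an Average row
#'
#' Rounds to `digits` decimals with round-half-even (the convention of the
#' base `round()`), matching standard published table formatting.
#'
#' @inheritParams macro_average
#' @param digits decimals for the report (default 4).
#' @return A tibble of per-class rows plus a final `"Average"` row.
#' @export
metric_report <- function(metrics, digits = 4L) {
  if (inherits(metrics, "confusion_matrix")) metrics <- per_class_metrics(metrics)
  avg <- macro_average(metrics)
  out <- dplyr::bind_rows(
    dplyr::select(metrics, "class", "sensitivity", "specificity", "precision", "accuracy"),
    dplyr::mutate(avg, class = "Average", .before = 1L)
  )
  dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric), ~ round(.x, digits)))
}

#' Per-class sensitivity from correct-classification counts
#'
#' Sensitivity needs only the number of correctly classified images per
#' class and the class sizes (`TP / (TP + FN)`), so published per-class
#' counts are enough to recompute the sensitivity column and its macro
#' average.
#'
#' @param correct integer vector of correctly classified counts per class.
#' @param total integer vector of class sizes (same order).
#' @param classes optional class names.
#' @return A tibble of per-class sensitivities plus attribute-free macro
#'   mean in the final `"Average"` row (unrounded; see [metric_report()]).
#' @export
sensitivity_from_counts <- function(correct, total, classes = NULL) {
  if (length(correct) != length(total)) {
    stop("`correct` and `total` must have equal length", call. = FALSE)
  }
  if (any(correct > total) || any(total <= 0)) {
    stop("counts must satisfy 0 <= correct <= total with total > 0", call. = FALSE)
  }
  if (is.null(classes)) classes <- paste0("class", seq_along(correct))
  sens <- correct / total
  dplyr::bind_rows(
    tibble::tibble(class = classes, sensitivity = sens),
    tibble::tibble(class = "Average", sensitivity = mean(sens))
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>\n")
  print(unclass(x))
  invisible(x)
}

#' Tidy a confusion matrix into long form
#'
#' @param x a [confusion()] matrix.
#' @param ... unused.
#' @return A tibble with columns `truth`, `predicted`, `n`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame(unclass(x))
  classes <- rownames(x)
  tibble::tibble(
    truth = rep(classes, times = length(classes)),
    predicted = rep(classes, each = length(classes)),
    n = as.integer(unclass(x))
  )
}

#' Heatmap of a confusion matrix
#'
#' @param object a [confusion()] matrix.
#' @param ... unused.
#' @return A ggplot tile plot of counts.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  d <- tidy.confusion_matrix(object)
  classes <- rownames(object)
  d$truth <- factor(d$truth, levels = rev(classes))
  d$predicted <- factor(d$predicted, levels = classes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$truth, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true class")
}
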