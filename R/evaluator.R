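#' Confusion matrix for two-class tile predictions
#'
#' Tallies the four outcome groups of a binary classification — true positive
#' (TP), false positive (FP), true negative (TN), false negative (FN) — with
#' the reed class as positive by default.
#'
#' @param true_labels,predicted_labels Equal-length vectors with values from
#'   the two-class vocabulary (`reed`, `non_reed`).
#' @param positive The positive class.
#' @return Object of class `confusion_matrix`: list with integer `TP`, `FP`,
#'   `TN`, `FN`, and `positive`.
#' @export
confusion_counts <- function(true_labels, predicted_labels,
                             positive = "reed") {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    stop("true and predicted label vectors differ in length (",
         length(true_labels), " vs ", length(predicted_labels), ")")
  vocab <- c("reed", "non_reed")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), vocab)
  if (length(bad) > 0)
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  if (!positive %in% vocab) stop("positive class must be one of: ",
                                 paste(vocab, collapse = ", "))
  tpos <- true_labels == positive
  ppos <- predicted_labels == positive
  structure(list(TP = sum(tpos & ppos), FP = sum(!tpos & ppos),
                 TN = sum(!tpos & !ppos), FN = sum(tpos & !ppos),
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(truth = c(x$positive, "other"),
                              predicted = c(x$positive, "other")))
  cat("Confusion matrix (positive =", x$positive, "):\n")
  print(m)
  invisible(x)
}

#' Derived metrics from a confusion matrix
#'
#' Ratios with a zero denominator are reported as missing (`NA`), never
#' coerced to 0, so degenerate splits cannot silently inflate a metric.
#'
#' @param cm A `confusion_matrix` with at least one evaluated tile.
#' @return List with `n`, `accuracy`, `precision`, `recall`, `specificity`,
#'   `f1`.
#' @export
summary_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$TP + cm$FP + cm$TN + cm$FN
  if (n == 0L) stop("confusion matrix is empty (n = 0)")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(cm$TP, cm$TP + cm$FP)
  recall <- ratio(cm$TP, cm$TP + cm$FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(n = n,
       accuracy = (cm$TP + cm$TN) / n,
       precision = precision,
       recall = recall,
       specificity = ratio(cm$TN, cm$TN + cm$FP),
       f1 = f1)
}

#' Write confusion counts and derived metrics as JSON
#'
#' @param cm A `confusion_matrix`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(cm, path) {
  m <- summary_metrics(cm)
  jsonlite::write_json(
    c(list(TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN,
           positive = cm$positive), m),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
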