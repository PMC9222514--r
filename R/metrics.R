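#' Multiclass confusion matrix
#'
#' @param true,predicted vectors of class labels (coerced to a common factor).
#' @param class_names optional explicit class ordering.
#' @return a `confusion_matrix`: integer C x C matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(true, predicted, class_names = NULL) {
  if (length(true) != length(predicted))
    stop("true and predicted must have equal length")
  if (length(true) == 0) stop("empty input")
  if (is.null(class_names))
    class_names <- sort(unique(c(as.character(true), as.character(predicted))))
  tf <- factor(as.character(true), levels = class_names)
  pf <- factor(as.character(predicted), levels = class_names)
  m <- unclass(table(tf, pf))
  dimnames(m) <- list(true = class_names, predicted = class_names)
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' One-vs-rest reduction of a confusion matrix
#'
#' Treats class `i` as positive and all others as negative.
#'
#' @param cm confusion matrix (rows = true, columns = predicted).
#' @param class_index class position (1-based) or class name.
#' @return named vector `c(TP, FP, FN, TN)`.
#' @export
one_vs_rest <- function(cm, class_index) {
  cm <- unclass(cm)
  if (is.character(class_index)) class_index <- match(class_index, rownames(cm))
  if (is.na(class_index) || class_index < 1 || class_index > nrow(cm))
    stop("class index out of range")
  i <- class_index
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' F-score from precision and recall percentages
#'
#' Harmonic mean `2PR/(P+R)`; defined as 0 when `P + R == 0`.
#'
#' @param precision_pct,recall_pct percentages in \[0, 100\].
#' @return F-score percentage.
#' @export
f_score <- function(precision_pct, recall_pct) {
  s <- precision_pct + recall_pct
  ifelse(s > 0, 2 * precision_pct * recall_pct / s, 0)
}

#' Matthews correlation coefficient (percentage)
#'
#' `100 * (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with 0
#' returned when any denominator factor is zero.
#'
#' @param TP,FP,FN,TN one-vs-rest counts.
#' @return MCC in \[-100, 100\].
#' @export
mcc <- function(TP, FP, FN, TN) {
  den <- sqrt((TP + FP) * (TP + FN)) * sqrt((TN + FP) * (TN + FN))
  if (den == 0) return(0)
  100 * (TP * TN - FP * FN) / den
}

#' Geometric mean of sensitivity and specificity (percentage)
#'
#' `100 * sqrt(sensitivity * specificity)` from the one-vs-rest counts;
#' degenerate denominators give 0.
#'
#' @inheritParams mcc
#' @return G-mean in \[0, 100\].
#' @export
g_mean <- function(TP, FP, FN, TN) {
  if (TP + FN == 0 || TN + FP == 0) return(0)
  100 * sqrt((TP / (TP + FN)) * (TN / (TN + FP)))
}

#' Per-class (one-vs-rest) accuracy percentage
#'
#' @inheritParams mcc
#' @return `100 * (TP + TN) / (TP + FP + FN + TN)`.
#' @export
per_class_accuracy <- function(TP, FP, FN, TN) {
  100 * (TP + TN) / (TP + FP + FN + TN)
}

#' Per-class metric table with macro-average row
#'
#' Computes, for every class of a confusion matrix, the one-vs-rest accuracy,
#' precision, recall, F-score, MCC and geometric mean (all percentages, full
#' precision), plus an unweighted macro-average row. This is the layout used
#' to report per-phase classification results.
#'
#' @param cm a [confusion_matrix()].
#' @return data frame with one row per class plus an `"Average"` row and
#'   columns `class, accuracy, precision, recall, f_score, mcc, g_mean`.
#' @export
class_metrics_table <- function(cm) {
  cls <- rownames(cm)
  rows <- lapply(seq_along(cls), function(i) {
    ct <- one_vs_rest(cm, i)
    tp <- ct["TP"]; fp <- ct["FP"]; fn <- ct["FN"]; tn <- ct["TN"]
    prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    rec  <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    data.frame(class = cls[i],
               accuracy = per_class_accuracy(tp, fp, fn, tn),
               precision = prec, recall = rec,
               f_score = f_score(prec, rec),
               mcc = mcc(tp, fp, fn, tn),
               g_mean = g_mean(tp, fp, fn, tn))
  })
  tab <- rbind(do.call(rbind, rows))
  tab <- rbind(tab, macro_average(tab))
  rownames(tab) <- NULL
  tab
}

#' Macro-average row of a per-class metric table
#'
#' Unweighted arithmetic mean of the per-class values.
#'
#' @param table data frame as produced by [class_metrics_table()] (per-class
#'   rows only; an existing `"Average"` row is ignored).
#' @return one-row data frame labeled `"Average"`.
#' @export
macro_average <- function(table) {
  tab <- table[table$class != "Average", , drop = FALSE]
  avg <- as.data.frame(lapply(tab[-1], mean))
  cbind(class = "Average", avg)
}

#' Render a metric table for reporting
#'
#' Two-decimal presentation (computation keeps full precision); optionally
#' writes the full-precision CSV and a Markdown table.
#'
#' @param cm a [confusion_matrix()].
#' @param csv,markdown optional output file paths.
#' @return invisibly, a list with `table` (full precision), `formatted`
#'   (two-decimal character table) and `markdown` (character vector).
#' @export
render_report <- function(cm, csv = NULL, markdown = NULL) {
  tab <- class_metrics_table(cm)
  fmt <- tab
  fmt[-1] <- lapply(fmt[-1], function(v) sprintf("%.2f", v))
  hdr <- c("Class Labels", "Accuracy", "Precision", "Recall", "F-Score",
           "MCC", "Geometric Mean")
  md <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
          paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
          apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (!is.null(markdown)) writeLines(md, markdown)
  invisible(list(table = tab, formatted = fmt, markdown = md))
}
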