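#' Tally a 2x2 confusion matrix
#'
#' Counts true/false positives and negatives with respect to a stated
#' positive class.
#'
#' @param y_true,y_pred Label vectors of equal length over a two-label
#'   alphabet.
#' @param positive The label treated as positive.
#' @return Object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn`, `positive`, `total`.
#' @export
confusion_counts <- function(y_true, y_pred, positive) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred length mismatch")
  alphabet <- unique(c(y_true, y_pred))
  if (length(alphabet) > 2) stop("more than two labels present")
  if (!positive %in% alphabet) stop("positive label '", positive, "' absent from labels")
  pt <- y_true == positive
  pp <- y_pred == positive
  structure(list(tp = sum(pt & pp), fp = sum(!pt & pp),
                 tn = sum(!pt & !pp), fn = sum(pt & !pp),
                 positive = positive, total = length(y_true)),
            class = "confusion_counts")
}

# Direct construction from counts (used when reconstructing published
# confusion matrices from class sizes and recalls).
counts_from_values <- function(tp, fp, tn, fn, positive = "presence") {
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 positive = positive, total = tp + fp + tn + fn),
            class = "confusion_counts")
}

# 0/0 rates are reported as 0 carrying a "degenerate" attribute rather than
# erroring: metaheuristic fitness evaluation must not abort mid-search.
safe_rate <- function(num, den) {
  if (den == 0) return(structure(0, degenerate = TRUE))
  num / den
}

#' Precision TP / (TP + FP)
#'
#' @param counts A [confusion_counts()] object.
#' @return Rate in \[0, 1\]; a 0/0 denominator yields 0 with attribute
#'   `degenerate = TRUE`.
#' @export
precision <- function(counts) safe_rate(counts$tp, counts$tp + counts$fp)

#' @rdname precision
#' @export
recall <- function(counts) safe_rate(counts$tp, counts$tp + counts$fn)

#' All per-class metrics from a confusion matrix
#'
#' Standard definitions: accuracy (TP+TN)/total, precision, recall,
#' F-measure 2PR/(P+R), Matthews correlation coefficient and Cohen's kappa
#' (chance agreement from the marginals). All math in full precision;
#' rounding happens only at report formatting.
#'
#' @param counts A [confusion_counts()] object.
#' @return Named list: `accuracy`, `precision`, `recall`, `f_measure`,
#'   `mcc`, `kappa`. Degenerate 0/0 cases carry attribute `degenerate`.
#' @export
class_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- counts$total
  if (n == 0) stop("empty confusion matrix")
  p <- precision(counts)
  r <- recall(counts)
  f <- safe_rate(2 * as.numeric(p) * as.numeric(r), as.numeric(p) + as.numeric(r))
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn)) * sqrt(as.numeric(tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) structure(0, degenerate = TRUE)
         else (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  po <- (tp + tn) / n
  pe <- (as.numeric(tp + fp) * (tp + fn) + as.numeric(tn + fn) * (tn + fp)) / n^2
  kap <- if (pe == 1) structure(0, degenerate = TRUE) else (po - pe) / (1 - pe)
  list(accuracy = (tp + tn) / n, precision = p, recall = r,
       f_measure = f, mcc = mcc, kappa = kap)
}

#' Per-class + macro-averaged classification report
#'
#' Computes every metric twice, once with each class treated as positive,
#' plus an unweighted average row, mirroring the reporting convention of
#' per-class rows followed by an "Average" row. The per-class `accu_y`
#' column is that class's recall-style tally (fraction of the class's own
#' members recovered); the overall accuracy (identical for both rows) is
#' reported separately as `overall_accuracy` to avoid ambiguity.
#'
#' @param y_true,y_pred Two-class label vectors.
#' @return Object of class `metrics_report`: `per_class` data frame (rows =
#'   classes + Average; columns accu_y, prec_n, reca_l, f_measure, mcc,
#'   kappa, as proportions), `overall_accuracy`, `degenerate` flag.
#' @export
macro_report <- function(y_true, y_pred) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)), decreasing = TRUE)  # presence first
  degenerate <- length(unique(y_true)) < 2 || length(classes) < 2
  rows <- lapply(classes, function(cl) {
    m <- class_metrics(confusion_counts(y_true, y_pred, positive = cl))
    data.frame(class = cl,
               accu_y = as.numeric(m$recall),  # per-class tally (see docs)
               prec_n = as.numeric(m$precision), reca_l = as.numeric(m$recall),
               f_measure = as.numeric(m$f_measure), mcc = as.numeric(m$mcc),
               kappa = as.numeric(m$kappa), stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  avg <- data.frame(class = "Average", t(colMeans(per_class[, -1])))
  names(avg) <- names(per_class)
  overall <- mean(y_true == y_pred)
  structure(list(per_class = rbind(per_class, avg),
                 overall_accuracy = overall, degenerate = degenerate),
            class = "metrics_report")
}

#' Format a metrics report as percentages
#'
#' Rates scaled to percent and rounded half-up to two decimals, in the
#' conventional column order (accu_y, prec_n, reca_l, f_measure, MCC,
#' kappa).
#'
#' @param report A `metrics_report`.
#' @return Data frame of formatted percentages.
#' @export
report_percent <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  df <- report$per_class
  df[-1] <- lapply(df[-1], function(v) round_half_up(100 * v, 2))
  df
}

#' @export
print.metrics_report <- function(x, ...) {
  df <- report_percent(x)
  cat("Classification report (%):\n")
  print(format(df, nsmall = 2), row.names = FALSE)
  cat(sprintf("Overall accuracy: %.2f%%\n", round_half_up(100 * x$overall_accuracy, 2)))
  if (x$degenerate) cat("[degenerate: single-class truth vector]\n")
  invisible(x)
}

#' Write a metrics report to JSON
#'
#' @param report A `metrics_report`.
#' @param path Output file; if `NULL` the JSON string is returned.
#' @export
report_to_json <- function(report, path = NULL) {
  doc <- list(per_class = report_percent(report),
              overall_accuracy_percent = round_half_up(100 * report$overall_accuracy, 2),
              degenerate = report$degenerate)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}
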