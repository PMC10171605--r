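# Confusion matrices and the per-class diagnostics reported for coding
# validation: sensitivity/recall, precision/PPV, specificity, NPV, overall
# accuracy (trace/total) and macro recall (unweighted mean per-class recall).
#
# Orientation convention throughout: rows = predicted category, columns =
# true category, both ordered by the codebook.

#' Build a confusion matrix
#'
#' @param predicted character vector of predicted categories.
#' @param truth character vector of true categories, same length.
#' @param codebook a [codebook()]; defines row/column order.
#' @return a K x K integer matrix of class `confusion_matrix`
#'   (rows = predicted, columns = truth).
#' @export
confusion <- function(predicted, truth, codebook) {
  stopifnot(inherits(codebook, "hitl_codebook"))
  if (length(predicted) != length(truth)) stop("predicted and truth differ in length")
  if (!length(predicted)) stop("cannot build a confusion matrix from zero pairs")
  cats <- codebook$categories
  bad <- setdiff(unique(c(predicted, truth)), cats)
  if (length(bad)) stop("label(s) outside the codebook: ",
                        paste(utils::head(bad, 3), collapse = ", "))
  m <- table(factor(predicted, levels = cats), factor(truth, levels = cats))
  m <- matrix(as.integer(m), nrow = length(cats),
              dimnames = list(predicted = cats, truth = cats))
  structure(m, class = c("confusion_matrix", "matrix"), codebook = codebook)
}

#' Construct a confusion matrix directly from counts
#'
#' Convenience for entering published validation tables.
#'
#' @param counts K x K matrix or row-wise vector of counts
#'   (rows = predicted, columns = truth).
#' @param codebook a [codebook()].
#' @return a `confusion_matrix`.
#' @export
confusion_from_counts <- function(counts, codebook) {
  cats <- codebook$categories
  m <- matrix(as.integer(counts), nrow = length(cats), byrow = is.null(dim(counts)),
              dimnames = list(predicted = cats, truth = cats))
  if (any(m < 0)) stop("confusion counts must be non-negative")
  structure(m, class = c("confusion_matrix", "matrix"), codebook = codebook)
}

#' Overall accuracy (trace / total)
#'
#' @param m a `confusion_matrix`.
#' @return fraction of cases on the diagonal.
#' @export
overall_accuracy <- function(m) {
  tot <- sum(m)
  if (tot == 0) stop("empty confusion matrix")
  sum(diag(unclass(m))) / tot
}

#' Macro recall (unweighted mean per-class recall)
#'
#' Classes absent from the truth margin have undefined recall and are
#' excluded from the mean; their names are attached as the
#' `undefined_classes` attribute.
#'
#' @param m a `confusion_matrix`.
#' @return fraction in [0, 1].
#' @export
macro_recall <- function(m) {
  pc <- per_class_metrics(m)$per_class
  undef <- pc$class[is.na(pc$recall)]
  structure(mean(pc$recall, na.rm = TRUE), undefined_classes = undef)
}

#' Per-class diagnostics
#'
#' For class c with TP the diagonal entry, FP the rest of its predicted row,
#' FN the rest of its truth column and TN the remainder:
#' recall = TP/(TP+FN), precision = TP/(TP+FP), specificity = TN/(TN+FP),
#' npv = TN/(TN+FN).  Division by zero yields `NA` (undefined), never an
#' error.
#'
#' @param m a `confusion_matrix`.
#' @return a list of class `metrics_report` with `overall_accuracy`,
#'   `macro_recall`, a `per_class` data frame (recall, precision,
#'   specificity, npv, row_total, col_total) and `total`.
#' @export
per_class_metrics <- function(m) {
  mm <- unclass(m)
  tp <- diag(mm)
  row_tot <- rowSums(mm)
  col_tot <- colSums(mm)
  tot <- sum(mm)
  if (tot == 0) stop("empty confusion matrix")
  fp <- row_tot - tp
  fn <- col_tot - tp
  tn <- tot - row_tot - col_tot + tp
  sdiv <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  pc <- data.frame(class = rownames(mm),
                   recall = sdiv(tp, tp + fn),
                   precision = sdiv(tp, tp + fp),
                   specificity = sdiv(tn, tn + fp),
                   npv = sdiv(tn, tn + fn),
                   row_total = row_tot, col_total = col_tot,
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(overall_accuracy = sum(tp) / tot,
                 macro_recall = mean(pc$recall, na.rm = TRUE),
                 per_class = pc, total = tot),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("overall accuracy %.3f | macro recall %.3f | n = %d\n",
              x$overall_accuracy, x$macro_recall, x$total))
  print(cbind(x$per_class[1],
              round(x$per_class[c("recall", "precision", "specificity", "npv")], 3),
              x$per_class[c("row_total", "col_total")]), row.names = FALSE)
  invisible(x)
}

#' Render a validation report table
#'
#' Emits the standard validation layout: predicted rows by truth columns
#' with TOTAL margins, per-row PPV, per-column specificity and NPV (rounded
#' half-up to 2 decimals), and the overall accuracy line.
#'
#' @param m a `confusion_matrix`.
#' @param style `"text"` for an aligned table or `"csv"`.
#' @return character vector of lines.
#' @export
render_report <- function(m, style = c("text", "csv")) {
  style <- match.arg(style)
  rep <- per_class_metrics(m)
  pc <- rep$per_class
  cats <- pc$class
  fmt2 <- function(v) ifelse(is.na(v), "", sprintf("%.2f", round_half_up(v, 2)))
  body <- cbind(as.data.frame(unclass(m)), TOTAL = pc$row_total,
                PPV = fmt2(pc$precision))
  total_row <- c(pc$col_total, rep$total, "")
  spec_row <- c(fmt2(pc$specificity), "", "")
  npv_row <- c(fmt2(pc$npv), "", "")
  acc_line <- sprintf("Accuracy = %.3f", rep$overall_accuracy)
  if (style == "csv") {
    lines <- c(paste(c("predicted", cats, "TOTAL", "PPV"), collapse = ","),
               vapply(seq_along(cats), function(i)
                 paste(c(cats[i], unlist(body[i, ])), collapse = ","), ""),
               paste(c("TOTAL", total_row), collapse = ","),
               paste(c("Specificity", spec_row), collapse = ","),
               paste(c("NPV", npv_row), collapse = ","),
               paste0("Accuracy,", sprintf("%.3f", rep$overall_accuracy)))
    return(lines)
  }
  tab <- rbind(as.matrix(format(body)),
               TOTAL = format(total_row),
               Specificity = format(spec_row),
               NPV = format(npv_row))
  rownames(tab) <- c(cats, "TOTAL", "Specificity", "NPV")
  w <- max(nchar(c(rownames(tab), "predicted")))
  header <- paste0(formatC("", width = w), "  ",
                   paste(formatC(colnames(tab), width = 12), collapse = " "))
  lines <- c("rows = predicted, columns = truth", header,
             vapply(seq_len(nrow(tab)), function(i)
               paste0(formatC(rownames(tab)[i], width = w, flag = "-"), "  ",
                      paste(formatC(tab[i, ], width = 12), collapse = " ")), ""),
             acc_line)
  lines
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(paste(render_report(x, "text"), collapse = "\n"), "\n")
  invisible(x)
}

#' Assemble a learning curve from a session trajectory
#'
#' Long format: one row per (round, metric, class); overall metrics carry
#' class `NA`.
#'
#' @param session an `hitl_session` from [run_session()].
#' @return a data frame with columns `round`, `n_labelled`, `metric`,
#'   `class`, `value`.
#' @export
learning_curve <- function(session) {
  stopifnot(inherits(session, "hitl_session"))
  tr <- session$trajectory
  if (!nrow(tr)) {
    return(data.frame(round = integer(0), n_labelled = integer(0),
                      metric = character(0), class = character(0),
                      value = numeric(0)))
  }
  overall <- do.call(rbind, lapply(c("overall_accuracy", "macro_recall"), function(met)
    data.frame(round = tr$round, n_labelled = tr$n_labelled, metric = met,
               class = NA_character_, value = tr[[met]],
               stringsAsFactors = FALSE)))
  pc <- session$per_class
  long <- do.call(rbind, lapply(c("recall", "precision", "specificity", "npv"),
    function(met) data.frame(round = pc$round, n_labelled = pc$n_labelled,
                             metric = met, class = pc$class, value = pc[[met]],
                             stringsAsFactors = FALSE)))
  rbind(overall, long)
}
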