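# Evaluation metrics: top-N accuracy and micro/macro F1 with rare-class
# aggregation into an "Other" class.

#' Top-N accuracy of ranked predictions
#'
#' Fraction of targets whose true state appears among the first N ranked
#' states.
#'
#' @param predictions List of [ranked_prediction()] tables.
#' @param truths List (or character vector) of true states, aligned with
#'   `predictions`.
#' @param N Rank cutoff (>= 1).
#' @return A fraction in `[0, 1]`.
#' @export
top_n_accuracy <- function(predictions, truths, N = 1L) {
  if (length(predictions) != length(truths)) {
    stop("predictions and truths must have equal length")
  }
  if (N < 1L) stop("N must be >= 1")
  if (!is.character(truths)) {
    truths <- vapply(truths, format_stoich, character(1))
  }
  hits <- vapply(seq_along(truths), function(i) {
    rp <- predictions[[i]]
    truths[i] %in% rp$stoichiometry[seq_len(min(N, nrow(rp)))]
  }, logical(1))
  mean(hits)
}

f1_from_confusion <- function(pred, truth, classes) {
  vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

#' Micro- and macro-F1 for single-label multiclass predictions
#'
#' Micro-F1 is computed over all classes without aggregation (for
#' single-label multiclass data it coincides with plain accuracy).  For
#' macro-F1, classes whose true-instance count is below `min_class_count`
#' are first relabeled `"Other"` (in both truth and prediction) so that
#' very rare classes do not dominate the macro average; `min_class_count =
#' 0` disables aggregation (appropriate for small benchmark sets).
#'
#' @param pred_labels Character vector of predicted class labels.
#' @param true_labels Character vector of true class labels.
#' @param min_class_count Aggregation threshold on true-label counts.
#' @return List with `micro`, `macro`, and `per_class` (named F1 per
#'   post-aggregation class, most frequent first).
#' @export
micro_macro_f1 <- function(pred_labels, true_labels, min_class_count = 10L) {
  if (!length(true_labels)) stop("empty evaluation set")
  if (length(pred_labels) != length(true_labels)) {
    stop("label vectors must have equal length")
  }
  pred_labels <- as.character(pred_labels)
  true_labels <- as.character(true_labels)
  # micro over all classes, no aggregation: for single-label data,
  # pooled TP = #correct and pooled FP = FN = #wrong, hence accuracy
  micro <- mean(pred_labels == true_labels)
  counts <- table(true_labels)
  rare <- names(counts)[counts < min_class_count]
  pred_agg <- ifelse(pred_labels %in% rare, "Other", pred_labels)
  true_agg <- ifelse(true_labels %in% rare, "Other", true_labels)
  classes <- unique(c(true_agg, pred_agg))
  agg_counts <- table(true_agg)
  ord <- order(-as.integer(agg_counts[classes]), classes, method = "radix",
               na.last = TRUE)
  classes <- classes[ord]
  per_class <- f1_from_confusion(pred_agg, true_agg, classes)
  names(per_class) <- classes
  list(micro = micro, macro = mean(per_class), per_class = per_class)
}

#' Full evaluation report for ranked predictions
#'
#' Combines top-N accuracy (separately for homomers and heteromers) with
#' micro/macro F1 over top-1 composition labels (entity-agnostic, so A2B3
#' and B3A2 count as the same class).
#'
#' @inheritParams top_n_accuracy
#' @param n_values N values for the top-N curves.
#' @param min_class_count Rare-class aggregation threshold for macro-F1.
#' @return List with `accuracy`, `micro_f1`, `macro_f1`, `per_class_f1`,
#'   and `top_n` (a `data.frame` with homomer/heteromer/overall columns).
#' @export
evaluation_report <- function(predictions, truths, n_values = 1:5,
                              min_class_count = 10L) {
  if (!is.character(truths)) {
    truths <- vapply(truths, format_stoich, character(1))
  }
  true_copies <- lapply(truths, parse_stoich)
  is_homo <- vapply(true_copies, length, integer(1)) == 1L
  top1 <- vapply(predictions, function(rp) rp$stoichiometry[1L], character(1))
  pred_lab <- vapply(top1, function(s) composition_label(parse_stoich(s)),
                     character(1))
  true_lab <- vapply(true_copies, composition_label, character(1))
  f1 <- micro_macro_f1(pred_lab, true_lab, min_class_count)
  top_n <- data.frame(
    N = n_values,
    overall = vapply(n_values, function(N) {
      top_n_accuracy(predictions, truths, N)
    }, numeric(1)),
    homomer = vapply(n_values, function(N) {
      if (!any(is_homo)) NA_real_ else {
        top_n_accuracy(predictions[is_homo], truths[is_homo], N)
      }
    }, numeric(1)),
    heteromer = vapply(n_values, function(N) {
      if (all(is_homo)) NA_real_ else {
        top_n_accuracy(predictions[!is_homo], truths[!is_homo], N)
      }
    }, numeric(1))
  )
  list(accuracy = mean(top1 == truths),
       micro_f1 = f1$micro, macro_f1 = f1$macro,
       per_class_f1 = f1$per_class, top_n = top_n)
}
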