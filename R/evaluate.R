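#' Threshold probability scores into class labels
#'
#' A peptide is called positive only when its score STRICTLY exceeds the
#' threshold; a score exactly at the threshold is negative.
#'
#' @param scores numeric scores in \[0, 1\] (optionally named by id).
#' @param threshold decision threshold (default 0.5).
#' @return integer 0/1 vector with the same names.
#' @examples
#' threshold_predictions(c(0.4, 0.5, 0.51))  # 0 0 1
#' @export
threshold_predictions <- function(scores, threshold = 0.5) {
  if (any(scores < 0 | scores > 1)) abort("Scores must lie in [0, 1].")
  setNames(as.integer(scores > threshold), names(scores))
}

#' Confusion counts
#'
#' @param truth integer 0/1 ground-truth labels.
#' @param predicted integer 0/1 predicted labels (same length/order).
#' @return a tibble with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  tibble(tp = sum(truth == 1 & predicted == 1),
         tn = sum(truth == 0 & predicted == 0),
         fp = sum(truth == 0 & predicted == 1),
         fn = sum(truth == 1 & predicted == 0))
}

#' Matthews correlation coefficient
#'
#' MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)), the
#' balanced binary-classification metric robust to class imbalance. When
#' any marginal factor is zero the denominator vanishes and the value is 0
#' by the standard convention (no better than chance). Equals the Pearson
#' correlation of the 0/1 truth and prediction vectors.
#'
#' @param tp,tn,fp,fn confusion counts, or a single-row data frame of them
#'   passed as `tp`.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    c0 <- tp; tp <- c0$tp; tn <- c0$tn; fp <- c0$fp; fn <- c0$fn
  }
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  # products can exceed integer range on large sets; compute in doubles
  (as.double(tp) * tn - as.double(fp) * fn) / sqrt(as.double(denom2))
}

mcc_score <- function(truth, predicted) {
  mcc(confusion_counts(truth, predicted))
}

binary_metrics <- function(truth, scores, threshold = 0.5) {
  predicted <- threshold_predictions(scores, threshold)
  cc <- confusion_counts(truth, predicted)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(
    mcc = mcc(cc),
    accuracy = safe_div(cc$tp + cc$tn, sum(unlist(cc))),
    precision = safe_div(cc$tp, cc$tp + cc$fp),
    recall = safe_div(cc$tp, cc$tp + cc$fn),
    specificity = safe_div(cc$tn, cc$tn + cc$fp),
    auroc = auroc(truth, scores),
    confusion = cc
  )
}

# Rank-based AUROC (equivalent to the Mann-Whitney U statistic); ties get
# midranks. NA when a class is absent.
auroc <- function(truth, scores) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Evaluate an ensemble on a held-out test set
#'
#' Computes MCC (headline), accuracy, precision, recall, specificity and
#' AUROC at the 0.5 threshold, together with the interdependence of the
#' actual train/test split as a leakage diagnostic. The test set must be
#' disjoint from the ensemble's recorded training ids; any overlap is an
#' evaluation-leakage error, not a warning.
#'
#' @param ensemble a `peptide_ensemble`.
#' @param test a labeled peptide tibble of held-out peptides.
#' @param backend the embedding backend the ensemble was trained with.
#' @param graph optional [similarity_graph()] over train + test ids, used
#'   to report the split's interdependence.
#' @param threshold decision threshold (default 0.5).
#' @return an object of class `evaluation_report`.
#' @export
evaluate_split <- function(ensemble, test, backend = backend_onehot(),
                           graph = NULL, threshold = 0.5) {
  test <- validate_peptides(test, require_labels = TRUE)
  overlap <- intersect(test$id, ensemble$train_ids)
  if (length(overlap)) {
    abort(paste0("Evaluation leakage: test id(s) present in the training ",
                 "set: ", paste(head(overlap, 5), collapse = ", ")))
  }
  emb <- pep_embed(test, backend)
  preds <- predict(ensemble, emb)
  truth <- setNames(test$label, test$id)[preds$id]
  m <- binary_metrics(truth, setNames(preds$score, preds$id), threshold)

  interdep <- if (!is.null(graph)) {
    split <- new_split(ensemble$train_ids, test$id,
                       ensemble$folds, "recorded", list())
    interdependence(split, graph)
  } else {
    NA_real_
  }
  guidance <- c(
    sprintf("Headline metric is MCC at threshold %.2f; 0 is chance level, 1 is perfect.", threshold),
    if (!is.na(interdep) && interdep == 0) {
      "Train/test interdependence is 0%: no test peptide is similar to any training peptide, so the MCC estimates generalization to novel sequences."
    } else if (!is.na(interdep)) {
      sprintf("Train/test interdependence is %.1f%%: similar sequences cross the split, so the MCC likely overestimates performance on novel peptides (no homology correction).", 100 * interdep)
    } else {
      "Interdependence not computed (no similarity graph supplied)."
    }
  )
  structure(
    list(metrics = m[c("mcc", "accuracy", "precision", "recall",
                       "specificity", "auroc")],
         confusion = m$confusion, threshold = threshold,
         interdependence = interdep,
         n_test = nrow(test), n_train = length(ensemble$train_ids),
         backend = ensemble$backend, guidance = guidance,
         predictions = dplyr::left_join(
           preds, tibble(id = test$id, label = test$label), by = "id")),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n_test=%d, threshold=%.2f\n",
              x$n_test, x$threshold))
  for (m in names(x$metrics)) {
    cat(sprintf("  %-12s %s\n", m,
                formatC(x$metrics[[m]], digits = 4, format = "f")))
  }
  if (!is.na(x$interdependence)) {
    cat(sprintf("  interdependence %.1f%%\n", 100 * x$interdependence))
  }
  invisible(x)
}

#' @rdname tidy_peptideml
#' @export
glance.evaluation_report <- function(x, ...) {
  dplyr::bind_cols(as_tibble(x$metrics), x$confusion,
                   tibble(threshold = x$threshold,
                          interdependence = x$interdependence,
                          n_test = x$n_test, n_train = x$n_train))
}

#' Render an evaluation report to JSON or markdown
#'
#' JSON is lossless (metrics, confusion counts, provenance, per-peptide
#' predictions); markdown is a human-readable summary with the metric
#' table, split provenance and plain-language guidance.
#'
#' @param report an `evaluation_report`.
#' @param path output file path.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(schema = "peptideml_report_v1",
           metrics = report$metrics, confusion = as.list(report$confusion),
           threshold = report$threshold,
           interdependence = report$interdependence,
           n_test = report$n_test, n_train = report$n_train,
           backend = report$backend, guidance = report$guidance,
           predictions = report$predictions),
      path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  } else {
    lines <- c(
      "# Peptide bioactivity model evaluation", "",
      sprintf("- Test peptides: %d (training: %d)", report$n_test,
              report$n_train),
      sprintf("- Decision threshold: %.2f", report$threshold),
      sprintf("- Representation backend: %s", report$backend), "",
      "| metric | value |", "|---|---|",
      vapply(names(report$metrics), function(m) {
        sprintf("| %s | %.4f |", ifelse(m == "mcc", "MCC", m),
                report$metrics[[m]])
      }, ""), "",
      "## Guidance", "",
      paste0("- ", report$guidance))
    writeLines(lines, path)
  }
  invisible(path)
}
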