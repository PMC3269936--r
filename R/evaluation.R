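# Evaluation protocol: confusion counts, Acc/Spec/Sens/P/R/F, MCC,
# micro/macro precision/recall/F over (document, method) pairs, AUC of the
# interpolated precision/recall curve, per-method reports, and the paired
# t-test comparison of feature sets across cross-validation folds.

#' Binary confusion counts
#'
#' @param pred 0/1 predicted classes.
#' @param gold 0/1 gold labels, same length.
#' @return a one-row tibble `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_binary <- function(pred, gold) {
  if (length(pred) != length(gold)) {
    rlang::abort("confusion_binary(): pred and gold differ in length")
  }
  tibble::tibble(
    tp = sum(pred == 1L & gold == 1L),
    fp = sum(pred == 1L & gold == 0L),
    fn = sum(pred == 0L & gold == 1L),
    tn = sum(pred == 0L & gold == 0L)
  )
}

#' Accuracy, specificity, sensitivity, precision, recall and F-score
#'
#' A metric whose denominator is zero is reported as `NA` (undefined)
#' rather than silently 0. `tn` may be `NA` for pooled multi-label counts,
#' in which case accuracy and specificity are undefined.
#'
#' @param counts a confusion tibble/list with `tp`, `fp`, `fn` and
#'   optionally `tn`.
#' @return a one-row tibble `accuracy`, `specificity`, `sensitivity`,
#'   `precision`, `recall`, `f_score`.
#' @export
basic_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  tn <- if (!is.null(counts$tn)) counts$tn else NA_real_
  safe <- function(num, den) if (!is.na(den) && den > 0) num / den else NA_real_
  n <- tp + fp + fn + tn
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  tibble::tibble(
    accuracy = safe(tp + tn, n),
    specificity = safe(tn, tn + fp),
    sensitivity = recall,
    precision = precision,
    recall = recall,
    f_score = f
  )
}

#' Matthews correlation coefficient (phi coefficient)
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; 1 is perfect
#' prediction, 0 an average random one. When any factor of the denominator
#' is zero the MCC is defined as 0, so degenerate cross-validation folds
#' aggregate without error.
#'
#' @param counts confusion counts with `tp`, `fp`, `fn`, `tn`.
#' @return a number in \[-1, 1\].
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn); tn <- as.numeric(counts$tn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Micro-averaged precision/recall/F over prediction pairs
#'
#' Pools all (document, method) pairs: `tp` are predicted pairs present in
#' the gold, `fp` predicted-only, `fn` gold-only.
#'
#' @param predictions tibble with `doc_id`, `method_id` (extra columns
#'   ignored).
#' @param gold tibble with `doc_id`, `method_id`.
#' @return one-row tibble `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_score`.
#' @export
micro_prf <- function(predictions, gold) {
  p <- dplyr::distinct(predictions[, c("doc_id", "method_id")])
  g <- dplyr::distinct(gold[, c("doc_id", "method_id")])
  tp <- nrow(dplyr::semi_join(p, g, by = c("doc_id", "method_id")))
  fp <- nrow(p) - tp
  fn <- nrow(g) - tp
  m <- basic_metrics(list(tp = tp, fp = fp, fn = fn))
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = m$precision, recall = m$recall,
                 f_score = m$f_score)
}

#' Macro-averaged (per-document) precision/recall/F
#'
#' Per-document precision, recall and F are averaged over the documents
#' with non-empty gold; a document with no predictions scores precision 0.
#'
#' @inheritParams micro_prf
#' @return one-row tibble `precision`, `recall`, `f_score`, `n_docs`.
#' @export
macro_prf <- function(predictions, gold) {
  g <- dplyr::distinct(gold[, c("doc_id", "method_id")])
  if (nrow(g) == 0L) {
    rlang::abort("macro_prf(): no documents with non-empty gold")
  }
  p <- dplyr::distinct(predictions[, c("doc_id", "method_id")])
  per_doc <- purrr::map(unique(g$doc_id), function(d) {
    gd <- g$method_id[g$doc_id == d]
    pd <- p$method_id[p$doc_id == d]
    tp <- length(intersect(pd, gd))
    prec <- if (length(pd) > 0L) tp / length(pd) else 0
    rec <- tp / length(gd)
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(doc_id = d, precision = prec, recall = rec, f_score = f)
  }) |> dplyr::bind_rows()
  tibble::tibble(
    precision = mean(per_doc$precision),
    recall = mean(per_doc$recall),
    f_score = mean(per_doc$f_score),
    n_docs = nrow(per_doc)
  )
}

# AUC of the interpolated P/R curve for one ranked 0/1 relevance vector
ipr_auc_walk <- function(is_hit, n_gold) {
  if (n_gold == 0L) rlang::abort("auc_ipr(): empty gold")
  if (length(is_hit) == 0L || !any(is_hit)) return(0)
  ranks <- seq_along(is_hit)
  prec_at <- cumsum(is_hit) / ranks
  hit_prec <- prec_at[is_hit]
  # interpolated precision at the i-th retrieved positive: max precision at
  # that or any later retrieved positive (i.e. any recall >= its recall)
  interp <- rev(cummax(rev(hit_prec)))
  sum(interp) / n_gold
}

#' Area under the interpolated precision/recall curve
#'
#' Walks the predictions ranked by confidence (ties broken by method id
#' then document id); at each retrieved gold pair the precision is
#' recorded, interpolated precision at recall r is the maximum precision
#' at any recall at or above r, and the AUC is the mean interpolated
#' precision over all gold positives (so positives never retrieved
#' contribute 0). `scope = "micro"` pools all pairs in one ranked list;
#' `scope = "macro"` averages per-document AUCs over documents with
#' non-empty gold.
#'
#' @param predictions tibble `doc_id`, `method_id`, `confidence`.
#' @param gold tibble `doc_id`, `method_id`.
#' @param scope `"micro"` or `"macro"`.
#' @return a number in \[0, 1\].
#' @export
auc_ipr <- function(predictions, gold, scope = c("micro", "macro")) {
  scope <- match.arg(scope)
  g <- dplyr::distinct(gold[, c("doc_id", "method_id")])
  if (nrow(g) == 0L) rlang::abort("auc_ipr(): empty gold")
  p <- predictions |>
    dplyr::distinct(.data$doc_id, .data$method_id, .keep_all = TRUE) |>
    dplyr::arrange(dplyr::desc(.data$confidence), .data$method_id,
                   .data$doc_id)
  gold_key <- paste(g$doc_id, g$method_id)
  if (scope == "micro") {
    is_hit <- paste(p$doc_id, p$method_id) %in% gold_key
    return(ipr_auc_walk(is_hit, nrow(g)))
  }
  aucs <- vapply(unique(g$doc_id), function(d) {
    pd <- p[p$doc_id == d, , drop = FALSE]
    gd <- g$method_id[g$doc_id == d]
    ipr_auc_walk(pd$method_id %in% gd, length(gd))
  }, numeric(1))
  mean(aucs)
}

# document-ranking AUC iP/R for the binary article task: rank documents by
# value descending, positives are the class-1 documents
act_auc_ipr <- function(values, labels) {
  if (sum(labels == 1L) == 0L) return(NA_real_)
  ord <- order(-values)
  ipr_auc_walk(labels[ord] == 1L, sum(labels == 1L))
}

#' Full report for the article-classification task
#'
#' @param values classifier values per document.
#' @param labels gold 0/1 labels, aligned.
#' @param dth discretization threshold applied.
#' @return one-row tibble mirroring the run-table columns: `accuracy`,
#'   `specificity`, `sensitivity`, `f_score`, `mcc`, `auc_ipr`, `dth` plus
#'   the confusion counts.
#' @export
act_report <- function(values, labels, dth = 0.5) {
  cls <- act_decide(values, dth)
  cc <- confusion_binary(cls, labels)
  bm <- basic_metrics(cc)
  tibble::tibble(
    accuracy = bm$accuracy, specificity = bm$specificity,
    sensitivity = bm$sensitivity, f_score = bm$f_score,
    mcc = mcc(cc), auc_ipr = act_auc_ipr(values, labels), dth = dth,
    tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn
  )
}

#' Full report for the method-detection task
#'
#' @param predictions ranked predictions tibble (`doc_id`, `method_id`,
#'   `confidence`).
#' @param gold gold pairs tibble.
#' @return one-row tibble with evaluated-result and confusion counts,
#'   micro and macro P/R/F and micro/macro AUC iP/R.
#' @export
imt_report <- function(predictions, gold) {
  mi <- micro_prf(predictions, gold)
  ma <- macro_prf(predictions, gold)
  tibble::tibble(
    evaluated = nrow(dplyr::distinct(
      predictions[, c("doc_id", "method_id")])),
    tp = mi$tp, fp = mi$fp, fn = mi$fn,
    micro_p = mi$precision, micro_r = mi$recall, micro_f = mi$f_score,
    micro_auc_ipr = auc_ipr(predictions, gold, "micro"),
    macro_p = ma$precision, macro_r = ma$recall, macro_f = ma$f_score,
    macro_auc_ipr = auc_ipr(predictions, gold, "macro")
  )
}

#' Per-method performance breakdown
#'
#' One row per gold method: gold frequency, precision and recall of the
#' full prediction output, and of the output cut at a rank threshold.
#'
#' @param predictions ranked predictions tibble (with `rank`).
#' @param gold gold pairs tibble.
#' @param rank_threshold rank cut for the thresholded columns (default 5).
#' @return tibble `method_id`, `n_gold`, `precision`, `recall`,
#'   `precision_thr`, `recall_thr`.
#' @export
per_method_report <- function(predictions, gold, rank_threshold = 5L) {
  g <- dplyr::distinct(gold[, c("doc_id", "method_id")])
  one <- function(preds) {
    purrr::map(sort(unique(g$method_id)), function(m) {
      pm <- preds[preds$method_id == m, , drop = FALSE]
      gm <- g[g$method_id == m, , drop = FALSE]
      tp <- nrow(dplyr::semi_join(pm, gm, by = c("doc_id", "method_id")))
      tibble::tibble(
        method_id = m, n_gold = nrow(gm),
        precision = if (nrow(pm) > 0L) tp / nrow(pm) else NA_real_,
        recall = tp / nrow(gm)
      )
    }) |> dplyr::bind_rows()
  }
  full <- one(predictions)
  thr <- one(predictions[predictions$rank <= rank_threshold, , drop = FALSE])
  dplyr::left_join(
    full,
    dplyr::rename(thr[, c("method_id", "precision", "recall")],
                  precision_thr = "precision", recall_thr = "recall"),
    by = "method_id"
  )
}

#' Paired t-test comparison of two feature sets across CV folds
#'
#' One-sided paired t-test (is system A better than system B?) on the
#' per-fold metric values, with df = n - 1. `ei` is the minimally expected
#' improvement: the lower bound of the one-sided 95% confidence interval
#' of the mean difference. Per-system two-sided 95% confidence intervals
#' use separately estimated variances with the Welch modification to the
#' degrees of freedom, and the Shapiro-Wilk normality statistic of the
#' differences is reported alongside.
#'
#' @param metric_a,metric_b per-fold metric values (equal length, paired).
#' @param conf_level confidence level (default 0.95).
#' @return one-row tibble `p_value`, `ei`, `mean_diff`, `ci_a_lower`,
#'   `ci_a_upper`, `ci_b_lower`, `ci_b_upper`, `shapiro_w`, `shapiro_p`,
#'   `degenerate`.
#' @export
paired_feature_test <- function(metric_a, metric_b, conf_level = 0.95) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 2L)
  d <- metric_a - metric_b
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    p <- if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5
    ei <- mean(d)
  } else {
    tt <- stats::t.test(metric_a, metric_b, paired = TRUE,
                        alternative = "greater",
                        conf.level = conf_level)
    p <- tt$p.value
    ei <- tt$conf.int[1]
  }
  ci <- function(x) {
    # two-sided CI with the system's own variance (Welch-style df treatment
    # reduces to the one-sample df here)
    tt <- stats::t.test(x, conf.level = conf_level)
    c(tt$conf.int[1], tt$conf.int[2])
  }
  ca <- ci(metric_a); cb <- ci(metric_b)
  sw <- tryCatch(stats::shapiro.test(d),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  tibble::tibble(
    p_value = p, ei = ei, mean_diff = mean(d),
    ci_a_lower = ca[1], ci_a_upper = ca[2],
    ci_b_lower = cb[1], ci_b_upper = cb[2],
    shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
    degenerate = degenerate
  )
}
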