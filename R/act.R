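# Binary curatable-article classification: feature groups W (bag of stems,
# cumulative count encoding), M (MeSH expansion), B (stem bigrams), an
# L2-regularised logistic (maximum-entropy) classifier with probabilistic
# output, DTH decision/confidence rules, DTH and percentile tuning,
# oversampling and stratified cross-validation.

#' Bag-of-stems features with cumulative count encoding
#'
#' Every stem occurring `c` times in a document yields the indicator
#' features `"stem 1"`, ..., `"stem c"`, so feature weights can react to
#' repetition, not just presence. Text defaults to title plus body.
#'
#' @param docs documents tibble.
#' @param text_fields which text columns to concatenate (default
#'   `c("title", "body")`).
#' @return a long feature tibble `doc_id`, `feature`.
#' @examples
#' docs <- tibble::tibble(doc_id = "d1", title = "",
#'                        body = "protein protein protein",
#'                        mesh = list(character()))
#' extract_bow_features(docs)
#' @export
extract_bow_features <- function(docs, text_fields = c("title", "body")) {
  texts <- do.call(paste, docs[text_fields])
  rows <- purrr::map2(docs$doc_id, texts, function(id, txt) {
    toks <- cm_tokenize(txt)
    if (nrow(toks) == 0L) return(NULL)
    cnt <- table(toks$stem)
    feats <- unlist(purrr::map2(names(cnt), as.integer(cnt), function(s, c) {
      paste(s, seq_len(c))
    }), use.names = FALSE)
    tibble::tibble(doc_id = id, feature = feats)
  })
  bind_feature_rows(rows)
}

#' MeSH descriptor/qualifier expansion features
#'
#' For each parsed MeSH string the following indicator features are
#' emitted: the descriptor joined with each qualifier
#' (`"signal/transduction/drug/effects"`), the descriptor alone
#' (`"signal/transduction"`), every suffix of a multi-word descriptor
#' obtained by iteratively removing the first word (`"transduction"`), and
#' each signed qualifier on its own (`"-drug/effects"`, `"+physiology"`).
#'
#' @param docs documents tibble with a `mesh` list-column of raw strings.
#' @return a long feature tibble `doc_id`, `feature`.
#' @export
extract_mesh_features <- function(docs) {
  rows <- purrr::map2(docs$doc_id, docs$mesh, function(id, lines) {
    if (length(lines) == 0L) return(NULL)
    feats <- unlist(lapply(lines, mesh_term_features), use.names = FALSE)
    if (length(feats) == 0L) return(NULL)
    tibble::tibble(doc_id = id, feature = unique(feats))
  })
  bind_feature_rows(rows)
}

# feature strings for one raw MeSH line
mesh_term_features <- function(line) {
  mt <- parse_mesh_line(line)
  d <- mt$descriptor
  feats <- character()
  for (q in mt$qualifiers) {
    feats <- c(feats, paste(c(d, q$words), collapse = "/"))
  }
  feats <- c(feats, paste(d, collapse = "/"))
  if (length(d) > 1L) {
    for (k in 2:length(d)) {
      feats <- c(feats, paste(d[k:length(d)], collapse = "/"))
    }
  }
  for (q in mt$qualifiers) {
    feats <- c(feats, paste0(q$sign, paste(q$words, collapse = "/")))
  }
  feats
}

#' Bigram features over a training-defined vocabulary
#'
#' `build_bigram_vocab()` counts stem bigrams over the training documents
#' and keeps those occurring at least `min_count` times (default 3).
#' `extract_bigram_features()` emits one indicator per document bigram
#' present in that vocabulary, so test-only bigrams can never become
#' features.
#'
#' @param docs documents tibble.
#' @param min_count minimum total training count (default 3).
#' @param text_fields text columns to use.
#' @return `build_bigram_vocab()`: tibble `w1`, `w2`, `n`;
#'   `extract_bigram_features()`: long feature tibble `doc_id`, `feature`.
#' @export
build_bigram_vocab <- function(docs, min_count = 3L,
                               text_fields = c("title", "body")) {
  texts <- do.call(paste, docs[text_fields])
  bg <- purrr::map(texts, function(txt) cm_bigrams(cm_tokenize(txt)$stem))
  bg <- dplyr::bind_rows(bg)
  if (nrow(bg) == 0L) {
    return(tibble::tibble(w1 = character(), w2 = character(), n = integer()))
  }
  dplyr::count(bg, .data$w1, .data$w2, name = "n") |>
    dplyr::filter(.data$n >= min_count)
}

#' @rdname build_bigram_vocab
#' @param vocab a vocabulary tibble from `build_bigram_vocab()` (built on
#'   the training split only).
#' @export
extract_bigram_features <- function(docs, vocab,
                                    text_fields = c("title", "body")) {
  texts <- do.call(paste, docs[text_fields])
  rows <- purrr::map2(docs$doc_id, texts, function(id, txt) {
    bg <- cm_bigrams(cm_tokenize(txt)$stem)
    if (nrow(bg) == 0L) return(NULL)
    hit <- dplyr::semi_join(dplyr::distinct(bg), vocab, by = c("w1", "w2"))
    if (nrow(hit) == 0L) return(NULL)
    tibble::tibble(doc_id = id, feature = paste(hit$w1, hit$w2))
  })
  bind_feature_rows(rows)
}

bind_feature_rows <- function(rows) {
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(doc_id = character(), feature = character())
  }
  out
}

#' Assemble the feature table for a set of feature groups
#'
#' Runs the selected extractors and prefixes each feature name with its
#' group letter (`"W "`, `"M "`, `"B "`) so groups cannot collide.
#'
#' @param docs documents tibble.
#' @param groups subset of `c("W", "M", "B")`.
#' @param bigram_vocab required when `"B"` is in `groups`; build it on the
#'   training split with [build_bigram_vocab()].
#' @param text_fields text columns for W and B.
#' @return a long feature tibble `doc_id`, `feature`.
#' @export
act_features <- function(docs, groups = c("W", "M"), bigram_vocab = NULL,
                         text_fields = c("title", "body")) {
  stopifnot(all(groups %in% c("W", "M", "B")))
  parts <- list()
  if ("W" %in% groups) {
    f <- extract_bow_features(docs, text_fields)
    f$feature <- paste("W", f$feature)
    parts <- c(parts, list(f))
  }
  if ("M" %in% groups) {
    f <- extract_mesh_features(docs)
    if (nrow(f) > 0L) f$feature <- paste("M", f$feature)
    parts <- c(parts, list(f))
  }
  if ("B" %in% groups) {
    if (is.null(bigram_vocab)) {
      rlang::abort("act_features(): group B needs a bigram_vocab")
    }
    f <- extract_bigram_features(docs, bigram_vocab, text_fields)
    if (nrow(f) > 0L) f$feature <- paste("B", f$feature)
    parts <- c(parts, list(f))
  }
  bind_feature_rows(parts)
}

#' Train the maximum-entropy (logistic) classifier
#'
#' Binary maximum entropy over indicator features is equivalent to
#' logistic regression; the model maximises the L2-penalised
#' log-likelihood (penalty `l2/2 * ||w||^2`, bias unpenalised) with a
#' deterministic quasi-Newton optimiser (L-BFGS-B on the analytic
#' gradient), so retraining on the same data reproduces the same weights.
#'
#' @param features long feature tibble `doc_id`, `feature`.
#' @param labels tibble `doc_id`, `label` with labels 0/1 covering every
#'   training document (documents without features still contribute via the
#'   bias).
#' @param l2 L2 regularisation strength (default 1.0).
#' @param tolerance projected-gradient tolerance for convergence
#'   (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @param min_feature_count optional minimum number of training documents a
#'   feature must occur in (default 1, i.e. no filtering).
#' @return an object of class `cm_maxent` with elements `weights` (named
#'   numeric), `bias` and `meta`.
#' @export
train_maxent <- function(features, labels, l2 = 1.0, tolerance = 1e-6,
                         max_iter = 500L, min_feature_count = 1L) {
  y <- labels$label
  if (length(unique(y)) < 2L) {
    rlang::abort("train_maxent(): need both classes in the training data")
  }
  if (min_feature_count > 1L) {
    keep <- features |>
      dplyr::count(.data$feature) |>
      dplyr::filter(.data$n >= min_feature_count)
    features <- dplyr::semi_join(features, keep, by = "feature")
  }
  doc_ids <- labels$doc_id
  feats <- sort(unique(features$feature))
  p <- length(feats)
  di <- match(features$doc_id, doc_ids)
  fi <- match(features$feature, feats)
  ok <- !is.na(di)
  di <- di[ok]; fi <- fi[ok]
  n <- length(y)

  eta_of <- function(w, b) {
    eta <- rep(b, n)
    if (p > 0L && length(di) > 0L) {
      s <- rowsum(w[fi], di, reorder = FALSE)
      eta[as.integer(rownames(s))] <- eta[as.integer(rownames(s))] + s[, 1]
    }
    eta
  }
  negll <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    eta <- eta_of(w, b)
    # numerically stable log(1 + exp(.)) via plogis
    ll <- sum(y * stats::plogis(eta, log.p = TRUE) +
                (1 - y) * stats::plogis(-eta, log.p = TRUE))
    -ll + 0.5 * l2 * sum(w^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    mu <- stats::plogis(eta_of(w, b))
    r <- mu - y
    gw <- numeric(p)
    if (p > 0L && length(di) > 0L) {
      s <- rowsum(r[di], fi, reorder = FALSE)
      gw[as.integer(rownames(s))] <- s[, 1]
    }
    c(gw + l2 * w, sum(r))
  }
  fit <- stats::optim(
    par = numeric(p + 1L), fn = negll, gr = grad, method = "L-BFGS-B",
    control = list(maxit = max_iter, pgtol = tolerance, factr = 1e1)
  )
  if (!is.finite(fit$value)) {
    rlang::abort("train_maxent(): non-finite penalised likelihood")
  }
  w <- fit$par[seq_len(p)]
  names(w) <- feats
  structure(
    list(weights = w, bias = fit$par[p + 1L],
         meta = list(l2 = l2, tolerance = tolerance,
                     max_iter = max_iter, converged = fit$convergence == 0L,
                     iterations = fit$counts[["function"]],
                     neg_loglik = fit$value, n_train = n)),
    class = "cm_maxent"
  )
}

#' @export
print.cm_maxent <- function(x, ...) {
  cat("<cm_maxent> ", length(x$weights), " features, bias ",
      signif(x$bias, 4), ", trained on ", x$meta$n_train,
      " documents (l2 = ", x$meta$l2, ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted maximum-entropy model
#'
#' @param x a `cm_maxent` object.
#' @param ... unused.
#' @return a tibble `term`, `estimate` sorted by absolute weight, with the
#'   bias as term `"(bias)"`.
#' @method tidy cm_maxent
#' @export
tidy.cm_maxent <- function(x, ...) {
  tibble::tibble(
    term = c("(bias)", names(x$weights)),
    estimate = c(x$bias, unname(x$weights))
  ) |>
    dplyr::arrange(dplyr::desc(abs(.data$estimate)))
}

#' @rdname tidy.cm_maxent
#' @return `glance()`: one-row tibble with fit summaries.
#' @method glance cm_maxent
#' @export
glance.cm_maxent <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$weights), n_train = x$meta$n_train,
    l2 = x$meta$l2, iterations = x$meta$iterations,
    converged = x$meta$converged, neg_loglik = x$meta$neg_loglik
  )
}

#' Probabilistic classification value for documents
#'
#' `value = logistic(bias + sum of weights of present features)`; features
#' unseen in training are ignored.
#'
#' @param model a `cm_maxent` model.
#' @param features long feature tibble for the documents to score.
#' @param doc_ids document ids to score (defaults to those present in
#'   `features`; pass explicitly so feature-less documents get
#'   `logistic(bias)`).
#' @return tibble `doc_id`, `value` with values in \[0, 1\].
#' @export
predict_value <- function(model, features, doc_ids = NULL) {
  if (is.null(doc_ids)) doc_ids <- unique(features$doc_id)
  eta <- rep(model$bias, length(doc_ids))
  names(eta) <- doc_ids
  known <- features[features$feature %in% names(model$weights) &
                      features$doc_id %in% doc_ids, , drop = FALSE]
  if (nrow(known) > 0L) {
    s <- tapply(model$weights[known$feature], known$doc_id, sum)
    eta[names(s)] <- eta[names(s)] + as.numeric(s)
  }
  tibble::tibble(doc_id = doc_ids, value = stats::plogis(unname(eta)))
}

#' Decision and confidence rules
#'
#' The discretization threshold (DTH) rule: class 1 iff `value >= dth`
#' (default 0.5); lowering the DTH boosts the positive minority class. The
#' confidence of a decision is `value` for class 1 and `1 - value` for
#' class 0, which preserves the within-class ranking needed for AUC iP/R.
#'
#' @param value numeric vector of classifier values in \[0, 1\].
#' @param dth discretization threshold in (0, 1).
#' @param class 0/1 decisions (for `act_confidence()`).
#' @return `act_decide()`: integer 0/1 vector; `act_confidence()`: numeric
#'   confidence vector.
#' @examples
#' act_decide(c(0.19, 0.5), dth = 0.2)
#' act_confidence(0.3, 0L)
#' @export
act_decide <- function(value, dth = 0.5) {
  if (dth <= 0 || dth >= 1) {
    rlang::abort("act_decide(): dth must lie strictly between 0 and 1")
  }
  stopifnot(all(value >= 0 & value <= 1))
  as.integer(value >= dth)
}

#' @rdname act_decide
#' @export
act_confidence <- function(value, class) {
  ifelse(class == 1L, value, 1 - value)
}

#' Classify documents with a trained model
#'
#' @param docs documents tibble.
#' @param model a `cm_maxent` model.
#' @param groups,bigram_vocab,text_fields feature configuration, matching
#'   training.
#' @param dth discretization threshold.
#' @return tibble `doc_id`, `value`, `class`, `confidence`, `dth`.
#' @export
act_predict <- function(docs, model, groups = c("W", "M"),
                        bigram_vocab = NULL, dth = 0.5,
                        text_fields = c("title", "body")) {
  fv <- act_features(docs, groups, bigram_vocab, text_fields)
  vals <- predict_value(model, fv, doc_ids = docs$doc_id)
  vals$class <- act_decide(vals$value, dth)
  vals$confidence <- act_confidence(vals$value, vals$class)
  vals$dth <- dth
  vals
}

#' Tune the discretization threshold on labelled values
#'
#' Evaluates every DTH on a grid and returns the one maximising the chosen
#' criterion; ties go to the lowest DTH.
#'
#' @param values classifier values.
#' @param labels 0/1 gold labels, aligned with `values`.
#' @param criterion `"mcc"` (default), `"fscore"` or `"accuracy"`.
#' @param grid_step grid resolution (default 0.01).
#' @return the selected DTH (single number).
#' @export
tune_dth <- function(values, labels, criterion = c("mcc", "fscore",
                                                   "accuracy"),
                     grid_step = 0.01) {
  criterion <- match.arg(criterion)
  if (length(values) == 0L) rlang::abort("tune_dth(): empty input")
  stopifnot(length(values) == length(labels))
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  crit <- vapply(grid, function(dth) {
    cls <- as.integer(values >= dth)
    cc <- confusion_binary(cls, labels)
    switch(criterion,
           mcc = mcc(cc),
           fscore = {
             f <- basic_metrics(cc)$f_score
             if (is.na(f)) 0 else f
           },
           accuracy = basic_metrics(cc)$accuracy)
  }, numeric(1))
  grid[which.max(crit)]  # which.max returns the first (lowest) maximiser
}

#' Percentile-based discretization threshold
#'
#' Returns the threshold under which exactly `ceiling(n * percentile /
#' 100)` items have value at or above it; items tied at the cut value are
#' all classified positive. Used to force every cross-validation test
#' subset to the same fraction of positive decisions.
#'
#' @param values classifier values.
#' @param percentile target percentage of positive decisions, in (0, 100\].
#' @return the threshold value.
#' @export
percentile_dth <- function(values, percentile) {
  if (length(values) == 0L) rlang::abort("percentile_dth(): empty values")
  if (percentile <= 0 || percentile > 100) {
    rlang::abort("percentile_dth(): percentile must lie in (0, 100]")
  }
  k <- ceiling(length(values) * percentile / 100)
  sort(values, decreasing = TRUE)[k]
}

#' Oversample the positive class to balance
#'
#' Every positive example is repeated `floor(neg/pos)` times, and
#' `neg - pos * floor(neg/pos)` distinct positives, chosen uniformly
#' without replacement, are taken once more, so positive and negative
#' counts end up equal. Negatives are untouched. With 612 positives and
#' 2979 negatives this is the "4 copies each plus 531 random fifth copies"
#' scheme.
#'
#' @param labels 0/1 vector.
#' @param seed integer seed for the random remainder draw.
#' @return integer vector of training indices (a multiset over
#'   `seq_along(labels)`).
#' @export
oversample <- function(labels, seed = 1L) {
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    rlang::abort("oversample(): both classes must be present")
  }
  if (length(pos) >= length(neg)) {
    rlang::abort("oversample(): positives must be the minority class")
  }
  d <- length(neg) %/% length(pos)
  r <- length(neg) - length(pos) * d
  extra <- integer()
  if (r > 0L) {
    extra <- with_seed_restore(seed, sample(pos, r, replace = FALSE))
  }
  sort(c(neg, rep(pos, d), extra))
}

#' Stratified k-fold split
#'
#' Shuffles each class separately (seeded) and deals indices round-robin
#' into `k` folds, so per-fold class proportions are within one item of the
#' global proportions.
#'
#' @param labels 0/1 vector.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return a list of `k` elements, each `list(train =, test =)` index
#'   vectors partitioning `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  stopifnot(k >= 2L)
  classes <- unique(labels)
  if (any(table(labels) < k)) {
    rlang::abort("stratified_kfold(): every class needs at least k items")
  }
  fold_of <- integer(length(labels))
  with_seed_restore(seed, {
    for (cl in sort(classes)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

# evaluate an expression with a temporary RNG seed, restoring global state
with_seed_restore <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Stratified cross-validation of the article classifier
#'
#' For each fold: features (including any bigram vocabulary) are built on
#' the training split only, the model is trained, values are predicted for
#' the test split, and a decision rule is applied according to `mode`:
#' `"dth"` uses the fixed `dth`; `"percentile"` thresholds each test fold
#' at the given percentile of positive decisions; `"oversample"` trains on
#' a class-balanced multiset (see [oversample()]) and decides at DTH 0.5.
#'
#' @param docs documents tibble.
#' @param gold ACT gold tibble `doc_id`, `label`.
#' @param groups feature groups.
#' @param k folds (default 10).
#' @param seed integer seed driving the fold split and any oversampling.
#' @param mode `"dth"`, `"percentile"` or `"oversample"`.
#' @param dth fixed threshold for `mode = "dth"`.
#' @param percentile percentage for `mode = "percentile"`.
#' @param l2 regularisation strength passed to [train_maxent()].
#' @return a tibble with one row per fold: confusion counts, the metrics
#'   of [basic_metrics()], `mcc`, `auc_ipr` and the threshold used.
#' @export
act_cv <- function(docs, gold, groups = c("W", "M"), k = 10L, seed = 1L,
                   mode = c("dth", "percentile", "oversample"),
                   dth = 0.5, percentile = 17, l2 = 1.0) {
  mode <- match.arg(mode)
  docs <- docs[match(gold$doc_id, docs$doc_id), , drop = FALSE]
  folds <- stratified_kfold(gold$label, k = k, seed = seed)
  res <- purrr::imap(folds, function(fold, f) {
    tr_docs <- docs[fold$train, , drop = FALSE]
    te_docs <- docs[fold$test, , drop = FALSE]
    tr_lab <- gold$label[fold$train]
    vocab <- if ("B" %in% groups) build_bigram_vocab(tr_docs) else NULL
    if (mode == "oversample") {
      idx <- oversample(tr_lab, seed = seed + f)
      tr_docs <- tr_docs[idx, , drop = FALSE]
      # duplicated rows need distinct ids for the feature join
      tr_docs$doc_id <- paste0(tr_docs$doc_id, "#", seq_along(idx))
      tr_lab <- tr_lab[idx]
    }
    fv_tr <- act_features(tr_docs, groups, vocab)
    model <- train_maxent(fv_tr,
                          tibble::tibble(doc_id = tr_docs$doc_id,
                                         label = tr_lab),
                          l2 = l2)
    fv_te <- act_features(te_docs, groups, vocab)
    vals <- predict_value(model, fv_te, doc_ids = te_docs$doc_id)$value
    thr <- switch(mode,
                  dth = dth,
                  percentile = percentile_dth(vals, percentile),
                  oversample = 0.5)
    cls <- as.integer(vals >= thr)
    y <- gold$label[fold$test]
    cc <- confusion_binary(cls, y)
    bm <- basic_metrics(cc)
    auc <- act_auc_ipr(vals, y)
    tibble::tibble(
      fold = f, threshold = thr, tp = cc$tp, fp = cc$fp, fn = cc$fn,
      tn = cc$tn, accuracy = bm$accuracy, specificity = bm$specificity,
      sensitivity = bm$sensitivity, precision = bm$precision,
      f_score = bm$f_score, mcc = mcc(cc), auc_ipr = auc
    )
  })
  dplyr::bind_rows(res)
}
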