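#' Confusion-matrix performance metrics
#'
#' Accuracy is reported as a percentage, `100 * (TP + TN) / n`;
#' sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)` and
#' `F1 = 2TP / (2TP + FN + FP)` as fractions. Undefined ratios (empty
#' denominators) are reported as NA, never silently 0.
#'
#' @param pred predicted labels (`"Ac"`/`"NAc"`).
#' @param truth true labels.
#' @return list with acc, sn, sp, f1, mcc (Matthews correlation, an
#'   optional extra diagnostic) and the counts tp, fp, tn, fn.
#' @export
confusionMetrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  tp <- sum(pred == "Ac" & truth == "Ac")
  fp <- sum(pred == "Ac" & truth == "NAc")
  tn <- sum(pred == "NAc" & truth == "NAc")
  fn <- sum(pred == "NAc" & truth == "Ac")
  n <- tp + fp + tn + fn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  mccDen <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(acc = ratio(tp + tn, n) * 100,
       sn = ratio(tp, tp + fn),
       sp = ratio(tn, tn + fp),
       f1 = ratio(2 * tp, 2 * tp + fn + fp),
       mcc = ratio(tp * tn - fp * fn, mccDen),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) formulation; tied scores are averaged,
#' which is equivalent to trapezoidal integration of the ROC curve.
#'
#' @param scores numeric scores, larger = more Ac-like.
#' @param truth true labels (`"Ac"`/`"NAc"`), both classes required.
#' @export
aucScore <- function(scores, truth) {
  pos <- truth == "Ac"
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Full evaluation report from scores
#'
#' @param scores numeric scores (posterior probability of Ac).
#' @param truth true labels.
#' @param cutoff classification threshold on the score, default 0.5.
#' @return list acc, auc, f1, sn, sp.
#' @export
evaluationReport <- function(scores, truth, cutoff = 0.5) {
  cm <- confusionMetrics(ifelse(scores >= cutoff, "Ac", "NAc"), truth)
  list(acc = cm$acc, auc = aucScore(scores, truth),
       f1 = cm$f1, sn = cm$sn, sp = cm$sp)
}

#' Seeded stratified fold assignment
#'
#' Folds are assigned within each class after ordering records by `ids`,
#' so the assignment depends only on the seed, the labels and the ids --
#' not on input row order. Classes smaller than `k` trigger a warning
#' and plain (unstratified) folds.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param ids record identifiers; defaults to names or sequence order.
#' @return integer fold index per record (sizes differ by at most 1 per
#'   class).
#' @export
stratifiedFolds <- function(labels, k = 5L, seed = 1L,
                            ids = names(labels) %||% seq_along(labels)) {
  n <- length(labels)
  ord <- order(ids)
  fold <- integer(n)
  if (min(table(labels)) < k) {
    warning("a class has fewer than ", k,
            " records; falling back to unstratified folds")
    fold[ord] <- withSeed(seed, sample(rep_len(seq_len(k), n)))
    return(fold)
  }
  withSeed(seed, {
    for (cl in sort(unique(labels))) {
      at <- ord[labels[ord] == cl]
      fold[at] <- sample(rep_len(seq_len(k), length(at)))
    }
  })
  fold
}

#' k-fold cross-validation of an arbitrary trainer
#'
#' Stratified, seeded folds; metrics are pooled over the concatenated
#' out-of-fold predictions (not averaged across folds).
#'
#' @param x feature matrix (records x columns).
#' @param labels `"Ac"`/`"NAc"` labels.
#' @param trainer `function(x_train, y_train)` returning a
#'   `function(x_new)` that emits Ac scores.
#' @param k folds, default 5.
#' @param seed RNG seed for fold assignment.
#' @param ids record ids (see [stratifiedFolds()]).
#' @return list: `report` (acc/auc/f1/sn/sp), `scores` (out-of-fold,
#'   input order), `fold` assignment.
#' @export
kfoldCv <- function(x, labels, trainer, k = 5L, seed = 1L,
                    ids = rownames(x) %||% seq_along(labels)) {
  if (length(labels) < k) stop("fewer records than folds")
  fold <- stratifiedFolds(labels, k, seed, ids)
  scores <- numeric(length(labels))
  for (f in seq_len(k)) {
    hold <- fold == f
    predictor <- trainer(x[!hold, , drop = FALSE], labels[!hold])
    scores[hold] <- predictor(x[hold, , drop = FALSE])
  }
  list(report = evaluationReport(scores, labels), scores = scores,
       fold = fold)
}

#' Run the four evaluation protocols on a pair of subset models
#'
#' For each trained subset model: 5-fold cross-validation within its own
#' training subset, self-consistency (its own training records),
#' exchange-testing (the other subset's records) and, when supplied,
#' independent testing. Feeds [modelSelectionScore()].
#'
#' @param fit1,fit2 subset fits from [trainSubsetModel()].
#' @param enc encoded training study (see [encodeStudy()]).
#' @param test_enc optional encoded independent test study; its record
#'   ids must not overlap the training subsets (leakage guard).
#' @return data.frame: model, protocol, acc, auc, f1, sn, sp.
#' @export
protocolSuite <- function(fit1, fit2, enc, test_enc = NULL) {
  if (!is.null(test_enc) &&
      length(intersect(test_enc$ids, c(fit1$ids, fit2$ids))) > 0)
    stop("independent test records overlap the training subsets")
  fits <- list(subset1 = fit1, subset2 = fit2)
  rows <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    other <- if (nm == "subset1") fit2 else fit1
    add <- function(protocol, rep)
      rows[[length(rows) + 1L]] <<- data.frame(
        model = nm, protocol = protocol, acc = rep$acc, auc = rep$auc,
        f1 = rep$f1, sn = rep$sn, sp = rep$sp)
    add("cross_validation", fit$cvReport)
    add("self_consistency",
        evaluationReport(predictTwoLayer(fit$model, enc, fit$ids),
                         encLabels(enc, fit$ids)))
    add("exchange_testing",
        evaluationReport(predictTwoLayer(fit$model, enc, other$ids),
                         encLabels(enc, other$ids)))
    if (!is.null(test_enc))
      add("independent_testing",
          evaluationReport(predictTwoLayer(fit$model, test_enc,
                                           test_enc$ids),
                           encLabels(test_enc, test_enc$ids)))
  }
  do.call(rbind, rows)
}

#' Overfitting-aware model-quality score
#'
#' For each of AUC, Sn and Sp the component is
#' `cross-validation x exchange-testing / self-consistency`; the total
#' is the sum of the three components. Lower totals indicate stronger
#' overfitting (inflated self-consistency relative to transfer).
#'
#' @param cv,ex,self evaluation reports containing `auc`, `sn`, `sp`
#'   (self values must be > 0).
#' @return list with `components` (named AUC/Sn/Sp) and `total`.
#' @export
modelSelectionScore <- function(cv, ex, self) {
  comp <- vapply(c(auc = "auc", sn = "sn", sp = "sp"), function(m) {
    if (is.na(self[[m]]) || self[[m]] == 0)
      stop("self-consistency ", m, " is zero or undefined")
    cv[[m]] * ex[[m]] / self[[m]]
  }, numeric(1))
  names(comp) <- c("AUC", "Sn", "Sp")
  list(components = comp, total = sum(comp))
}
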