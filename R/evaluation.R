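#' Binary confusion counts
#'
#' The normal fetal state is the positive class: `tp` counts images that
#' are normal and predicted normal, `tn` pathological predicted
#' pathological.
#'
#' @param labels true classes (`"normal"` / `"pathological"`).
#' @param predictions predicted classes, same length.
#' @return A [ConfusionCounts-class].
#' @examples
#' confusionCounts(c("normal", "normal", "pathological", "pathological"),
#'                 c("normal", "pathological", "pathological", "normal"))
#' @export
confusionCounts <- function(labels, predictions) {
  if (length(labels) == 0) stop("confusionCounts: empty input")
  if (length(labels) != length(predictions))
    stop("confusionCounts: length mismatch")
  if (!all(labels %in% c("normal", "pathological")))
    stop("confusionCounts: labels must be normal/pathological")
  pos <- labels == "normal"
  ppos <- predictions == "normal"
  new("ConfusionCounts",
      tp = sum(pos & ppos), fp = sum(!pos & ppos),
      fn = sum(pos & !ppos), tn = sum(!pos & !ppos))
}

#' Accuracy, sensitivity, specificity and quality index
#'
#' Standard confusion-matrix ratios reported as percentages:
#' `Acc = (TP+TN)/(TP+FP+FN+TN)`, `Se = TP/(TP+FN)`, `Sp = TN/(FP+TN)`, and
#' the quality index `QI = sqrt(Se * Sp)` -- the geometric mean of
#' sensitivity and specificity, used against class imbalance.
#'
#' @param counts a [ConfusionCounts-class].
#' @return Named numeric vector `c(acc, se, sp, qi)` in percent.
#' @examples
#' classificationMetrics(new("ConfusionCounts", tp = 9L, fp = 2L,
#'                           fn = 1L, tn = 8L))
#' @export
classificationMetrics <- function(counts) {
  tp <- counts@tp; fp <- counts@fp; fn <- counts@fn; tn <- counts@tn
  if (tp + fn == 0) stop("classificationMetrics: sensitivity undefined (no positives)")
  if (fp + tn == 0) stop("classificationMetrics: specificity undefined (no negatives)")
  acc <- (tp + tn) / (tp + fp + fn + tn) * 100
  se <- tp / (tp + fn) * 100
  sp <- tn / (fp + tn) * 100
  c(acc = acc, se = se, sp = sp, qi = qualityIndex(se, sp))
}

#' Quality index: geometric mean of sensitivity and specificity
#'
#' @param se sensitivity, percent.
#' @param sp specificity, percent.
#' @return `sqrt(se * sp)`, percent.
#' @examples
#' qualityIndex(98.22, 94.87)
#' @export
qualityIndex <- function(se, sp) sqrt(se * sp)

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve over all score thresholds,
#' which equals the concordance probability that a random positive scores
#' above a random negative, with ties contributing one half.
#'
#' @param scores positive-class (normal) probabilities or any monotone
#'   score, finite.
#' @param labels true classes.
#' @param positive the positive class.
#' @return AUC in percent.
#' @examples
#' rocAuc(c(0.9, 0.4, 0.8, 0.3),
#'        c("normal", "normal", "pathological", "pathological"))  # 75
#' @export
rocAuc <- function(scores, labels, positive = "normal") {
  if (!all(is.finite(scores))) stop("rocAuc: scores must be finite")
  pos <- labels == positive
  P <- sum(pos); Nn <- sum(!pos)
  if (P == 0 || Nn == 0) stop("rocAuc: AUC undefined with one class absent")
  ord <- order(scores, decreasing = TRUE)
  y <- pos[ord]
  s <- scores[ord]
  cuts <- which(diff(s) != 0)
  cuts <- c(cuts, length(s))
  tpr <- c(0, cumsum(y)[cuts] / P)
  fpr <- c(0, cumsum(!y)[cuts] / Nn)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2) * 100
}

#' Stratified fold assignment
#'
#' Partitions images into `k` disjoint, exhaustive folds with
#' class-proportional sizes (remainders go to the last folds, so with 2682
#' normal images and k = 10 the first eight folds hold 268 and the last two
#' 269). With `groups` set, whole groups (e.g. all images of one recording)
#' are assigned to a single fold so no group leaks across the train/test
#' boundary.
#'
#' @param labels class labels, one per image.
#' @param k number of folds.
#' @param seed RNG seed for the shuffle.
#' @param groups optional grouping vector (e.g. source record ids).
#' @return Integer vector of fold indices in `1..k`.
#' @export
stratifiedFolds <- function(labels, k = 10, seed = 1, groups = NULL) {
  if (k < 2) stop("stratifiedFolds: k must be >= 2")
  set.seed(seed)
  n <- length(labels)
  fold <- integer(n)
  if (is.null(groups)) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop("stratifiedFolds: class ", cl, " has fewer members than folds")
      idx <- sample(idx)
      base <- length(idx) %/% k
      extra <- length(idx) %% k
      sizes <- rep(base, k) + c(rep(0, k - extra), rep(1, extra))
      fold[idx] <- rep(seq_len(k), times = sizes)
    }
  } else {
    gl <- tapply(labels, groups, function(v) v[1])
    gnames <- names(gl)
    gfold <- integer(length(gnames))
    names(gfold) <- gnames
    for (cl in unique(gl)) {
      gidx <- which(gl == cl)
      if (length(gidx) < k)
        stop("stratifiedFolds: fewer ", cl, " groups than folds")
      gidx <- sample(gidx)
      base <- length(gidx) %/% k
      extra <- length(gidx) %% k
      sizes <- rep(base, k) + c(rep(0, k - extra), rep(1, extra))
      gfold[gidx] <- rep(seq_len(k), times = sizes)
    }
    fold <- gfold[as.character(groups)]
    names(fold) <- NULL
  }
  fold
}

#' Ten-fold cross-validated evaluation of the CNN
#'
#' Stratified k-fold cross-validation: per fold, a fresh model is trained
#' on the other k-1 folds and evaluated on the held-out fold, producing
#' accuracy, sensitivity, specificity, quality index and AUC (positive
#' class = normal; AUC scores are the softmax normal-class probabilities).
#' The final row reports the unweighted mean over folds. `grouping =
#' "record"` keeps all images of one recording inside a single fold, which
#' guards against leakage when several images per recording exist.
#'
#' @param images a [TFImageSet-class].
#' @param cfg a [cnnConfig()]; fold models use seeds derived from
#'   `cfg@seed`.
#' @param k number of folds.
#' @param grouping `"image"` (plain stratified images) or `"record"`.
#' @param seed seed for the fold partition (defaults to `cfg@seed`).
#' @param verbose print per-fold progress.
#' @return List with `perFold` (data.frame of per-fold metrics, percent)
#'   and `mean` (named vector, the unweighted per-fold average).
#' @export
tenFoldCV <- function(images, cfg = cnnConfig(), k = 10,
                      grouping = c("image", "record"), seed = cfg@seed,
                      verbose = FALSE) {
  grouping <- match.arg(grouping)
  labels <- imageLabels(images)
  groups <- if (grouping == "record") imageMeta(images)$sourceId else NULL
  fold <- stratifiedFolds(labels, k, seed, groups)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    trainIdx <- which(fold != f)
    testIdx <- which(fold == f)
    cfgF <- cfg
    cfgF@seed <- seed + f
    model <- trainModel(buildModel(cfgF), .subsetImageSet(images, trainIdx))
    prob <- predict(model, .subsetImageSet(images, testIdx))
    pred <- .CLASSES[max.col(prob, ties.method = "first")]
    m <- classificationMetrics(confusionCounts(labels[testIdx], pred))
    auc <- rocAuc(prob[, "normal"], labels[testIdx])
    rows[[f]] <- data.frame(fold = f, acc = m["acc"], se = m["se"],
                            sp = m["sp"], qi = m["qi"], auc = auc,
                            row.names = NULL)
    if (verbose)
      .msg("fold %d/%d: acc %.2f, se %.2f, sp %.2f, qi %.2f, auc %.2f",
           f, k, m["acc"], m["se"], m["sp"], m["qi"], auc)
  }
  perFold <- do.call(rbind, rows)
  list(perFold = perFold,
       mean = colMeans(perFold[, c("acc", "se", "sp", "qi", "auc")]))
}
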