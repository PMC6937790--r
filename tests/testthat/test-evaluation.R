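test_that("confusion counts treat the normal class as positive", {
  labs <- c(rep("normal", 268), rep("pathological", 63))
  cc <- confusionCounts(labs, labs)
  expect_identical(c(cc@tp, cc@tn, cc@fp, cc@fn), c(268L, 63L, 0L, 0L))
  allNormal <- confusionCounts(labs, rep("normal", 331))
  expect_identical(c(allNormal@tp, allNormal@fp, allNormal@fn, allNormal@tn),
                   c(268L, 63L, 0L, 0L))
  hand <- confusionCounts(c("normal", "normal", "pathological", "pathological"),
                          c("normal", "pathological", "pathological", "normal"))
  expect_identical(c(hand@tp, hand@fn, hand@tn, hand@fp), rep(1L, 4))
  expect_error(confusionCounts(character(), character()), "empty")
})

test_that("metrics evaluate the confusion-matrix formulas as percentages", {
  m <- classificationMetrics(new("ConfusionCounts", tp = 9L, fp = 2L,
                                 fn = 1L, tn = 8L))
  expect_equal(unname(m["acc"]), 85)
  expect_equal(unname(m["se"]), 90)
  expect_equal(unname(m["sp"]), 80)
  expect_equal(unname(m["qi"]), sqrt(90 * 80), tolerance = 1e-12)
  # geometric-mean identity and bounds
  expect_equal(qualityIndex(77.7, 77.7), 77.7, tolerance = 1e-12)
  for (se in c(20, 55, 90)) {
    for (sp in c(35, 60, 99)) {
      qi <- qualityIndex(se, sp)
      expect_gte(qi, min(se, sp))
      expect_lte(qi, max(se, sp))
    }
  }
  expect_error(
    classificationMetrics(new("ConfusionCounts", tp = 0L, fp = 2L,
                              fn = 0L, tn = 8L)), "sensitivity")
})

test_that("AUC equals the concordance probability with half-credit ties", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c("normal", "normal",
               "pathological", "pathological")), 100)
  expect_equal(rocAuc(rep(0.5, 8), rep(c("normal", "pathological"), 4)), 50)
  expect_equal(rocAuc(c(0.9, 0.4, 0.8, 0.3),
                      c("normal", "normal", "pathological", "pathological")),
               75)
  expect_error(rocAuc(c(0.1, 0.2), c("normal", "normal")), "one class")
})

test_that("trapezoidal AUC matches pairwise concordance over all permutations", {
  concordance <- function(scores, labels) {
    pos <- scores[labels == "normal"]
    neg <- scores[labels != "normal"]
    gr <- outer(pos, neg, ">")
    eq <- outer(pos, neg, "==")
    (sum(gr) + 0.5 * sum(eq)) / (length(pos) * length(neg)) * 100
  }
  scores <- c(0.1, 0.2, 0.2, 0.5, 0.5, 0.7, 0.9, 0.9)  # with ties
  labels <- c(rep("normal", 4), rep("pathological", 4))
  perms <- allPerms(seq_along(scores))
  agree <- vapply(seq_len(nrow(perms)), function(i) {
    s <- scores[perms[i, ]]
    abs(rocAuc(s, labels) - concordance(s, labels)) < 1e-10
  }, TRUE)
  expect_true(all(agree))
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(31)
  scores <- runif(40)
  labels <- sample(c("normal", "pathological"), 40, TRUE, prob = c(0.7, 0.3))
  a0 <- rocAuc(scores, labels)
  expect_equal(rocAuc(qlogis(scores / 1.01 + 0.001), labels), a0)
  expect_equal(rocAuc(scores^3, labels), a0)
  expect_equal(rocAuc(1000 * scores - 5, labels), a0)
})

test_that("stratified folds are disjoint, exhaustive and class-proportional", {
  labels <- c(rep("normal", 2682), rep("pathological", 630))
  fold <- stratifiedFolds(labels, k = 10, seed = 4)
  expect_identical(sort(unique(fold)), 1:10)
  expect_length(fold, 3312)
  # per-class fold sizes reproduce the 90/10 split counts
  nTab <- table(fold[labels == "normal"])
  pTab <- table(fold[labels == "pathological"])
  expect_identical(sort(unique(as.integer(pTab))), 63L)
  expect_true(all(as.integer(nTab) %in% c(268L, 269L)))
  # fold 1 training share matches nearest-integer 90%
  expect_identical(sum(labels == "normal") - as.integer(nTab[["1"]]),
                   2414L)
  expect_identical(round(0.9 * 2682), 2414)
  expect_identical(sum(labels == "pathological") - 63L, 567L)
  expect_error(stratifiedFolds(c("normal", rep("pathological", 30)), 10),
               "fewer")
})

test_that("record grouping keeps every record inside a single fold", {
  recs <- sprintf("r%02d", 1:40)
  labels <- rep(c(rep("normal", 30), rep("pathological", 10)), each = 6)
  groups <- rep(recs, each = 6)
  fold <- stratifiedFolds(labels, k = 5, seed = 2, groups = groups)
  perRecord <- tapply(fold, groups, function(f) length(unique(f)))
  expect_true(all(perRecord == 1))
  expect_identical(sort(unique(fold)), 1:5)
  expect_error(stratifiedFolds(labels, k = 12, seed = 1, groups = groups),
               "fewer")
})

test_that("cross-validation reports per-fold metrics and their plain mean", {
  skip_if_not_installed("pROC")
  set.seed(6)
  # logistic toy problem evaluated through the CV harness with a tiny CNN
  set <- randomImageSet(30, 30, res = 6, seed = 8)
  # make classes separable so every fold has sane metrics
  imgs <- imageArray(set)
  imgs[, , , imageLabels(set) == "normal"] <-
    imgs[, , , imageLabels(set) == "normal"] * 0.3 + 0.7
  set@images <- imgs
  cfg <- cnnConfig(inputResolution = 6, kernelSize = 3, numFilters = 2,
                   fcWidth = 4, maxEpochs = 4, miniBatch = 10, seed = 3)
  cv <- tenFoldCV(set, cfg, k = 5)
  expect_identical(nrow(cv$perFold), 5L)
  expect_equal(unname(cv$mean),
               unname(colMeans(cv$perFold[, c("acc", "se", "sp", "qi", "auc")])),
               tolerance = 1e-9)
  expect_true(all(cv$perFold$qi <= pmax(cv$perFold$se, cv$perFold$sp) + 1e-9))
  expect_true(all(cv$perFold$qi >= pmin(cv$perFold$se, cv$perFold$sp) - 1e-9))
  # AUC agrees with an independent implementation on one fold's scores
  prob <- predict(trainModel(buildModel(cfg), set), set)
  ours <- rocAuc(prob[, "normal"], imageLabels(set))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(imageLabels(set), levels = c("pathological", "normal")),
    predictor = prob[, "normal"], quiet = TRUE))) * 100
  expect_equal(ours, ref, tolerance = 1e-9)
})
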