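test_that("confusion matrix counts and row percentages by hand", {
  cm <- confusion_matrix(c("A", "A", "B", "B"), c("A", "B", "B", "B"),
                         c("A", "B"))
  expect_equal(unname(cm$counts), rbind(c(1, 1), c(0, 2)))
  expect_equal(unname(cm$row_percentages), rbind(c(50, 50), c(0, 100)))
  expect_equal(unname(rowSums(cm$row_percentages)), c(100, 100))
  expect_equal(accuracy(cm), 0.75)

  perfect <- confusion_matrix(letters[1:3], letters[1:3])
  expect_equal(unname(diag(perfect$row_percentages)), rep(100, 3))

  # sample order is irrelevant
  p <- sample(4)
  cm2 <- confusion_matrix(c("A", "A", "B", "B")[p], c("A", "B", "B", "B")[p],
                          c("A", "B"))
  expect_identical(cm2$counts, cm$counts)
  expect_error(confusion_matrix("A", "C", class_labels = c("A", "B")),
               "outside")
})

test_that("row percentages are invariant to duplicating every sample", {
  yt <- c("A", "A", "B", "B", "B")
  yp <- c("A", "B", "B", "A", "B")
  cm1 <- confusion_matrix(yt, yp, c("A", "B"))
  cm2 <- confusion_matrix(rep(yt, 2), rep(yp, 2), c("A", "B"))
  expect_equal(cm2$row_percentages, cm1$row_percentages)
})

test_that("ROC matches pair enumeration on the worked example", {
  curve <- roc_ovr(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8), 1)
  expect_equal(curve$auc, 0.75)   # 3 of 4 (pos, neg) pairs concordant
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$tpr[1], 0)
  expect_equal(curve$fpr[length(curve$fpr)], 1)
  expect_equal(curve$tpr[length(curve$tpr)], 1)
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$tpr) >= 0))

  sep <- roc_ovr(rep(c("n", "p"), each = 5), c(1:5, 6:10), "p")
  expect_equal(sep$auc, 1)
  ties <- roc_ovr(rep(c("n", "p"), each = 5), rep(0.3, 10), "p")
  expect_equal(ties$auc, 0.5)
  expect_error(roc_ovr(rep("p", 4), 1:4, "p"), "positive and negative")
})

test_that("trapezoid and pair-count AUC agree to 1e-12", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    pos <- runif(n) < runif(1, 0.2, 0.8)
    if (!any(pos) || all(pos)) next
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    a1 <- roc_ovr(pos, scores, TRUE)$auc
    a2 <- auc_pair_count(pos, scores)
    expect_equal(a1, a2, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent reference implementation", {
  set.seed(12)
  y <- rbinom(80, 1, 0.4)
  s <- rnorm(80) + y
  ours <- roc_ovr(y, s, 1)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, s,
                                                         quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ROC is invariant under monotone score transforms", {
  set.seed(13)
  y <- rbinom(50, 1, 0.5)
  s <- rnorm(50)
  a <- roc_ovr(y, s, 1)
  b <- roc_ovr(y, exp(s / 2), 1)       # strictly increasing transform
  expect_equal(a$fpr, b$fpr)
  expect_equal(a$tpr, b$tpr)
  expect_equal(a$auc, b$auc)
})

test_that("micro average pools all class-sample decisions", {
  # perfect classifier: micro AUC 1
  y <- rep(c("a", "b", "c"), each = 4)
  S <- sapply(c("a", "b", "c"), function(cl) as.numeric(y == cl))
  expect_equal(micro_average(y, S)$auc, 1)

  # two classes with antisymmetric complementary scores: the pooled binary
  # problem mirrors the original one, so micro equals the binary AUC
  y2 <- rep(c("p", "n"), each = 3)
  sp <- c(2, -1, 0.5)
  s <- c(sp, -sp)
  S2 <- cbind(p = s, n = -s)
  expect_equal(micro_average(y2, S2)$auc, roc_ovr(y2, s, "p")$auc)

  # pooled-pair oracle on arbitrary scores
  set.seed(14)
  y2b <- rep(c("p", "n"), each = 20)
  sb <- rnorm(40) + (y2b == "p")
  S2b <- cbind(p = sb, n = -sb)
  pooled_pos <- c(y2b == "p", y2b == "n")
  pooled_scores <- c(S2b[, "p"], S2b[, "n"])
  expect_equal(micro_average(y2b, S2b)$auc,
               auc_pair_count(pooled_pos, pooled_scores),
               tolerance = 1e-12)

  # label-independent scores hover at 0.5
  set.seed(15)
  y3 <- sample(rep(letters[1:4], each = 500))
  S3 <- matrix(runif(2000 * 4), 2000, 4,
               dimnames = list(NULL, letters[1:4]))
  expect_gt(micro_average(y3, S3)$auc, 0.46)
  expect_lt(micro_average(y3, S3)$auc, 0.54)
})

test_that("macro average is the unweighted mean of class AUCs", {
  expect_equal(macro_auc(c(0.77, 0.97, 0.89, 0.94)), 0.8925)
  set.seed(16)
  y <- rep(c("p", "n"), each = 15)
  s <- rnorm(30) + 2 * (y == "p")
  c1 <- roc_ovr(y, s, "p")
  # identical curves: macro equals each; single curve: macro is that curve
  mac <- macro_average(list(c1, c1))
  expect_equal(mac$auc, c1$auc)
  expect_true(all(diff(mac$tpr) >= 0))
  expect_equal(range(mac$tpr), c(0, 1))
  expect_equal(macro_average(list(c1))$auc, c1$auc)
  expect_error(macro_average(list()), "no per-class")
})

test_that("evaluate_classifier bundles confusion and curves consistently", {
  g <- gaussian_classes(30, matrix(c(0, 0, 4, 0, 0, 4), 3, 2, byrow = TRUE),
                       seed = 17)
  ev <- evaluate_split(g$X, g$y, 0.2, seed = 18, shrinkage = 0)
  bundle <- evaluate_classifier(ev$test_labels, ev$predictions, ev$scores)
  expect_identical(names(bundle$per_class), levels(g$y))
  expect_equal(bundle$accuracy, ev$accuracy)
  expect_equal(bundle$macro$auc,
               mean(vapply(bundle$per_class, `[[`, numeric(1), "auc")))
})

test_that("report writes a round-trippable metrics file and both figures", {
  g <- gaussian_classes(25, matrix(c(0, 0, 4, 4), 2, 2, byrow = TRUE),
                       seed = 19)
  ev <- evaluate_split(g$X, g$y, 0.2, seed = 20, shrinkage = 0)
  bundle <- evaluate_classifier(ev$test_labels, ev$predictions, ev$scores)
  out <- withr::local_tempdir()
  res <- report(bundle$confusion,
                c(bundle$per_class, list(micro = bundle$micro)),
                bundle$accuracy, out)
  expect_true(all(file.exists(res$paths)))
  back <- jsonlite::read_json(res$paths[["metrics"]],
                              simplifyVector = TRUE)
  expect_equal(back$accuracy, bundle$accuracy)
  expect_equal(as.numeric(back$auc$micro), bundle$micro$auc)
  expect_equal(matrix(unlist(back$confusion_counts),
                      nrow = 2, byrow = TRUE),
               unname(bundle$confusion$counts))
})
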