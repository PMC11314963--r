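#' Confusion matrix with row percentages
#'
#' Counts with true classes in rows and predicted classes in columns, plus
#' row-normalized percentages (each non-empty row sums to 100), the
#' convention used when reporting "x% of class c was classified as ...".
#'
#' @param y_true,y_pred Equal-length label vectors over `class_labels`.
#' @param class_labels Class vocabulary; defaults to the union of observed
#'   labels.
#' @return Object of class `confusion_matrix`: `class_labels`, `counts`,
#'   `row_percentages` (NA rows where a true class is absent), `n`.
#' @export
confusion_matrix <- function(y_true, y_pred, class_labels = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  if (is.null(class_labels))
    class_labels <- sort(unique(c(y_true, y_pred)))
  bad <- setdiff(unique(c(y_true, y_pred)), class_labels)
  if (length(bad))
    stop("labels outside class vocabulary: ", paste(bad, collapse = ", "),
         call. = FALSE)
  counts <- table(factor(y_true, levels = class_labels),
                  factor(y_pred, levels = class_labels))
  counts <- unclass(counts)
  rs <- rowSums(counts)
  pct <- counts / ifelse(rs == 0, NA_real_, rs) * 100
  structure(
    list(class_labels = class_labels, counts = counts,
         row_percentages = pct, n = length(y_true),
         empty_rows = class_labels[rs == 0]),
    class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 1, ...) {
  cat("Confusion matrix (", x$n, " samples; rows = true class)\n", sep = "")
  print(round(x$row_percentages, digits))
  invisible(x)
}

#' Overall accuracy of a confusion matrix
#' @param cm A [confusion_matrix()].
#' @return Fraction of correctly classified samples.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  sum(diag(cm$counts)) / cm$n
}

# Mann-Whitney pair-counting AUC: (concordant + half ties) / (n_pos * n_neg).
# Average ranks make the half-tie credit exact. Shipped as an independent
# route that must agree with the trapezoidal AUC.
#' Pair-counting AUC (Mann-Whitney statistic)
#'
#' @param positive Logical vector (TRUE = positive class).
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_pair_count <- function(positive, scores) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0)
    stop("ROC undefined: need both positive and negative examples",
         call. = FALSE)
  r <- rank(scores)   # average ranks: ties get half credit
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest ROC curve
#'
#' Threshold sweep over the unique scores in descending order with tied
#' scores grouped, yielding a step curve from (0,0) to (1,1); the AUC is
#' its trapezoidal area (for tie groups the trapezoid gives the standard
#' half-credit) and is checked at build time against the pair-counting
#' route in tests.
#'
#' @param y_true Label vector.
#' @param scores Numeric score for the positive class, higher = more
#'   positive; finite.
#' @param positive_class Which label of `y_true` is the positive class.
#' @return Object of class `roc_curve`: `class_label`, `fpr`, `tpr`, `auc`,
#'   `thresholds`.
#' @examples
#' roc_ovr(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8), positive_class = 1)$auc
#' @export
roc_ovr <- function(y_true, scores, positive_class) {
  if (any(!is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  pos <- as.character(y_true) == as.character(positive_class)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("ROC undefined: need both positive and negative examples",
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  keep <- c(s[-length(s)] != s[-1], TRUE)   # last index of each tie group
  tps <- cumsum(p)[keep]
  fps <- cumsum(!p)[keep]
  fpr <- c(0, fps / n0)
  tpr <- c(0, tps / n1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(class_label = as.character(positive_class), fpr = fpr, tpr = tpr,
         auc = auc, thresholds = c(Inf, s[keep])),
    class = "roc_curve")
}

#' Micro-averaged one-vs-rest ROC
#'
#' Pools every (class indicator, class score) pair across all classes into
#' one binary problem and computes its ROC, so every sample-class decision
#' carries equal weight.
#'
#' @param y_true Label vector.
#' @param score_matrix Numeric matrix, one column per class (named by
#'   `class_labels`).
#' @param class_labels Class vocabulary matching the score columns.
#' @return A `roc_curve` with `class_label = "micro"`.
#' @export
micro_average <- function(y_true, score_matrix,
                          class_labels = colnames(score_matrix)) {
  score_matrix <- as.matrix(score_matrix)
  if (is.null(class_labels) || ncol(score_matrix) != length(class_labels))
    stop("score_matrix needs one named column per class", call. = FALSE)
  ind <- sapply(class_labels, function(cl) as.character(y_true) == cl)
  curve <- roc_ovr(as.vector(ind), as.vector(score_matrix),
                   positive_class = TRUE)
  curve$class_label <- "micro"
  curve
}

#' Macro-averaged ROC
#'
#' Macro AUC is the unweighted mean of the per-class AUCs (each class
#' considered independently); the macro curve is the mean TPR interpolated
#' on the union grid of all class FPR points.
#'
#' @param per_class_curves List of `roc_curve` objects.
#' @return A `roc_curve` with `class_label = "macro"`.
#' @export
macro_average <- function(per_class_curves) {
  if (length(per_class_curves) == 0L)
    stop("no per-class curves supplied", call. = FALSE)
  stopifnot(all(vapply(per_class_curves, inherits, logical(1), "roc_curve")))
  grid <- sort(unique(c(0, 1,
                        unlist(lapply(per_class_curves, `[[`, "fpr")))))
  tprs <- sapply(per_class_curves, function(cv)
    stats::approx(cv$fpr, cv$tpr, xout = grid, ties = max, rule = 2)$y)
  mean_tpr <- rowMeans(as.matrix(tprs))
  # re-anchor at (0, 0): max-tie interpolation keeps only the top of the
  # vertical riser at fpr = 0
  grid <- c(0, grid)
  mean_tpr <- c(0, mean_tpr)
  structure(
    list(class_label = "macro", fpr = grid, tpr = mean_tpr,
         auc = macro_auc(vapply(per_class_curves, `[[`, numeric(1), "auc")),
         thresholds = NULL),
    class = "roc_curve")
}

#' @rdname macro_average
#' @param aucs Numeric vector of per-class AUC values.
#' @return `macro_auc()`: their unweighted mean.
#' @export
macro_auc <- function(aucs) {
  if (length(aucs) == 0L) stop("no AUC values supplied", call. = FALSE)
  mean(aucs)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve [%s]: %d points, AUC = %.4f\n",
              x$class_label, length(x$fpr), x$auc))
  invisible(x)
}

#' Evaluate a classifier run: confusion, per-class and averaged ROC
#'
#' Convenience wrapper turning test labels plus posterior scores into the
#' full evaluation bundle.
#'
#' @param y_true Test labels.
#' @param y_pred Predicted labels.
#' @param score_matrix Posterior score matrix (columns = classes).
#' @return List: `confusion`, `per_class` (ROC curves), `micro`, `macro`,
#'   `accuracy`.
#' @export
evaluate_classifier <- function(y_true, y_pred, score_matrix) {
  labels <- colnames(score_matrix)
  cm <- confusion_matrix(y_true, y_pred, class_labels = labels)
  per_class <- lapply(labels, function(cl)
    roc_ovr(y_true, score_matrix[, cl], positive_class = cl))
  names(per_class) <- labels
  list(confusion = cm, per_class = per_class,
       micro = micro_average(y_true, score_matrix, labels),
       macro = macro_average(per_class),
       accuracy = accuracy(cm))
}

#' Write an evaluation report
#'
#' Writes a machine-readable metrics file (JSON: accuracy, per-class AUC,
#' micro/macro AUC, confusion counts and row percentages) plus two figures:
#' a confusion heat map and a ROC panel with the chance diagonal.
#'
#' @param cmatrix A [confusion_matrix()].
#' @param curves List of `roc_curve`s (per-class plus optional micro/macro).
#' @param accuracy Scalar test accuracy.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the metrics and the written file paths.
#' @export
report <- function(cmatrix, curves, accuracy, out_dir) {
  stopifnot(inherits(cmatrix, "confusion_matrix"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  aucs <- vapply(curves, `[[`, numeric(1), "auc")
  names(aucs) <- vapply(curves, `[[`, character(1), "class_label")
  metrics <- list(accuracy = accuracy, auc = as.list(aucs),
                  confusion_counts = cmatrix$counts,
                  confusion_row_percentages = cmatrix$row_percentages,
                  class_labels = cmatrix$class_labels, n = cmatrix$n)
  metrics_path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(metrics, metrics_path, digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor", na = "null")

  cm_path <- file.path(out_dir, "confusion.png")
  grDevices::png(cm_path, width = 720, height = 640)
  k <- length(cmatrix$class_labels)
  pct <- cmatrix$row_percentages
  pct[is.na(pct)] <- 0
  graphics::par(mar = c(6, 7, 3, 2))
  graphics::image(seq_len(k), seq_len(k), t(pct[k:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Confusion matrix (row %)")
  graphics::axis(1, seq_len(k), cmatrix$class_labels, las = 2)
  graphics::axis(2, seq_len(k), rev(cmatrix$class_labels), las = 1)
  for (i in seq_len(k)) for (j in seq_len(k))
    graphics::text(j, k - i + 1, sprintf("%.0f", pct[i, j]))
  grDevices::dev.off()

  roc_path <- file.path(out_dir, "roc.png")
  grDevices::png(roc_path, width = 720, height = 640)
  graphics::par(mar = c(5, 5, 3, 2))
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "One-vs-rest ROC")
  graphics::abline(0, 1, lty = 2)   # chance diagonal
  cols <- grDevices::hcl.colors(max(3L, length(curves)), "Dark 3")
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$fpr, curves[[i]]$tpr, col = cols[i],
                    lwd = 2)
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC = %.2f)", names(aucs), aucs),
                   col = cols[seq_along(curves)], lwd = 2, bty = "n")
  grDevices::dev.off()

  invisible(list(metrics = metrics,
                 paths = c(metrics = metrics_path, confusion = cm_path,
                           roc = roc_path)))
}
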