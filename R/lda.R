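#' Fit a multi-class linear discriminant model
#'
#' Fisher-style LDA built from scratch. The within-class scatter matrix
#' S_w = sum_c sum_{i in c} (x_i - mu_c)(x_i - mu_c)' is shrunk toward its
#' diagonal, S_w(s) = (1 - s) S_w + s diag(S_w), which keeps the fit
#' well-posed when the feature count (66 here) rivals the sample count; the
#' between-class scatter is S_b = sum_c n_c (mu_c - mu)(mu_c - mu)'. The
#' discriminant basis holds the leading eigenvectors of S_w(s)^{-1} S_b, at
#' most k - 1 of them for k classes. Eigenvector signs are fixed so the
#' largest-magnitude component is positive, making projections reproducible.
#'
#' @param X Numeric matrix, rows = observations, columns = features; all
#'   entries finite.
#' @param y Class labels (factor or character), one per row; at least two
#'   classes, each with at least two observations.
#' @param shrinkage Regularization weight in `[0, 1]` toward diag(S_w).
#' @return An object of class `lda_model`: `class_labels`, `class_means`,
#'   `pooled_within_scatter` (shrunk), `discriminant_basis` (columns LD1..),
#'   `eigenvalues`, `class_priors`, `shrinkage`, plus the projected class
#'   means and pooled covariance used for prediction.
#' @export
lda_fit <- function(X, y, shrinkage = 0.1) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("X must be a numeric matrix with finite entries", call. = FALSE)
  if (shrinkage < 0 || shrinkage > 1)
    stop("shrinkage must lie in [0, 1]", call. = FALSE)
  y <- factor(y)
  y <- droplevels(y)
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)", call. = FALSE)
  k <- nlevels(y)
  if (k < 2) stop("need at least two classes", call. = FALSE)
  n_c <- table(y)
  if (any(n_c < 2))
    stop("every class needs at least two observations; offending: ",
         paste(names(n_c)[n_c < 2], collapse = ", "), call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)

  mu <- colMeans(X)
  means <- matrix(0, k, p, dimnames = list(levels(y), colnames(X)))
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (cl in levels(y)) {
    Xc <- X[y == cl, , drop = FALSE]
    mc <- colMeans(Xc)
    means[cl, ] <- mc
    Sw <- Sw + crossprod(sweep(Xc, 2, mc))
    d <- mc - mu
    Sb <- Sb + nrow(Xc) * tcrossprod(d)
  }
  Sw_s <- (1 - shrinkage) * Sw + shrinkage * diag(diag(Sw), p)

  M <- tryCatch(solve(Sw_s, Sb), error = function(e)
    stop("within-class scatter is singular; increase `shrinkage` above 0 ",
         "or remove collinear/constant features (", conditionMessage(e), ")",
         call. = FALSE))
  eig <- eigen(M)
  vals <- Re(eig$values)
  vecs <- Re(eig$vectors)
  ord <- order(vals, decreasing = TRUE)
  m <- min(k - 1L, p)
  vals <- vals[ord][seq_len(m)]
  W <- vecs[, ord[seq_len(m)], drop = FALSE]
  for (j in seq_len(ncol(W))) {
    W[, j] <- W[, j] / sqrt(sum(W[, j]^2))
    if (W[which.max(abs(W[, j])), j] < 0) W[, j] <- -W[, j]
  }
  dimnames(W) <- list(colnames(X), paste0("LD", seq_len(m)))

  proj_means <- means %*% W
  # shared covariance in discriminant space, from the shrunk pooled scatter
  proj_cov <- crossprod(W, Sw_s %*% W) / (n - k)
  proj_cov <- (proj_cov + t(proj_cov)) / 2

  structure(
    list(class_labels = levels(y), class_means = means,
         pooled_within_scatter = Sw_s, discriminant_basis = W,
         eigenvalues = vals, class_priors = as.numeric(n_c) / n,
         shrinkage = shrinkage, projected_means = proj_means,
         projected_cov = proj_cov, n_features = p, n_obs = n),
    class = "lda_model")
}

#' Project observations into discriminant space
#'
#' @param model An [lda_fit()] result.
#' @param X Matrix with the same columns as the training data.
#' @return Score matrix, one row per observation, up to k - 1 columns.
#' @export
lda_project <- function(model, X) {
  stopifnot(inherits(model, "lda_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop("X has ", ncol(X), " columns; model was trained on ",
         model$n_features, call. = FALSE)
  X %*% model$discriminant_basis
}

#' Classify observations
#'
#' Gaussian class-conditionals with a shared covariance in discriminant
#' space: posterior(c | x) is proportional to prior_c times the normal
#' density at the projected x around the projected class mean. Labels are
#' the posterior argmax; exact ties go to the earlier class in
#' `model$class_labels`.
#'
#' @param model An [lda_fit()] result.
#' @param X Feature matrix.
#' @return List with `labels` (factor) and `posterior` (matrix, rows sum
#'   to 1, one column per class).
#' @export
lda_predict <- function(model, X) {
  stopifnot(inherits(model, "lda_model"))
  Z <- lda_project(model, X)
  k <- length(model$class_labels)
  Sigma <- model$projected_cov
  # guard: ridge for numerically semi-definite projected covariance
  Sinv <- tryCatch(solve(Sigma), error = function(e)
    solve(Sigma + diag(1e-10 * mean(diag(Sigma)), nrow(Sigma))))
  loglik <- matrix(0, nrow(Z), k,
                   dimnames = list(rownames(X), model$class_labels))
  for (j in seq_len(k)) {
    D <- sweep(Z, 2, model$projected_means[j, ])
    loglik[, j] <- -0.5 * rowSums((D %*% Sinv) * D) +
      log(model$class_priors[j])
  }
  post <- exp(loglik - apply(loglik, 1, max))
  post <- post / rowSums(post)
  idx <- apply(post, 1, which.max)   # which.max: first maximum wins ties
  list(labels = factor(model$class_labels[idx],
                       levels = model$class_labels),
       posterior = post)
}

#' Stratified train/test split
#'
#' Draws, within each class, `ceiling(test_fraction * n_c)` test
#' observations (capped so the training set keeps at least one), so for a
#' single stratum of 228 at 20% the test set holds 46 and for 209 it holds
#' 42. Seeded and class-proportional.
#'
#' @param y Class labels.
#' @param test_fraction Fraction of each class assigned to the test set.
#' @param seed Integer RNG seed.
#' @return List of integer index vectors `train`, `test`.
#' @export
stratified_split <- function(y, test_fraction = 0.2, seed = 1L) {
  y <- factor(y)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  set.seed(as.integer(seed))
  test <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_test <- min(ceiling(test_fraction * length(idx)), length(idx) - 1L)
    if (n_test < 1L)
      stop("class ", cl, " has no test candidate under stratification",
           call. = FALSE)
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(y), test), test = test)
}

#' Fit and score on a stratified holdout split
#'
#' Splits the data 80/20 (by default) with [stratified_split()], fits the
#' discriminant model on the training portion, and reports test-set
#' predictions, posteriors and accuracy (training accuracy is logged
#' alongside).
#'
#' @param X Feature matrix.
#' @param y Class labels.
#' @param test_fraction Held-out fraction per class.
#' @param seed Split seed.
#' @param shrinkage Passed to [lda_fit()].
#' @return List: `model`, `split`, `test_labels`, `predictions`, `scores`
#'   (test posteriors), `accuracy` (test), `train_accuracy`.
#' @export
evaluate_split <- function(X, y, test_fraction = 0.2, seed = 1L,
                           shrinkage = 0.1) {
  y <- factor(y)
  sp <- stratified_split(y, test_fraction, seed)
  model <- lda_fit(X[sp$train, , drop = FALSE], y[sp$train], shrinkage)
  pred <- lda_predict(model, X[sp$test, , drop = FALSE])
  pred_train <- lda_predict(model, X[sp$train, , drop = FALSE])
  list(model = model, split = sp,
       test_labels = factor(y[sp$test], levels = model$class_labels),
       predictions = pred$labels, scores = pred$posterior,
       accuracy = mean(as.character(pred$labels) ==
                         as.character(y[sp$test])),
       train_accuracy = mean(as.character(pred_train$labels) ==
                               as.character(y[sp$train])))
}

#' Serialize / restore a discriminant model as structured text
#'
#' JSON round-trip of the model fields (labels, means, basis, priors,
#' shrinkage and the projected-space quantities used for prediction).
#'
#' @param model An [lda_fit()] result.
#' @param path File path.
#' @return `write_lda_model()` returns `path` invisibly;
#'   `read_lda_model()` returns the restored `lda_model`.
#' @export
write_lda_model <- function(model, path) {
  stopifnot(inherits(model, "lda_model"))
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("class_means", "pooled_within_scatter", "discriminant_basis",
              "projected_means", "projected_cov"))
    raw[[f]] <- as.matrix(raw[[f]])
  rownames(raw$class_means) <- raw$class_labels
  rownames(raw$projected_means) <- raw$class_labels
  colnames(raw$discriminant_basis) <-
    paste0("LD", seq_len(ncol(raw$discriminant_basis)))
  structure(raw, class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("Linear discriminant model\n")
  cat("  classes:", paste(x$class_labels, collapse = ", "), "\n")
  cat("  features:", x$n_features, " observations:", x$n_obs, "\n")
  cat("  discriminants:", ncol(x$discriminant_basis),
      " shrinkage:", x$shrinkage, "\n")
  invisible(x)
}
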