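as_binary <- function(y, positive = NULL) {
  f <- factor(y)
  if (nlevels(f) != 2L)
    stop("need exactly two classes, got ", nlevels(f))
  lev <- levels(f)
  if (is.null(positive))
    positive <- if ("with_sputum" %in% lev) "with_sputum" else lev[2]
  if (!positive %in% lev) stop("positive class '", positive, "' not in labels")
  list(code = as.integer(f == positive), positive = positive,
       negative = setdiff(lev, positive))
}

#' Fit a ridge-penalised logistic classifier
#'
#' Maximises the binomial log-likelihood minus `ridge/2 * sum(beta_j^2)`
#' (intercept unpenalised) by iteratively reweighted least squares. Features
#' are standardised internally (location/scale stored in the model and
#' reapplied at prediction time); the default near-zero ridge gives plain
#' maximum likelihood with numerical stabilisation.
#'
#' @param X Numeric feature matrix, rows = instances.
#' @param y Two-class labels; `"with_sputum"` is the positive class when
#'   present, otherwise the second factor level (override with `positive`).
#' @param ridge Penalty weight (default 1e-8).
#' @param positive Positive-class label.
#' @param max_iter,tol IRLS iteration cap and penalised-deviance tolerance.
#' @return A `ridge_logistic` model object.
#' @export
fit_logistic <- function(X, y, ridge = 1e-8, positive = NULL,
                         max_iter = 100L, tol = 1e-10) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must be finite (no missing values)")
  bin <- as_binary(y, positive)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 instances")
  if (length(bin$code) != n) stop("length(y) must match nrow(X)")
  if (all(bin$code == bin$code[1])) stop("y contains a single class")
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Z <- cbind(1, sweep(sweep(X, 2, center), 2, scale, "/"))
  log1pexp <- function(e) ifelse(e > 30, e, log1p(exp(pmin(e, 30))))
  pen <- diag(c(0, rep(ridge, p)), p + 1L)
  beta <- numeric(p + 1L)
  obj_old <- Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z_work <- eta + (bin$code - mu) / w
    A <- crossprod(Z, Z * w) + pen
    beta_new <- solve(A, crossprod(Z, w * z_work))
    beta <- drop(beta_new)
    eta <- drop(Z %*% beta)
    ll <- sum(bin$code * eta - log1pexp(eta))
    obj <- -ll + ridge / 2 * sum(beta[-1]^2)
    if (abs(obj_old - obj) < tol * (abs(obj) + 1)) { converged <- TRUE; break }
    obj_old <- obj
  }
  if (!converged)
    warning("IRLS did not converge in ", max_iter, " iterations")
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  structure(list(coefficients = stats::setNames(beta, c("(Intercept)", nm)),
                 center = stats::setNames(center, nm),
                 scale = stats::setNames(scale, nm),
                 ridge = ridge, converged = converged, iterations = iter,
                 log_likelihood = sum(bin$code * drop(Z %*% beta) -
                                        log1pexp(drop(Z %*% beta))),
                 positive = bin$positive, negative = bin$negative,
                 features = nm, n = n),
            class = "ridge_logistic")
}

#' @export
print.ridge_logistic <- function(x, ...) {
  cat(sprintf("<ridge_logistic> %d features, n = %d, ridge = %g (%s, %d IRLS iterations)\n",
              length(x$features), x$n, x$ridge,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat("positive class:", x$positive, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.ridge_logistic <- function(object, ...) object$coefficients

#' @export
summary.ridge_logistic <- function(object, ...) {
  cat("Ridge-penalised logistic model (standardised features)\n")
  print(object)
  cat(sprintf("penalised log-likelihood: %.4f\n",
              object$log_likelihood - object$ridge / 2 *
                sum(object$coefficients[-1]^2)))
  invisible(object)
}

#' Predict sputum probabilities and labels
#'
#' @param object A fitted `ridge_logistic`.
#' @param newdata Feature matrix with the training columns (by name when
#'   both are named).
#' @param type `"response"` (probability of the positive class, default),
#'   `"class"` or `"link"`.
#' @param ... Unused.
#' @export
predict.ridge_logistic <- function(object, newdata,
                                   type = c("response", "class", "link"),
                                   ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$features))
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object$features))
  if (!is.null(colnames(X)) && all(object$features %in% colnames(X)))
    X <- X[, object$features, drop = FALSE]
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  eta <- drop(object$coefficients[1] + Z %*% object$coefficients[-1])
  switch(type,
         link = eta,
         response = 1 / (1 + exp(-eta)),
         class = ifelse(eta > 0, object$positive, object$negative))
}

#' Confusion-matrix metrics
#'
#' Positive class = with sputum. Per-class accuracy is correct/row-total —
#' the positive row gives the sensitivity, the negative row the specificity.
#' A zero row total makes the affected metric `NA` (flagged, never silently
#' 0).
#'
#' @param TP,FN,FP,TN Non-negative confusion counts.
#' @return List with `sensitivity`, `specificity`, `accuracy`,
#'   `per_class_accuracy` (named positive/negative) and the counts.
#' @export
compute_metrics <- function(TP, FN, FP, TN) {
  stopifnot(TP >= 0, FN >= 0, FP >= 0, TN >= 0, TP + FN + FP + TN > 0)
  sens <- if (TP + FN == 0) NA_real_ else TP / (TP + FN)
  spec <- if (TN + FP == 0) NA_real_ else TN / (TN + FP)
  if (is.na(sens) || is.na(spec))
    warning("a confusion-matrix row is empty; metric undefined (NA)")
  list(sensitivity = sens, specificity = spec,
       accuracy = (TP + TN) / (TP + FN + FP + TN),
       per_class_accuracy = c(positive = sens, negative = spec),
       counts = c(TP = TP, FN = FN, FP = FP, TN = TN))
}

stratified_folds <- function(code, folds, seed) {
  assign <- integer(length(code))
  with_seed(seed, {
    for (cls in unique(code)) {
      idx <- sample(which(code == cls))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Stratified k-fold cross-validation of the texture classifier
#'
#' Seeded stratified fold assignment; the model (and, when `select_k` is
#' given, the feature subset) is refit on each training split and the pooled
#' out-of-fold confusion matrix is reported. `select_once = TRUE` instead
#' ranks features once on the full data before cross-validation (the
#' rank-then-validate variant; keeps selection out of the folds for
#' comparability at the cost of selection leakage).
#'
#' @param X Feature matrix.
#' @param y Two-class labels.
#' @param folds Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param ridge Passed to [fit_logistic()].
#' @param select_k If non-NULL, keep this many features by `select_criterion`.
#' @param select_criterion Criterion passed to [select_features()].
#' @param select_once Rank on the full data once instead of per fold.
#' @param positive Positive-class label.
#' @return A `breath_cv` report: confusion counts, sensitivity, specificity,
#'   accuracy, per-fold assignment, out-of-fold probabilities, selected
#'   features and the seed.
#' @export
cross_validate <- function(X, y, folds = 10L, seed = 1L, ridge = 1e-8,
                           select_k = NULL,
                           select_criterion = "information_gain",
                           select_once = FALSE, positive = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds > n) stop("more folds than instances")
  bin <- as_binary(y, positive)
  fold <- stratified_folds(bin$code, folds, seed)
  prob <- numeric(n)
  global_sel <- NULL
  if (!is.null(select_k) && select_once)
    global_sel <- select_features(X, y, k = select_k,
                                  criterion = select_criterion)
  fold_sel <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    sel <- if (is.null(select_k)) seq_len(ncol(X))
           else if (select_once) global_sel
           else select_features(X[tr, , drop = FALSE], y[tr], k = select_k,
                                criterion = select_criterion)
    fold_sel[[f]] <- sel
    fit <- fit_logistic(X[tr, sel, drop = FALSE], y[tr], ridge = ridge,
                        positive = bin$positive)
    prob[te] <- predict(fit, X[te, sel, drop = FALSE])
  }
  pred_pos <- prob > 0.5
  truth_pos <- bin$code == 1L
  TP <- sum(pred_pos & truth_pos); FN <- sum(!pred_pos & truth_pos)
  FP <- sum(pred_pos & !truth_pos); TN <- sum(!pred_pos & !truth_pos)
  m <- compute_metrics(TP, FN, FP, TN)
  structure(c(m, list(fold = fold, probabilities = prob, seed = seed,
                      folds = folds, ridge = ridge,
                      selected = if (select_once) list(global_sel)
                                 else fold_sel,
                      positive = bin$positive, negative = bin$negative)),
            class = "breath_cv")
}

#' @export
print.breath_cv <- function(x, ...) {
  cnt <- x$counts
  cat(sprintf("<breath_cv> %d-fold stratified cross-validation (seed %d)\n",
              x$folds, x$seed))
  cat(sprintf("                 classified %s | classified %s | class accuracy\n",
              x$positive, x$negative))
  cat(sprintf("  %-14s %12d | %15d | %.1f%%\n", x$positive, cnt["TP"],
              cnt["FN"], 100 * x$sensitivity))
  cat(sprintf("  %-14s %12d | %15d | %.1f%%\n", x$negative, cnt["FP"],
              cnt["TN"], 100 * x$specificity))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy))
  invisible(x)
}
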