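test_that("separable data fit perfectly with a large weight", {
  x <- matrix(c(rnorm(20, -3, 0.3), rnorm(20, 3, 0.3)), ncol = 1)
  y <- rep(c("without_sputum", "with_sputum"), each = 20)
  fit <- suppressWarnings(fit_logistic(x, y, ridge = 1e-8))
  pred <- predict(fit, x, type = "class")
  expect_identical(pred, y)
  expect_gt(abs(coef(fit)[2]), 10)
  # training point deep inside the positive class
  expect_gt(predict(fit, matrix(4), type = "response"), 0.99)
})

test_that("a constant feature yields the intercept-only prevalence model", {
  X <- matrix(1, 40, 1)
  y <- c(rep("with_sputum", 10), rep("without_sputum", 30))
  fit <- fit_logistic(X, y)
  expect_equal(unname(predict(fit, X)[1]), 0.25, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[2]), 0)
})

test_that("learned boundary aligns with the Bayes discriminant direction", {
  set.seed(501)
  n <- 1000
  mu <- c(1.2, -0.8)                      # isotropic classes: Bayes normal = mu
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             matrix(rnorm(2 * n), n, 2) + rep(mu, each = n))
  y <- rep(c("without_sputum", "with_sputum"), each = n)
  fit <- fit_logistic(X, y)
  w <- coef(fit)[2:3] / fit$scale         # back to original feature scale
  angle <- acos(sum(w * mu) / sqrt(sum(w^2) * sum(mu^2))) * 180 / pi
  expect_lt(angle, 10)
})

test_that("prediction contracts hold", {
  set.seed(502)
  X <- matrix(rnorm(60), 30, 2)
  y <- rep(c("with_sputum", "without_sputum"), 15)
  # near-infinite ridge shrinks weights to ~0: balanced prevalence -> 0.5
  fit0 <- fit_logistic(X, y, ridge = 1e12)
  expect_equal(unname(predict(fit0, X)), rep(0.5, 30), tolerance = 1e-3)
  fit <- fit_logistic(X, y)
  expect_identical(predict(fit, X), predict(fit, X))  # deterministic
  expect_error(predict(fit, X[, 1, drop = FALSE]), "columns")
  expect_error(fit_logistic(X, rep("with_sputum", 30)), "two classes")
})

test_that("IRLS solution matches a generic optimiser of the same objective", {
  set.seed(503)
  X <- matrix(rnorm(60), 30, 2)
  y <- rbinom(30, 1, plogis(0.5 + X[, 1] - 0.7 * X[, 2]))
  labels <- ifelse(y == 1, "with_sputum", "without_sputum")
  ridge <- 0.1
  fit <- fit_logistic(X, labels, ridge = ridge)
  Z <- cbind(1, scale(X))
  negobj <- function(beta) {
    eta <- drop(Z %*% beta)
    -(sum(y * eta - log1p(exp(eta))) - ridge / 2 * sum(beta[-1]^2))
  }
  opt <- optim(numeric(3), negobj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_equal(negobj(unname(coef(fit))), opt$value, tolerance = 1e-6)
})

test_that("monotone ridge shrinkage drives weights to zero", {
  set.seed(504)
  X <- matrix(rnorm(200), 100, 2)
  y <- ifelse(X[, 1] + rnorm(100, sd = 0.5) > 0, "with_sputum",
              "without_sputum")
  wmax <- vapply(c(1e-8, 1, 100, 1e6), function(r)
    max(abs(coef(fit_logistic(X, y, ridge = r))[-1])), 1)
  expect_true(all(diff(wmax) < 0))
  acc_huge <- mean(predict(fit_logistic(X, y, ridge = 1e8), X,
                           type = "class") == y)
  expect_equal(acc_huge, max(table(y)) / 100, tolerance = 0.02)
})

test_that("stratified cross-validation partitions the data reproducibly", {
  set.seed(505)
  X <- matrix(rnorm(220 * 3), 220, 3)
  y <- rep(c("with_sputum", "without_sputum"), each = 110)
  X[, 1] <- X[, 1] + 2 * (y == "with_sputum")
  cv <- cross_validate(X, y, folds = 10, seed = 1)
  expect_equal(as.vector(table(cv$fold)), rep(22, 10))  # 22 per fold
  # every sample predicted exactly once out of fold
  expect_equal(sum(cv$counts), 220)
  # stratification: 11 per class per fold
  expect_true(all(table(cv$fold, y) == 11))
  cv2 <- cross_validate(X, y, folds = 10, seed = 1)
  expect_identical(cv2$probabilities, cv$probabilities)
  cv3 <- cross_validate(X, y, folds = 10, seed = 2)
  expect_false(identical(cv3$fold, cv$fold))
  expect_error(cross_validate(X[1:5, ], y[1:5], folds = 10), "folds")
})

test_that("label permutation yields chance-level accuracy", {
  set.seed(506)
  X <- matrix(rnorm(200 * 4), 200, 4)
  accs <- vapply(1:20, function(i) {
    y <- sample(rep(c("with_sputum", "without_sputum"), 100))
    cross_validate(X, y, folds = 10, seed = i)$accuracy
  }, 1)
  expect_lt(abs(mean(accs) - 0.5), 0.10)
})

test_that("confusion metrics follow their definitions", {
  m <- compute_metrics(TP = 94, FN = 16, FP = 15, TN = 95)
  expect_equal(round(100 * m$per_class_accuracy[["positive"]], 1), 85.5)
  expect_equal(round(100 * m$per_class_accuracy[["negative"]], 1), 86.4)
  expect_equal(m$accuracy, 189 / 220)
  m2 <- compute_metrics(25, 25, 25, 25)
  expect_equal(m2$sensitivity, 0.5)
  expect_equal(m2$specificity, 0.5)
  expect_equal(m2$accuracy, 0.5)
  expect_warning(compute_metrics(0, 0, 10, 10), "empty")
  expect_true(is.na(suppressWarnings(compute_metrics(0, 0, 10, 10))$sensitivity))
})
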