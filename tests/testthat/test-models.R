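# Prediction models: fitting, cross-validation, BIC, serialization.

test_that("noiseless linear data is recovered exactly", {
  score <- seq(-1, 1, length.out = 20)
  m <- fit_model(score, 2 * score, "linear")
  expect_equal(unname(m$coefficients), c(0, 2), tolerance = 1e-10)
  expect_lt(m$training_metrics$rmse, 1e-10)
})

test_that("quadratic data separates the model classes", {
  score <- seq(-1, 1, length.out = 21)   # symmetric grid
  auc <- score^2
  q <- fit_model(score, auc, "quadratic")
  l <- fit_model(score, auc, "linear")
  expect_lt(q$training_metrics$rmse, 1e-10)
  expect_gt(l$training_metrics$rmse, 0.1)
})

test_that("linear coefficients match the normal-equations oracle", {
  for (i in 1:10) {
    d <- withr::with_seed(i, list(x = stats::rnorm(30),
                                  y = stats::rnorm(30)))
    m <- fit_model(d$x, d$y, "linear")
    X <- cbind(1, d$x)
    beta <- solve(t(X) %*% X, t(X) %*% d$y)
    expect_equal(unname(m$coefficients), as.numeric(beta), tolerance = 1e-8)
  }
})

test_that("degenerate constant scores fall back or fail as specified", {
  x <- rep(0.3, 10)
  y <- withr::with_seed(5, stats::rnorm(10, 0.5, 0.1))
  expect_warning(m <- fit_model(x, y, "linear"), "intercept-only")
  expect_equal(unname(m$coefficients), mean(y))
  expect_equal(predict(m, c(-1, 2)), rep(mean(y), 2))
  expect_error(fit_model(x, y, "svm_rbf"), "constant scores")
  expect_error(fit_model(1:2, 1:2, "linear"), "at least 3")
})

test_that("SVM methods fit monotone data sensibly", {
  score <- seq(-1, 1, length.out = 40)
  auc <- withr::with_seed(8, 0.5 + 0.3 * score + stats::rnorm(40, 0, 0.02))
  for (method in c("svm_linear", "svm_poly", "svm_rbf")) {
    m <- fit_model(score, auc, method, list(cost = 1, epsilon = 0.01))
    expect_lt(m$training_metrics$rmse, 0.1)
    expect_gt(stats::cor(predict(m, score), auc), 0.8)
  }
})

test_that("cv_partition yields balanced deterministic folds", {
  for (n in c(9, 10, 11, 60)) {
    f <- cv_partition(n, 3, seed = 42)
    expect_identical(f, cv_partition(n, 3, seed = 42))
    expect_equal(sort(unique(f)), 1:3)
    expect_lte(diff(range(table(f))), 1)
  }
  expect_error(cv_partition(2, 3, 1), "cannot partition")
})

test_that("cross-validation of noiseless linear data has ~zero error", {
  score <- seq(0, 1, length.out = 30)
  cv <- cross_validate(score, 0.2 + 0.5 * score, methods = "linear",
                       repeats = 3, seed = 2)
  expect_lt(cv$best$rmse_mean, 1e-8)
  expect_true(is.finite(cv$best$bic) || cv$best$bic == -Inf)
})

test_that("hyperparameter selection picks the lowest mean RMSE", {
  d <- withr::with_seed(11, {
    x <- stats::rnorm(45)
    list(x = x, y = 0.5 + 0.2 * x + stats::rnorm(45, 0, 0.05))
  })
  cv <- cross_validate(d$x, d$y, methods = c("linear", "svm_rbf"),
                       repeats = 2, seed = 3)
  for (mth in unique(cv$summary$method)) {
    rows <- cv$summary[cv$summary$method == mth, ]
    expect_equal(cv$best$rmse_mean[cv$best$method == mth], min(rows$rmse_mean))
  }
  expect_named(cv$final_models, c("linear", "svm_rbf"))
  expect_error(cross_validate(d$x, d$y, methods = "linear",
                              grids = list(linear = data.frame())),
               "empty hyperparameter grid")
})

test_that("held-out folds never influence their own fold's model", {
  d <- withr::with_seed(21, {
    x <- stats::rnorm(30)
    list(x = x, y = 0.5 + 0.3 * x + stats::rnorm(30, 0, 0.05))
  })
  cv1 <- cross_validate(d$x, d$y, methods = "linear", repeats = 1,
                        seed = 7, keep_fold_coefs = TRUE)
  folds <- cv_partition(30, 3, seed = 7 + 1)  # repeat 1 uses seed + 1
  y2 <- d$y
  y2[folds == 1] <- y2[folds == 1] + 10       # poison fold 1
  cv2 <- cross_validate(d$x, y2, methods = "linear", repeats = 1,
                        seed = 7, keep_fold_coefs = TRUE)
  # the model evaluated on fold 1 is trained on folds 2-3: unchanged
  expect_equal(cv1$fold_coefs$linear_g1_r1_f1, cv2$fold_coefs$linear_g1_r1_f1)
  # models trained with fold 1 inside must move
  expect_false(isTRUE(all.equal(cv1$fold_coefs$linear_g1_r1_f2,
                                cv2$fold_coefs$linear_g1_r1_f2)))
})

test_that("BIC follows its closed form and penalizes the extra term", {
  # residuals orthogonal to (1, x) with RSS = 10, so the fitted linear model
  # leaves exactly that RSS: BIC = n ln(RSS/n) + p ln(n) = 2 ln(10)
  x <- 1:10
  e <- c(1, -1, -1, 1, 0, 0, 1, -1, -1, 1) * sqrt(10 / 8)
  stopifnot(abs(sum(e)) < 1e-12, abs(sum(e * x)) < 1e-12)
  y <- 0.3 + 0.1 * x + e
  m <- fit_model(x, y, "linear")
  expect_equal(bic(m, x, y), 2 * log(10), tolerance = 1e-8)

  # on truly linear data the quadratic model pays its penalty
  d <- withr::with_seed(31, {
    xs <- stats::rnorm(40)
    list(x = xs, y = 0.4 + 0.25 * xs + stats::rnorm(40, 0, 0.05))
  })
  bl <- bic(fit_model(d$x, d$y, "linear"), d$x, d$y)
  bq <- bic(fit_model(d$x, d$y, "quadratic"), d$x, d$y)
  expect_lt(bl, bq)

  # location shifts of the response leave BIC unchanged after refit
  bl2 <- bic(fit_model(d$x, d$y + 5, "linear"), d$x, d$y + 5)
  expect_equal(bl, bl2, tolerance = 1e-8)

  expect_warning(b0 <- bic(fit_model(1:5, 2 * (1:5), "linear"), 1:5,
                           2 * (1:5)),
                 "RSS = 0")
  expect_identical(b0, -Inf)
  expect_error(bic(fit_model(d$x, d$y, "svm_rbf"), d$x, d$y),
               "regression methods only")
})

test_that("models survive the JSON round trip", {
  d <- withr::with_seed(41, {
    x <- stats::rnorm(35)
    list(x = x, y = 0.5 + 0.2 * x - 0.1 * x^2 + stats::rnorm(35, 0, 0.03))
  })
  grid <- seq(-2, 2, length.out = 50)
  for (method in c("linear", "quadratic", "svm_linear", "svm_poly",
                   "svm_rbf")) {
    m <- fit_model(d$x, d$y, method,
                   if (startsWith(method, "svm"))
                     list(cost = 1, epsilon = 0.1) else list())
    path <- withr::local_tempfile(fileext = ".json")
    write_model_json(m, path)
    m2 <- read_model_json(path)
    expect_equal(predict(m2, grid), predict(m, grid), tolerance = 1e-8)
  }
})
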