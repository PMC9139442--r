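#' Fit a per-drug response prediction model
#'
#' Maps a single feature — the drug's signature score — to the observed AUC.
#' `"linear"` and `"quadratic"` are least-squares fits via [stats::lm()];
#' the three SVM methods are epsilon-regression via [e1071::svm()] with the
#' named kernel.
#'
#' @param scores Numeric signature scores, one per sample.
#' @param auc Numeric observed AUC values aligned with `scores`.
#' @param method One of `"linear"`, `"quadratic"`, `"svm_linear"`,
#'   `"svm_poly"`, `"svm_rbf"`.
#' @param hyperparameters Named list for the SVM methods (`cost`,
#'   `epsilon`, and `gamma` / `degree` where the kernel uses them);
#'   ignored by the regression methods.
#' @param drug_id Optional drug identifier stored in the model.
#' @return Object of class `prediction_model`: `method`, `hyperparameters`,
#'   the fitted engine, `coefficients` (regression methods), and training
#'   metrics (`rmse`, `mae`, `r_squared`).
#' @export
fit_model <- function(scores, auc,
                      method = c("linear", "quadratic", "svm_linear",
                                 "svm_poly", "svm_rbf"),
                      hyperparameters = list(), drug_id = NULL) {
  method <- match.arg(method)
  scores <- as.numeric(scores)
  auc <- as.numeric(auc)
  if (length(scores) != length(auc)) stop("scores and auc must be aligned")
  if (length(scores) < 3) stop("need at least 3 samples to fit")
  degenerate <- stats::sd(scores) == 0
  if (degenerate && startsWith(method, "svm"))
    stop("constant scores: SVM fit is undefined")

  if (method %in% c("linear", "quadratic")) {
    df <- data.frame(score = scores, auc = auc)
    fit <- if (degenerate) {
      warning("constant scores: fitting intercept-only model")
      stats::lm(auc ~ 1, data = df)
    } else if (method == "linear") {
      stats::lm(auc ~ score, data = df)
    } else {
      stats::lm(auc ~ score + I(score^2), data = df)
    }
    engine <- fit
    coefs <- stats::coef(fit)
  } else {
    kernel <- switch(method, svm_linear = "linear", svm_poly = "polynomial",
                     svm_rbf = "radial")
    args <- c(list(x = matrix(scores, ncol = 1), y = auc,
                   type = "eps-regression", kernel = kernel),
              hyperparameters)
    engine <- do.call(e1071::svm, args)
    coefs <- NULL
  }
  model <- structure(list(drug_id = drug_id, method = method,
                          hyperparameters = hyperparameters,
                          engine = engine, coefficients = coefs),
                     class = "prediction_model")
  pred <- predict(model, scores)
  model$training_metrics <- regression_metrics(pred, auc)
  model
}

#' Predict AUC from signature scores
#'
#' @param object A `prediction_model`.
#' @param newscores Numeric vector of scores.
#' @param ... Unused.
#' @return Numeric vector of predicted AUC values.
#' @export
predict.prediction_model <- function(object, newscores, ...) {
  newscores <- as.numeric(newscores)
  if (inherits(object$engine, "drugsig_json_svm"))
    return(predict_json_svm(object$engine, newscores))
  if (object$method %in% c("linear", "quadratic") &&
      is.null(object$engine)) {
    # JSON-restored regression model: evaluate the polynomial directly
    co <- object$coefficients
    return(drop(outer(newscores, seq_along(co) - 1, "^") %*% co))
  }
  if (object$method %in% c("linear", "quadratic")) {
    unname(stats::predict(object$engine,
                          newdata = data.frame(score = newscores)))
  } else {
    unname(stats::predict(object$engine, matrix(newscores, ncol = 1)))
  }
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf("prediction_model [%s]%s\n", x$method,
              if (!is.null(x$drug_id)) paste0(" for ", x$drug_id) else ""))
  if (!is.null(x$coefficients)) {
    cat("  coefficients:",
        paste(sprintf("%.4g", x$coefficients), collapse = ", "), "\n")
  }
  if (!is.null(x$training_metrics))
    cat(sprintf("  training RMSE %.4g, MAE %.4g, R2 %.4g\n",
                x$training_metrics$rmse, x$training_metrics$mae,
                x$training_metrics$r_squared))
  invisible(x)
}

# internal: held-out fit metrics. R^2 is the squared Pearson correlation
# between predictions and observations (NA when either is constant).
regression_metrics <- function(predicted, observed) {
  resid <- predicted - observed
  r2 <- if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) NA_real_
    else stats::cor(predicted, observed)^2
  list(rmse = sqrt(mean(resid^2)), mae = mean(abs(resid)), r_squared = r2)
}

#' Seeded partition into k near-equal folds
#'
#' Deterministic under `seed`; fold sizes differ by at most one.
#'
#' @param n Number of samples.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1:k`, length `n`.
#' @export
cv_partition <- function(n, k, seed) {
  if (n < k) stop("cannot partition ", n, " samples into ", k, " folds")
  withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

#' Default SVM hyperparameter grids
#'
#' Small logarithmic grids over cost (and gamma for the radial kernel,
#' degree for the polynomial kernel) with epsilon fixed at 0.1. The
#' regression methods take no hyperparameters.
#'
#' @return Named list of data.frames, one per method.
#' @export
default_grids <- function() {
  list(linear = data.frame(row.names = 1),
       quadratic = data.frame(row.names = 1),
       svm_linear = expand.grid(cost = c(0.1, 1, 10), epsilon = 0.1),
       svm_poly = expand.grid(cost = c(0.1, 1, 10), degree = 2:3,
                              epsilon = 0.1),
       svm_rbf = expand.grid(cost = c(0.1, 1, 10),
                             gamma = c(0.1, 1, 10), epsilon = 0.1))
}

#' Repeated k-fold cross-validation over methods and hyperparameter grids
#'
#' For each repeat, samples are partitioned once into `k` near-equal folds
#' (partition seed = `seed + repeat index`) and the same partition is used
#' for every method and hyperparameter set, so methods are compared on
#' identical splits. Each fold is held out once; RMSE, MAE and R-squared
#' are computed on each held-out fold and aggregated (mean and SD) over the
#' `k * repeats` evaluations. Per method, the hyperparameter set with the
#' lowest mean RMSE is selected and a final model is fitted on all data;
#' for the regression methods the BIC of the final fit is reported.
#'
#' @inheritParams fit_model
#' @param methods Character vector of methods to evaluate.
#' @param grids Named list of hyperparameter data.frames (one row per
#'   candidate set), as [default_grids()].
#' @param k Number of folds (default 3).
#' @param repeats Number of repeats (default 20).
#' @param seed Integer seed for the fold partitions.
#' @param keep_fold_coefs If `TRUE`, per-fold fitted coefficients of the
#'   regression methods are returned (for audit).
#' @return Object of class `cv_report`: `summary` (per method x grid row:
#'   mean/SD of RMSE, MAE, R2), `best` (chosen row per method, with BIC for
#'   regression methods), `final_models` (fitted on all data with the
#'   chosen hyperparameters), and optionally `fold_coefs`.
#' @export
cross_validate <- function(scores, auc, methods = c("linear", "quadratic"),
                           grids = default_grids(), k = 3, repeats = 20,
                           seed = 1L, keep_fold_coefs = FALSE) {
  scores <- as.numeric(scores)
  auc <- as.numeric(auc)
  n <- length(scores)
  if (length(auc) != n) stop("scores and auc must be aligned")
  if (n < k) stop("need at least k samples")
  methods <- match.arg(methods, names(default_grids()), several.ok = TRUE)
  rows <- list()
  fold_coefs <- list()
  for (method in methods) {
    grid <- grids[[method]]
    if (is.null(grid)) grid <- data.frame(row.names = 1)
    if (nrow(grid) == 0) stop("empty hyperparameter grid for ", method)
    for (gi in seq_len(nrow(grid))) {
      hp <- as.list(grid[gi, , drop = FALSE])
      metrics <- list()
      for (r in seq_len(repeats)) {
        folds <- cv_partition(n, k, seed + r)
        for (f in seq_len(k)) {
          train <- folds != f
          fit <- fit_model(scores[train], auc[train], method, hp)
          pred <- predict(fit, scores[!train])
          metrics[[length(metrics) + 1]] <-
            regression_metrics(pred, auc[!train])
          if (keep_fold_coefs && !is.null(fit$coefficients))
            fold_coefs[[sprintf("%s_g%d_r%d_f%d", method, gi, r, f)]] <-
              fit$coefficients
        }
      }
      rmse <- vapply(metrics, `[[`, 0, "rmse")
      mae <- vapply(metrics, `[[`, 0, "mae")
      r2 <- vapply(metrics, `[[`, 0, "r_squared")
      rows[[length(rows) + 1]] <- data.frame(
        method = method, grid_row = gi,
        hyperparameters = I(list(hp)),
        rmse_mean = mean(rmse), rmse_sd = stats::sd(rmse),
        mae_mean = mean(mae), mae_sd = stats::sd(mae),
        r2_mean = mean(r2, na.rm = TRUE), r2_sd = stats::sd(r2, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  best_idx <- vapply(unique(summary$method), function(mth) {
    rows_m <- which(summary$method == mth)
    rows_m[which.min(summary$rmse_mean[rows_m])]
  }, 0L)
  best <- summary[best_idx, , drop = FALSE]
  final_models <- lapply(seq_len(nrow(best)), function(i) {
    fit_model(scores, auc, best$method[i], best$hyperparameters[[i]])
  })
  names(final_models) <- best$method
  best$bic <- vapply(seq_len(nrow(best)), function(i) {
    if (best$method[i] %in% c("linear", "quadratic"))
      bic(final_models[[i]], scores, auc)
    else NA_real_
  }, 0)
  rownames(summary) <- rownames(best) <- NULL
  out <- list(summary = summary, best = best, final_models = final_models,
              k = k, repeats = repeats, seed = seed)
  if (keep_fold_coefs) out$fold_coefs <- fold_coefs
  structure(out, class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d-fold x %d repeats\n", x$k, x$repeats))
  print(x$best[, c("method", "rmse_mean", "mae_mean", "r2_mean", "bic")])
  invisible(x)
}

#' Bayesian information criterion of a fitted regression model
#'
#' Gaussian-likelihood form `BIC = n * ln(RSS / n) + p * ln(n)`, where `p`
#' is the number of fitted coefficients (2 for linear, 3 for quadratic).
#' Defined for the regression methods only.
#'
#' @param model A `prediction_model` with method `"linear"` or
#'   `"quadratic"`, fitted on `scores` / `auc`.
#' @param scores,auc The training data.
#' @return The BIC; `-Inf` with a warning when the fit is exact (RSS = 0).
#' @export
bic <- function(model, scores, auc) {
  stopifnot(inherits(model, "prediction_model"))
  if (!model$method %in% c("linear", "quadratic"))
    stop("BIC is defined for the regression methods only")
  n <- length(auc)
  rss <- sum((predict(model, scores) - auc)^2)
  p <- length(model$coefficients)
  if (rss == 0) {
    warning("exact fit (RSS = 0): BIC is -Inf")
    return(-Inf)
  }
  n * log(rss / n) + p * log(n)
}
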