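# End-to-end orchestration: derive signatures per drug, score test cohorts,
# evaluate predictions and classify confidence. Stage seeds are fanned out
# from one global seed so each stage is independently reproducible.

#' Assemble a pipeline configuration
#'
#' Bundles every tunable the pipeline uses: signature-derivation settings,
#' model methods and grids, scoring method with its anchor panel, and the
#' confidence-tier thresholds. Can be populated from a YAML file with
#' [read_pipeline_config()].
#'
#' @param derivation A [signature_params()].
#' @param methods Model methods for training (see [fit_model()]).
#' @param grids Hyperparameter grids (see [default_grids()]).
#' @param scoring_method `"singscore"` or `"stingscore"`.
#' @param stable_panel Anchor gene ids (required for stingscore).
#' @param rho_high,ci_high,rho_low,ci_low Confidence-tier thresholds
#'   (defaults 0.4 / 0.65 and 0.3 / 0.6; see [classify_confidence()]).
#' @param seed Global seed fanned out to stage-specific child seeds.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(derivation = signature_params(),
                            methods = c("linear", "quadratic"),
                            grids = default_grids(),
                            scoring_method = c("singscore", "stingscore"),
                            stable_panel = NULL,
                            rho_high = 0.4, ci_high = 0.65,
                            rho_low = 0.3, ci_low = 0.6,
                            seed = 1L) {
  scoring_method <- match.arg(scoring_method)
  thr <- c(rho_high, ci_high, rho_low, ci_low)
  if (any(thr < 0 | thr > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(derivation = derivation, methods = methods, grids = grids,
                 scoring_method = scoring_method,
                 stable_panel = stable_panel,
                 rho_high = rho_high, ci_high = ci_high,
                 rho_low = rho_low, ci_low = ci_low,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the [pipeline_config()] arguments;
#' `derivation` is a mapping of [signature_params()] arguments. Absent keys
#' fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  deriv <- do.call(signature_params, as.list(y$derivation))
  args <- y[setdiff(names(y), "derivation")]
  do.call(pipeline_config, c(list(derivation = deriv), args))
}

#' Derive drug efficacy signatures for every drug in a response table
#'
#' Runs [resample_correlations()] and [derive_signature()] per drug, on the
#' samples shared between the expression matrix and the response table
#' (samples with a missing AUC for a drug are dropped for that drug). Each
#' drug receives a child seed `derivation$seed + drug index` so the stage
#' is reproducible drug by drug.
#'
#' @param expr Log-expression matrix (genes x samples).
#' @param response data.frame with `sample_id` and one AUC column per drug.
#' @param params A [signature_params()].
#' @param drugs Drugs to derive (default: every non-id column of
#'   `response`). A requested drug missing from `response` is skipped with
#'   a warning.
#' @param gmt_path If non-`NULL`, the derived signatures are also written
#'   as GMT.
#' @return List: `signatures` (named list of [drug_signature]),
#'   `frequencies` (named list of tail-frequency tables) and `manifest`
#'   (echo of parameters, seeds and cohort dimensions).
#' @export
run_derivation <- function(expr, response, params = signature_params(),
                           drugs = NULL, gmt_path = NULL) {
  check_expression(expr)
  stopifnot("sample_id" %in% names(response))
  if (is.null(drugs)) drugs <- setdiff(names(response), "sample_id")
  missing_drugs <- setdiff(drugs, names(response))
  if (length(missing_drugs)) {
    warning("drug column(s) missing from response table, skipped: ",
            paste(missing_drugs, collapse = ", "))
    drugs <- intersect(drugs, names(response))
  }
  shared <- intersect(colnames(expr), response$sample_id)
  if (length(shared) < 5)
    stop("fewer than 5 samples shared between expression and response")
  signatures <- list()
  frequencies <- list()
  for (i in seq_along(drugs)) {
    drug <- drugs[i]
    auc <- stats::setNames(response[[drug]], response$sample_id)[shared]
    keep <- !is.na(auc)
    drug_params <- params
    drug_params$seed <- params$seed + i
    message(sprintf("deriving signature for %s on %d samples", drug,
                    sum(keep)))
    freq <- resample_correlations(expr[, shared[keep], drop = FALSE],
                                  auc[keep], drug_params)
    signatures[[drug]] <- derive_signature(freq, drug_params, drug)
    frequencies[[drug]] <- freq
  }
  if (!is.null(gmt_path)) write_gmt(signatures, gmt_path)
  manifest <- list(resample_fraction = params$resample_fraction,
                   n_resamples = params$n_resamples,
                   tail_fraction = params$tail_fraction,
                   min_frequency = params$min_frequency,
                   seed = params$seed,
                   drugs = drugs,
                   drug_seeds = params$seed + seq_along(drugs),
                   n_genes = nrow(expr), n_samples = length(shared))
  list(signatures = signatures, frequencies = frequencies,
       manifest = manifest)
}

#' Score and evaluate signatures across independent test datasets
#'
#' For each test dataset and each drug present in both the signature list
#' and the dataset's response table, samples are scored against the drug's
#' signature, predictions (model predictions when a fitted model is
#' supplied, otherwise the scores themselves — rank metrics are unchanged
#' by the monotone model map) are compared with the observed AUC, and the
#' per-drug evaluations are classified into confidence tiers.
#'
#' @param signatures Named list of [drug_signature] objects.
#' @param test_sets Named list of datasets, each a list with elements
#'   `expr` (log-expression matrix) and `response` (data.frame with
#'   `sample_id` and AUC columns). A dataset lacking a drug is skipped for
#'   that drug with a message.
#' @param config A [pipeline_config()] (scoring method, panel, tier
#'   thresholds).
#' @param models Optional named list of `prediction_model`s keyed by drug.
#' @param drop_samples Optional character vector of sample ids (e.g.
#'   training cell lines) removed from every test dataset before
#'   evaluation.
#' @param min_samples Minimum evaluable samples per (drug, dataset).
#' @return List: `evaluations` (data.frame with one row per drug x
#'   dataset: rho, ci, rmse, mae, n_samples) and `confidence` (data.frame
#'   drug x tier).
#' @export
run_validation <- function(signatures, test_sets, config = pipeline_config(),
                           models = NULL, drop_samples = NULL,
                           min_samples = 3) {
  if (!length(test_sets)) stop("no test datasets supplied")
  if (is.null(names(test_sets)) || any(names(test_sets) == ""))
    stop("test_sets must be a named list")
  evals <- list()
  for (ds in names(test_sets)) {
    set <- test_sets[[ds]]
    for (drug in names(signatures)) {
      if (!drug %in% names(set$response)) {
        message(sprintf("dataset %s lacks drug %s; skipped", ds, drug))
        next
      }
      auc <- stats::setNames(set$response[[drug]], set$response$sample_id)
      samples <- intersect(colnames(set$expr), names(auc)[!is.na(auc)])
      samples <- setdiff(samples, drop_samples)
      if (length(samples) < min_samples) {
        message(sprintf("dataset %s, drug %s: fewer than %d samples; skipped",
                        ds, drug, min_samples))
        next
      }
      scores <- score_matrix(set$expr[, samples, drop = FALSE],
                             signatures[[drug]],
                             method = config$scoring_method,
                             panel = config$stable_panel)
      predicted <- if (!is.null(models) && drug %in% names(models))
        predict(models[[drug]], scores$total_score)
      else scores$total_score
      evals[[length(evals) + 1]] <-
        evaluate_predictions(predicted, auc[samples], drug, ds)
    }
  }
  if (!length(evals)) stop("no (drug, dataset) pair could be evaluated")
  evaluations <- do.call(rbind, evals)
  confidence <- do.call(rbind, lapply(split(evaluations,
                                            evaluations$drug_id),
    function(e) data.frame(drug_id = e$drug_id[1],
                           tier = classify_confidence(
                             e, config$rho_high, config$ci_high,
                             config$rho_low, config$ci_low),
                           n_datasets = nrow(e),
                           stringsAsFactors = FALSE)))
  rownames(confidence) <- NULL
  list(evaluations = evaluations, confidence = confidence)
}
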