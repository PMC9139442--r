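# Tabular I/O. All matrices travel as TSV with the gene id in the first
# column; gene lengths as a two-column TSV; signatures as GMT; growth curves
# as long-format CSV; models and ground truth as JSON.

#' Write / read a log-expression matrix as TSV
#'
#' Genes in rows, samples in columns; first column `gene_id`.
#'
#' @param expr Log-expression matrix.
#' @param path File path.
#' @return `read_expression_tsv` returns the matrix; the writer returns
#'   `path` invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  check_expression(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  check_expression(m)
  m
}

#' Write / read a count matrix (counts TSV + gene-length TSV)
#'
#' @param counts A [count_matrix].
#' @param path Path of the counts TSV (first column `gene_id`).
#' @param lengths_path Path of the two-column (`gene_id`, `length_bp`)
#'   gene-length TSV.
#' @return `read_counts_tsv` returns a [count_matrix]; the writer returns
#'   `path` invisibly.
#' @export
write_counts_tsv <- function(counts, path, lengths_path) {
  stopifnot(inherits(counts, "count_matrix"))
  df <- data.frame(gene_id = rownames(counts$counts), counts$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(counts$gene_lengths),
               length_bp = unname(counts$gene_lengths)),
    lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path, lengths_path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  len <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  count_matrix(m, stats::setNames(len[[2]], len[[1]]))
}

#' Write / read a drug-response table as TSV
#'
#' First column `sample_id`, one AUC column per drug.
#'
#' @param response data.frame with a `sample_id` column.
#' @param path File path.
#' @export
write_response_tsv <- function(response, path) {
  stopifnot("sample_id" %in% names(response))
  utils::write.table(response, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_tsv
#' @export
read_response_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write signatures to a GMT file
#'
#' Each [drug_signature] becomes two records, `<drug>_UP` and `<drug>_DN`.
#' The second GMT column (description) carries the drug id.
#'
#' @param signatures A [drug_signature] or list of them.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  if (inherits(signatures, "drug_signature")) signatures <- list(signatures)
  lines <- unlist(lapply(signatures, function(sig) {
    c(paste(c(paste0(sig$drug_id, "_UP"), sig$drug_id, sig$up_genes),
            collapse = "\t"),
      paste(c(paste0(sig$drug_id, "_DN"), sig$drug_id, sig$down_genes),
            collapse = "\t"))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read signatures from a GMT file
#'
#' Record pairs `<drug>_UP` / `<drug>_DN` (as written by [write_gmt()]) are
#' reassembled into [drug_signature] objects; parsing is delegated to
#' [fgsea::gmtPathways()].
#'
#' @param path GMT file path.
#' @return Named list of [drug_signature] objects.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  drugs <- unique(sub("_(UP|DN)$", "", names(sets)))
  sigs <- lapply(drugs, function(d) {
    up <- sets[[paste0(d, "_UP")]]
    dn <- sets[[paste0(d, "_DN")]]
    drug_signature(d, up_genes = if (is.null(up)) character() else up,
                   down_genes = if (is.null(dn)) character() else dn)
  })
  stats::setNames(sigs, drugs)
}

#' Write / read per-sample scores as TSV
#'
#' @param scores data.frame from [score_matrix()].
#' @param drug_id Drug id column added to the output.
#' @param path File path.
#' @export
write_scores_tsv <- function(scores, drug_id, path) {
  out <- cbind(scores[, "sample_id", drop = FALSE], drug_id = drug_id,
               scores[, setdiff(names(scores), "sample_id"), drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read cohort ground truth as JSON
#'
#' @param truth Truth list from [generate_cohort()].
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  truth$latent <- as.list(truth$latent)   # keep sample names in the JSON
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$latent <- unlist(x$latent)
  x
}

#' Write / read growth curves as long-format CSV
#'
#' Columns: `mouse_id`, `model_id`, `arm`, `day`, `volume_mm3`,
#' `first_injection_day`.
#'
#' @param curves List of [growth_curve] objects.
#' @param path File path.
#' @export
write_growth_curves_csv <- function(curves, path) {
  if (inherits(curves, "growth_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(mouse_id = cv$mouse_id, model_id = cv$model_id, arm = cv$arm,
               day = cv$days, volume_mm3 = cv$volumes,
               first_injection_day = cv$first_injection_day,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_growth_curves_csv
#' @export
read_growth_curves_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$mouse_id)[unique(df$mouse_id)], function(d) {
    d <- d[order(d$day), ]
    growth_curve(d$mouse_id[1], d$model_id[1], d$arm[1], d$day,
                 d$volume_mm3, d$first_injection_day[1])
  })
}

#' Serialize a fitted prediction model to JSON
#'
#' Regression models store their coefficients; SVM models store the kernel,
#' scaling, support vectors and dual coefficients, from which
#' [read_model_json()] reconstructs the decision function exactly.
#'
#' @param model A `prediction_model`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "prediction_model"))
  obj <- list(drug_id = model$drug_id, method = model$method,
              hyperparameters = model$hyperparameters,
              training_metrics = model$training_metrics)
  if (model$method %in% c("linear", "quadratic")) {
    obj$coefficients <- as.list(model$coefficients)
  } else {
    eng <- model$engine
    obj$svm <- list(
      kernel = c("linear", "polynomial", "radial")[
        match(eng$kernel, c(0, 1, 2))],
      gamma = eng$gamma, degree = eng$degree, coef0 = eng$coef0,
      rho = eng$rho,
      support_vectors = as.numeric(eng$SV),
      dual_coefs = as.numeric(eng$coefs),
      x_center = if (is.null(eng$x.scale)) 0
        else eng$x.scale$`scaled:center`,
      x_scale = if (is.null(eng$x.scale)) 1 else eng$x.scale$`scaled:scale`,
      y_center = if (is.null(eng$y.scale)) 0
        else eng$y.scale$`scaled:center`,
      y_scale = if (is.null(eng$y.scale)) 1 else eng$y.scale$`scaled:scale`)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a prediction model from JSON
#'
#' @param path File path written by [write_model_json()].
#' @return A `prediction_model` usable with [predict.prediction_model()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(drug_id = obj$drug_id, method = obj$method,
                hyperparameters = as.list(obj$hyperparameters),
                training_metrics = obj$training_metrics)
  if (obj$method %in% c("linear", "quadratic")) {
    model$coefficients <- unlist(obj$coefficients)
    model$engine <- NULL
  } else {
    model$coefficients <- NULL
    model$engine <- structure(obj$svm, class = "drugsig_json_svm")
  }
  structure(model, class = "prediction_model")
}

# internal: decision function of a JSON-restored epsilon-regression SVM
predict_json_svm <- function(eng, newscores) {
  x <- (newscores - eng$x_center) / eng$x_scale
  sv <- eng$support_vectors
  k <- switch(eng$kernel,
              linear = outer(x, sv),
              polynomial = (eng$gamma * outer(x, sv) + eng$coef0)^eng$degree,
              radial = exp(-eng$gamma * outer(x, sv, "-")^2))
  raw <- drop(k %*% eng$dual_coefs) - eng$rho
  raw * eng$y_scale + eng$y_center
}

#' Packaged published cross-dataset validation correlations
#'
#' Long-format table of published Spearman correlations between per-drug
#' efficacy signature scores and observed drug response across one training
#' screen (`GRAY`) and six independent test datasets, for the 28 drugs whose
#' models reached medium-or-better confidence, together with the published
#' confidence labels. Used as a worked example for the confidence-tier
#' rule; the `GRAY` rows are the training screen and are excluded from tier
#' classification.
#'
#' @return data.frame: `drug`, `dataset`, `rho`, `confidence`.
#' @export
reported_validation_correlations <- function() {
  path <- system.file("extdata", "reported_validation_rho.tsv",
                      package = "drugsig", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
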