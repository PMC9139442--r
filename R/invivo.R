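#' Per-mouse tumor growth curve
#'
#' Tumor-volume time series for one mouse, with the day of the first drug
#' injection marked. Days must be non-decreasing, volumes strictly
#' positive, and at least one measurement must exist at or after the first
#' injection.
#'
#' @param mouse_id,model_id Identifiers of the mouse and xenograft model.
#' @param arm `"treated"` or `"control"`.
#' @param days Numeric vector of measurement days.
#' @param volumes Tumor volumes (mm3) aligned with `days`.
#' @param first_injection_day Day of the first drug injection.
#' @return Object of class `growth_curve`.
#' @export
growth_curve <- function(mouse_id, model_id, arm = c("treated", "control"),
                         days, volumes, first_injection_day) {
  arm <- match.arg(arm)
  if (length(days) != length(volumes))
    stop("days and volumes must be aligned")
  if (is.unsorted(days)) stop("days must be non-decreasing")
  if (any(volumes <= 0)) stop("volumes must be strictly positive")
  if (!any(days >= first_injection_day))
    stop("no measurement at or after the first injection")
  structure(list(mouse_id = mouse_id, model_id = model_id, arm = arm,
                 days = as.numeric(days), volumes = as.numeric(volumes),
                 first_injection_day = as.numeric(first_injection_day)),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("growth_curve %s (%s, %s): %d points, injection day %g\n",
              x$mouse_id, x$model_id, x$arm, length(x$days),
              x$first_injection_day))
  invisible(x)
}

#' Normalized tumor response (NTR) of a growth curve
#'
#' `NTR = V_min / V_inj`, where `V_inj` is the tumor volume at the first
#' drug injection and `V_min` the smallest volume measured at or after that
#' day (the injection-day measurement itself included, so NTR is always in
#' `(0, 1]` and equals 1 exactly for a tumor that never shrinks below its
#' injection volume). Smaller values mean deeper regression. `invert =
#' TRUE` returns the reciprocal `V_inj / V_min` (>= 1, larger = better
#' response) for workflows using that orientation.
#'
#' If no measurement falls exactly on the injection day, the nearest prior
#' measurement is used as `V_inj` (with a warning); if there is none, an
#' error is thrown.
#'
#' @param curve A [growth_curve].
#' @param invert Return `V_inj / V_min` instead.
#' @return The NTR as a single number.
#' @export
normalized_tumor_response <- function(curve, invert = FALSE) {
  stopifnot(inherits(curve, "growth_curve"))
  inj <- curve$first_injection_day
  at <- which(curve$days == inj)
  if (length(at)) {
    v_inj <- curve$volumes[at[1]]
  } else {
    prior <- which(curve$days < inj)
    if (!length(prior))
      stop("no measurement at or before the first injection")
    warning("no measurement on the injection day; using nearest prior")
    v_inj <- curve$volumes[max(prior)]
  }
  v_min <- min(curve$volumes[curve$days >= inj])
  v_min <- min(v_min, v_inj)
  if (invert) v_inj / v_min else v_min / v_inj
}

#' Summarize per-model in-vivo response
#'
#' Computes per-mouse NTR values and the per-model median, by default over
#' the treated arm only (control arms of a working treatment sit near
#' NTR = 1 and would dilute the response signal).
#'
#' @param curves List of [growth_curve] objects.
#' @param arm Arm(s) to include (default `"treated"`).
#' @return data.frame: `model_id`, `median_ntr`, `n_mice`.
#' @export
summarize_model_response <- function(curves, arm = "treated") {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, TRUE, "growth_curve")))
  keep <- vapply(curves, function(cv) cv$arm %in% arm, TRUE)
  curves <- curves[keep]
  if (!length(curves)) stop("no curves in the requested arm(s)")
  models <- vapply(curves, `[[`, "", "model_id")
  ntr <- vapply(curves, normalized_tumor_response, 0)
  agg <- tapply(ntr, models, stats::median)
  data.frame(model_id = names(agg), median_ntr = as.numeric(agg),
             n_mice = as.integer(table(models)[names(agg)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlate efficacy scores with in-vivo response
#'
#' Spearman correlation between per-model drug efficacy scores and median
#' NTR. A working signature yields a strongly negative correlation: models
#' predicted sensitive (high score) regress deeply (low NTR).
#'
#' @param summaries data.frame with columns `model_id`, `efficacy_score`
#'   and `median_ntr` (as produced by merging [summarize_model_response()]
#'   with per-model scores); at least 3 models.
#' @return Spearman correlation, or `NA` (with a warning) for constant
#'   scores.
#' @export
correlate_scores_with_response <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("efficacy_score", "median_ntr") %in% names(summaries)))
  if (nrow(summaries) < 3) stop("need at least 3 models")
  spearman_rho(summaries$efficacy_score, summaries$median_ntr)
}
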