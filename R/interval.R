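#' Longitudinal interval-change classification
#'
#' Disease trajectory between consecutive visits is rated from the change
#' in the extent score. With `delta = score_next - score_prev` in
#' percentage points and a change threshold (default 5 points): an
#' increase of more than the threshold is *aggravation* (code 1), a
#' decrease of more than the threshold is *improvement* (code 3), and
#' anything else is *no change* (code 2). The inequalities are strict, so
#' a delta of exactly +5.0 is no change.
#'
#' @name interval
NULL

interval_levels <- c(aggravation = 1L, no_change = 2L, improvement = 3L)

#' Classify one visit-to-visit interval
#'
#' @param score_prev,score_next extent scores in percent, in `[0, 100]`.
#' @param change_threshold threshold in score percentage points
#'   (default 5).
#' @return an `interval_result`: list with `delta`, `label`
#'   (`"aggravation"`, `"no_change"`, `"improvement"`), `code` (1, 2, 3)
#'   and `change_threshold`.
#' @export
#' @examples
#' classify_interval(10, 16.1)$label  # "aggravation"
classify_interval <- function(score_prev, score_next, change_threshold = 5) {
  stopifnot(change_threshold > 0,
            score_prev >= 0, score_prev <= 100,
            score_next >= 0, score_next <= 100)
  delta <- score_next - score_prev
  label <- if (delta > change_threshold) "aggravation"
           else if (delta < -change_threshold) "improvement"
           else "no_change"
  structure(list(delta = delta, label = label,
                 code = unname(interval_levels[label]),
                 change_threshold = change_threshold),
            class = "interval_result")
}

#' Score a chronological visit series and rate its intervals
#'
#' Runs the extent-scoring pipeline on every visit of a series and
#' classifies each consecutive visit pair. For a phantom `visit_series`
#' the per-visit virtual normal and lung mask come from the configured
#' backends (the ground-truth oracle by default).
#'
#' @param series a `visit_series` from [generate_followup_series()], or a
#'   list of `phantom_sample` in chronological order.
#' @param params a [scoring_params()].
#' @param change_threshold interval threshold in points (default 5).
#' @param backend virtual-normal backend: `"oracle"` (the paired truth)
#'   or a trained `cut_model`.
#' @param seg_model optional trained `unet_model`; when NULL the
#'   ground-truth lung mask is used.
#' @return list with `scores` (per-visit `extent_result`) and `intervals`
#'   (per-pair `interval_result`, length `visits - 1`).
#' @export
score_series <- function(series, params = scoring_params(),
                         change_threshold = 5, backend = "oracle",
                         seg_model = NULL) {
  visits <- if (inherits(series, "visit_series")) series$visits else series
  if (length(visits) < 2) stop("a series needs at least 2 visits", call. = FALSE)
  scores <- lapply(visits, function(s) {
    stopifnot(inherits(s, "phantom_sample"))
    vn <- if (identical(backend, "oracle")) s$paired_normal
          else generate_virtual_normal(backend, s$diseased)
    lung <- if (is.null(seg_model)) lung_mask(s$lung_mask_truth)
            else predict_lung_mask(seg_model, s$diseased)
    compute_extent(subtract(s$diseased, vn), lung, params)
  })
  intervals <- lapply(seq_len(length(scores) - 1), function(i)
    classify_interval(scores[[i]]$Score_ILD, scores[[i + 1]]$Score_ILD,
                      change_threshold))
  list(scores = scores, intervals = intervals)
}
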