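#' Extent scoring: subtraction, lung masking, area ratio
#'
#' The core quantification step. A diseased radiograph and its virtual
#' normal are subtracted; interstitial opacities are hyperintense relative
#' to normal parenchyma, so disease shows up as positive difference
#' (negative values are clipped). The clipped difference is binarized at a
#' threshold `tau`, restricted to the lung field, and the extent score is
#' the flagged area as a percentage of the lung area:
#' `Score_ILD = 100 * A_ILD / A_Lung`.
#'
#' @name scoring
NULL

#' Scoring parameters
#'
#' @param tau binarization threshold on the clipped difference map,
#'   in intensity units on the `[0, 1]` scale (default 0.10). The
#'   continuous subtraction map must become an area somehow; a fixed,
#'   configurable threshold is the simplest reproducible rule.
#' @param epsilon presence tolerance in score percentage points
#'   (default 0): scores at or below `epsilon` classify as normal.
#' @param clip_negative clip negative differences (default TRUE).
#' @return a `scoring_params` list.
#' @export
scoring_params <- function(tau = 0.10, epsilon = 0, clip_negative = TRUE) {
  stopifnot(tau > 0, tau < 1, epsilon >= 0)
  structure(list(tau = tau, epsilon = epsilon, clip_negative = clip_negative),
            class = "scoring_params")
}

#' Subtract a virtual normal from the original image
#'
#' @param original diseased image, numeric matrix in `[0, 1]`.
#' @param virtual_normal same-size matrix in `[0, 1]` (or a
#'   `virtual_normal` object).
#' @param clip_negative clip negative differences to zero (default TRUE).
#' @return a `difference_map`: list with `values` (matrix >= 0) and
#'   `frame_size`.
#' @export
subtract <- function(original, virtual_normal, clip_negative = TRUE) {
  if (inherits(virtual_normal, "virtual_normal"))
    virtual_normal <- virtual_normal$image
  assert_image(original); assert_image(virtual_normal)
  if (!all(dim(original) == dim(virtual_normal)))
    stop("original and virtual normal are in different frames", call. = FALSE)
  d <- original - virtual_normal
  if (clip_negative) d <- pmax(d, 0)
  structure(list(values = d, frame_size = dim(original)),
            class = "difference_map")
}

#' Compute the extent score from a difference map and a lung mask
#'
#' Flags pixels whose difference exceeds `tau` *and* lie inside the lung,
#' then divides the flagged area by the lung area. Exact integer pixel
#' counting; `Score_ILD = 100 * A_ILD / A_Lung_used` holds to the last bit.
#'
#' @param diff a `difference_map` from [subtract()].
#' @param lung a `lung_mask` (see [lung_mask()]), already in the frame of
#'   `diff` (use [resize_mask()] if needed).
#' @param params a [scoring_params()].
#' @return an `extent_result`: `abnormal_mask`, `A_ILD`, `A_Lung_used`,
#'   `Score_ILD` (percent).
#' @export
compute_extent <- function(diff, lung, params = scoring_params()) {
  stopifnot(inherits(diff, "difference_map"), inherits(params, "scoring_params"))
  lung <- as_lung_mask(lung)
  if (!all(dim(diff$values) == dim(lung$mask)))
    stop("lung mask frame does not match difference map; resize_mask() first",
         call. = FALSE)
  if (lung$a_lung == 0) stop("empty lung mask", call. = FALSE)
  abnormal <- (diff$values > params$tau) & (lung$mask == 1L)
  a_ild <- sum(abnormal)
  structure(list(abnormal_mask = abnormal * 1L,
                 A_ILD = a_ild,
                 A_Lung_used = lung$a_lung,
                 Score_ILD = 100 * a_ild / lung$a_lung),
            class = "extent_result")
}

#' Classify disease presence from an extent score
#'
#' A score of exactly 0% is normal; any positive score indicates ILD. The
#' tolerance `epsilon` generalizes the exact-zero rule for noisy inputs.
#'
#' @param result an `extent_result`.
#' @param params a [scoring_params()].
#' @return `"normal"` or `"ILD"`.
#' @export
classify_presence <- function(result, params = scoring_params()) {
  stopifnot(inherits(result, "extent_result"))
  if (result$Score_ILD <= params$epsilon) "normal" else "ILD"
}

#' Render a heatmap overlay of the abnormal region
#'
#' Writes a PNG in which pixels outside the abnormal mask show the base
#' image in grayscale and abnormal pixels are color-coded by difference
#' magnitude on a fixed black-red-yellow ramp anchored to `[0, 1]`, so
#' colors are comparable across images.
#'
#' @param diff a `difference_map`.
#' @param result an `extent_result` in the same frame.
#' @param out output PNG path.
#' @param base optional background image (defaults to the difference map's
#'   zero raster if not given).
#' @return invisibly, `out`.
#' @export
render_heatmap <- function(diff, result, out, base = NULL) {
  stopifnot(inherits(diff, "difference_map"), inherits(result, "extent_result"))
  d <- dim(diff$values)
  if (is.null(base)) base <- matrix(0, d[1], d[2])
  assert_image(base)
  stopifnot(all(dim(base) == d))
  rgb <- array(rep(pmin(pmax(base, 0), 1), 3), c(d, 3))
  hot <- result$abnormal_mask == 1L
  if (any(hot)) {
    v <- pmin(pmax(diff$values[hot], 0), 1)
    # black-red-yellow ramp on [0,1]
    rgb[, , 1][hot] <- pmin(2 * v, 1)
    rgb[, , 2][hot] <- pmax(2 * v - 1, 0)
    rgb[, , 3][hot] <- 0
  }
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(rgb, out)
  invisible(out)
}

#' Per-image scoring report
#'
#' @param result an `extent_result`.
#' @param params the [scoring_params()] used.
#' @param backend backend identifier string.
#' @param heatmap_file optional heatmap path.
#' @param out optional JSON path; written when given.
#' @return the report list.
#' @export
extent_report <- function(result, params, backend = "oracle",
                          heatmap_file = NULL, out = NULL) {
  rep <- list(score_percent = result$Score_ILD,
              a_ild_px = result$A_ILD,
              a_lung_px = result$A_Lung_used,
              tau = params$tau,
              backend = backend,
              heatmap_file = heatmap_file)
  if (!is.null(out))
    jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(rep)
}
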