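#' Evaluation metrics
#'
#' Dice overlap for masks, SSIM/PSNR image fidelity, one-vs-rest
#' multiclass classification metrics, and an exhaustive-search oracle that
#' recovers integer confusion marginals from printed per-class
#' percentages.
#'
#' @name metrics
NULL

#' Dice overlap of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks are identical, so the score
#' is 1 by convention.
#'
#' @param a,b binary matrices (0/1 or logical) in the same frame.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_score <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask frames differ", call. = FALSE)
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# 1-D Gaussian taps for the SSIM window
ssim_window <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

#' Structural similarity index (mean SSIM)
#'
#' Standard formulation: local statistics under an 11x11 Gaussian window
#' (sigma 1.5), stability constants `K1 = 0.01`, `K2 = 0.03`, data range
#' 1.0, valid-mode windows (borders cropped), averaged over the image.
#' Symmetric in its arguments.
#'
#' @param a,b numeric matrices in `[0, 1]`, same frame, at least 11x11.
#' @return mean SSIM in `[-1, 1]` (1 for identical images).
#' @export
ssim <- function(a, b) {
  assert_image(a); assert_image(b)
  if (!all(dim(a) == dim(b))) stop("image frames differ", call. = FALSE)
  if (nrow(a) < 11 || ncol(a) < 11)
    stop("images must be at least 11x11 for the SSIM window", call. = FALSE)
  w <- ssim_window()
  c1 <- 0.01^2; c2 <- 0.03^2
  mu_a <- .filter2_valid(a, w);  mu_b <- .filter2_valid(b, w)
  saa  <- .filter2_valid(a * a, w) - mu_a^2
  sbb  <- .filter2_valid(b * b, w) - mu_b^2
  sab  <- .filter2_valid(a * b, w) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * sab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (saa + sbb + c2)
  mean(num / den)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(1 / MSE)` for intensities on a `[0, 1]` data range, in
#' decibels. Identical images have zero MSE and return `Inf`.
#'
#' @param a,b numeric matrices in `[0, 1]`, same frame.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(a, b) {
  assert_image(a); assert_image(b)
  if (!all(dim(a) == dim(b))) stop("image frames differ", call. = FALSE)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

#' One-vs-rest confusion marginals for the three interval classes
#'
#' @param tp,fp,fn,tn named integer vectors over the classes
#'   `aggravation`, `no_change`, `improvement` (any consistent class set
#'   is accepted).
#' @return a `confusion_marginals` object.
#' @export
confusion_marginals <- function(tp, fp, fn, tn) {
  classes <- names(tp)
  if (is.null(classes)) classes <- c("aggravation", "no_change", "improvement")
  n <- unique(tp + fp + fn + tn)
  if (length(n) != 1)
    stop("TP+FP+FN+TN must equal the same n for every class", call. = FALSE)
  if (sum(tp) + sum(fn) != n)
    stop("actual class counts (TP+FN) must sum to n", call. = FALSE)
  if (sum(fn) != sum(fp))
    stop("total FN must equal total FP across classes", call. = FALSE)
  structure(list(classes = classes,
                 tp = stats::setNames(as.integer(tp), classes),
                 fp = stats::setNames(as.integer(fp), classes),
                 fn = stats::setNames(as.integer(fn), classes),
                 tn = stats::setNames(as.integer(tn), classes),
                 n = as.integer(n)),
            class = "confusion_marginals")
}

#' @rdname confusion_marginals
#' @param truth,pred factors or vectors of class labels of equal length.
#' @param levels class levels; defaults to the union of observed labels
#'   (pass explicitly to keep classes absent from a small cohort).
#' @export
marginals_from_labels <- function(truth, pred, levels = NULL) {
  lv <- if (!is.null(levels)) levels
        else union(unique(as.character(truth)), unique(as.character(pred)))
  truth <- factor(as.character(truth), levels = lv)
  pred <- factor(as.character(pred), levels = lv)
  n <- length(truth)
  tp <- fp <- fn <- tn <- stats::setNames(integer(length(lv)), lv)
  for (c in lv) {
    tp[c] <- sum(truth == c & pred == c)
    fp[c] <- sum(truth != c & pred == c)
    fn[c] <- sum(truth == c & pred != c)
    tn[c] <- n - tp[c] - fp[c] - fn[c]
  }
  confusion_marginals(tp, fp, fn, tn)
}

#' Per-class and overall classification metrics
#'
#' One-vs-rest accuracy, precision, recall, specificity and F1 per class,
#' plus the overall accuracy `100 * sum(TP) / n`. All values are
#' percentages. A zero denominator yields 0 with a warning rather than an
#' error, so cohorts with an empty class still evaluate.
#'
#' @param marginals a [confusion_marginals()].
#' @return a `metrics_report`: data frame of per-class metrics plus an
#'   `overall_accuracy` attribute.
#' @export
per_class_metrics <- function(marginals) {
  stopifnot(inherits(marginals, "confusion_marginals"))
  if (marginals$n == 0) stop("n = 0", call. = FALSE)
  safe_div <- function(num, den, what) {
    out <- numeric(length(num))
    zero <- den == 0
    if (any(zero))
      warning("zero denominator in ", what, " for class(es) ",
              paste(marginals$classes[zero], collapse = ", "),
              "; reporting 0", call. = FALSE)
    out[!zero] <- num[!zero] / den[!zero]
    out
  }
  with(marginals, {
    acc <- 100 * (tp + tn) / n
    prec <- 100 * safe_div(tp, tp + fp, "precision")
    rec <- 100 * safe_div(tp, tp + fn, "recall")
    spec <- 100 * safe_div(tn, tn + fp, "specificity")
    f1 <- 100 * safe_div(2 * tp, 2 * tp + fp + fn, "F1")
    out <- data.frame(class = classes, accuracy = acc, precision = prec,
                      recall = rec, f1 = f1, specificity = spec,
                      row.names = NULL)
    attr(out, "overall_accuracy") <- 100 * sum(tp) / n
    class(out) <- c("metrics_report", "data.frame")
    out
  })
}

#' Recover integer confusion marginals from printed percentages
#'
#' Exhaustive-search oracle: given per-class printed precision, recall and
#' specificity (percent, 2 decimals) for a 3-class one-vs-rest table,
#' searches all integer marginals `(actual count, TP, FP)` per class and
#' all totals `n <= n_max` for combinations whose computed metrics are
#' consistent with the printed values. A computed value matches a printed
#' one when it lies at most 0.011 above or 0.006 below it, which covers
#' both rounding and truncation to two decimals. Cross-class consistency
#' is enforced: actual counts sum to `n`, total FN equals total FP, and an
#' off-diagonal confusion matrix with those marginals must exist.
#'
#' @param printed data frame (or list) with columns/fields `precision`,
#'   `recall`, `specificity`, one row per class, in class order.
#' @param n_max largest total count to consider (default 300).
#' @param classes class names.
#' @return list with `n` (smallest consistent total), `solutions` (list of
#'   [confusion_marginals()]), and `actual_counts` for the first solution.
#' @export
recover_confusion_marginals <- function(printed, n_max = 300L,
                                        classes = c("aggravation", "no_change",
                                                    "improvement")) {
  printed <- as.data.frame(printed)
  stopifnot(nrow(printed) == length(classes), n_max >= 10)
  ok <- function(computed, print_val)
    computed >= print_val - 0.006 & computed <= print_val + 0.011

  # per-class candidates for a given n: rows (a, tp, fp)
  class_candidates <- function(n, p, r, s) {
    out <- list()
    for (a in 1:(n - 1)) {
      # recall pins TP given a
      tp_guess <- round(r * a / 100)
      for (tp in max(0, tp_guess - 1):min(a, tp_guess + 1)) {
        if (!ok(100 * tp / a, r)) next
        if (tp == 0) next  # printed precision > 0 requires TP > 0
        tot_guess <- round(100 * tp / p)     # TP+FP from precision
        for (tot in max(tp, tot_guess - 1):(tot_guess + 1)) {
          fp <- tot - tp
          if (fp < 0 || a + fp > n) next
          if (!ok(100 * tp / (tp + fp), p)) next
          tn <- n - a - fp
          if (tn + fp > 0 && !ok(100 * tn / (tn + fp), s)) next
          out[[length(out) + 1]] <- c(a = a, tp = tp, fp = fp)
        }
      }
    }
    out
  }

  for (n in 10:n_max) {
    cand <- lapply(seq_along(classes), function(i)
      class_candidates(n, printed$precision[i], printed$recall[i],
                       printed$specificity[i]))
    if (any(vapply(cand, length, 1L) == 0)) next
    sols <- list()
    for (c1 in cand[[1]]) for (c2 in cand[[2]]) for (c3 in cand[[3]]) {
      a <- c(c1["a"], c2["a"], c3["a"])
      if (sum(a) != n) next
      tp <- c(c1["tp"], c2["tp"], c3["tp"])
      fp <- c(c1["fp"], c2["fp"], c3["fp"])
      fn <- a - tp
      if (sum(fn) != sum(fp)) next
      # an off-diagonal 3x3 matrix with row sums fn and col sums fp exists
      # iff no single column wants more than the other rows can give
      if (any(fp > sum(fn) - fn)) next
      m <- confusion_marginals(
        stats::setNames(tp, classes), stats::setNames(fp, classes),
        stats::setNames(fn, classes), stats::setNames(n - a - fp, classes))
      sols[[length(sols) + 1]] <- m
    }
    if (length(sols) > 0) {
      reports <- lapply(sols, per_class_metrics)
      agree <- function(get) {
        v <- vapply(reports, get, numeric(length(classes)))
        all(apply(rbind(v), 1, function(x) diff(range(x)) <= 0.01))
      }
      if (!agree(function(r) r$accuracy) || !agree(function(r) r$f1))
        stop("solutions at n = ", n, " disagree on derived accuracy/F1",
             call. = FALSE)
      return(list(n = n, solutions = sols,
                  actual_counts = stats::setNames(
                    sols[[1]]$tp + sols[[1]]$fn, classes)))
    }
  }
  stop("no consistent confusion marginals found with n <= ", n_max,
       call. = FALSE)
}
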