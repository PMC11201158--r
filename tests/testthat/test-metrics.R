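test_that("dice score follows the overlap formula with the empty-empty convention", {
  a <- matrix(0L, 10, 10); a[1:5, 1:5] <- 1L
  expect_equal(dice_score(a, a), 1)
  b <- matrix(0L, 10, 10); b[6:10, 6:10] <- 1L
  expect_equal(dice_score(a, b), 0)
  # |a| = |b| = 100, overlap 50 -> 0.5
  a2 <- matrix(0L, 20, 20); a2[1:10, 1:10] <- 1L
  b2 <- matrix(0L, 20, 20); b2[6:15, 1:10] <- 1L
  expect_equal(dice_score(a2, b2), 0.5)
  expect_equal(dice_score(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)
  expect_error(dice_score(a, matrix(0L, 4, 4)), "frames differ")
})

test_that("SSIM is 1 for identical images, symmetric, and low for unrelated noise", {
  s <- generate_phantom(phantom_spec(seed = 8, lesion_extent_target = 0.2))
  x <- s$diseased
  expect_equal(ssim(x, x), 1)
  set.seed(4)
  y <- pmin(pmax(x + matrix(rnorm(length(x), sd = 0.05), nrow(x)), 0), 1)
  expect_equal(ssim(x, y), ssim(y, x))
  expect_lt(ssim(x, y), 1)
  noise <- matrix(runif(length(x)), nrow(x))
  expect_lt(ssim(x, noise), 0.2)
  expect_error(ssim(x, matrix(0.5, 8, 8)), "frames differ")
})

test_that("PSNR matches its closed form and gains ~3.01 dB per MSE halving", {
  a <- matrix(0.3, 32, 32)
  expect_identical(psnr(a, a), Inf)
  b <- a + 16 / 255
  expect_equal(psnr(a, b), 20 * log10(255 / 16), tolerance = 1e-12)
  expect_equal(psnr(a, b), 24.05, tolerance = 0.005)
  b2 <- a + (16 / 255) / sqrt(2)   # halves the MSE
  expect_equal(psnr(a, b2) - psnr(a, b), 10 * log10(2), tolerance = 1e-9)
  expect_equal(10 * log10(2), 3.01, tolerance = 0.001)
})

# straightforward per-class formulas, kept separate from the implementation
hand_metrics <- function(cm) {
  n <- sum(cm)
  lapply(seq_len(nrow(cm)), function(c) {
    tp <- cm[c, c]; fn <- sum(cm[c, ]) - tp; fp <- sum(cm[, c]) - tp
    tn <- n - tp - fn - fp
    div <- function(a, b) if (b == 0) 0 else a / b
    list(acc = 100 * (tp + tn) / n, prec = 100 * div(tp, tp + fp),
         rec = 100 * div(tp, tp + fn), spec = 100 * div(tn, tn + fp),
         f1 = 100 * div(2 * tp, 2 * tp + fp + fn))
  })
}

test_that("per-class metrics agree with hand formulas over exhaustive small matrices", {
  perfect <- confusion_marginals(tp = c(a = 3, b = 4, c = 5),
                                 fp = c(a = 0, b = 0, c = 0),
                                 fn = c(a = 0, b = 0, c = 0),
                                 tn = c(a = 9, b = 8, c = 7))
  m <- per_class_metrics(perfect)
  expect_true(all(as.matrix(m[, -1]) == 100))
  expect_equal(attr(m, "overall_accuracy"), 100)

  grid <- expand.grid(rep(list(0:2), 9))
  set.seed(1)
  grid <- grid[rowSums(grid) > 0, ]
  grid <- grid[sample(nrow(grid), 400), ]
  for (r in seq_len(nrow(grid))) {
    cm <- matrix(as.numeric(grid[r, ]), 3, 3, byrow = TRUE)
    truth <- rep(rep(c("a", "b", "c"), each = 3), times = as.vector(t(cm)))
    pred <- rep(rep(c("a", "b", "c"), times = 3), times = as.vector(t(cm)))
    marg <- marginals_from_labels(truth, pred, levels = c("a", "b", "c"))
    rep_ <- suppressWarnings(per_class_metrics(marg))
    hand <- hand_metrics(cm)
    ord <- match(c("a", "b", "c"), rep_$class)
    for (c in 1:3) {
      expect_equal(rep_$accuracy[ord[c]], hand[[c]]$acc)
      expect_equal(rep_$precision[ord[c]], hand[[c]]$prec)
      expect_equal(rep_$recall[ord[c]], hand[[c]]$rec)
      expect_equal(rep_$specificity[ord[c]], hand[[c]]$spec)
      expect_equal(rep_$f1[ord[c]], hand[[c]]$f1)
    }
    expect_equal(attr(rep_, "overall_accuracy"), 100 * sum(diag(cm)) / sum(cm))
  }
})

test_that("zero denominators warn and report 0 instead of failing", {
  marg <- marginals_from_labels(c("a", "a", "b"), c("a", "a", "a"))
  expect_warning(m <- per_class_metrics(marg), "zero denominator")
  expect_equal(m$precision[m$class == "b"], 0)
})

test_that("marginal recovery finds a perfect classifier and rejects contradictions", {
  perfect <- data.frame(precision = c(100, 100, 100), recall = c(100, 100, 100),
                        specificity = c(100, 100, 100))
  rec <- recover_confusion_marginals(perfect, n_max = 30)
  for (s in rec$solutions) {
    expect_true(all(s$fp == 0))
    expect_true(all(s$fn == 0))
  }
  bad <- data.frame(precision = c(100, 100, 100), recall = c(100, 100, 100),
                    specificity = c(0, 0, 0))
  expect_error(recover_confusion_marginals(bad, n_max = 50), "no consistent")
})
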