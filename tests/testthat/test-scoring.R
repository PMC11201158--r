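# independent per-pixel oracle: plain double loop, no vectorization shared
# with the implementation
brute_force_extent <- function(diff_values, lung, tau) {
  a_ild <- 0L; a_lung <- 0L
  for (i in seq_len(nrow(diff_values))) {
    for (j in seq_len(ncol(diff_values))) {
      if (lung[i, j] == 1) {
        a_lung <- a_lung + 1L
        if (diff_values[i, j] > tau) a_ild <- a_ild + 1L
      }
    }
  }
  list(a_ild = a_ild, a_lung = a_lung, score = 100 * a_ild / a_lung)
}

test_that("subtraction clips negative differences and demands matching frames", {
  a <- matrix(0.8, 8, 8); b <- matrix(0.3, 8, 8)
  expect_equal(subtract(a, b)$values, matrix(0.5, 8, 8))
  expect_equal(subtract(b, a)$values, matrix(0, 8, 8))
  expect_equal(subtract(a, a)$values, matrix(0, 8, 8))
  expect_error(subtract(a, matrix(0.3, 4, 4)), "different frames")
})

test_that("compute_extent equals the brute-force pixel count on random fixtures", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(16:40, 1)
    diff_values <- matrix(runif(n * n, 0, 0.4), n)
    lung <- matrix(rbinom(n * n, 1, 0.6), n)
    if (sum(lung) == 0) lung[1, 1] <- 1L
    tau <- runif(1, 0.05, 0.3)
    res <- compute_extent(structure(list(values = diff_values, frame_size = c(n, n)),
                                    class = "difference_map"),
                          lung_mask(lung), scoring_params(tau = tau))
    bf <- brute_force_extent(diff_values, lung, tau)
    expect_identical(res$A_ILD, bf$a_ild)
    expect_identical(res$A_Lung_used, bf$a_lung)
    expect_equal(res$Score_ILD, bf$score)
  }
})

test_that("extent worked examples: region fully and partially inside the lung", {
  n <- 160
  lung <- matrix(0L, n, n); lung[11:110, 11:110] <- 1L  # 10000 px
  diff0 <- matrix(0, n, n)
  region <- matrix(FALSE, n, n); region[31:60, 31:80] <- TRUE  # 1500 px
  diffr <- diff0; diffr[region] <- 0.5
  p <- scoring_params(tau = 0.1)
  dm <- function(v) structure(list(values = v, frame_size = dim(v)),
                              class = "difference_map")
  expect_equal(compute_extent(dm(diff0), lung_mask(lung), p)$Score_ILD, 0)
  expect_equal(compute_extent(dm(diffr), lung_mask(lung), p)$Score_ILD, 15)
  # shift the region so only half its pixels stay inside the lung
  region2 <- matrix(FALSE, n, n); region2[31:60, 86:135] <- TRUE  # 750 inside
  diffr2 <- diff0; diffr2[region2] <- 0.5
  expect_equal(compute_extent(dm(diffr2), lung_mask(lung), p)$Score_ILD, 7.5)
  expect_error(compute_extent(dm(diff0), lung_mask(matrix(0L, n, n)), p),
               "empty lung mask")
})

test_that("score is monotone in the lesion region and presence follows epsilon", {
  set.seed(5)
  n <- 32
  lung <- matrix(1L, n, n)
  base <- matrix(0, n, n); base[5:10, 5:10] <- 0.5
  sup <- base; sup[5:14, 5:14] <- 0.5
  dm <- function(v) structure(list(values = v, frame_size = dim(v)),
                              class = "difference_map")
  p <- scoring_params()
  s1 <- compute_extent(dm(base), lung_mask(lung), p)$Score_ILD
  s2 <- compute_extent(dm(sup), lung_mask(lung), p)$Score_ILD
  expect_gte(s2, s1)
  r <- compute_extent(dm(base), lung_mask(lung), p)
  expect_equal(classify_presence(r, p), "ILD")
  r0 <- compute_extent(dm(matrix(0, n, n)), lung_mask(lung), p)
  expect_equal(classify_presence(r0, p), "normal")
  expect_equal(classify_presence(structure(list(Score_ILD = 0.3),
                                           class = "extent_result"),
                                 scoring_params(epsilon = 0.5)), "normal")
})

test_that("heatmaps are deterministic and color exactly the abnormal pixels", {
  s <- generate_phantom(phantom_spec(lesion_extent_target = 0.2, seed = 4))
  diff <- subtract(s$diseased, s$paired_normal)
  res <- compute_extent(diff, lung_mask(s$lung_mask_truth), scoring_params())
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_heatmap(diff, res, f1, base = s$diseased)
  render_heatmap(diff, res, f2, base = s$diseased)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  px <- png::readPNG(f1)
  colored <- px[, , 1] != px[, , 2] | px[, , 2] != px[, , 3]
  expect_equal(colored * 1L, unclass(res$abnormal_mask))
  # empty abnormal mask renders pure grayscale
  res0 <- compute_extent(subtract(s$paired_normal, s$paired_normal),
                         lung_mask(s$lung_mask_truth), scoring_params())
  f3 <- withr::local_tempfile(fileext = ".png")
  render_heatmap(subtract(s$paired_normal, s$paired_normal), res0, f3,
                 base = s$paired_normal)
  px3 <- png::readPNG(f3)
  expect_true(all(px3[, , 1] == px3[, , 2] & px3[, , 2] == px3[, , 3]))
})
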