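test_that("min-max normalization maps endpoints affinely and handles the degenerate range", {
  out <- minmax_normalize(matrix(c(0, 128, 255) / 255, 1))
  expect_equal(out, matrix(c(0, 128 / 255, 1), 1))
  expect_equal(minmax_normalize(matrix(c(10, 20, 30), 1)),
               matrix(c(0, 0.5, 1), 1))
  expect_equal(minmax_normalize(matrix(77, 4, 4)), array(0, c(4, 4)))
  # idempotence
  img <- matrix(runif(64), 8)
  expect_equal(minmax_normalize(minmax_normalize(img)), minmax_normalize(img))
  expect_error(minmax_normalize(matrix(c(1, NA, 3), 1)), "non-finite")
})

test_that("CLAHE increases contrast of a low-contrast image and is deterministic", {
  set.seed(7)
  img <- pmin(pmax(0.5 + matrix(rnorm(64 * 64, sd = 0.02), 64), 0), 1)
  out <- clahe(img)
  expect_gte(min(out), 0); expect_lte(max(out), 1)
  expect_gt(sd(out), sd(img))
  expect_identical(out, clahe(img))
  # flat histogram is a fixed point
  expect_equal(clahe(matrix(0.4, 32, 32)), matrix(0.4, 32, 32))
  expect_error(clahe(matrix(0.5, 4, 4), tile_grid = c(8, 8)), "tile grid")
})

test_that("letterbox scales the long side to the target with centered zero pads", {
  img <- matrix(runif(512 * 256), 512, 256)
  lb <- letterbox(img, 1024)
  g <- lb$geometry
  expect_equal(dim(lb$image), c(1024, 1024))
  expect_equal(g$scale, 2)
  expect_equal(c(g$pad_top, g$pad_bottom), c(0, 0))
  expect_equal(c(g$pad_left, g$pad_right), c(256, 256))
  expect_equal(lb$image[, c(1:256, 769:1024)], matrix(0, 1024, 512))
  # square input: no padding
  sq <- letterbox(matrix(runif(64^2), 64), 128)
  expect_equal(with(sq$geometry,
                    c(pad_top, pad_bottom, pad_left, pad_right)), rep(0, 4))
  expect_error(letterbox(img, 8), "at least 16")
})

test_that("letterbox approximately conserves binary area and round-trips coordinates", {
  mask <- matrix(0, 64, 48); mask[20:40, 10:30] <- 1
  lb <- letterbox(mask, 128)  # 2x scale
  n0 <- sum(mask > 0); n1 <- sum(lb$image > 0.5)
  perim_scaled <- 2 * (2 * 21 + 2 * 21)
  expect_lte(abs(n1 - 4 * n0), 2 * perim_scaled)
  # coordinate round trip
  rc <- cbind(c(1, 33, 64), c(1, 17, 48))
  fwd <- source_to_letterbox(lb$geometry, rc)
  back <- letterbox_to_source(lb$geometry, fwd)
  expect_lt(max(abs(back - rc)), 1)
})

test_that("unletterbox inverts letterbox up to resampling error", {
  # smooth content: noise-free phantom anatomy (bilinear round trips cannot
  # bound per-pixel error on i.i.d. noise)
  s <- generate_phantom(phantom_spec(seed = 9, noise_sigma = 0))
  img <- s$paired_normal[1:64, 1:48]
  lb <- letterbox(img, 128)
  rec <- unletterbox(lb$image, lb$geometry)
  expect_equal(dim(rec), dim(img))
  expect_lt(max(abs(rec - img)), 0.02)
  # identity geometry is bitwise exact
  sq <- letterbox(img[1:48, 1:48], 48)
  expect_identical(unletterbox(sq$image, sq$geometry), img[1:48, 1:48])
  expect_error(unletterbox(matrix(0, 64, 64), lb$geometry), "target_size")
})

test_that("image files round-trip through PNG and TIFF with bit-depth scaling", {
  img <- matrix(seq(0, 1, length.out = 32 * 32), 32)
  png_path <- withr::local_tempfile(fileext = ".png")
  tif_path <- withr::local_tempfile(fileext = ".tif")
  write_image(img, png_path)
  expect_lt(max(abs(read_image(png_path) - img)), 1 / 255)
  write_image(img, tif_path, bits = 16)
  expect_lt(max(abs(read_image(tif_path) - img)), 1 / 65535)
  expect_error(read_image("x.bmp"), "unsupported")
})
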