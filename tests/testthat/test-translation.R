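test_that("the oracle backend returns the paired normal exactly and rejects strangers", {
  samples <- lapply(1:3, function(i)
    generate_phantom(phantom_spec(seed = i, lesion_extent_target = 0.2)))
  be <- oracle_backend(samples)
  vn <- generate_virtual_normal(be, samples[[2]]$diseased)
  expect_identical(vn$image, samples[[2]]$paired_normal)
  expect_equal(vn$backend_id, "oracle")
  expect_error(generate_virtual_normal(be, matrix(0.5, 64, 64)),
               "no registered pair")
})

test_that("oracle scoring closure: the full pipeline reproduces true extent exactly", {
  for (seed in c(2, 9)) {
    s <- generate_phantom(phantom_spec(seed = seed, lesion_extent_target = 0.25))
    vn <- generate_virtual_normal(oracle_backend(list(s)), s$diseased)
    res <- compute_extent(subtract(s$diseased, vn),
                          lung_mask(s$lung_mask_truth),
                          scoring_params(tau = 0.1))
    expect_equal(res$Score_ILD, 100 * s$true_extent)
  }
})

test_that("an untrained generator already honors the output contract", {
  m0 <- train_cut(list(matrix(0.5, 32, 32)), list(matrix(0.4, 32, 32)),
                  cut_config(epochs = 0L, image_size = 32L, seed = 2))
  out <- generate_virtual_normal(m0, matrix(runif(32 * 32), 32))
  expect_equal(dim(out$image), c(32L, 32L))
  expect_gte(min(out$image), 0); expect_lte(max(out$image), 1)
  expect_error(generate_virtual_normal(m0, matrix(0.5, 16, 16)), "input size")
  expect_error(train_cut(list(), list(matrix(0.4, 32, 32)),
                         cut_config(image_size = 32L)), "nonempty")
})

test_that("short adversarial-contrastive training keeps every logged loss finite", {
  dis <- lapply(1:4, function(i)
    generate_phantom(phantom_spec(seed = i, image_size = 32L,
                                  lesion_extent_target = 0.3))$diseased)
  nor <- lapply(5:8, function(i)
    generate_phantom(phantom_spec(seed = i, image_size = 32L))$diseased)
  m <- train_cut(dis, nor, cut_config(epochs = 3L, image_size = 32L,
                                      ngf = 4L, ndf = 4L, num_patches = 32L,
                                      seed = 7))
  expect_equal(nrow(m$history), 3)
  expect_true(all(is.finite(as.matrix(m$history))))
  # determinism under a fixed seed
  m2 <- train_cut(dis, nor, cut_config(epochs = 3L, image_size = 32L,
                                       ngf = 4L, ndf = 4L, num_patches = 32L,
                                       seed = 7))
  expect_identical(m$g, m2$g)
})

test_that("a trained generator attenuates lesions and approximately preserves normals", {
  model <- trained_cut(1)
  sets <- cut_train_sets()
  s <- sets$test[[1]]
  vn <- generate_virtual_normal(model, s$diseased)$image
  les <- s$lesion_mask_truth == 1
  expect_lt(mean(vn[les]), mean(s$diseased[les]))
  # identity behavior on a normal-domain image
  nrm <- sets$normal[[1]]$diseased
  expect_gte(ssim(generate_virtual_normal(model, nrm)$image, nrm), 0.80)
})
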