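test_that("phantom pairs share everything outside the lesion and hit the extent target", {
  spec <- phantom_spec(lesion_extent_target = 0.15, seed = 7)
  s <- generate_phantom(spec)
  # determinism
  expect_identical(s, generate_phantom(spec))
  # lesion inside lung
  expect_true(all(s$lesion_mask_truth <= s$lung_mask_truth))
  # exact equality outside the lesion (shared noise draw)
  out <- s$lesion_mask_truth == 0
  expect_identical(s$diseased[out], s$paired_normal[out])
  # lesion pixels strictly brighter by at least half the amplitude
  margins <- (s$diseased - s$paired_normal)[s$lesion_mask_truth == 1]
  expect_gte(min(margins), spec$lesion_amplitude / 2)
  # achieved extent within 5% relative of the target
  achieved <- sum(s$lesion_mask_truth) / sum(s$lung_mask_truth)
  expect_lt(abs(achieved - 0.15) / 0.15, 0.05)
  expect_equal(achieved, s$true_extent)
})

test_that("zero-extent phantoms are identical to their paired normal", {
  s <- generate_phantom(phantom_spec(lesion_extent_target = 0, seed = 3))
  expect_identical(s$diseased, s$paired_normal)
  expect_equal(sum(s$lesion_mask_truth), 0)
  expect_error(phantom_spec(lesion_extent_target = 0.7), "0, 0.6")
})

test_that("cohorts are reproducible and meet their per-sample extent targets", {
  a <- generate_cohort(12, c(0, 0.4), phantom_spec(), seed = 11)
  b <- generate_cohort(12, c(0, 0.4), phantom_spec(), seed = 11)
  expect_identical(a, b)
  expect_length(a, 12)
  for (s in a) {
    tgt <- s$spec$lesion_extent_target
    if (tgt * sum(s$lung_mask_truth) >= 1)
      expect_lt(abs(s$true_extent - tgt), pmax(0.05 * tgt, 1e-3))
  }
  # degenerate range: all-normal cohort
  nrm <- generate_cohort(5, c(0, 0), phantom_spec(), seed = 2)
  expect_true(all(vapply(nrm, function(s) sum(s$lesion_mask_truth), 0) == 0))
  expect_error(generate_cohort(5, c(NA, 1)), "two numbers")
})

test_that("follow-up series share anatomy while only lesions evolve", {
  ser <- generate_followup_series(c(0.05, 0.12, 0.12), phantom_spec(), seed = 3)
  expect_length(ser$visits, 3)
  # identical lung mask (anatomy) across visits
  for (v in ser$visits[-1])
    expect_identical(v$lung_mask_truth, ser$visits[[1]]$lung_mask_truth)
  # achieved extents within 5% relative of the trajectory
  expect_true(all(abs(ser$extent_trajectory - c(0.05, 0.12, 0.12)) /
                    c(0.05, 0.12, 0.12) < 0.05))
  # monotone trajectories give nested lesions
  expect_true(all(ser$visits[[1]]$lesion_mask_truth <=
                    ser$visits[[2]]$lesion_mask_truth))
  # determinism
  expect_identical(ser, generate_followup_series(c(0.05, 0.12, 0.12),
                                                 phantom_spec(), seed = 3))
  expect_error(generate_followup_series(0.1), "at least 2")
})

test_that("phantom samples serialize to PNG plus JSON sidecar and a manifest", {
  dir <- withr::local_tempdir()
  s <- generate_phantom(phantom_spec(lesion_extent_target = 0.2, seed = 5))
  sidecar <- write_phantom(s, dir, "p1")
  expect_true(file.exists(file.path(dir, "p1_diseased.png")))
  meta <- jsonlite::read_json(sidecar)
  expect_equal(meta$true_extent, s$true_extent, tolerance = 1e-12)
  rt <- read_image(file.path(dir, "p1_lung_mask.png"))
  expect_equal((rt > 0.5) * 1L, unclass(s$lung_mask_truth))
  manifest <- write_cohort(generate_cohort(3, c(0, 0.2), phantom_spec(), seed = 1),
                           withr::local_tempdir())
  expect_equal(nrow(utils::read.csv(manifest)), 3)
})
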