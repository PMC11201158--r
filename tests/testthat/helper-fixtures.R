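# Shared fixtures. Training is expensive, so trained models are cached in
# this environment and reused across test files (test files share a
# process; the acceptance file trains first alphabetically).

.fixtures <- new.env(parent = emptyenv())

fixture_get <- function(key, build) {
  if (!exists(key, envir = .fixtures)) assign(key, build(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# 58 phantoms: 40 train / 8 val / 10 held-out test
desk_cohort <- function() {
  fixture_get("desk_cohort", function()
    generate_cohort(58, c(0, 0.4), phantom_spec(), seed = 42))
}

seg_samples <- function(samples) {
  lapply(samples, function(s)
    list(image = clahe(minmax_normalize(s$diseased)), mask = s$lung_mask_truth))
}

trained_unet <- function(seed) {
  fixture_get(paste0("unet_seed", seed), function() {
    cohort <- desk_cohort()
    train_unet(seg_samples(cohort[1:40]), seg_samples(cohort[41:48]),
               seg_config_desk(seed = seed))
  })
}

heldout_unet_dice <- function(seed) {
  model <- trained_unet(seed)
  cohort <- desk_cohort()
  mean(vapply(cohort[49:58], function(s) {
    pm <- predict_lung_mask(model, clahe(minmax_normalize(s$diseased)))
    dice_score(pm$mask, s$lung_mask_truth)
  }, 0))
}

# CUT training sets: 60 diseased + 60 normal, 10 held-out diseased
cut_train_sets <- function() {
  fixture_get("cut_sets", function() list(
    diseased = generate_cohort(60, c(0.10, 0.45), phantom_spec(), seed = 101),
    normal = generate_cohort(60, c(0, 0), phantom_spec(), seed = 202),
    test = generate_cohort(10, c(0.10, 0.45), phantom_spec(), seed = 303)))
}

trained_cut <- function(seed) {
  fixture_get(paste0("cut_seed", seed), function() {
    sets <- cut_train_sets()
    train_cut(lapply(sets$diseased, `[[`, "diseased"),
              lapply(sets$normal, `[[`, "diseased"),
              cut_config(epochs = 30L, learning_rate = 1e-3, seed = seed),
              diseased_masks = lapply(sets$diseased, `[[`, "lung_mask_truth"),
              normal_masks = lapply(sets$normal, `[[`, "lung_mask_truth"))
  })
}

# mean SSIM of (virtual normal vs paired truth) and (input vs paired truth)
cut_heldout_ssim <- function(seed) {
  model <- trained_cut(seed)
  sets <- cut_train_sets()
  ss <- vapply(sets$test, function(s) {
    vn <- generate_virtual_normal(model, s$diseased)$image
    c(ssim(vn, s$paired_normal), ssim(s$diseased, s$paired_normal))
  }, c(0, 0))
  c(vn = mean(ss[1, ]), baseline = mean(ss[2, ]))
}

# printed per-class metrics of the interval-change evaluation table
printed_interval_table <- function() {
  data.frame(class = c("aggravation", "no_change", "improvement"),
             accuracy = c(88.24, 85.29, 97.06),
             precision = c(72.58, 93.08, 58.82),
             recall = c(80.35, 86.04, 100),
             f1 = c(76.27, 89.42, 74.07),
             specificity = c(90.66, 83.33, 96.93))
}
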