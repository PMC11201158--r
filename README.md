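# ildquant

Pixel-wise quantification of interstitial lung disease (ILD) extent on
chest radiographs, and longitudinal interval-change classification, in R.

ILD shows as reticular opacities on radiographs, but radiograph reading is
subjective and interobserver agreement is poor. `ildquant` implements a
weakly supervised quantification pipeline that needs no pixel-level lesion
labels — only image-level domain membership (diseased vs normal):

1. **Lung segmentation** — a U-Net produces the binary lung mask with area
   *A*<sub>Lung</sub>;
2. **Virtual-normal synthesis** — an unpaired contrastive translation
   model (CUT family) maps a diseased radiograph to a lesion-free
   counterpart with the same anatomy;
3. **Subtraction scoring** — opacities are hyperintense, so the clipped
   difference `max(original − virtual_normal, 0)`, binarized at a
   threshold τ (default 0.10) and restricted to the lung, gives the
   abnormal area *A*<sub>ILD</sub> and the extent score

   Score<sub>ILD</sub> = 100 · *A*<sub>ILD</sub> / *A*<sub>Lung</sub> (%);

4. **Presence & interval change** — Score<sub>ILD</sub> = 0% is normal,
   anything positive is ILD; between consecutive visits a change of more
   than 5 percentage points is aggravation (+) or improvement (−), else
   no change (strict inequalities).

Because clinical radiographs of this kind cannot be redistributed, the
package ships a seeded **phantom generator** producing paired
diseased/normal pseudo-radiographs with exact lung and lesion masks and a
known true extent. With the phantom's paired normal as an oracle virtual
normal, the scoring stage reproduces the true extent *exactly* (an integer
pixel-count identity), which is how the pipeline is tested end to end. The
evaluation toolkit includes Dice, SSIM, PSNR, one-vs-rest multiclass
metrics, and an exhaustive-search oracle that recovers integer confusion
marginals from printed per-class percentages.

## Worked example

```r
library(ildquant)

# a diseased phantom with ~18% true extent, and its follow-up
series <- generate_followup_series(c(0.18, 0.26, 0.25),
                                   phantom_spec(noise_sigma = 0), seed = 7)
r <- score_series(series)                    # oracle backends
round(sapply(r$scores, `[[`, "Score_ILD"), 2)
#> [1] 18.04 26.01 25.00
sapply(r$intervals, `[[`, "label")
#> [1] "aggravation" "no_change"
```

The first visit scores 18.04% of lung pixels abnormal; the score rises by
+7.97 points (more than 5) to the second visit, so the interval is rated
aggravation; the −1.01-point change to the third visit is no change.

Training the learned components at desk scale (64×64 phantoms, CPU):

```r
cohort <- generate_cohort(48, c(0, 0.4), phantom_spec(), seed = 42)
prep <- function(s) list(image = clahe(minmax_normalize(s$diseased)),
                         mask = s$lung_mask_truth)
unet <- train_unet(lapply(cohort[1:40], prep), lapply(cohort[41:48], prep),
                   seg_config_desk(seed = 1))
pm <- predict_lung_mask(unet, prep(cohort[[41]])$image)
pm$a_lung        # lung area in pixels at the 64^2 frame
#> [1] 1192
```

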