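#' Synthetic phantom radiographs with exact ground truth
#'
#' Clinical chest radiographs cannot be redistributed, so the package ships
#' a seeded phantom generator that emulates the features the pipeline
#' depends on: two dark elliptical lung fields on a brighter thorax, a
#' bright mediastinal band, rib-like bright stripes, and additive bright
#' reticular-opacity lesions confined to the lung with a controllable area
#' fraction. Each phantom comes as a *pair* — the diseased image and the
#' ideal lesion-free counterpart sharing every other structure pixel for
#' pixel — together with exact lung and lesion masks and the true extent
#' fraction. The paired normal plays the role of a perfect virtual-normal
#' synthesis, which makes the downstream scoring algorithm testable against
#' a pixel-count identity.
#'
#' @name phantom
NULL

#' Phantom generation parameters
#'
#' @param image_size side length in pixels (square frame).
#' @param lung_ellipses list of two lists, each with `center` (row, col,
#'   as fractions of the frame), `axes` (semi-axes as fractions) and
#'   `rotation` (radians). Defaults place two slightly tilted lung fields.
#' @param rib_count number of rib-like bright stripes.
#' @param rib_amplitude stripe intensity in `[0, 1]`.
#' @param mediastinum_amplitude intensity of the central bright band.
#' @param lesion_extent_target target lesion area as a fraction of lung
#'   area, in `[0, 0.6]`.
#' @param lesion_amplitude added lesion brightness in `[0, 1]`; must be
#'   positive when the extent target is positive.
#' @param lesion_texture_scale correlation length (pixels) of the
#'   band-limited lesion texture.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise,
#'   applied as the *same* draw to both images of a pair.
#' @param seed integer seed; fixes every random element.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 64L,
                         lung_ellipses = NULL,
                         rib_count = 5L,
                         rib_amplitude = 0.10,
                         mediastinum_amplitude = 0.20,
                         lesion_extent_target = 0,
                         lesion_amplitude = 0.35,
                         lesion_texture_scale = 3,
                         noise_sigma = 0.01,
                         seed = 1L) {
  if (is.null(lung_ellipses)) {
    lung_ellipses <- list(
      list(center = c(0.52, 0.30), axes = c(0.30, 0.155), rotation = -0.12),
      list(center = c(0.52, 0.70), axes = c(0.30, 0.155), rotation = 0.12))
  }
  if (lesion_extent_target < 0 || lesion_extent_target > 0.6)
    stop("lesion_extent_target must lie in [0, 0.6]", call. = FALSE)
  if (lesion_extent_target > 0 && lesion_amplitude <= 0)
    stop("lesion_amplitude must be positive when lesions are requested",
         call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (rib_amplitude > 1 || mediastinum_amplitude > 1 || lesion_amplitude > 1)
    stop("amplitudes must be <= 1", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 lung_ellipses = lung_ellipses,
                 rib_count = as.integer(rib_count),
                 rib_amplitude = rib_amplitude,
                 mediastinum_amplitude = mediastinum_amplitude,
                 lesion_extent_target = lesion_extent_target,
                 lesion_amplitude = lesion_amplitude,
                 lesion_texture_scale = lesion_texture_scale,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# rasterize the union of the spec's lung ellipses into a 0/1 matrix
phantom_lung_mask <- function(spec) {
  n <- spec$image_size
  rr <- matrix(seq_len(n) / n, n, n)
  cc <- matrix(seq_len(n) / n, n, n, byrow = TRUE)
  mask <- matrix(0L, n, n)
  for (e in spec$lung_ellipses) {
    dr <- rr - e$center[1]; dc <- cc - e$center[2]
    u <- cos(e$rotation) * dr + sin(e$rotation) * dc
    v <- -sin(e$rotation) * dr + cos(e$rotation) * dc
    mask[(u / e$axes[1])^2 + (v / e$axes[2])^2 <= 1] <- 1L
  }
  mask
}

# anatomy shared by both images of a pair (and across visits of a series)
phantom_anatomy <- function(spec) {
  n <- spec$image_size
  lung <- phantom_lung_mask(spec)
  rr <- matrix(seq_len(n) / n, n, n)
  cc <- matrix(seq_len(n) / n, n, n, byrow = TRUE)
  body <- 0.55 + 0.08 * (rr - 0.5)              # soft vertical gradient
  mediastinum <- spec$mediastinum_amplitude * exp(-((cc - 0.5) / 0.10)^2)
  ribs <- spec$rib_amplitude *
    pmax(sin(2 * pi * spec$rib_count * (rr + 0.15 * cc)), 0)^2
  base <- body + mediastinum + ribs - 0.32 * lung
  # slight point-spread blur: real radiographs have no step edges
  base <- as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(base),
                                                      sigma = 0.8)))
  list(base = base, lung = lung)
}

# band-limited texture field used to carve lesions and to modulate their
# brightness; deterministic given the active RNG state
phantom_texture <- function(n, scale) {
  z <- matrix(stats::rnorm(n * n), n, n)
  sm <- EBImage::gblur(EBImage::Image(z), sigma = scale)
  as.matrix(EBImage::imageData(sm))
}

#' Generate one paired phantom sample
#'
#' Lesions are carved from a smoothed-noise texture field: the
#' highest-texture pixels inside the lung are flagged until the requested
#' area fraction is met, so the achieved extent equals the target up to a
#' single pixel of rounding. The lesion is added to the paired normal as
#' `amplitude * (0.6 + 0.4 u)` with `u` the rank-scaled texture, so every
#' lesion pixel is brighter than the paired normal by at least 60% of
#' `lesion_amplitude`. Outside the lesion mask the two images are equal
#' bit for bit (noise is a single shared draw).
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_sample`: list with `diseased`, `paired_normal`,
#'   `lung_mask_truth`, `lesion_mask_truth`, `true_extent`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  n <- spec$image_size
  anat <- phantom_anatomy(spec)
  lung <- anat$lung
  a_lung <- sum(lung)
  stopifnot(a_lung > 0)

  texture <- phantom_texture(n, spec$lesion_texture_scale)
  noise <- if (spec$noise_sigma > 0)
    matrix(stats::rnorm(n * n, sd = spec$noise_sigma), n, n) else 0

  lesion <- matrix(0L, n, n)
  target_px <- round(spec$lesion_extent_target * a_lung)
  if (target_px > 0) {
    inside <- which(lung == 1L)
    take <- inside[order(texture[inside], decreasing = TRUE)[seq_len(target_px)]]
    lesion[take] <- 1L
  }

  normal <- pmin(pmax(anat$base + noise, 0), 1)
  add <- matrix(0, n, n)
  if (target_px > 0) {
    idx <- which(lesion == 1L)
    tx <- texture[idx]
    u <- if (length(idx) > 1 && diff(range(tx)) > 0)
      (tx - min(tx)) / (max(tx) - min(tx)) else rep(1, length(idx))
    add[idx] <- spec$lesion_amplitude * (0.6 + 0.4 * u)
  }
  diseased <- pmin(pmax(anat$base + noise + add, 0), 1)
  # keep the exact-equality invariant outside lesions even if clamping acted
  diseased[lesion == 0L] <- normal[lesion == 0L]

  structure(list(diseased = diseased,
                 paired_normal = normal,
                 lung_mask_truth = lung,
                 lesion_mask_truth = lesion,
                 true_extent = target_px / a_lung,
                 spec = spec),
            class = "phantom_sample")
}

#' Generate a cohort of phantom samples
#'
#' @param n number of samples.
#' @param extent_range length-2 numeric; per-sample lesion extent targets
#'   are drawn uniformly from this range.
#' @param spec template [phantom_spec()] supplying everything except the
#'   extent target and seed.
#' @param seed master seed; per-sample seeds are derived from it.
#' @return list of `phantom_sample`.
#' @export
generate_cohort <- function(n, extent_range = c(0, 0.4), spec = phantom_spec(),
                            seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (length(extent_range) != 2 || any(is.na(extent_range)))
    stop("extent_range must be two numbers", call. = FALSE)
  if (diff(range(extent_range)) < 0) stop("empty extent range", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  extents <- stats::runif(n, extent_range[1], extent_range[2])
  seeds <- sample.int(.Machine$integer.max %/% 2L, n)
  lapply(seq_len(n), function(i) {
    s <- spec
    s$lesion_extent_target <- extents[i]
    s$seed <- seeds[i]
    generate_phantom(s)
  })
}

#' Generate a longitudinal visit series with fixed anatomy
#'
#' All visits share the anatomy (lung fields, ribs, mediastinum) and the
#' lesion texture field of the master seed; only the lesion extent changes
#' along `extent_trajectory`, so later visits of a worsening trajectory
#' contain earlier lesions as subsets. Per-visit noise draws differ, as
#' repeat acquisitions would.
#'
#' @param extent_trajectory numeric vector (length >= 2) of extent targets.
#' @param spec template [phantom_spec()].
#' @param seed master seed.
#' @return a `visit_series`: list with `visits` (list of `phantom_sample`)
#'   and `extent_trajectory` (achieved extents).
#' @export
generate_followup_series <- function(extent_trajectory, spec = phantom_spec(),
                                     seed = 1L) {
  if (length(extent_trajectory) < 2)
    stop("a visit series needs at least 2 visits", call. = FALSE)
  if (any(extent_trajectory < 0 | extent_trajectory > 0.6))
    stop("every extent target must lie in [0, 0.6]", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)

  n <- spec$image_size
  set.seed(seed)
  anat <- phantom_anatomy(spec)
  texture <- phantom_texture(n, spec$lesion_texture_scale)
  visit_seeds <- sample.int(.Machine$integer.max %/% 2L, length(extent_trajectory))
  lung <- anat$lung
  a_lung <- sum(lung)
  inside <- which(lung == 1L)
  ord <- inside[order(texture[inside], decreasing = TRUE)]

  visits <- vector("list", length(extent_trajectory))
  achieved <- numeric(length(extent_trajectory))
  for (v in seq_along(extent_trajectory)) {
    set.seed(visit_seeds[v])
    noise <- if (spec$noise_sigma > 0)
      matrix(stats::rnorm(n * n, sd = spec$noise_sigma), n, n) else 0
    target_px <- round(extent_trajectory[v] * a_lung)
    lesion <- matrix(0L, n, n)
    if (target_px > 0) lesion[ord[seq_len(target_px)]] <- 1L
    normal <- pmin(pmax(anat$base + noise, 0), 1)
    add <- matrix(0, n, n)
    if (target_px > 0) {
      idx <- which(lesion == 1L)
      tx <- texture[idx]
      u <- if (length(idx) > 1 && diff(range(tx)) > 0)
        (tx - min(tx)) / (max(tx) - min(tx)) else rep(1, length(idx))
      add[idx] <- spec$lesion_amplitude * (0.6 + 0.4 * u)
    }
    diseased <- pmin(pmax(anat$base + noise + add, 0), 1)
    diseased[lesion == 0L] <- normal[lesion == 0L]
    s <- spec; s$lesion_extent_target <- extent_trajectory[v]; s$seed <- visit_seeds[v]
    visits[[v]] <- structure(list(diseased = diseased, paired_normal = normal,
                                  lung_mask_truth = lung,
                                  lesion_mask_truth = lesion,
                                  true_extent = target_px / a_lung,
                                  spec = s),
                             class = "phantom_sample")
    achieved[v] <- target_px / a_lung
  }
  structure(list(visits = visits, extent_trajectory = achieved),
            class = "visit_series")
}

#' Write a phantom sample to disk
#'
#' Writes the diseased image, paired normal and the two masks as PNG plus
#' a JSON sidecar with the spec, seed and true extent.
#'
#' @param sample a `phantom_sample`.
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return invisibly, the sidecar path.
#' @export
write_phantom <- function(sample, dir, stem = "phantom") {
  stopifnot(inherits(sample, "phantom_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(sfx) file.path(dir, paste0(stem, "_", sfx))
  write_image(sample$diseased, p("diseased.png"))
  write_image(sample$paired_normal, p("normal.png"))
  write_image(sample$lung_mask_truth + 0, p("lung_mask.png"))
  write_image(sample$lesion_mask_truth + 0, p("lesion_mask.png"))
  sidecar <- p("meta.json")
  meta <- list(spec = sample$spec[setdiff(names(sample$spec), "lung_ellipses")],
               true_extent = sample$true_extent)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Write a cohort manifest
#'
#' @param samples list of `phantom_sample`.
#' @param dir output directory.
#' @return invisibly, the manifest CSV path.
#' @export
write_cohort <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    stem <- sprintf("sample%03d", i)
    write_phantom(samples[[i]], dir, stem)
    data.frame(id = stem, seed = samples[[i]]$spec$seed,
               true_extent = samples[[i]]$true_extent,
               diseased = paste0(stem, "_diseased.png"),
               normal = paste0(stem, "_normal.png"))
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
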