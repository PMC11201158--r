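#' End-to-end orchestration
#'
#' `run_quantify()` scores a batch of images (preprocess, lung
#' segmentation, virtual-normal synthesis, subtraction scoring, presence
#' classification); `run_interval()` scores chronological visit series
#' per patient and rates the interval changes. Both return a
#' machine-readable report with provenance.
#'
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param backend `"oracle"` (phantom ground truth) or a trained
#'   `cut_model`.
#' @param seg_model optional trained `unet_model`; ground-truth masks are
#'   used when NULL (oracle segmentation).
#' @param scoring a [scoring_params()].
#' @param change_threshold interval threshold, score percentage points.
#' @param seg_size,translate_size square frame sizes in pixels (clinical
#'   profile 512/1024; desk profile 64/64).
#' @param seed integer seed recorded in the provenance block.
#' @param out_dir optional output directory for JSON reports/heatmaps.
#' @return a `run_config` list.
#' @export
run_config <- function(backend = "oracle", seg_model = NULL,
                       scoring = scoring_params(), change_threshold = 5,
                       seg_size = 512L, translate_size = 1024L, seed = 1L,
                       out_dir = NULL) {
  structure(list(backend = backend, seg_model = seg_model, scoring = scoring,
                 change_threshold = change_threshold,
                 seg_size = as.integer(seg_size),
                 translate_size = as.integer(translate_size),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Desk-scale run profile (64/64 frames)
#' @param ... overrides passed to [run_config()].
#' @export
run_config_desk <- function(...) {
  args <- list(seg_size = 64L, translate_size = 64L)
  args[names(list(...))] <- list(...)
  do.call(run_config, args)
}

run_provenance <- function(config) {
  cfg <- list(backend = if (is.character(config$backend)) config$backend else "cut",
              tau = config$scoring$tau, epsilon = config$scoring$epsilon,
              change_threshold = config$change_threshold,
              seg_size = config$seg_size, translate_size = config$translate_size)
  list(config = cfg,
       config_hash = sum(utils::head(utf8ToInt(
         paste(names(cfg), unlist(cfg), collapse = "|")), 10000)),
       seed = config$seed,
       version = as.character(utils::packageVersion("ildquant")))
}

score_one <- function(sample, config) {
  stopifnot(inherits(sample, "phantom_sample"))
  vn <- if (identical(config$backend, "oracle")) sample$paired_normal
        else generate_virtual_normal(config$backend, sample$diseased)
  lung <- if (is.null(config$seg_model)) lung_mask(sample$lung_mask_truth)
          else predict_lung_mask(config$seg_model, sample$diseased)
  if (!all(dim(if (inherits(vn, "virtual_normal")) vn$image else vn) ==
           lung$frame_size))
    lung <- resize_mask(lung, config$translate_size)
  res <- compute_extent(subtract(sample$diseased, vn), lung, config$scoring)
  res
}

#' Quantify ILD extent for a batch of images
#'
#' @param images list of `phantom_sample` objects (or a `visit_series`'
#'   visits).
#' @param config a [run_config()].
#' @return a `report` list: `per_image` data frame (score, areas,
#'   presence label), `results` (the `extent_result`s), `provenance`.
#'   Per-image failures are logged and skipped; the report counts them.
#' @export
run_quantify <- function(images, config = run_config_desk()) {
  stopifnot(inherits(config, "run_config"))
  if (length(images) == 0) stop("empty image list", call. = FALSE)
  results <- vector("list", length(images))
  failures <- 0L
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    r <- tryCatch(score_one(images[[i]], config), error = function(e) e)
    if (inherits(r, "error")) {
      warning("image ", i, " failed: ", conditionMessage(r), call. = FALSE)
      failures <- failures + 1L
      next
    }
    results[[i]] <- r
    rows[[i]] <- data.frame(image = i, score_percent = r$Score_ILD,
                            a_ild_px = r$A_ILD, a_lung_px = r$A_Lung_used,
                            presence = classify_presence(r, config$scoring))
  }
  rep <- list(per_image = do.call(rbind, rows), results = results,
              n_failed = failures, provenance = run_provenance(config))
  class(rep) <- "ild_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(per_image = rep$per_image,
                              n_failed = failures,
                              provenance = rep$provenance),
                         file.path(config$out_dir, "quantify_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  rep
}

#' Score visit series and classify interval change
#'
#' @param series_list named list of `visit_series` (or lists of
#'   `phantom_sample` in chronological order), one entry per patient.
#' @param config a [run_config()].
#' @param truth_labels optional list of per-patient integer vectors of
#'   true interval codes (1 = aggravation, 2 = no change,
#'   3 = improvement); when given, cohort confusion marginals and metrics
#'   are added to the report.
#' @return a `report` list: `per_interval` data frame, optional
#'   `marginals` and `metrics`, `provenance`. Patients with fewer than 2
#'   visits are skipped with a warning.
#' @export
run_interval <- function(series_list, config = run_config_desk(),
                         truth_labels = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (length(series_list) == 0) stop("empty series list", call. = FALSE)
  if (is.null(names(series_list)))
    names(series_list) <- sprintf("patient%03d", seq_along(series_list))
  if (!is.null(truth_labels) && is.null(names(truth_labels)))
    names(truth_labels) <- names(series_list)[seq_along(truth_labels)]
  rows <- list(); pred <- c(); truth <- c()
  for (pid in names(series_list)) {
    visits <- series_list[[pid]]
    if (inherits(visits, "visit_series")) visits <- visits$visits
    if (length(visits) < 2) {
      warning("patient ", pid, " has a single visit; skipped", call. = FALSE)
      next
    }
    scored <- lapply(visits, function(s) score_one(s, config))
    for (i in seq_len(length(scored) - 1)) {
      ic <- classify_interval(scored[[i]]$Score_ILD, scored[[i + 1]]$Score_ILD,
                              config$change_threshold)
      rows[[length(rows) + 1]] <- data.frame(
        patient = pid, pair = i,
        score_prev = scored[[i]]$Score_ILD,
        score_next = scored[[i + 1]]$Score_ILD,
        delta = ic$delta, label = ic$label, code = ic$code)
      pred <- c(pred, ic$label)
      if (!is.null(truth_labels))
        truth <- c(truth, names(interval_levels)[truth_labels[[pid]][i]])
    }
  }
  rep <- list(per_interval = do.call(rbind, rows),
              provenance = run_provenance(config))
  if (!is.null(truth_labels)) {
    rep$marginals <- marginals_from_labels(truth, pred)
    rep$metrics <- per_class_metrics(rep$marginals)
  }
  class(rep) <- "ild_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(per_interval = rep$per_interval,
                              provenance = rep$provenance),
                         file.path(config$out_dir, "interval_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    utils::write.csv(rep$per_interval,
                     file.path(config$out_dir, "interval_report.csv"),
                     row.names = FALSE)
  }
  rep
}
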