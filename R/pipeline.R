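#' Default pipeline configuration
#'
#' Nested settings for every stage, per detection channel. Total
#' hepatocyte nuclei are detected in the red channel (all nuclei are
#' dark there), proliferating nuclei in the blue channel (only
#' BrdU-positive, red-stained nuclei are dark there). The defaults are
#' the working set for 200-fold magnification sections: moderate
#' smoothing for the red channel and much stronger smoothing for the
#' blue channel (which suppresses the brighter non-proliferating nuclei
#' before the two-class thresholding), shared shape-filter ranges, and
#' channel-specific Hough closeness factors (0.5 total, 0.75
#' proliferating).
#'
#' @return A nested list of class `pipeline_config` with entries
#'   `total`, `proliferating` (each holding `smoothing`,
#'   `thresholding`, `morphology`, `hough`) and `vein`.
#' @export
default_config <- function() {
  channel_cfg <- function(sigma_s, sigma_r, closeness) list(
    smoothing = list(variant = "fast", sigma_s = sigma_s, sigma_r = sigma_r),
    thresholding = list(method = "em", tol = 1e-4, max_iter = 500L),
    morphology = list(selem_radius = 2L, area_range = c(700, 8000),
                      deq_range = c(35, 200), min_form_factor = 0.2),
    hough = list(radius_range = c(14L, 50L), radius_step = 2L,
                 acc_sigma = 10, relevance = 0.5,
                 closeness_factor = closeness, max_circles = 5000L))
  structure(list(
    total = channel_cfg(16, 0.15, 0.5),
    proliferating = channel_cfg(50, 0.10, 0.75),
    vein = list(mode = "auto", fragmentation_threshold = 0.95,
                base_sigma = 30, min_sigma = 5, sigma_r = 1.0)),
    class = "pipeline_config")
}

#' Load and save pipeline configurations
#'
#' Configurations are YAML files mirroring [default_config()]; missing
#' keys fall back to the defaults, so a file only needs the settings it
#' overrides.
#'
#' @param path YAML file path.
#' @return `load_config` returns a `pipeline_config`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modifyList(unclass(default_config()), user)
  structure(cfg, class = "pipeline_config")
}

#' @rdname load_config
#' @param cfg a `pipeline_config`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Detect nuclei in one channel
#'
#' The per-channel flow: bilateral smoothing, EM (or Otsu) histogram
#' thresholding into 2 or 3 classes, optional vein-mask subtraction,
#' morphological cleaning (erode, fill holes, label, size filter,
#' dilate, roundness filter), and circle Hough detection with
#' post-filtering. Used by [process_image()] for both channels; exposed
#' for parameter studies.
#'
#' @param channel numeric matrix in `[0, 255]`.
#' @param cfg one channel's configuration block (e.g.
#'   `default_config()$total`).
#' @param n_classes 2, or 3 when the image contains venous structures.
#' @param vein_exclusion optional logical matrix. For the 3-class (red)
#'   path the mask is built internally from the brightest class; pass
#'   the built mask here for the blue path, where it is excluded from
#'   the histogram before thresholding and no nucleus may be found
#'   inside it.
#' @return A list with `circles`, `n`, `candidate_mask`, `vein_mask`
#'   (the built exclusion mask or `NULL`), and `mixture`.
#' @export
detect_channel <- function(channel, cfg, n_classes = 2L,
                           vein_exclusion = NULL) {
  smoothed <- smooth_channel(channel, cfg$smoothing)
  hist <- intensity_histogram(smoothed, exclusion_mask = vein_exclusion)
  if (hist$degenerate) stop("degenerate input: empty histogram")
  th <- cfg$thresholding
  mix <- NULL
  ts <- switch(match.arg(th$method, c("em", "otsu", "multiotsu")),
    em = {
      mix <- em_fit(hist, n_classes, tol = th$tol, max_iter = th$max_iter)
      thresholds_from_mixture(mix)
    },
    otsu = otsu(hist),
    multiotsu = multilevel_otsu(hist, n_classes))
  cm <- class_masks(smoothed, ts, exclusion_mask = vein_exclusion)
  nucleus <- cm$masks[[1]]
  vein_mask <- NULL
  if (n_classes == 3L && is.null(vein_exclusion)) {
    vein_raw <- cm$masks[[cm$n_classes]]
    vein_mask <- build_exclusion_mask(vein_raw, do.call(vein_params, cfg$vein))
    nucleus <- subtract_mask(nucleus, vein_mask)
  }

  mo <- cfg$morphology
  sp <- shape_filter_params(mo$area_range, mo$deq_range, mo$min_form_factor)
  m <- erode_mask(nucleus, mo$selem_radius)
  m <- fill_holes(m)
  comp <- shape_metrics(label_components(m))
  m <- filter_components(comp, sp, criteria = c("area", "deq"))$mask
  m <- dilate_mask(m, mo$selem_radius)
  comp <- shape_metrics(label_components(m))
  m <- filter_components(comp, sp, criteria = "form_factor")$mask

  hp <- as_hough_params(cfg$hough)
  circles <- detect_circles(m, hp)
  list(circles = circles, n = nrow(circles), candidate_mask = m,
       vein_mask = vein_mask, mixture = mix)
}

#' Quantify one region-of-interest image
#'
#' Runs the full two-channel pipeline on one image. Red channel: smooth,
#' EM-threshold into 3 classes when the filename signals venous
#' structures (2 otherwise), build and subtract the vein exclusion mask,
#' clean morphologically, detect circles — the total hepatocyte count.
#' Blue channel: smooth strongly, threshold into 2 classes with the vein
#' mask excluded from the histogram, clean, detect — the proliferating
#' count. The BrdU labeling index is the ratio of proliferating to total
#' nuclei.
#'
#' @param roi a [roi_image()].
#' @param cfg a [default_config()]-style configuration.
#' @param keep_masks keep per-stage masks in the result (memory-heavy).
#' @return An object of class `image_result`: `stem`, `n_total`,
#'   `n_proliferating`, `brdu_li` (`NA` when no total nucleus was
#'   found), `circles_total`, `circles_proliferating`, `status`
#'   (`"ok"` or `"failed"`), `message`, and optionally `masks`.
#' @export
process_image <- function(roi, cfg = default_config(), keep_masks = FALSE) {
  stopifnot(inherits(roi, "roi_image"))
  res <- list(stem = roi$stem, n_total = NA_integer_,
              n_proliferating = NA_integer_, brdu_li = NA_real_,
              circles_total = NULL, circles_proliferating = NULL,
              status = "ok", message = "")
  cfg_total <- cfg$total; cfg_total$vein <- cfg$vein
  out <- tryCatch({
    red <- detect_channel(roi$pixels[, , 1], cfg_total,
                          n_classes = if (roi$has_vein) 3L else 2L)
    blue <- detect_channel(roi$pixels[, , 3], cfg$proliferating,
                           n_classes = 2L,
                           vein_exclusion = red$vein_mask)
    res$n_total <- red$n
    res$n_proliferating <- blue$n
    res$brdu_li <- if (red$n > 0) blue$n / red$n else NA_real_
    res$circles_total <- red$circles
    res$circles_proliferating <- blue$circles
    if (keep_masks)
      res$masks <- list(total = red$candidate_mask,
                        proliferating = blue$candidate_mask,
                        vein = red$vein_mask)
    res
  }, error = function(e) {
    res$status <- "failed"
    res$message <- conditionMessage(e)
    res
  })
  structure(out, class = "image_result")
}

#' @export
print.image_result <- function(x, ...) {
  cat(sprintf("<image_result> %s [%s]: total = %s, proliferating = %s, BrdU-LI = %s\n",
              x$stem, x$status, x$n_total, x$n_proliferating,
              ifelse(is.na(x$brdu_li), "NA", sprintf("%.3f", x$brdu_li))))
  invisible(x)
}

#' Batch quantification without user interaction
#'
#' Processes a set of images with one configuration (no per-image
#' adjustment) and returns one row per image. A failing image is
#' reported in its row and never aborts the batch, so entire digitized
#' sections can be processed unattended. When a ground-truth directory
#' is given, images with a `<stem>.csv` point file also get per-class
#' `tp`, `fp`, `fn`, `sensitivity` and `fpf` columns.
#'
#' @param paths character vector of image paths, or a list of
#'   [roi_image()] objects.
#' @param cfg a `pipeline_config`.
#' @param gt_dir optional directory of ground-truth CSV files.
#' @return A data frame with columns `image`, `detected_total`,
#'   `detected_proliferating`, `brdu_li`, `status` (and validation
#'   columns when ground truth is present).
#' @export
process_batch <- function(paths, cfg = default_config(), gt_dir = NULL) {
  if (length(paths) == 0L) stop("empty batch: need at least one image")
  rows <- lapply(paths, function(p) {
    roi <- tryCatch(if (inherits(p, "roi_image")) p else read_roi(p),
                    error = function(e) e)
    if (inherits(roi, "error"))
      return(data.frame(image = as.character(p), detected_total = NA,
                        detected_proliferating = NA, brdu_li = NA,
                        status = paste("error:", conditionMessage(roi))))
    r <- process_image(roi, cfg)
    row <- data.frame(image = r$stem, detected_total = r$n_total,
                      detected_proliferating = r$n_proliferating,
                      brdu_li = r$brdu_li, status = r$status)
    if (!is.null(gt_dir)) {
      gt_path <- file.path(gt_dir, paste0(r$stem, ".csv"))
      if (file.exists(gt_path) && r$status == "ok") {
        gt <- read_ground_truth(gt_path)
        for (cl in c("total", "proliferating")) {
          circ <- if (cl == "total") r$circles_total else r$circles_proliferating
          m <- match_points(circ, gt[gt$class == cl, , drop = FALSE])
          met <- detection_metrics(m, nrow(circ))
          row[[paste0("tp_", cl)]] <- m$tp
          row[[paste0("fp_", cl)]] <- m$fp
          row[[paste0("fn_", cl)]] <- m$fn
          row[[paste0("sensitivity_", cl)]] <- met$sensitivity
          row[[paste0("fpf_", cl)]] <- met$fpf
        }
      }
    }
    row
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    r[cols]
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
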