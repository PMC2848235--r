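#' Match detected circles against point ground truth
#'
#' A ground-truth point may match a circle only when it lies inside (or
#' on) that circle. The assignment is one-to-one and greedy by
#' ascending center-to-point distance: the closest eligible pair is
#' matched first, both members are removed, and so on. Unmatched
#' circles are false positives, unmatched points false negatives.
#'
#' @param circles a `circle_set` (columns `cx`, `cy`, `r`).
#' @param points data frame with columns `x`, `y` in the same 0-based
#'   pixel frame.
#' @return A list of class `match_result`: `tp`, `fp`, `fn` and `pairs`
#'   (data frame `circle`, `point`, `dist` of matched index pairs).
#' @export
match_points <- function(circles, points) {
  nc <- nrow(circles); np <- nrow(points)
  pairs <- data.frame(circle = integer(0), point = integer(0),
                      dist = numeric(0))
  if (nc > 0L && np > 0L) {
    d <- sqrt(outer(circles$cx, points$x, "-")^2 +
              outer(circles$cy, points$y, "-")^2)
    eligible <- d <= matrix(circles$r, nc, np)
    d[!eligible] <- Inf
    free_c <- rep(TRUE, nc); free_p <- rep(TRUE, np)
    repeat {
      k <- arrayInd(which.min(d), dim(d))
      if (!is.finite(d[k])) break
      pairs <- rbind(pairs, data.frame(circle = k[1], point = k[2],
                                       dist = d[k]))
      free_c[k[1]] <- FALSE; free_p[k[2]] <- FALSE
      d[k[1], ] <- Inf; d[, k[2]] <- Inf
      if (!any(free_c) || !any(free_p)) break
    }
  }
  structure(list(tp = nrow(pairs), fp = nc - nrow(pairs),
                 fn = np - nrow(pairs), pairs = pairs),
            class = "match_result")
}

round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Sensitivity and false positive fraction
#'
#' Sensitivity is `TP / (TP + FN)`, the fraction of expert-marked
#' nuclei that were detected. The false positive fraction (FPF) is
#' `FP / Detected`, the fraction of detections not matching any marked
#' nucleus; it replaces specificity because true negatives are not
#' meaningful for point-marked nuclei. Either value is `NA` when its
#' denominator is zero. Rounded values (2 decimals for sensitivity, 2
#' for FPF) are reported alongside the raw ratios.
#'
#' @param match a [match_points()] result, or a list with `tp`, `fp`,
#'   `fn`.
#' @param n_detected total number of detected circles
#'   (`= tp + fp` for a self-consistent match).
#' @return A list of class `detection_metrics` with `sensitivity`,
#'   `fpf`, `sensitivity_rounded`, `fpf_rounded`.
#' @export
detection_metrics <- function(match, n_detected = match$tp + match$fp) {
  tp <- match$tp; fn <- match$fn; fp <- match$fp
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpf <- if (n_detected > 0) fp / n_detected else NA_real_
  structure(list(sensitivity = sens, fpf = fpf,
                 sensitivity_rounded = round_half_up(sens, 2),
                 fpf_rounded = round_half_up(fpf, 2)),
            class = "detection_metrics")
}

#' Vectorized metrics for benchmark tables
#'
#' Computes raw sensitivity and FPF for whole result tables (one row
#' per image) as used in published validation summaries.
#'
#' @param tp,fn,fp,detected integer vectors of equal length.
#' @return A data frame with `sensitivity` and `fpf`.
#' @export
benchmark_metrics <- function(tp, fn, fp, detected) {
  data.frame(sensitivity = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_),
             fpf = ifelse(detected > 0, fp / detected, NA_real_))
}

#' ROC-like parameter sweep
#'
#' Re-runs the pipeline on one image for each value of a scalar
#' configuration parameter (addressed by a dotted path such as
#' `"total.hough.relevance"`) and scores each run against ground truth.
#' With FPF on the abscissa and sensitivity on the ordinate this traces
#' the ROC-like trade-off curve used to select the Hough relevance
#' threshold.
#'
#' @param roi a [roi_image()].
#' @param gt ground-truth points (columns `x`, `y`, `class`).
#' @param cfg base configuration.
#' @param param_path dotted path to one scalar config entry.
#' @param values numeric vector of parameter values to try.
#' @param channel `"total"` or `"proliferating"`: which detection to
#'   score.
#' @return A data frame ordered by `value` with columns `value`,
#'   `detected`, `tp`, `fp`, `fn`, `sensitivity`, `fpf`.
#' @export
roc_sweep <- function(roi, gt, cfg, param_path, values,
                      channel = c("total", "proliferating")) {
  channel <- match.arg(channel)
  keys <- strsplit(param_path, ".", fixed = TRUE)[[1]]
  probe <- tryCatch(cfg[[keys]], error = function(e) NULL)
  if (is.null(probe) || length(probe) != 1L)
    stop("`param_path` does not address a scalar config entry: ", param_path)
  gt_pts <- gt[gt$class == channel, , drop = FALSE]
  rows <- lapply(sort(values), function(v) {
    cfg[[keys]] <- v
    r <- process_image(roi, cfg)
    circ <- if (channel == "total") r$circles_total else r$circles_proliferating
    m <- match_points(circ, gt_pts)
    met <- detection_metrics(m, nrow(circ))
    data.frame(value = v, detected = nrow(circ), tp = m$tp, fp = m$fp,
               fn = m$fn, sensitivity = met$sensitivity, fpf = met$fpf)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Inter-observer dispersion
#'
#' Several experts independently mark the same images; the dispersion of
#' their counts bounds what any automatic method can be validated
#' against. For each image and category the relative standard deviation
#' — 100 times the sample standard deviation (n - 1 denominator) of the
#' observer counts divided by their mean — is computed, and the
#' unweighted mean over images is reported per category. Images with
#' fewer than two observers in a category are skipped for that
#' category; a category with no usable image yields `NA`.
#'
#' @param counts data frame with columns `image`, `observer`,
#'   `category`, `count`.
#' @return A named numeric vector: mean relative standard deviation
#'   (percent) per category.
#' @export
interobserver <- function(counts) {
  stopifnot(all(c("image", "category", "count") %in% names(counts)))
  vapply(split(counts, counts$category), function(df) {
    per_image <- vapply(split(df$count, df$image), function(x) {
      if (length(x) < 2L) return(NA_real_)
      100 * sd(x) / mean(x)
    }, numeric(1))
    if (all(is.na(per_image))) NA_real_ else mean(per_image, na.rm = TRUE)
  }, numeric(1))
}
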