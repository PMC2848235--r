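#' Vein exclusion parameters
#'
#' Venous structures (portal tracts, central veins) appear as the
#' brightest threshold class and must be removed before counting. How
#' the exclusion mask is built depends on how fragmented the vein region
#' is: a single connected region only needs its blood-cell holes filled,
#' while a region split into several components by blood must first be
#' smoothed back into one piece.
#'
#' @param mode `"auto"` chooses between the two strategies from the
#'   fragmentation ratio; `"fill-only"` and `"smooth"` force one.
#' @param fragmentation_threshold ratio in `(0, 1]` above which `auto`
#'   treats the vein as a single component (default 0.95).
#' @param base_sigma,min_sigma the smoothing strength is mapped from the
#'   fragmentation ratio as
#'   `sigma_s = base_sigma * (1 - ratio) + min_sigma`, a continuous
#'   monotone map: the more fragmented the vein, the stronger the
#'   smoothing that reconnects it.
#' @param sigma_r range standard deviation (fraction of the intensity
#'   range) used when smoothing the 0/255 mask raster. The default of 1
#'   makes the range term permissive, which is what reconnecting
#'   disjoint fragments requires.
#' @return A list of class `vein_params`.
#' @export
vein_params <- function(mode = c("auto", "fill-only", "smooth"),
                        fragmentation_threshold = 0.95,
                        base_sigma = 30, min_sigma = 5, sigma_r = 1.0) {
  mode <- match.arg(mode)
  if (fragmentation_threshold <= 0 || fragmentation_threshold > 1)
    stop("`fragmentation_threshold` must lie in (0, 1]")
  structure(list(mode = mode,
                 fragmentation_threshold = fragmentation_threshold,
                 base_sigma = base_sigma, min_sigma = min_sigma,
                 sigma_r = sigma_r),
            class = "vein_params")
}

#' Fragmentation ratio of a vein mask
#'
#' The ratio between the area of the largest 8-connected vein component
#' and the whole area covered by vein, in `(0, 1]`. A value near 1 means
#' one dominant component; small values mean the blood has split the
#' vein into fragments.
#'
#' @param vein_mask logical matrix.
#' @return The ratio, or `NA` (with a warning) for an empty mask,
#'   signalling that no vein is present.
#' @export
fragmentation_ratio <- function(vein_mask) {
  check_mask(vein_mask)
  total <- sum(vein_mask)
  if (total == 0L) {
    warning("empty vein mask: no vein present")
    return(NA_real_)
  }
  labels <- cpp_label8(vein_mask)
  max(tabulate(labels[labels > 0L], nbins = max(labels))) / total
}

#' Build the vein exclusion mask
#'
#' For a vein region that is one major connected component (fragmentation
#' ratio at or above the threshold, or `mode = "fill-only"`), filling the
#' blood-cell holes suffices. Otherwise the 0/255 mask raster is smoothed
#' with the fast bilateral filter at a strength driven by the
#' fragmentation ratio, re-binarized at a quarter of the foreground
#' level (a density, not majority, criterion — see Details), united
#' with the original
#' vein pixels, and hole-filled, which merges nearby fragments into one
#' exclusion region. The result is always a superset of the input vein
#' pixels.
#'
#' @param vein_mask logical matrix, the brightest class of a three-class
#'   thresholding.
#' @param params a [vein_params()].
#' @return A logical matrix; empty input returns an empty mask with a
#'   warning.
#' @export
build_exclusion_mask <- function(vein_mask, params = vein_params()) {
  check_mask(vein_mask)
  if (sum(vein_mask) == 0L) {
    warning("empty vein mask: returning empty exclusion mask")
    return(vein_mask)
  }
  ratio <- fragmentation_ratio(vein_mask)
  smooth_it <- switch(params$mode,
    "fill-only" = FALSE,
    "smooth" = TRUE,
    "auto" = ratio < params$fragmentation_threshold)
  out <- vein_mask
  if (smooth_it) {
    sigma_s <- params$base_sigma * (1 - ratio) + params$min_sigma
    raster <- ifelse(vein_mask, 255, 0)
    sm <- fast_bilateral(raster, bilateral_params(sigma_s, params$sigma_r))
    # re-binarize at a quarter of the foreground level: on a binary
    # raster the smoothed value tracks the local vein density, and
    # fragments whose blood gaps are thin relative to the smoothing
    # scale only reach moderate density there — a majority threshold
    # would never reconnect them, defeating the purpose of this branch
    out <- (sm > 255 / 4) | vein_mask
  }
  fill_holes(out)
}

#' Subtract an exclusion mask
#'
#' Sets to background every target pixel that is foreground in the
#' exclusion mask: `target AND NOT exclusion`.
#'
#' @param target,exclusion logical matrices of equal dimensions.
#' @return A logical matrix.
#' @export
subtract_mask <- function(target, exclusion) {
  check_mask(target)
  check_mask(exclusion)
  if (!identical(dim(target), dim(exclusion)))
    stop("mask dimensions do not match")
  target & !exclusion
}
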