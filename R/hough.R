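#' Circle Hough transform parameters
#'
#' Nuclei are detected as circles in the radius interval
#' `radius_range`, searched at integer steps of `radius_step`.
#' `acc_sigma` is the standard deviation of the Gaussian used to smooth
#' each accumulator plane. Peak extraction stops when the current
#' maximum falls to `relevance` times the first (largest) maximum, and
#' `closeness_factor` scales the duplicate-suppression distance in the
#' post-filter: two circles are close when their center distance is
#' below `closeness_factor * (r1 + r2)`.
#'
#' @param radius_range length-2 integer vector, `1 <= r_min <= r_max`.
#' @param radius_step integer radius increment.
#' @param acc_sigma accumulator smoothing std in pixels.
#' @param relevance stopping fraction in `(0, 1]`.
#' @param closeness_factor positive scale factor.
#' @param max_circles safety bound on extracted circles.
#' @return A list of class `hough_params`.
#' @export
hough_params <- function(radius_range = c(14, 50), radius_step = 2L,
                         acc_sigma = 10, relevance = 0.5,
                         closeness_factor = 0.5, max_circles = 5000L) {
  if (length(radius_range) != 2L || radius_range[1] < 1 ||
      radius_range[1] > radius_range[2])
    stop("`radius_range` must satisfy 1 <= r_min <= r_max")
  if (relevance <= 0 || relevance > 1)
    stop("`relevance` must lie in (0, 1]")
  if (closeness_factor <= 0) stop("`closeness_factor` must be positive")
  structure(list(radius_range = as.integer(radius_range),
                 radius_step = as.integer(radius_step),
                 acc_sigma = acc_sigma, relevance = relevance,
                 closeness_factor = closeness_factor,
                 max_circles = as.integer(max_circles)),
            class = "hough_params")
}

as_hough_params <- function(p) {
  if (inherits(p, "hough_params")) return(p)
  do.call(hough_params, p[intersect(names(p), names(formals(hough_params)))])
}

#' Outer boundary pixels of a mask
#' @noRd
boundary_pixels <- function(mask) {
  interior <- erode_mask(mask, 1L)
  mask & !interior
}

#' Build the circle Hough accumulator
#'
#' Operates in the parameter space of circles `(cx, cy, r)`. Each mask
#' boundary pixel estimates the inward normal from the local mask
#' content and casts one vote per candidate radius `r` at the point `r`
#' pixels along that normal — the center that a circle of radius `r`
#' through the pixel would have (compact, direction-informed voting,
#' which keeps arcs of overlapping nuclei from interfering). Each
#' `(cx, cy)` plane is smoothed with a Gaussian of std `acc_sigma` and
#' normalized by the circumference `2 pi r`, so an accumulator value
#' approximates the fraction of a circle's boundary present in the mask
#' and is comparable across radii.
#'
#' @param mask logical matrix of nucleus candidates.
#' @param params a [hough_params()].
#' @return A list of class `hough_accumulator` with `acc` (array
#'   `height x width x n_radii`), `radii`, and `params`.
#' @export
hough_accumulate <- function(mask, params = hough_params()) {
  check_mask(mask)
  params <- as_hough_params(params)
  radii <- seq(params$radius_range[1], params$radius_range[2],
               by = params$radius_step)
  if (sum(mask) == 0L) {
    acc <- array(0, c(nrow(mask), ncol(mask), length(radii)))
  } else {
    b <- which(boundary_pixels(mask), arr.ind = TRUE)
    acc <- cpp_hough_accumulate(mask, b[, 1] - 1L, b[, 2] - 1L,
                                as.integer(radii), params$acc_sigma,
                                TRUE)
    acc <- array(acc, c(nrow(mask), ncol(mask), length(radii)))
  }
  structure(list(acc = acc, radii = as.integer(radii), params = params),
            class = "hough_accumulator")
}

#' Extract circles from the accumulator
#'
#' Iteratively takes the global accumulator maximum as the next circle,
#' re-estimates its radius from the best-supported radius plane at that
#' center, and suppresses a cylinder of the estimated radius around the
#' peak so the same nucleus is not re-detected. Extraction stops when
#' the current maximum is no longer strictly above `relevance` times
#' the first maximum, so `relevance = 1` returns exactly the single
#' strongest circle. Scores are non-increasing in extraction order.
#'
#' @param accumulator a [hough_accumulate()] result.
#' @param params optional [hough_params()] overriding those stored in
#'   the accumulator (e.g. to sweep `relevance`).
#' @return A data frame of class `circle_set`: `cx`, `cy` (0-based
#'   center pixel), `r`, `score`.
#' @export
hough_detect <- function(accumulator, params = NULL) {
  stopifnot(inherits(accumulator, "hough_accumulator"))
  params <- if (is.null(params)) accumulator$params else as_hough_params(params)
  a <- accumulator$acc
  if (all(a == 0))
    return(empty_circles())
  det <- cpp_hough_detect(a, accumulator$radii, params$relevance,
                          accumulator$radii[1], params$max_circles, TRUE)
  circles <- data.frame(cx = det[, "j"], cy = det[, "i"],
                        r = det[, "r"], score = det[, "score"])
  class(circles) <- c("circle_set", "data.frame")
  circles
}

empty_circles <- function() {
  circles <- data.frame(cx = numeric(0), cy = numeric(0),
                        r = numeric(0), score = numeric(0))
  class(circles) <- c("circle_set", "data.frame")
  circles
}

#' Fraction of a circle's disc lying on a mask
#' @noRd
circle_mask_overlap <- function(cx, cy, r, mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  i0 <- max(1L, floor(cy + 1 - r)); i1 <- min(nr, ceiling(cy + 1 + r))
  j0 <- max(1L, floor(cx + 1 - r)); j1 <- min(nc, ceiling(cx + 1 + r))
  if (i0 > i1 || j0 > j1) return(0)
  ii <- i0:i1; jj <- j0:j1
  inside <- outer((ii - 1 - cy)^2, (jj - 1 - cx)^2, "+") <= r^2
  n_inside <- sum(inside)
  if (n_inside == 0L) return(0)
  sum(mask[ii, jj] & inside) / n_inside
}

#' Post-filter detected circles
#'
#' Two rules: (a) circles whose center lies outside the image or on a
#' background pixel of the candidate region mask are dropped; (b) among
#' a group of circles lying close together — center distance below
#' `closeness_factor * (r1 + r2)` — only the circle with the largest
#' fraction of its disc area overlapping the region mask is kept (ties
#' broken by the higher accumulator score). Groups are resolved
#' greedily in descending score order.
#'
#' @param circles a `circle_set` from [hough_detect()].
#' @param region_mask logical matrix of the hepatocyte candidate
#'   regions.
#' @param closeness_factor see [hough_params()].
#' @return The filtered `circle_set`.
#' @export
hough_postfilter <- function(circles, region_mask, closeness_factor = 0.5) {
  check_mask(region_mask)
  if (nrow(circles) == 0L) return(circles)
  nr <- nrow(region_mask); nc <- ncol(region_mask)
  # (a) center inside the image and on the candidate mask
  inb <- circles$cx >= 0 & circles$cx <= nc - 1 &
         circles$cy >= 0 & circles$cy <= nr - 1
  on_mask <- rep(FALSE, nrow(circles))
  on_mask[inb] <- region_mask[cbind(round(circles$cy[inb]) + 1L,
                                    round(circles$cx[inb]) + 1L)]
  circles <- circles[inb & on_mask, , drop = FALSE]
  if (nrow(circles) <= 1L) { rownames(circles) <- NULL; return(circles) }
  # (b) greedy closeness grouping in score order, keep best mask overlap
  ov <- vapply(seq_len(nrow(circles)), function(k)
    circle_mask_overlap(circles$cx[k], circles$cy[k], circles$r[k],
                        region_mask), numeric(1))
  ord <- order(-circles$score)
  state <- rep("open", nrow(circles))   # open | kept | dropped
  d <- as.matrix(dist(circles[, c("cx", "cy")]))
  rsum <- outer(circles$r, circles$r, "+")
  close <- d < closeness_factor * rsum
  for (k in ord) {
    if (state[k] != "open") next
    group <- union(k, which(close[k, ] & state == "open"))
    # keep the largest overlap; ties -> higher score
    best <- group[order(-ov[group], -circles$score[group])][1]
    state[setdiff(group, best)] <- "dropped"
    state[best] <- "kept"
  }
  out <- circles[state == "kept", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect nuclei as circles in a candidate mask
#'
#' Convenience wrapper: accumulate, extract, post-filter against the
#' same candidate mask.
#'
#' @inheritParams hough_accumulate
#' @return A filtered `circle_set`.
#' @export
detect_circles <- function(mask, params = hough_params()) {
  params <- as_hough_params(params)
  acc <- hough_accumulate(mask, params)
  circles <- hough_detect(acc)
  hough_postfilter(circles, mask, params$closeness_factor)
}
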