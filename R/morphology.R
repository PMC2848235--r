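#' Morphological erosion and dilation with a disc
#'
#' Erosion shrinks mask regions, separating weakly connected regions
#' (thin bridges between touching nuclei); dilation expands regions and
#' restores the original sizes after filtering. The structuring element
#' is a disc of the given radius.
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels, `>= 1`.
#' @return A logical matrix; `erode_mask(m) <= m <= dilate_mask(m)`
#'   pixel-wise.
#' @export
erode_mask <- function(mask, radius = 2L) {
  check_mask(mask)
  if (!is.numeric(radius) || radius < 1) stop("`radius` must be >= 1")
  kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  EBImage::erode(mask * 1, kern) > 0.5
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, radius = 2L) {
  check_mask(mask)
  if (!is.numeric(radius) || radius < 1) stop("`radius` must be >= 1")
  kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  EBImage::dilate(mask * 1, kern) > 0.5
}

#' Fill interior holes of mask regions
#'
#' Every background component not connected to the image border is set to
#' foreground, making all regions simply connected. Used both on nucleus
#' candidates and on vein regions (where the enclosed "holes" are blood
#' cells that must not survive as detection candidates).
#'
#' @param mask logical matrix.
#' @return A logical matrix, a superset of the input.
#' @export
fill_holes <- function(mask) {
  check_mask(mask)
  EBImage::fillHull(mask * 1) > 0.5
}

check_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  invisible(mask)
}

#' Connected-component labeling and measurement
#'
#' Labels the 8-connected foreground components of a binary mask and
#' measures each one: area `A` (pixel count), perimeter `P` (length of
#' the outer boundary trace: neighbouring border pixels contribute their
#' Euclidean step distance, 1 for axis steps and sqrt(2) for diagonal
#' steps; width-1 structures are traced out and back so both sides
#' count, and an isolated pixel has perimeter 4 by convention), and the
#' bounding box in 0-based (x, y) pixel coordinates.
#'
#' @param mask logical matrix.
#' @return A list of class `component_table` with `labels` (integer
#'   matrix, 0 = background) and `table` (data frame with one row per
#'   component: `label`, `area`, `perimeter`, `xmin`, `xmax`, `ymin`,
#'   `ymax`).
#' @export
label_components <- function(mask) {
  check_mask(mask)
  labels <- cpp_label8(mask)
  n <- max(labels)
  if (n == 0L) {
    tab <- data.frame(label = integer(0), area = integer(0),
                      perimeter = numeric(0), xmin = integer(0),
                      xmax = integer(0), ymin = integer(0), ymax = integer(0))
  } else {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    ri <- (idx - 1L) %% nrow(mask)       # 0-based row = y
    ci <- (idx - 1L) %/% nrow(mask)      # 0-based col = x
    tab <- data.frame(
      label = seq_len(n),
      area = tabulate(lab, nbins = n),
      perimeter = cpp_perimeters(labels, n),
      xmin = as.integer(tapply(ci, lab, min)),
      xmax = as.integer(tapply(ci, lab, max)),
      ymin = as.integer(tapply(ri, lab, min)),
      ymax = as.integer(tapply(ri, lab, max)))
  }
  structure(list(labels = labels, table = tab), class = "component_table")
}

#' Equivalent diameter and form factor
#'
#' Adds to a component table the equivalent diameter
#' `d_eq = sqrt(4 A / pi)` (the diameter of the circle with the same
#' area) and the form factor `F = 4 pi A / P^2`, which equals 1 for
#' circles and approaches 0 for elongated regions. On a coarse raster
#' `F` can marginally exceed 1; the raw value is kept for filtering and
#' a value clamped to 1 is reported alongside.
#'
#' @param comp a [label_components()] result.
#' @return The same object with columns `d_eq`, `form_factor` and
#'   `form_factor_clamped` added to `$table`.
#' @export
shape_metrics <- function(comp) {
  stopifnot(inherits(comp, "component_table"))
  tab <- comp$table
  tab$d_eq <- sqrt(4 * tab$area / pi)
  tab$form_factor <- ifelse(tab$perimeter > 0,
                            4 * pi * tab$area / tab$perimeter^2, NA_real_)
  tab$form_factor_clamped <- pmin(tab$form_factor, 1)
  comp$table <- tab
  comp
}

#' Shape filter parameters
#'
#' Default ranges select single hepatocyte nuclei: area between 700 and
#' 8000 pixels, equivalent diameter between 35 and 200 pixels, form
#' factor at least 0.2 (all at the working magnification where nucleus
#' radii span roughly 14 to 50 pixels).
#'
#' @param area_range numeric length-2, inclusive pixel-area range.
#' @param deq_range numeric length-2, inclusive equivalent-diameter
#'   range in pixels.
#' @param min_form_factor minimum form factor in `[0, 1]`.
#' @return A list of class `shape_filter_params`.
#' @export
shape_filter_params <- function(area_range = c(700, 8000),
                                deq_range = c(35, 200),
                                min_form_factor = 0.2) {
  if (length(area_range) != 2L || area_range[1] > area_range[2])
    stop("`area_range` must be a non-empty range")
  if (length(deq_range) != 2L || deq_range[1] > deq_range[2])
    stop("`deq_range` must be a non-empty range")
  if (min_form_factor < 0 || min_form_factor > 1)
    stop("`min_form_factor` must lie in [0, 1]")
  structure(list(area_range = area_range, deq_range = deq_range,
                 min_form_factor = min_form_factor),
            class = "shape_filter_params")
}

#' Filter components by size and roundness
#'
#' Accepts a component when its area and equivalent diameter fall within
#' the configured ranges and its (raw, unclamped) form factor reaches the
#' minimum; each rejected component records the criteria it failed. The
#' `criteria` argument restricts which checks apply, because the pipeline
#' applies the size criteria before dilation and the roundness criterion
#' after.
#'
#' @param comp a [shape_metrics()]-annotated component table.
#' @param params a [shape_filter_params()].
#' @param criteria subset of `c("area", "deq", "form_factor")`.
#' @return A list with `mask` (logical matrix of accepted components)
#'   and `table` (the component table with `accepted` and `reason`
#'   columns).
#' @export
filter_components <- function(comp, params = shape_filter_params(),
                              criteria = c("area", "deq", "form_factor")) {
  stopifnot(inherits(comp, "component_table"))
  criteria <- match.arg(criteria, several.ok = TRUE)
  tab <- comp$table
  if (!all(c("d_eq", "form_factor") %in% names(tab)))
    stop("run shape_metrics() first")
  fail <- matrix(FALSE, nrow(tab), 3,
                 dimnames = list(NULL, c("area", "deq", "form_factor")))
  if ("area" %in% criteria)
    fail[, "area"] <- tab$area < params$area_range[1] |
                      tab$area > params$area_range[2]
  if ("deq" %in% criteria)
    fail[, "deq"] <- tab$d_eq < params$deq_range[1] |
                     tab$d_eq > params$deq_range[2]
  if ("form_factor" %in% criteria)
    fail[, "form_factor"] <- is.na(tab$form_factor) |
                             tab$form_factor < params$min_form_factor
  tab$accepted <- rowSums(fail) == 0L
  tab$reason <- apply(fail, 1, function(f)
    if (any(f)) paste(colnames(fail)[f], collapse = ",") else "")
  keep <- tab$label[tab$accepted]
  mask <- matrix(comp$labels %in% keep, nrow(comp$labels), ncol(comp$labels))
  comp$table <- tab
  list(mask = mask, table = tab)
}
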