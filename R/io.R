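#' Construct a region-of-interest image
#'
#' Bundles an 8-bit RGB raster with its filename stem and the vein flag
#' derived from the stem. The raster is stored as a `height x width x 3`
#' array with values in `[0, 255]`.
#'
#' @param pixels numeric array of dimension `c(height, width, 3)`, values
#'   in `[0, 255]`.
#' @param stem character scalar, the filename without directory and
#'   extension. Stems containing a `PT` or `CV` token (e.g. `"D5-PT1"`)
#'   mark images taken from liver zones 1 or 2, which contain venous
#'   structures.
#' @return An object of class `roi_image` with fields `pixels`, `stem`,
#'   `has_vein`, `width`, `height`.
#' @seealso [read_roi()], [parse_vein_convention()]
#' @export
roi_image <- function(pixels, stem) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] < 3L)
    stop("`pixels` must be a height x width x 3 array")
  pixels <- pixels[, , 1:3, drop = FALSE]
  if (any(pixels < 0) || any(pixels > 255))
    stop("channel values must lie in [0, 255]")
  if (!is.character(stem) || length(stem) != 1L || !nzchar(stem))
    stop("`stem` must be a non-empty character scalar")
  structure(
    list(pixels = pixels, stem = stem,
         has_vein = parse_vein_convention(stem),
         width = dim(pixels)[2], height = dim(pixels)[1]),
    class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image> %s: %d x %d px, vein structures: %s\n",
              x$stem, x$width, x$height,
              if (x$has_vein) "yes" else "no"))
  invisible(x)
}

#' Read an RGB region-of-interest image
#'
#' Reads an 8-bit RGB TIFF or PNG raster and derives the vein-presence
#' flag from the filename, following the naming scheme in which `PT`
#' (portal tract) and `CV` (central vein) tokens mark images from liver
#' zones that contain venous structures.
#'
#' @param path path to a TIFF (`.tif`/`.tiff`) or PNG (`.png`) file.
#' @return A [roi_image()].
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    "png" = png::readPNG(path),
    "tif" = , "tiff" = tiff::readTIFF(path),
    stop("unsupported image format (need TIFF or PNG): ", path))
  if (length(dim(px)) != 3L || dim(px)[3] < 3L)
    stop("not an RGB image: ", path)
  stem <- tools::file_path_sans_ext(basename(path))
  roi_image(round(px[, , 1:3, drop = FALSE] * 255), stem)
}

#' Vein presence from the filename stem
#'
#' Liver zones 1 (portal tract) and 2 (central vein) contain vessel
#' structures; images from these zones carry a `PT` or `CV` token in
#' their name (e.g. `"D5-PT1"`, `"D7-CV1"`), while zone-3 images are
#' named by dataset only (e.g. `"D3"`). A token is a `-`-delimited
#' segment of the stem beginning with `PT` or `CV` followed only by
#' digits, so `"DCV"` does not count.
#'
#' @param stem non-empty character scalar.
#' @return `TRUE` if the stem signals venous structures.
#' @export
parse_vein_convention <- function(stem) {
  if (!is.character(stem) || length(stem) != 1L || !nzchar(stem))
    stop("`stem` must be a non-empty string")
  tokens <- strsplit(stem, "-", fixed = TRUE)[[1]]
  any(grepl("^(PT|CV)[0-9]*$", tokens))
}

#' Read and write point ground truth
#'
#' Ground truth is a point per marked nucleus, not an outline: a CSV with
#' header `x,y,class`, coordinates 0-based (x = column, y = row), and
#' class one of `"total"` or `"proliferating"`. Proliferating nuclei are
#' conventionally also listed under `"total"` by the marking experts.
#'
#' @param path CSV file path.
#' @return A data frame with columns `x`, `y`, `class`.
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("cannot read ground truth: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df)[1:3], c("x", "y", "class")))
    stop("ground truth must have header x,y,class: ", path)
  if (nrow(df) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$x))) |
               !is.finite(suppressWarnings(as.numeric(df$y))) |
               !(df$class %in% c("total", "proliferating")))
  if (length(bad))
    stop(sprintf("malformed ground truth row at line %d in %s",
                 bad[1] + 1L, path))
  data.frame(x = as.numeric(df$x), y = as.numeric(df$y),
             class = df$class, stringsAsFactors = FALSE)
}

#' @rdname read_ground_truth
#' @param points data frame with columns `x`, `y`, `class`.
#' @export
write_ground_truth <- function(points, path) {
  stopifnot(all(c("x", "y", "class") %in% names(points)))
  write.csv(points[, c("x", "y", "class")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read and write binary masks as single-channel PNG
#'
#' Masks are written with foreground 255 and background 0 and read back
#' as logical matrices.
#'
#' @param mask logical matrix.
#' @param path PNG file path.
#' @return `read_mask` returns a logical matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  px >= 0.5
}

#' Write a batch results table
#'
#' One row per processed image with the detected counts and the BrdU
#' labeling index, plus per-class validation columns when ground truth
#' was available.
#'
#' @param results data frame as produced by [process_batch()].
#' @param path output CSV path.
#' @export
write_results <- function(results, path) {
  write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
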