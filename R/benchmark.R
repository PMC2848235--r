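#' Bundled reference validation tables
#'
#' The package ships the published validation tables of the eight-animal
#' rat partial-hepatectomy study this pipeline was developed for:
#' per-image detection results against one expert's point ground truth,
#' for 23 regions of interest spanning the three liver zones (plain,
#' `PT` and `CV` images) and two staining batches. Columns: `detected`
#' (circles found), `tp`, `fp`, `fn`, the sensitivity and FPF as
#' printed in the study report (`*_printed`), and `user_p` (nuclei
#' marked by the expert, `= tp + fn`). These tables drive the metric
#' regression tests and the reproduction script; note that the printed
#' ratios were typeset with an inconsistent mix of rounding and
#' truncation, and one `detected` entry differs from `tp + fp` — the
#' raw counts are authoritative.
#'
#' @param channel `"total"` or `"proliferating"`.
#' @return A data frame, one row per region of interest.
#' @export
reference_results <- function(channel = c("total", "proliferating")) {
  channel <- match.arg(channel)
  path <- system.file("extdata",
                      paste0("benchmark_", channel, ".csv"),
                      package = "hepaquant", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Bundled inter-observer count table
#'
#' Four experts (three for one image) independently counted four event
#' categories — total hepatocytes, total non-hepatocytes, proliferating
#' hepatocytes, proliferating non-hepatocytes — on eleven regions of
#' interest of one staining batch. Used to quantify the dispersion of
#' the manual gold standard via [interobserver()].
#'
#' @return A long data frame with columns `image`, `observer`,
#'   `category`, `count`.
#' @export
observer_counts <- function() {
  path <- system.file("extdata", "observer_counts.csv",
                      package = "hepaquant", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
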