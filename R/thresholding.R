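#' Intensity histogram of an 8-bit channel
#'
#' Counts pixel intensities into 256 bins after rounding the (possibly
#' smoothed, hence fractional) channel back to integer levels. Pixels
#' under an optional exclusion mask contribute nothing; this is how the
#' vein region found in the red channel is discarded before thresholding
#' the blue channel, so that a negligible cell class is not swamped by
#' vein intensities.
#'
#' @param channel numeric matrix with values in `[0, 255]`.
#' @param exclusion_mask optional logical matrix of the same dimensions;
#'   `TRUE` pixels are excluded from the counts.
#' @return An object of class `intensity_histogram`: a list with `counts`
#'   (256 integers, bin `i + 1` holds intensity `i`), `n_pixels`, and
#'   `degenerate` (`TRUE` when no pixel remains).
#' @export
intensity_histogram <- function(channel, exclusion_mask = NULL) {
  check_channel(channel)
  v <- round(channel)
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), dim(channel)))
      stop("exclusion mask dimensions must match the channel")
    v <- v[!exclusion_mask]
  }
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  structure(list(counts = counts, n_pixels = sum(counts),
                 degenerate = sum(counts) == 0L,
                 excluded = !is.null(exclusion_mask)),
            class = "intensity_histogram")
}

as_histogram <- function(hist) {
  if (inherits(hist, "intensity_histogram")) return(hist)
  if (is.numeric(hist) && length(hist) == 256L)
    return(structure(list(counts = as.integer(hist),
                          n_pixels = sum(hist), degenerate = sum(hist) == 0,
                          excluded = FALSE),
                     class = "intensity_histogram"))
  stop("`hist` must be an intensity_histogram or a 256-bin count vector")
}

#' Threshold sets
#'
#' A threshold set partitions the 256 intensity levels into ordered
#' classes (darkest first). `cuts` holds, for each class boundary, the
#' highest intensity still assigned to the lower class, so a two-class
#' set with `cuts = 127` maps levels 0..127 to class 0 and 128..255 to
#' class 1.
#'
#' @param cuts strictly increasing integer vector of length 1 or 2.
#' @param method character tag recording how the cuts were obtained.
#' @return An object of class `threshold_set` with `cuts`, `class_of_bin`
#'   (a 256-vector of 0-based class indices, non-decreasing) and
#'   `n_classes`.
#' @export
threshold_set <- function(cuts, method = "manual") {
  cuts <- as.numeric(cuts)
  if (length(cuts) < 1L || length(cuts) > 2L || is.unsorted(cuts, strictly = TRUE))
    stop("`cuts` must be 1 or 2 strictly increasing values")
  class_of_bin <- rowSums(outer(0:255, cuts, ">"))
  structure(list(cuts = cuts, class_of_bin = class_of_bin,
                 n_classes = length(cuts) + 1L, method = method),
            class = "threshold_set")
}

between_class_variance <- function(counts, cuts) {
  # total between-class variance of the partition defined by `cuts`
  n <- sum(counts)
  y <- 0:255
  mu <- sum(counts * y) / n
  cls <- rowSums(outer(y, cuts, ">"))
  v <- 0
  for (c in unique(cls)) {
    sel <- cls == c
    p <- sum(counts[sel]) / n
    if (p > 0) v <- v + p * (sum(counts[sel] * y[sel]) / sum(counts[sel]) - mu)^2
  }
  v
}

#' Otsu histogram thresholding
#'
#' Finds the single cut that maximizes the between-class variance of the
#' two resulting classes (equivalently, minimizes the within-class
#' variance), by an exhaustive scan over all 255 candidate cuts. Among
#' equal-variance cuts the midpoint of the optimal plateau is chosen, so
#' the result is deterministic and symmetric.
#'
#' @param hist an [intensity_histogram()] with at least 2 nonzero bins.
#' @return A [threshold_set()] with one cut.
#' @export
otsu <- function(hist) {
  hist <- as_histogram(hist)
  counts <- hist$counts
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: need at least 2 populated intensity levels")
  y <- 0:255
  n <- sum(counts)
  cw <- cumsum(counts)                  # pixels in class 0 for cut t = 0..255
  cm <- cumsum(counts * y)
  w0 <- cw[1:255] / n
  w1 <- 1 - w0
  mu0 <- ifelse(cw[1:255] > 0, cm[1:255] / cw[1:255], 0)
  mu1 <- ifelse(cw[256] - cw[1:255] > 0,
                (cm[256] - cm[1:255]) / (cw[256] - cw[1:255]), 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2       # between-class variance at cut t-1
  cand <- which(bcv >= max(bcv) - 1e-12) - 1L
  cut <- cand[(length(cand) + 1L) %/% 2L]
  threshold_set(cut, method = "otsu")
}

#' Multi-level Otsu thresholding (three classes)
#'
#' Exhaustive search over all ordered cut pairs for the pair maximizing
#' the between-class variance of the three resulting classes. Used as a
#' baseline for images containing nucleus, background and vein classes.
#'
#' @param hist an [intensity_histogram()] with at least 3 nonzero bins.
#' @param n_classes must be 3.
#' @return A [threshold_set()] with two cuts.
#' @export
multilevel_otsu <- function(hist, n_classes = 3L) {
  if (n_classes != 3L) stop("only 3-class multi-level Otsu is supported")
  hist <- as_histogram(hist)
  counts <- hist$counts
  if (sum(counts > 0) < 3L)
    stop("degenerate histogram: need at least 3 populated intensity levels")
  y <- 0:255
  n <- sum(counts)
  cw <- c(0, cumsum(counts))           # cw[t+1] = pixels with intensity <= t-1
  cm <- c(0, cumsum(counts * y))
  mu <- cm[257] / n
  # class over (a, b]: weight and mean from cumulative sums (1-based offsets)
  wsum <- function(a, b) cw[b + 2L] - cw[a + 2L]
  msum <- function(a, b) cm[b + 2L] - cm[a + 2L]
  best <- -Inf; best_cuts <- NULL
  for (t1 in 0:253) {
    t2 <- (t1 + 1L):254L
    w0 <- wsum(-1L, t1); m0 <- msum(-1L, t1)
    w1 <- wsum(t1, t2);  m1 <- msum(t1, t2)
    w2 <- wsum(t2, 255L); m2 <- msum(t2, 255L)
    v <- ifelse(w0 > 0, w0 / n * (m0 / pmax(w0, 1) - mu)^2, 0) +
         ifelse(w1 > 0, w1 / n * (m1 / pmax(w1, 1) - mu)^2, 0) +
         ifelse(w2 > 0, w2 / n * (m2 / pmax(w2, 1) - mu)^2, 0)
    k <- which.max(v)
    if (v[k] > best) { best <- v[k]; best_cuts <- c(t1, t2[k]) }
  }
  threshold_set(best_cuts, method = "multiotsu")
}

#' Gaussian-mixture fit of a histogram by expectation-maximization
#'
#' Models the pixel intensities of a channel as draws from `n_classes`
#' univariate Gaussians with unknown means, standard deviations and class
#' proportions, and fits the parameters by EM. For speed the algorithm
#' operates on the 256-bin histogram rather than on the raw pixels: each
#' intensity level enters the expectation and maximization sums weighted
#' by its count, which is an exact reformulation of pixel-level EM (all
#' pixels at one level share one responsibility vector).
#'
#' Initialization divides the histogram into `n_classes` equal parts and
#' uses each part's mean intensity as the initial class mean; the initial
#' standard deviations all equal the maximum intensity present in the
#' image, and the initial proportions are `1/n_classes`. Iteration stops
#' when the log-likelihood changes by less than `tol` (default `1e-4`)
#' or after `max_iter` iterations.
#'
#' Standard deviations are floored at 0.5 intensity levels to prevent
#' singular collapse on spiky histograms; a class pinned at the floor
#' with proportion below `1e-4` is frozen and reported via the
#' `collapsed` field.
#'
#' @param hist an [intensity_histogram()] with at least `n_classes`
#'   populated bins.
#' @param n_classes 2 (nucleus, background) or 3 (nucleus, background,
#'   vein).
#' @param tol stopping accuracy on the log-likelihood difference.
#' @param max_iter iteration safety bound.
#' @return An object of class `gaussian_mixture`: `mu`, `sigma`, `pi`
#'   (each of length `n_classes`, sorted by ascending mean),
#'   `log_likelihood`, `n_iter`, `converged`, `collapsed`.
#' @export
em_fit <- function(hist, n_classes, tol = 1e-4, max_iter = 500L) {
  hist <- as_histogram(hist)
  counts <- hist$counts
  if (!n_classes %in% c(2L, 3L)) stop("`n_classes` must be 2 or 3")
  if (sum(counts > 0) < n_classes)
    stop("degenerate histogram: fewer populated levels than classes")
  y <- 0:255
  w <- counts
  n <- sum(w)
  sigma_floor <- 0.5

  # initial means: mean intensity of each of n equal histogram parts
  part <- ceiling(seq_along(y) / (256 / n_classes))
  mu <- vapply(seq_len(n_classes), function(k) {
    sel <- part == k
    if (sum(w[sel]) > 0) sum(w[sel] * y[sel]) / sum(w[sel])
    else mean(y[sel])
  }, numeric(1))
  sigma <- rep(max(y[w > 0]), n_classes)
  sigma <- pmax(sigma, sigma_floor)
  pi_k <- rep(1 / n_classes, n_classes)
  frozen <- rep(FALSE, n_classes)

  loglik_of <- function(mu, sigma, pi_k) {
    ld <- vapply(seq_len(n_classes),
                 function(k) log(pi_k[k]) + dnorm(y, mu[k], sigma[k], log = TRUE),
                 numeric(256))
    m <- apply(ld, 1, max)
    sum(w * (m + log(rowSums(exp(ld - m)))))
  }

  ll_prev <- loglik_of(mu, sigma, pi_k)
  ll_trace <- ll_prev
  n_iter <- 0L
  converged <- FALSE
  while (n_iter < max_iter) {
    n_iter <- n_iter + 1L
    # E-step: responsibilities per intensity level (log-sum-exp guarded)
    ld <- vapply(seq_len(n_classes),
                 function(k) log(pi_k[k]) + dnorm(y, mu[k], sigma[k], log = TRUE),
                 numeric(256))
    m <- apply(ld, 1, max)
    r <- exp(ld - m)
    r <- r / rowSums(r)
    # M-step, weighted by bin counts
    for (k in seq_len(n_classes)) {
      if (frozen[k]) next
      nk <- sum(w * r[, k])
      if (nk <= 0) { frozen[k] <- TRUE; next }
      pi_k[k] <- nk / n
      mu[k] <- sum(w * r[, k] * y) / nk
      sigma[k] <- sqrt(sum(w * r[, k] * (y - mu[k])^2) / nk)
      if (sigma[k] < sigma_floor) {
        sigma[k] <- sigma_floor
        if (pi_k[k] < 1e-4) frozen[k] <- TRUE
      }
    }
    pi_k <- pi_k / sum(pi_k)
    ll <- loglik_of(mu, sigma, pi_k)
    ll_trace <- c(ll_trace, ll)
    if (abs(ll - ll_prev) < tol) { ll_prev <- ll; converged <- TRUE; break }
    ll_prev <- ll
  }

  ord <- order(mu)
  structure(list(n_classes = n_classes, mu = mu[ord], sigma = sigma[ord],
                 pi = pi_k[ord], log_likelihood = ll_prev,
                 ll_trace = ll_trace, n_iter = n_iter,
                 converged = converged, collapsed = frozen[ord]),
            class = "gaussian_mixture")
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat(sprintf("<gaussian_mixture> %d classes, logL = %.4f after %d iterations%s\n",
              x$n_classes, x$log_likelihood, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  print(data.frame(mu = x$mu, sigma = x$sigma, pi = x$pi,
                   collapsed = x$collapsed))
  invisible(x)
}

#' Classification thresholds from a fitted mixture
#'
#' Each intensity level is assigned to the class whose proportion-weighted
#' Gaussian density is highest; the classification changes where the
#' weighted density curves intersect, and those intersection levels are
#' the cuts. If very unequal standard deviations make the per-level
#' argmax non-monotone in class order, the boundary between each pair of
#' adjacent classes is repaired to the outermost density crossing between
#' their means.
#'
#' @param mix a [em_fit()] result.
#' @return A [threshold_set()].
#' @export
thresholds_from_mixture <- function(mix) {
  stopifnot(inherits(mix, "gaussian_mixture"))
  y <- 0:255
  ld <- vapply(seq_len(mix$n_classes),
               function(k) log(mix$pi[k]) + dnorm(y, mix$mu[k], mix$sigma[k], log = TRUE),
               numeric(256))
  cls <- max.col(ld, ties.method = "first") - 1L
  if (length(unique(cls)) == 1L)
    stop("degenerate thresholds: all intensity levels map to one class")
  if (!is.unsorted(cls)) {
    cuts <- y[which(diff(cls) > 0)]
    if (length(cuts) == mix$n_classes - 1L)
      return(threshold_set(cuts, method = "em"))
  }
  # repair: outermost crossing between each pair of adjacent classes
  cuts <- numeric(0)
  for (k in seq_len(mix$n_classes - 1L)) {
    d <- ld[, k] - ld[, k + 1L]
    cross <- which(d[-256] >= 0 & d[-1] < 0) - 1L  # level before sign change
    lo <- floor(mix$mu[k]); hi <- ceiling(mix$mu[k + 1L])
    inside <- cross[cross >= lo & cross <= hi]
    cut <- if (length(inside)) max(inside)
           else if (length(cross)) cross[which.min(abs(cross - (lo + hi) / 2))]
           else NA_real_
    if (is.na(cut))
      stop("degenerate thresholds: no density crossing between classes ",
           k, " and ", k + 1L)
    cuts <- c(cuts, cut)
  }
  if (length(cuts) == 2L && cuts[2] <= cuts[1]) cuts[2] <- cuts[1] + 1
  if (is.unsorted(cuts, strictly = TRUE) ||
      length(cuts) != mix$n_classes - 1L)
    stop("degenerate thresholds: could not separate all classes")
  threshold_set(cuts, method = "em")
}

#' Per-class binary masks from a threshold set
#'
#' Applies a threshold set to a channel and returns one binary mask per
#' class (darkest class first) together with a composite RGB mask image
#' in which each class occupies one color channel. The darkest class
#' holds the nucleus candidates; in the three-class case the brightest
#' class is the vein. Pixels under an optional exclusion mask belong to
#' no class.
#'
#' @param channel numeric matrix, values in `[0, 255]`.
#' @param ts a [threshold_set()].
#' @param exclusion_mask optional logical matrix; excluded pixels are
#'   assigned to no class.
#' @return A list with `masks` (list of logical matrices, dark to
#'   bright), `composite` (height x width x 3 array in `[0, 1]`), and
#'   `n_classes`.
#' @export
class_masks <- function(channel, ts, exclusion_mask = NULL) {
  stopifnot(inherits(ts, "threshold_set"))
  check_channel(channel)
  v <- round(channel)
  cls <- matrix(ts$class_of_bin[as.integer(v) + 1L], nrow(channel), ncol(channel))
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), dim(channel)))
      stop("exclusion mask dimensions must match the channel")
    cls[exclusion_mask] <- NA_integer_
  }
  masks <- lapply(seq_len(ts$n_classes) - 1L,
                  function(c) !is.na(cls) & cls == c)
  composite <- array(0, c(nrow(channel), ncol(channel), 3))
  for (c in seq_len(min(ts$n_classes, 3L)))
    composite[, , c] <- masks[[c]] * 1
  list(masks = masks, composite = composite, n_classes = ts$n_classes)
}
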