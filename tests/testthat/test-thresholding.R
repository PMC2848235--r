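test_that("histograms count unmasked pixels only", {
  ch <- matrix(c(0, 0, 255, 255), 2, 2)
  h <- intensity_histogram(ch)
  expect_equal(h$counts[1], 2)
  expect_equal(h$counts[256], 2)
  expect_equal(h$n_pixels, 4)

  mask <- ch == 255
  h2 <- intensity_histogram(ch, exclusion_mask = mask)
  expect_equal(h2$counts[256], 0)
  expect_equal(h2$n_pixels, 2)

  h3 <- intensity_histogram(ch, exclusion_mask = matrix(TRUE, 2, 2))
  expect_true(h3$degenerate)
  expect_equal(sum(h3$counts), 0)

  expect_error(intensity_histogram(ch, exclusion_mask = matrix(TRUE, 3, 2)),
               "dimensions")
})

test_that("otsu separates spikes, matches brute force, and breaks ties at the plateau midpoint", {
  spikes <- rep(0L, 256); spikes[51] <- 100L; spikes[201] <- 100L
  cut <- otsu(spikes)$cuts
  expect_gte(cut, 50); expect_lt(cut, 200)

  set.seed(3)
  h <- sample_mixture_hist(1e5, c(80, 180), c(10, 10), c(0.5, 0.5))
  cut2 <- otsu(h)$cuts
  expect_gte(cut2, 120); expect_lte(cut2, 140)
  expect_equal(cut2, oracle_otsu(h))

  uniform <- rep(10L, 256)
  expect_equal(otsu(uniform)$cuts, 127)

  expect_error(otsu(c(5L, rep(0L, 255))), "degenerate")
})

test_that("otsu equals the within-class-variance oracle on random histograms", {
  set.seed(11)
  for (k in 1:20) {
    h <- sample_mixture_hist(2e4, sort(runif(2, 30, 220)),
                             runif(2, 5, 25), c(0.5, 0.5))
    if (sum(h > 0) < 2) next
    expect_equal(otsu(h)$cuts, oracle_otsu(h))
  }
})

test_that("multilevel otsu separates three spikes and matches the exhaustive oracle", {
  spikes <- rep(0L, 256)
  spikes[c(31, 121, 221)] <- 100L
  cuts <- multilevel_otsu(spikes)$cuts
  expect_true(cuts[1] >= 30 && cuts[1] < 120)
  expect_true(cuts[2] >= 120 && cuts[2] < 220)

  set.seed(5)
  h <- sample_mixture_hist(5e4, c(50, 130, 210), c(8, 8, 8), rep(1/3, 3))
  expect_equal(multilevel_otsu(h)$cuts, oracle_multiotsu(h))

  two <- rep(0L, 256); two[c(10, 200)] <- 5L
  expect_error(multilevel_otsu(two), "degenerate")
})

test_that("EM recovers two well-separated mixture components", {
  set.seed(9)
  h <- sample_mixture_hist(1e5, c(80, 180), c(12, 12), c(0.5, 0.5))
  fit <- em_fit(h, 2L)
  expect_lt(abs(fit$mu[1] - 80), 3)
  expect_lt(abs(fit$mu[2] - 180), 3)
  expect_lt(abs(fit$pi[1] - 0.5), 0.05)
  expect_true(all(fit$sigma > 0))
  expect_equal(sum(fit$pi), 1, tolerance = 1e-9)
})

test_that("EM on a single Gaussian either merges means or empties a class", {
  set.seed(13)
  h <- sample_mixture_hist(5e4, 120, 15, 1)
  fit <- em_fit(h, 2L)
  expect_true((abs(fit$mu[1] - 120) < 3 && abs(fit$mu[2] - 120) < 3) ||
              min(fit$pi) < 0.05)
})

test_that("EM log-likelihood is monotone and the stopping rule is exact", {
  set.seed(17)
  h <- sample_mixture_hist(2e4, c(70, 190), c(10, 15), c(0.3, 0.7))
  fit <- em_fit(h, 2L)
  expect_true(all(diff(fit$ll_trace) >= -1e-6))
  expect_lt(abs(diff(tail(fit$ll_trace, 2))), 1e-4)

  one_iter <- em_fit(h, 2L, tol = Inf)
  expect_equal(one_iter$n_iter, 1L)

  expect_error(em_fit(c(5L, rep(0L, 255)), 2L), "degenerate")
})

test_that("histogram-weighted EM equals pixel-level EM", {
  set.seed(23)
  px <- pmin(pmax(round(c(rnorm(700, 90, 10), rnorm(1300, 190, 12))), 0), 255)
  h <- tabulate(px + 1L, nbins = 256L)
  fit <- em_fit(h, 2L, tol = 1e-8, max_iter = 300L)
  ref <- oracle_pixel_em(px, 2L, tol = 1e-8, max_iter = 300L)
  expect_equal(fit$mu, ref$mu, tolerance = 1e-6)
  expect_equal(fit$sigma, ref$sigma, tolerance = 1e-6)
  expect_equal(fit$pi, ref$pi, tolerance = 1e-6)
})

test_that("mixture thresholds sit at the weighted density crossings", {
  sym <- structure(list(n_classes = 2L, mu = c(80, 180), sigma = c(10, 10),
                        pi = c(0.5, 0.5), log_likelihood = 0, n_iter = 1L,
                        converged = TRUE, collapsed = c(FALSE, FALSE)),
                   class = "gaussian_mixture")
  cut <- thresholds_from_mixture(sym)$cuts
  expect_lte(abs(cut - 130), 1)

  heavier_dark <- sym; heavier_dark$pi <- c(0.9, 0.1)
  cut2 <- thresholds_from_mixture(heavier_dark)$cuts
  expect_gt(cut2, cut)  # cut shifts toward the lighter class

  three <- structure(list(n_classes = 3L, mu = c(60, 150, 230),
                          sigma = c(10, 12, 8), pi = c(0.2, 0.6, 0.2),
                          log_likelihood = 0, n_iter = 1L, converged = TRUE,
                          collapsed = rep(FALSE, 3)),
                     class = "gaussian_mixture")
  cuts <- thresholds_from_mixture(three)$cuts
  expect_length(cuts, 2)
  expect_lt(cuts[1], cuts[2])
})

test_that("class masks partition the unmasked pixels", {
  ch <- matrix(c(0, 0, 255, 255), 2, 2)
  cm <- class_masks(ch, threshold_set(127))
  expect_identical(cm$masks[[1]], ch == 0)

  set.seed(31)
  rnd <- matrix(sample(0:255, 400, TRUE), 20, 20)
  ts <- threshold_set(c(85, 170))
  cm3 <- class_masks(rnd, ts)
  total <- Reduce(`+`, lapply(cm3$masks, as.numeric))
  expect_true(all(total == 1))  # disjoint and covering

  excl <- rnd > 200
  cm4 <- class_masks(rnd, ts, exclusion_mask = excl)
  total4 <- Reduce(`|`, cm4$masks)
  expect_true(!any(total4 & excl))
})

test_that("three-class EM assigns nuclei dark and vein bright", {
  set.seed(37)
  h <- sample_mixture_hist(1e5, c(80, 210, 245), c(8, 8, 4),
                           c(0.2, 0.7, 0.1))
  fit <- em_fit(h, 3L)
  expect_lt(abs(fit$mu[1] - 80), 3)
  expect_lt(abs(fit$mu[3] - 245), 3)
  cuts <- thresholds_from_mixture(fit)$cuts
  expect_length(cuts, 2)
  expect_true(cuts[1] > 80 && cuts[1] < 210)
  expect_true(cuts[2] > 210 && cuts[2] < 245)
})
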