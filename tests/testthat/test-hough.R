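small_params <- function(...) {
  hough_params(radius_range = c(14, 30), radius_step = 2L, acc_sigma = 10,
               ...)
}

test_that("the accumulator peaks at a planted circle's center and radius", {
  m <- fix_disc(101, 101, 50, 50, 20)
  acc <- hough_accumulate(m, small_params())
  peak <- arrayInd(which.max(acc$acc), dim(acc$acc))
  expect_lte(abs(peak[1] - 1 - 50), 2)
  expect_lte(abs(peak[2] - 1 - 50), 2)

  circ <- hough_detect(acc)
  expect_lte(abs(circ$r[1] - 20), 2)

  m2 <- fix_discs(101, 201, rbind(c(50, 50), c(50, 150)), c(18, 18))
  circ2 <- hough_detect(hough_accumulate(m2, small_params()))
  expect_equal(nrow(circ2), 2L)
  expect_setequal(round(circ2$cx / 10), c(5, 15))

  empty <- matrix(FALSE, 30, 30)
  acc0 <- hough_accumulate(empty, small_params())
  expect_true(all(acc0$acc == 0))
  expect_equal(nrow(hough_detect(acc0)), 0L)
})

test_that("relevance 1 keeps only the first maximum; equals are both kept at 0.5", {
  m2 <- fix_discs(101, 201, rbind(c(50, 50), c(50, 150)), c(18, 18))
  acc <- hough_accumulate(m2, small_params())
  expect_equal(nrow(hough_detect(acc, small_params(relevance = 1.0))), 1L)
  expect_equal(nrow(hough_detect(acc, small_params(relevance = 0.5))), 2L)
})

test_that("low-level clutter stays below the relevance threshold", {
  set.seed(53)
  m <- fix_disc(151, 151, 75, 75, 22)
  clutter <- matrix(runif(151^2) > 0.995, 151, 151)  # isolated specks
  circ <- hough_detect(hough_accumulate(m | clutter, small_params()))
  circ <- hough_postfilter(circ, m | clutter, 0.5)
  keep <- sqrt((circ$cx - 75)^2 + (circ$cy - 75)^2) < 5
  expect_equal(sum(keep), 1L)
})

test_that("the post-filter drops off-mask centers and resolves close groups", {
  m <- fix_disc(101, 101, 50, 50, 20)
  circles <- data.frame(cx = c(50, 50, 5), cy = c(50, 52, 5),
                        r = c(20, 18, 15), score = c(2, 1.5, 1))
  class(circles) <- c("circle_set", "data.frame")
  out <- hough_postfilter(circles, m, 0.5)
  expect_equal(nrow(out), 1L)            # off-mask dropped, concentric merged
  expect_equal(out$cx, 50)

  far <- data.frame(cx = c(30, 95), cy = c(50, 50), r = c(20, 20),
                    score = c(2, 1.9))
  class(far) <- c("circle_set", "data.frame")
  big <- matrix(TRUE, 101, 131)
  # distance 65 = 1.625 * (r1 + r2) * 0.5-factor -> not close
  expect_equal(nrow(hough_postfilter(far, big, 0.5)), 2L)
})

test_that("counts are exact on clean non-overlapping discs", {
  set.seed(59)
  for (rep in 1:3) {
    N <- sample(10:25, 1)
    ctr <- NULL; rads <- NULL
    while (length(rads) < N) {
      r <- runif(1, 16, 40)
      p <- c(runif(1, r + 5, 495 - r), runif(1, r + 5, 495 - r))
      if (is.null(ctr) ||
          all(sqrt(colSums((t(ctr) - p)^2)) > rads + r + 6)) {
        ctr <- rbind(ctr, p); rads <- c(rads, r)
      }
    }
    m <- fix_discs(500, 500, ctr, rads)
    circ <- detect_circles(m, hough_params())
    expect_equal(nrow(circ), N)
    d <- sqrt(outer(circ$cy, ctr[, 1], "-")^2 +
              outer(circ$cx, ctr[, 2], "-")^2)
    covered <- colSums(d <= matrix(circ$r, nrow(circ), N))
    expect_true(all(covered == 1))       # each center in exactly one circle
  }
})

test_that("overlapping disc pairs are resolved into two detections", {
  set.seed(61)
  resolved <- 0L
  for (rep in 1:20) {
    r1 <- runif(1, 18, 28); r2 <- runif(1, 18, 28)
    d12 <- r1 + r2 - 0.4 * min(r1, r2)
    a <- runif(1, 0, pi)
    c1 <- c(75, 75) - d12 / 2 * c(sin(a), cos(a))
    c2 <- c(75, 75) + d12 / 2 * c(sin(a), cos(a))
    m <- fix_discs(151, 151, rbind(c1, c2), c(r1, r2))
    circ <- detect_circles(m, hough_params())
    ok <- nrow(circ) == 2 &&
      min(sqrt((circ$cx - c1[2])^2 + (circ$cy - c1[1])^2)) < r1 / 2 &&
      min(sqrt((circ$cx - c2[2])^2 + (circ$cy - c2[1])^2)) < r2 / 2
    resolved <- resolved + ok
  }
  expect_gte(resolved / 20, 0.9)
})

test_that("raising relevance never increases the detection count", {
  set.seed(67)
  m <- fix_discs(300, 300,
                 cbind(runif(8, 40, 260), runif(8, 40, 260)) |>
                   (\(x) x[order(x[, 1]), ])(),
                 runif(8, 16, 28))
  acc <- hough_accumulate(m, hough_params())
  counts <- vapply(seq(0.1, 0.9, 0.1), function(rel)
    nrow(hough_detect(acc, hough_params(relevance = rel))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})
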