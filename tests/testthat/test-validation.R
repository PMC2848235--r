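circle_df <- function(cx, cy, r, score = 1) {
  d <- data.frame(cx = cx, cy = cy, r = r, score = score)
  class(d) <- c("circle_set", "data.frame")
  d
}

test_that("matching is one-to-one, point-in-circle, nearest-first", {
  circ <- circle_df(c(10, 50, 90), c(10, 10, 10), c(8, 8, 8))
  pts <- data.frame(x = c(11, 49, 91), y = c(10, 11, 9))
  m <- match_points(circ, pts)
  expect_equal(c(m$tp, m$fp, m$fn), c(3, 0, 0))

  one <- circle_df(20, 20, 10)
  two_pts <- data.frame(x = c(19, 22), y = c(20, 20))
  m2 <- match_points(one, two_pts)
  expect_equal(c(m2$tp, m2$fn), c(1, 1))
  expect_equal(m2$pairs$point, 1)  # nearest point wins

  m3 <- match_points(circle_df(10, 10, 5), data.frame(x = 50, y = 50))
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0, 1, 1))
})

test_that("matching is invariant under relabeling of identical geometry", {
  set.seed(71)
  circ <- circle_df(runif(10, 0, 100), runif(10, 0, 100), runif(10, 8, 15))
  pts <- data.frame(x = runif(12, 0, 100), y = runif(12, 0, 100))
  m1 <- match_points(circ, pts)
  perm <- sample(10); permp <- sample(12)
  m2 <- match_points(circ[perm, ], pts[permp, ])
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(m2$tp, m2$fp, m2$fn))
})

test_that("sensitivity and FPF reproduce a reference table row", {
  met <- detection_metrics(list(tp = 221, fp = 9, fn = 22), n_detected = 230)
  expect_equal(met$sensitivity_rounded, 0.91)
  expect_equal(met$fpf, 9 / 230)
  expect_equal(round(met$fpf, 3), 0.039)

  und <- detection_metrics(list(tp = 0, fp = 0, fn = 0), n_detected = 0)
  expect_true(is.na(und$sensitivity))
  expect_true(is.na(und$fpf))
})

test_that("ROC-like sweeps re-run the pipeline and order by value", {
  s <- synth_generate(synth_params(n_total = 18L, n_proliferating = 4L,
                                   seed = 37))
  vals <- c(0.3, 0.6, 0.9)
  sw <- roc_sweep(s$roi, s$ground_truth, default_config(),
                  "total.hough.relevance", vals, channel = "total")
  expect_equal(sw$value, vals)
  expect_true(all(diff(sw$detected) <= 0))

  single <- roc_sweep(s$roi, s$ground_truth, default_config(),
                      "total.hough.relevance", 0.5, channel = "total")
  direct <- process_image(s$roi)
  expect_equal(single$detected, direct$n_total)

  expect_error(roc_sweep(s$roi, s$ground_truth, default_config(),
                         "total.hough.bogus", vals), "param_path")
})

test_that("inter-observer dispersion uses the sample relative standard deviation", {
  tab <- data.frame(image = rep(c("A", "B"), each = 2),
                    observer = rep(1:2, 2),
                    category = "total_hc",
                    count = c(10, 12, 20, 20))
  out <- interobserver(tab)
  # image A: sd(10,12)/11 = sqrt(2)/11; image B: 0
  expect_equal(unname(out["total_hc"]),
               mean(c(100 * sqrt(2) / 11, 0)), tolerance = 1e-9)

  same <- data.frame(image = "A", observer = 1:3, category = "c",
                     count = c(7, 7, 7))
  expect_equal(unname(interobserver(same)["c"]), 0)

  lone <- data.frame(image = "A", observer = 1, category = "c", count = 5)
  expect_true(is.na(interobserver(lone)["c"]))
})
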