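test_that("generation is bit-identical for a fixed seed", {
  a <- synth_generate(synth_params(seed = 7))
  b <- synth_generate(synth_params(seed = 7))
  expect_identical(a$roi$pixels, b$roi$pixels)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$vein_mask, b$vein_mask)
})

test_that("ground truth counts equal the planted counts", {
  s <- synth_generate(synth_params(n_total = 50L, n_proliferating = 9L,
                                   seed = 3))
  gt <- s$ground_truth
  expect_equal(sum(gt$class == "total"), 50L)
  expect_equal(sum(gt$class == "proliferating"), 9L)
  expect_true(all(gt$x >= 0 & gt$x < s$params$width))
  expect_true(all(gt$y >= 0 & gt$y < s$params$height))
  expect_error(synth_params(n_total = 5L, n_proliferating = 9L),
               "n_proliferating")
})

test_that("the fragmented vein preset really fragments the vein", {
  s <- synth_generate(synth_presets(5)$vein_fragmented)
  expect_lt(fragmentation_ratio(s$vein_mask), 0.95)
  expect_gt(nrow(label_components(s$vein_mask)$table), 1L)
  expect_true(s$roi$has_vein)  # stem carries the CV token
})

test_that("presets cover the pipeline branches and generate cleanly", {
  ps <- synth_presets(2)
  expect_gte(length(ps), 5L)
  for (nm in setdiff(names(ps), "full_scale")) {
    out <- synth_generate(ps[[nm]])
    expect_s3_class(out$roi, "roi_image")
  }
  # full-scale preset: parameters only (the raster itself is large)
  expect_equal(ps$full_scale$width, 2576L)
})

test_that("overlapping pairs are planted at the prescribed distance", {
  s <- synth_generate(synth_params(n_total = 8L, n_proliferating = 0L,
                                   n_overlap_pairs = 4L, seed = 13))
  gt <- s$ground_truth[s$ground_truth$class == "total", ]
  for (k in seq_len(4)) {
    i <- 2 * k - 1; j <- 2 * k
    d <- sqrt((gt$x[i] - gt$x[j])^2 + (gt$y[i] - gt$y[j])^2)
    r1 <- s$radii[i]; r2 <- s$radii[j]
    expect_equal(d, r1 + r2 - 0.4 * min(r1, r2), tolerance = 1e-6)
  }
})

test_that("contrast batches shift the intensity levels", {
  p2 <- synth_params(contrast = "batch2", seed = 1)
  expect_equal(p2$background, 190)
  expect_equal(p2$nucleus_level, 110)
})

test_that("generated datasets round-trip to disk", {
  dir <- withr::local_tempdir()
  s <- synth_generate(synth_params(n_total = 10L, n_proliferating = 2L,
                                   seed = 17, vein = "connected"))
  write_synth(s, dir)
  stem <- s$roi$stem
  roi <- read_roi(file.path(dir, paste0(stem, ".png")))
  expect_equal(roi$pixels, s$roi$pixels, tolerance = 1e-12)
  expect_identical(read_mask(file.path(dir, paste0(stem, "-vein.png"))),
                   s$vein_mask)
  gt <- read_ground_truth(file.path(dir, paste0(stem, "-gt.csv")))
  expect_equal(gt$class, s$ground_truth$class)
  expect_equal(gt$x, s$ground_truth$x, tolerance = 1e-6)
  expect_true(file.exists(file.path(dir, paste0(stem, "-manifest.yaml"))))
})
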