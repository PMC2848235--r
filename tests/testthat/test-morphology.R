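test_that("erosion and dilation bracket the mask and validate radius", {
  m <- fix_disc(40, 40, 20, 20, 10)
  e <- erode_mask(m, 2); d <- dilate_mask(m, 2)
  expect_true(all(!e | m))   # e subset m
  expect_true(all(!m | d))   # m subset d
  expect_error(erode_mask(m, 0), "radius")
  expect_error(dilate_mask(m, 0.5), "radius")
  empty <- matrix(FALSE, 10, 10)
  expect_identical(erode_mask(empty, 2), empty)
})

test_that("erosion severs a one-pixel bridge between two discs", {
  m <- fix_discs(60, 110, rbind(c(30, 25), c(30, 75)), c(20, 20))
  m[31, 45:56] <- TRUE  # 1-px bridge
  expect_equal(nrow(label_components(m)$table), 1L)
  e <- erode_mask(m, 2)
  expect_equal(nrow(label_components(e)$table), 2L)
})

test_that("erode-then-dilate approximately restores a disc", {
  m <- fix_disc(40, 40, 20, 20, 10)
  back <- dilate_mask(erode_mask(m, 2), 2)
  expect_lt(abs(sum(back) - sum(m)) / sum(m), 0.05)
})

test_that("fill_holes makes regions simply connected", {
  ann <- fix_annulus(31, 31, 15, 15, 4, 10)
  filled <- fill_holes(ann)
  expect_identical(filled, fix_disc(31, 31, 15, 15, 10))

  solid <- fix_disc(21, 21, 10, 10, 7)
  expect_identical(fill_holes(solid), solid)

  ring <- fix_annulus(101, 101, 50, 50, 20, 45)
  holes <- fix_discs(101, 101,
                     rbind(c(50, 40), c(40, 55), c(60, 55), c(50, 62), c(45, 47)),
                     rep(3, 5))
  vein <- ring & !holes  # holes inside the ring wall
  out <- fill_holes(vein)
  expect_identical(out, fix_disc(101, 101, 50, 50, 45))
})

test_that("labeling is 8-connected and conserves area", {
  two <- fix_discs(40, 80, rbind(c(20, 20), c(20, 60)), c(8, 8))
  expect_equal(nrow(label_components(two)$table), 2L)

  diag2 <- matrix(FALSE, 5, 5); diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_equal(nrow(label_components(diag2)$table), 1L)

  set.seed(41)
  rnd <- matrix(runif(900) > 0.6, 30, 30)
  tab <- label_components(rnd)$table
  expect_equal(sum(tab$area), sum(rnd))

  expect_equal(nrow(label_components(matrix(FALSE, 5, 5))$table), 0L)
})

test_that("labeling agrees with a flood-fill oracle on random small masks", {
  set.seed(43)
  for (k in 1:5) {
    m <- matrix(runif(64 * 64) > 0.55, 64, 64)
    mine <- label_components(m)$labels
    ref <- oracle_label8(m)
    # same partition: label images must be a relabeling of each other
    expect_equal(max(mine), max(ref))
    expect_true(all((mine > 0) == (ref > 0)))
    pairs <- unique(cbind(mine[mine > 0], ref[ref > 0]))
    expect_equal(nrow(pairs), max(mine))
  }
})

test_that("boundary-trace perimeter follows the stated conventions", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  expect_equal(label_components(sq)$table$perimeter, 36)

  ln <- matrix(FALSE, 5, 9); ln[3, 3:7] <- TRUE
  expect_equal(label_components(ln)$table$perimeter, 8)

  px1 <- matrix(FALSE, 3, 3); px1[2, 2] <- TRUE
  expect_equal(label_components(px1)$table$perimeter, 4)

  disc <- fix_disc(51, 51, 25, 25, 20)
  per <- label_components(disc)$table$perimeter
  expect_lt(abs(per - 2 * pi * 20) / (2 * pi * 20), 0.05)
})

test_that("shape metrics implement the equivalent diameter and form factor", {
  m <- fix_disc(120, 120, 60, 60, 50)
  ct <- shape_metrics(label_components(m))
  expect_equal(ct$table$d_eq, sqrt(4 * ct$table$area / pi), tolerance = 1e-9)
  expect_lt(abs(ct$table$d_eq - 100) / 100, 0.02)
  expect_gt(ct$table$form_factor, 0.9)  # near 1 for a circle

  # square of side s: P = 4(s-1), so F = (pi/4) * (s/(s-1))^2 exactly,
  # converging to the continuous closed form pi/4 as s grows
  sq <- matrix(FALSE, 30, 30); sq[6:25, 6:25] <- TRUE
  fs <- shape_metrics(label_components(sq))$table$form_factor
  expect_equal(fs, (pi / 4) * (20 / 19)^2, tolerance = 1e-9)
  big <- matrix(FALSE, 110, 110); big[6:105, 6:105] <- TRUE
  fb <- shape_metrics(label_components(big))$table$form_factor
  expect_lt(abs(fb - pi / 4), 0.02)

  expect_equal(sqrt(4 * 700 / pi), 29.85, tolerance = 1e-2)
})

test_that("component filtering applies the configured criteria with reasons", {
  sp <- shape_filter_params()
  disc <- fix_disc(80, 80, 40, 40, 25)   # area ~1963
  f <- filter_components(shape_metrics(label_components(disc)), sp)
  expect_true(all(f$table$accepted))

  small <- fix_disc(60, 60, 30, 30, 12)  # area ~452 < 700
  fs <- filter_components(shape_metrics(label_components(small)), sp)
  expect_false(fs$table$accepted)
  expect_match(fs$table$reason, "area")

  bar <- matrix(FALSE, 20, 220); bar[8:12, 11:210] <- TRUE  # 5 x 200
  fb <- filter_components(shape_metrics(label_components(bar)), sp,
                          criteria = "form_factor")
  expect_false(fb$table$accepted)
  expect_match(fb$table$reason, "form_factor")
})

test_that("filtering is monotone in its parameters", {
  set.seed(47)
  m <- fix_discs(200, 200,
                 cbind(runif(6, 30, 170), runif(6, 30, 170)),
                 runif(6, 10, 28))
  ct <- shape_metrics(label_components(m))
  base <- filter_components(ct, shape_filter_params(c(300, 9000), c(10, 300), 0.1))
  tighter_area <- filter_components(ct, shape_filter_params(c(800, 3000), c(10, 300), 0.1))
  higher_ff <- filter_components(ct, shape_filter_params(c(300, 9000), c(10, 300), 0.8))
  expect_true(all(tighter_area$table$accepted <= base$table$accepted))
  expect_true(all(higher_ff$table$accepted <= base$table$accepted))
})
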