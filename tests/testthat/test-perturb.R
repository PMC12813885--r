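test_that("dilation matches the brute-force structuring-element oracle", {
  m <- square_mask(10, 10, 4:7, 4:7)          # centered 4x4 square
  out <- mask_dilate_erode(m, "dilate", "both", 2)
  expect_equal(sum(m), 16)
  expect_equal(sum(out), 64)                  # 4x4 -> 8x8
  expect_equal(out, oracle_morph(m, matrix(1, 5, 5), "dilate"))
  # x-only and y-only agree with the rectangular-kernel oracle too
  expect_equal(mask_dilate_erode(m, "dilate", "x"),
               oracle_morph(m, matrix(1, 1, 5), "dilate"))
  expect_equal(mask_dilate_erode(m, "erode", "y", 1),
               oracle_morph(m, matrix(1, 3, 1), "erode"))
})

test_that("erosion that would empty the mask is a degenerate perturbation", {
  m <- square_mask(10, 10, 4:7, 4:7)          # 4 px wide < 2*2+1 kernel
  expect_error(mask_dilate_erode(m, "erode", "x", 2),
               class = "contourqa_degenerate")
})

test_that("dilation/erosion set relations and axis confinement hold", {
  for (s in 1:40) {
    m <- random_mask(s)
    d <- mask_dilate_erode(m, "dilate", sample(c("x", "y", "both"), 1))
    expect_true(all(d >= m))                  # superset
    expect_gt(sum(d), sum(m))                 # strictly grows
    e <- tryCatch(mask_dilate_erode(m, "erode", sample(c("x", "y", "both"), 1)),
                  contourqa_degenerate = function(cond) NULL)
    if (!is.null(e)) {
      expect_true(all(e <= m))                # subset
      expect_lt(sum(e), sum(m))               # strictly shrinks
    }
  }
  # x-only dilation cannot create new occupied rows
  m <- disc_mask(20, 5)
  dx <- mask_dilate_erode(m, "dilate", "x")
  expect_identical(which(rowSums(dx) > 0), which(rowSums(m) > 0))
  dy <- mask_dilate_erode(m, "dilate", "y")
  expect_identical(which(colSums(dy) > 0), which(colSums(m) > 0))
})

test_that("shift is an exact translation and clips at the frame", {
  m <- square_mask(10, 10, 4:7, 4:7)
  out <- mask_shift(m, 1, 0)
  expect_equal(out, square_mask(10, 10, 4:7, 5:8))
  expect_equal(sum(out), sum(m))
  expect_error(mask_shift(m, 0, 0), "both be zero")
  # flush against the right border: shifting by 2 clips 2 columns of pixels
  flush <- square_mask(10, 10, 4:7, 7:10)
  clipped <- mask_shift(flush, 2, 0)
  expect_equal(sum(flush) - sum(clipped), 2 * 4)
  expect_equal(clipped, oracle_shift(flush, 2, 0))
  # interior masks: area preserved and equal to the oracle, all 24 offsets
  m2 <- disc_mask(20, 4)
  for (dx in -2:2) for (dy in -2:2) {
    if (dx == 0 && dy == 0) next
    got <- mask_shift(m2, dx, dy)
    expect_equal(got, oracle_shift(m2, dx, dy))
    expect_equal(sum(got), sum(m2))
  }
})

test_that("boundary noise with zero offsets reproduces the mask", {
  m <- square_mask(12, 12, 4:9, 3:8)
  out <- mask_boundary_noise(m, matrix(0L, 4, 2), vertex_idx = c(1, 5, 9, 13))
  expect_equal(out, m)
})

test_that("a displaced vertex bulges the polygon as the fill oracle predicts", {
  m <- square_mask(12, 12, 4:9, 4:9)
  bd <- contourqa:::trace_boundary(m)
  # displace the first traced vertex by (dx, dy) = (2, 2)
  out <- mask_boundary_noise(m, matrix(c(2L, 2L), 1), vertex_idx = 1)
  expect_gt(sum(out != m), 0)
  # oracle: ray-cast fill of the displaced vertex list + its edges
  verts <- bd
  verts[1, ] <- verts[1, ] + c(2, 2)          # (row, col) += (dy, dx)
  inside <- matrix(0L, 12, 12)
  for (y in 0:11) for (x in 0:11)
    if (oracle_point_in_polygon(y, x, verts[, 1], verts[, 2]))
      inside[y + 1, x + 1] <- 1L
  # every oracle-interior pixel must be foreground in the package fill
  expect_true(all(out[inside == 1] == 1))
  # and the perturbed region stays within 2 px of the original square
  grown <- oracle_morph(m, matrix(1, 5, 5), "dilate")
  expect_true(all(out <= grown))
})

test_that("boundary-noise offsets beyond the +-2 px bound are rejected", {
  m <- square_mask(12, 12, 4:9, 4:9)
  expect_error(mask_boundary_noise(m, matrix(c(3L, 0L), 1), vertex_idx = 1),
               "\\[-2, 2\\]")
  expect_error(mask_boundary_noise(m, matrix(0L, 16, 2)), "15")
})

test_that("the perturbation sampler respects all family bounds", {
  m <- disc_mask(28, 8)
  fams <- character(400)
  for (s in seq_len(400)) {
    res <- sample_perturbation(m, seed = s)
    fams[s] <- res$spec$family
    expect_true(all(res$mask %in% c(0L, 1L)))
    expect_equal(dim(res$mask), dim(m))
    expect_gt(sum(res$mask != m), 0)          # meaningful perturbation
    sp <- res$spec
    if (sp$family == "shift") {
      expect_true(abs(sp$dx) <= 2 && abs(sp$dy) <= 2)
      expect_false(sp$dx == 0 && sp$dy == 0)
    } else if (sp$family == "boundary_noise") {
      expect_true(sp$n_points >= 1 && sp$n_points <= 15)
      expect_true(all(abs(sp$offsets) <= 2))
    } else {
      expect_equal(sp$magnitude, 2)
      expect_true(sp$axis_mode %in% c("x", "y", "both"))
    }
  }
  expect_setequal(unique(fams), c("dilate", "erode", "shift", "boundary_noise"))
})

test_that("the sampler is deterministic and resamples degenerate draws", {
  m <- disc_mask(28, 8)
  r1 <- sample_perturbation(m, seed = 99)
  r2 <- sample_perturbation(m, seed = 99)
  expect_identical(r1, r2)
  # a 2-px-thick mask can only be eroded along its long axis; the sampler
  # must discover that through degenerate-retry
  thin <- square_mask(12, 12, 5:6, 3:10)
  res <- sample_perturbation(thin, seed = 1, family = "erode")
  expect_equal(res$spec$family, "erode")
  expect_equal(res$spec$axis_mode, "x")
  expect_lt(sum(res$mask), sum(thin))
  # a mask that admits no erosion at all exhausts the retry budget
  tiny <- square_mask(8, 8, 4:5, 4:5)
  expect_error(sample_perturbation(tiny, seed = 1, family = "erode"),
               "no non-degenerate")
})
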