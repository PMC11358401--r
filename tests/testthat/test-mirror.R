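# single-voxel mask whose voxel center sits at a chosen world x
point_mask <- function(x_mm) {
  as_mask(array(1L, dim = c(1, 1, 1)), make_affine(rep(1, 3), c(x_mm, 0, 0)))
}

box_mask <- function(x_range_mm, sp = 0.3, ny = 20, nz = 20) {
  nx <- round(diff(x_range_mm) / sp) + 1
  as_mask(array(1L, dim = c(nx, ny, nz)),
          make_affine(rep(sp, 3),
                      c(x_range_mm[1], -(ny - 1) * sp / 2,
                        -(nz - 1) * sp / 2)))
}

test_that("the mirror cost evaluates the crossing penalty and proximity reward", {
  id <- rigid_transform()
  # voxel at x = +2, alpha 0.5: cost = 2 - 0.5*2 = 1
  expect_equal(mirror_cost(point_mask(2), id, alpha = 0.5), 1.0)
  # voxel at x = -3, alpha 0.5: cost = 0 - 0.5*(-3) = 1.5
  expect_equal(mirror_cost(point_mask(-3), id, alpha = 0.5), 1.5)
  # mask fully at x < 0: first term vanishes; cost -> 0 as alpha -> 0
  m <- box_mask(c(-8, -2))
  P <- hemilabel:::mask_world_coords(m, Inf)
  for (a in c(0.3, 1e-3, 1e-6)) {
    expect_equal(mirror_cost(m, id, alpha = a), -a * sum(P[, 1]))
  }
  expect_lt(mirror_cost(m, id, alpha = 1e-9), 1e-3)
})

test_that("crossing the mirror always raises the cost for alpha < 1", {
  for (a in c(0.05, 0.3, 0.7, 0.95)) {
    at_zero <- mirror_cost(point_mask(0), rigid_transform(), alpha = a)
    for (eps in c(0.01, 0.5, 2)) {
      crossed <- mirror_cost(point_mask(eps), rigid_transform(), alpha = a)
      expect_gt(crossed, at_zero)
      expect_equal(crossed - at_zero, (1 - a) * eps, tolerance = 1e-12)
    }
  }
})

test_that("an already-flush hemisphere yields a near-identity transform", {
  m <- box_mask(c(-6, 0))
  t <- optimize_mirror_transform(m, mirror_config())
  expect_lt(max(abs(t$rotation)), 0.1)
  expect_lt(sqrt(sum(t$translation^2)), 0.1)
  expect_lte(attr(t, "cost"), attr(t, "initial_cost"))
})

test_that("the optimal shift matches a dense 1-D grid-search oracle", {
  m <- box_mask(c(-10, -4))
  t <- optimize_mirror_transform(m, mirror_config())
  oracle <- bf_mirror_shift(m, attr(t, "alpha"))
  expect_equal(t$translation[1], 4, tolerance = 0.05)
  expect_equal(t$translation[1], oracle, tolerance = 0.05)
})

test_that("a hemisphere crossing the mirror is pushed back within tolerance", {
  m <- box_mask(c(-8, 3))
  cfg <- mirror_config()
  t <- optimize_mirror_transform(m, cfg)
  P <- hemilabel:::mask_world_coords(m, cfg$max_subsample)
  x <- transform_points(t, P)[, 1]
  expect_equal(sum(x > cfg$crossing_tolerance_mm), 0)
  expect_gt(max(x), -2)
})

test_that("reflection across the midplane is an exact involution", {
  ph <- small_phantom(seed = 51, shape = 40)
  lm <- ph$labels
  r <- reflect_across_midplane(lm)
  expect_equal(reflect_across_midplane(r), lm)
  expect_identical(table(r$data), table(lm$data))
  wx <- function(v) {
    ijk <- which(v$data > 0, arr.ind = TRUE) - 1
    range(hemilabel:::voxels_to_world(v$affine, ijk)[, 1])
  }
  expect_equal(wx(r), rev(-wx(lm)))
})

test_that("composition doubles the subregions with non-overlapping hemispheres", {
  ph <- small_phantom(seed = 52, shape = 48, noise_sigma = 0)
  v <- ph$volume
  mask <- as_mask(v$data > 0, v$affine)
  ctx <- cluster_intensities(v, mask, k = 4, seed = 3)
  merged <- merge_labels(ph$labels, ctx)
  cfg <- mirror_config()
  t <- optimize_mirror_transform(mask, cfg)
  fb <- compose_full_brain(merged, t, cfg)
  sub <- fb$data[fb$data >= 1L & fb$data <= 10L]
  expect_setequal(unique(sub), 1:10)
  expect_equal(attr(fb, "overlap_voxels"), 0)
  # subregion volume is doubled up to resampling error
  n_single <- sum(merged$data %in% 1:5)
  expect_lt(abs(sum(fb$data %in% 1:10) - 2 * n_single) / (2 * n_single),
            0.02)
  # mirrored context voxels keep their context ids
  expect_setequal(unique(as.vector(fb$data[fb$data > 10L])),
                  unique(as.vector(merged$data[merged$data > 10L])))
})

test_that("the composed map is mirror-symmetric after swapping hemisphere ids", {
  ph <- small_phantom(seed = 53, shape = 40, noise_sigma = 0)
  mask <- as_mask(ph$volume$data > 0, ph$volume$affine)
  merged <- ph$labels  # subregions only: symmetry must hold exactly
  t <- optimize_mirror_transform(mask, mirror_config())
  fb <- compose_full_brain(merged, t, mirror_config())
  flipped <- reflect_across_midplane(fb)
  swap <- flipped$data
  orig <- flipped$data >= 1L & flipped$data <= 5L
  mirr <- flipped$data >= 6L & flipped$data <= 10L
  swap[orig] <- flipped$data[orig] + 5L
  swap[mirr] <- flipped$data[mirr] - 5L
  expect_identical(swap, fb$data)
})

test_that("optimization is deterministic and reports failures to converge", {
  m <- box_mask(c(-9, -3))
  t1 <- optimize_mirror_transform(m, mirror_config())
  t2 <- optimize_mirror_transform(m, mirror_config())
  expect_identical(t1, t2)
  # even an aggressive alpha cannot push the hemisphere across the mirror:
  # candidates are projected back onto the non-crossing half-space
  ta <- optimize_mirror_transform(m, mirror_config(alpha = 0.9))
  x <- transform_points(ta, hemilabel:::mask_world_coords(m, Inf))[, 1]
  expect_lte(max(x), 1e-9)
})

test_that("powell coordinate descent agrees with the simplex optimizer", {
  m <- box_mask(c(-7, -2.5))
  tn <- optimize_mirror_transform(m, mirror_config())
  tp <- optimize_mirror_transform(m, mirror_config(optimizer = "powell"))
  expect_equal(tp$translation[1], tn$translation[1], tolerance = 0.05)
})
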