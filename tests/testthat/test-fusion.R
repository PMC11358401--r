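make_context_block <- function(dm = c(12, 12, 12), id = 103L,
                               affine = make_affine(rep(0.3, 3), c(0, 0, 0))) {
  ctx <- array(0L, dim = dm)
  ctx[2:11, 2:11, 2:11] <- id
  as_labelmap(ctx, affine)
}

test_that("merging respects manual precedence and the identity case", {
  ctx <- make_context_block()
  empty <- as_labelmap(array(0L, dim = dim(ctx$data)), ctx$affine)
  out <- merge_labels(empty, ctx)
  expect_identical(out$data, ctx$data)

  md <- array(0L, dim = dim(ctx$data))
  md[5:7, 5:7, 5:7] <- 2L
  manual <- as_labelmap(md, ctx$affine)
  merged <- merge_labels(manual, ctx)
  expect_true(all(merged$data[5:7, 5:7, 5:7] == 2L))
  # manual lies inside the context support: labeled voxel count unchanged
  expect_equal(sum(merged$data > 0), sum(ctx$data > 0))
  # no ids invented
  expect_setequal(unique(as.vector(merged$data)), c(0L, 2L, 103L))
})

test_that("merging rejects grid mismatches and id collisions", {
  ctx <- make_context_block()
  other <- make_context_block(affine = make_affine(rep(0.31, 3), c(0, 0, 0)))
  manual <- as_labelmap(array(0L, dim = dim(ctx$data)), ctx$affine)
  expect_error(merge_labels(manual, other), "grid")
  bad_manual <- manual
  bad_manual$data[2, 2, 2] <- 7L
  expect_error(merge_labels(bad_manual, ctx), "1..5")
  bad_ctx <- as_labelmap(array(3L, dim = dim(ctx$data)), ctx$affine)
  expect_error(merge_labels(manual, bad_ctx), "collide")
})

test_that("closing uses a 4-voxel ball at 0.3 mm spacing (1.2 mm / 0.3 mm)", {
  # two full-cross-section slabs: along the slab normal the closing acts
  # one-dimensionally, so a gap of 2r-1 = 7 voxels is bridged and a gap of
  # 2r+1 = 9 voxels is not — pinning the effective radius to 4 voxels
  aff <- make_affine(rep(0.3, 3), c(0, 0, 0))
  near <- array(0L, dim = c(16, 7, 7))
  near[2:4, , ] <- 1L
  near[12:14, , ] <- 2L         # gap of 7 voxels (5..11)
  out <- refine_with_closing(as_labelmap(near, aff))
  expect_true(all(out$data[5:11, , ] > 0))
  far <- array(0L, dim = c(18, 7, 7))
  far[2:3, , ] <- 1L
  far[13:14, , ] <- 2L          # gap of 9 voxels (4..12)
  out2 <- refine_with_closing(as_labelmap(far, aff))
  expect_true(all(out2$data[6:10, , ] == 0L))
})

test_that("an interior hole is filled with the surrounding subregion id", {
  aff <- make_affine(rep(0.3, 3), c(0, 0, 0))
  a <- array(0L, dim = c(9, 9, 9))
  a[3:7, 3:7, 3:7] <- 3L
  a[5, 5, 5] <- 0L
  out <- refine_with_closing(as_labelmap(a, aff))
  expect_equal(out$data[5, 5, 5], 3L)
  # nothing outside the closing region changes
  expect_identical(out$data[a == 3L], a[a == 3L])
})

test_that("closing is idempotent and extensive on the hypothalamus mask", {
  set.seed(41)
  aff <- make_affine(rep(0.3, 3), c(0, 0, 0))
  a <- array(0L, dim = c(14, 14, 14))
  a[sample(length(a), 180)] <- sample(1:5, 180, TRUE)
  lm <- as_labelmap(a, aff)
  once <- refine_with_closing(lm)
  twice <- refine_with_closing(once)
  expect_identical(twice$data, once$data)
  expect_true(all(once$data[lm$data > 0] == lm$data[lm$data > 0]))
})

test_that("closing matches the brute-force dilate-then-erode oracle on 16-cube instances", {
  set.seed(42)
  aff <- make_affine(rep(0.3, 3), c(0, 0, 0))
  for (trial in 1:4) {
    a <- array(0L, dim = c(16, 16, 16))
    n_seed <- sample(3:6, 1)
    ctr <- cbind(sample(4:13, n_seed, TRUE), sample(4:13, n_seed, TRUE),
                 sample(4:13, n_seed, TRUE))
    for (s in seq_len(n_seed)) {
      ii <- pmax(1, ctr[s, 1] - 1):pmin(16, ctr[s, 1] + 1)
      a[ii, ctr[s, 2], ctr[s, 3]] <- 2L
      a[ctr[s, 1], ctr[s, 2], pmax(1, ctr[s, 3] - 1)] <- 2L
    }
    lm <- as_labelmap(a, aff)
    out <- refine_with_closing(lm, fusion_config(closing_radius_mm = 0.6))
    oracle <- bf_ball_close(a > 0L, r_vox = 2)
    expect_identical(out$data > 0L, oracle)
  }
})

test_that("closed-in voxels take the nearest subregion id, ties to the lowest", {
  aff <- make_affine(rep(0.3, 3), c(0, 0, 0))
  a <- array(0L, dim = c(11, 9, 9))
  a[3:4, 4:6, 4:6] <- 2L
  a[8:9, 4:6, 4:6] <- 1L
  out <- refine_with_closing(as_labelmap(a, aff))
  # the gap (columns 5..7) is closed; its center column 6 is equidistant
  expect_true(all(out$data[5:7, 5, 5] > 0L))
  expect_equal(out$data[6, 5, 5], 1L)      # tie -> lowest id
  expect_equal(out$data[5, 5, 5], 2L)      # nearer to the id-2 block
  expect_equal(out$data[7, 5, 5], 1L)
})

test_that("a sub-voxel closing radius warns and degrades to one voxel", {
  aff <- make_affine(rep(1.5, 3), c(0, 0, 0))
  a <- array(0L, dim = c(8, 8, 8))
  a[3:5, 3:5, 3:5] <- 4L
  expect_warning(refine_with_closing(as_labelmap(a, aff),
                                     fusion_config(closing_radius_mm = 0.5)),
                 "one voxel")
})
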