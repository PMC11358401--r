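identity_cfg <- function(...) {
  synth_config(rotation_range = 0, scale_range = c(1, 1), shear_range = 0,
               translation_range = 0, elastic_scale_mm = 0, ...)
}

test_that("augmentation with zero-width ranges is the identity", {
  lm <- small_phantom(seed = 61, shape = 40)$labels
  out <- augment_labels(lm, identity_cfg(), seed = 5)
  expect_identical(out$data, lm$data)
})

test_that("augmented label ids are a subset of the input ids", {
  lm <- small_phantom(seed = 62, shape = 40)$labels
  for (s in 1:3) {
    out <- augment_labels(lm, synth_config(), seed = s)
    expect_true(all(unique(as.vector(out$data)) %in%
                    unique(as.vector(lm$data))))
  }
})

test_that("the drawn affine moves the structure centroid as the closed form predicts", {
  lm <- small_phantom(seed = 63, shape = 48)$labels
  cfg <- synth_config(rotation_range = 10, scale_range = c(1, 1),
                      shear_range = 0, translation_range = 2,
                      elastic_scale_mm = 0)
  out <- augment_labels(lm, cfg, seed = 9)
  fwd <- attr(out, "deformation")$forward
  centroid <- function(x) {
    m <- x$data %in% 1:5
    dim(m) <- dim(x$data)
    ijk <- which(m, arr.ind = TRUE) - 1
    colMeans(hemilabel:::voxels_to_world(x$affine, ijk))
  }
  expected <- drop(fwd$matrix[1:3, 1:3] %*% centroid(lm) + fwd$matrix[1:3, 4])
  # agreement within one voxel (0.3 mm)
  expect_lt(sqrt(sum((centroid(out) - expected)^2)), 0.3)
})

test_that("augmentation is reproducible for a fixed seed", {
  lm <- small_phantom(seed = 64, shape = 40)$labels
  a <- augment_labels(lm, synth_config(), seed = 3)
  b <- augment_labels(lm, synth_config(), seed = 3)
  expect_identical(a$data, b$data)
})

test_that("collapsed variance yields one intensity per label", {
  lm <- small_phantom(seed = 65, shape = 32)$labels
  cfg <- synth_config(std_range = c(1e-6, 2e-6))
  img <- sample_gmm_image(lm, cfg, seed = 2)
  spread <- tapply(as.vector(img$data), as.vector(lm$data), stats::sd)
  expect_true(all(spread < 1e-6))
})

test_that("per-label sample means track the drawn Gaussian parameters", {
  lm <- small_phantom(seed = 66, shape = 48)$labels
  img <- sample_gmm_image(lm, synth_config(), seed = 7)
  par <- attr(img, "gmm_params")
  rng <- attr(img, "intensity_range")
  raw <- img$data * diff(rng) + rng[1]   # undo min-max normalisation
  for (r in seq_len(nrow(par))) {
    vox <- raw[lm$data == par$label[r]]
    n <- length(vox)
    if (n < 1e4) next
    expect_lt(abs(mean(vox) - par$mu[r]), 4 * par$sd[r] / sqrt(n))
  }
})

test_that("labels with identical drawn parameters are statistically indistinguishable", {
  lm <- small_phantom(seed = 67, shape = 40)$labels
  cfg <- synth_config(mean_range = c(100, 100), std_range = c(10, 10))
  img <- sample_gmm_image(lm, cfg, seed = 4)
  rng <- attr(img, "intensity_range")
  raw <- img$data * diff(rng) + rng[1]
  mus <- tapply(as.vector(raw), as.vector(lm$data), mean)
  ns <- table(as.vector(lm$data))
  big <- ns >= 1e4
  expect_true(all(abs(mus[big] - 100) < 4 * 10 / sqrt(ns[big])))
})

test_that("within-label intensities look Gaussian", {
  lm <- small_phantom(seed = 68, shape = 40)$labels
  img <- sample_gmm_image(lm, synth_config(), seed = 11)
  vox <- img$data[lm$data == 0L]
  expect_gt(stats::shapiro.test(vox[seq(1, length(vox),
                                        length.out = 3000)])$p.value, 1e-3)
})

test_that("contrast is randomised across seeds: label mean ordering varies", {
  lm <- small_phantom(seed = 69, shape = 32)$labels
  orders <- vapply(1:20, function(s) {
    img <- sample_gmm_image(lm, synth_config(), seed = s)
    mus <- tapply(as.vector(img$data), as.vector(lm$data), mean)
    paste(order(mus), collapse = "-")
  }, character(1))
  expect_gt(length(unique(orders)), 1)
})

test_that("resolution simulation is the identity at the native spacing", {
  ph <- small_phantom(seed = 70, shape = 32)
  out <- simulate_resolution(ph$volume, 0.3)
  expect_identical(out$data, ph$volume$data)
})

test_that("resolution simulation only removes variance", {
  ph <- small_phantom(seed = 71, shape = 40, noise_sigma = 4)
  for (th in list(1, c(0.3, 0.3, 5), c(2, 1, 0.5))) {
    out <- simulate_resolution(ph$volume, th)
    expect_lte(stats::var(as.vector(out$data)),
               stats::var(as.vector(ph$volume$data)))
  }
  expect_error(simulate_resolution(ph$volume, 0.1), "below the native")
})

test_that("training pairs share one deformation and collapse context ids", {
  ph <- small_phantom(seed = 72, shape = 48, noise_sigma = 0)
  mask <- as_mask(ph$volume$data > 0, ph$volume$affine)
  ctx <- cluster_intensities(ph$volume, mask, k = 4, seed = 1)
  merged <- merge_labels(ph$labels, ctx)
  t <- optimize_mirror_transform(mask, mirror_config())
  fb <- compose_full_brain(merged, t, mirror_config())

  cfg <- identity_cfg(std_range = c(1e-6, 2e-6),
                      thickness_range = c(0.3, 0.3))
  pair <- generate_training_pair(fb, cfg, seed = 31)
  expect_true(all(unique(as.vector(pair$target$data)) %in% 0:10))
  # voxelwise alignment: with near-zero variance every subregion voxel in
  # the image carries (normalised) mu of its label in the target
  par <- attr(pair$image, "gmm_params")
  rng <- attr(pair$image, "intensity_range")
  raw <- pair$image$data * diff(rng) + rng[1]
  for (id in 1:10) {
    vox <- raw[pair$target$data == id]
    expect_lt(max(abs(vox - par$mu[par$label == id])), 1e-3)
  }

  p1 <- generate_training_pair(fb, synth_config(), seed = 8)
  p2 <- generate_training_pair(fb, synth_config(), seed = 8)
  expect_identical(p1$image$data, p2$image$data)
  expect_identical(p1$target$data, p2$target$data)
})

test_that("a label map without all 10 subregions warns", {
  lm <- small_phantom(seed = 73, shape = 32)$labels  # only ids 0..5
  expect_warning(generate_training_pair(lm, identity_cfg(
    thickness_range = c(0.3, 0.3)), seed = 2), "missing")
})
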