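#' Phantom specification
#'
#' Parameters of the deterministic hemisphere phantom: a half-ellipsoid
#' "hemisphere" with concentric constant-intensity shells (plus noise and
#' an optional multiplicative bias ramp) and a 5-label medial block playing
#' the role of the manually segmented hypothalamus subregions (anterior
#' superior/inferior, tuberal superior/inferior, posterior). Phantoms are
#' geometric, not anatomically realistic: every pipeline stage needs known
#' ground truth, not realism.
#'
#' @param shape voxel dimensions (default 96^3; minimum 32 per axis).
#' @param spacing_mm isotropic voxel size (default 0.3).
#' @param n_shells number of intensity shells, 4..9 (default 4).
#' @param hemisphere_side `"left"` (anatomy at x < 0) or `"right"`.
#' @param subregion_extent_mm mm box (x, y, z) of the 5-label block
#'   abutting the medial face (default `c(4.2, 6, 6)`).
#' @param noise_sigma additive Gaussian intensity noise (default 2).
#' @param bias_gradient multiplicative field range across the
#'   field of view, e.g. `c(0.7, 1.3)`; the default `c(1, 1)` disables it.
#' @param medial_gap_mm distance between the flat medial face and the
#'   mirror plane x = 0 (default 2).
#' @param seed RNG seed; identical seeds give bitwise-identical phantoms.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(96, 96, 96), spacing_mm = 0.3,
                         n_shells = 4, hemisphere_side = c("left", "right"),
                         subregion_extent_mm = c(4.2, 6, 6),
                         noise_sigma = 2, bias_gradient = c(1, 1),
                         medial_gap_mm = 2, seed = 1) {
  hemisphere_side <- match.arg(hemisphere_side)
  shape <- rep_len(as.integer(shape), 3)
  stopifnot(all(shape >= 32), n_shells >= 4, n_shells <= 9,
            spacing_mm > 0, medial_gap_mm >= 0, noise_sigma >= 0)
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 n_shells = as.integer(n_shells),
                 hemisphere_side = hemisphere_side,
                 subregion_extent_mm = rep_len(subregion_extent_mm, 3),
                 noise_sigma = noise_sigma, bias_gradient = bias_gradient,
                 medial_gap_mm = medial_gap_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one hemisphere phantom
#'
#' Builds the intensity volume and its 5-subregion label map. For a left
#' phantom all tissue sits at world x < 0 with the flat medial face
#' `medial_gap_mm` from the mirror plane; the subregion block abuts that
#' face, with anterior/tuberal/posterior thirds along y and the
#' superior/inferior split along z. Shell intensities are well separated
#' so k-means with k = n_shells recovers them.
#'
#' @param spec [phantom_spec()].
#' @return list with `volume` (`hemi_volume`) and `labels`
#'   (`hemi_labelmap`, ids 0-5).
#' @export
make_phantom_hemisphere <- function(spec = phantom_spec()) {
  set.seed(spec$seed)
  dm <- spec$shape
  sp <- spec$spacing_mm
  gap <- spec$medial_gap_mm
  affine <- diag(c(sp, sp, sp, 1))
  affine[1:3, 4] <- c(-gap - (dm[1] - 1) * sp,
                      -(dm[2] - 1) * sp / 2, -(dm[3] - 1) * sp / 2)
  x <- affine[1, 4] + (seq_len(dm[1]) - 1) * sp
  y <- affine[2, 4] + (seq_len(dm[2]) - 1) * sp
  z <- affine[3, 4] + (seq_len(dm[3]) - 1) * sp
  a <- 0.85 * (dm[1] - 1) * sp          # depth of the half-ellipsoid
  b <- 0.42 * dm[2] * sp
  cc <- 0.42 * dm[3] * sp
  # normalised ellipsoidal radius about the face center (-gap, 0, 0)
  r2 <- outer(((x + gap) / a)^2, outer((y / b)^2, (z / cc)^2, `+`), `+`)
  inside <- r2 <= 1
  shell <- array(0L, dim = dm)
  shell[inside] <- pmin(spec$n_shells,
                        1L + as.integer(floor(sqrt(r2[inside]) *
                                              spec$n_shells)))
  # air/solution background sits far below tissue: the background-tissue
  # step exceeds any inter-shell step, as in fixed ex vivo acquisitions
  means <- seq(80, 220, length.out = spec$n_shells)
  vol <- array(0, dim = dm)
  vol[inside] <- means[shell[inside]] +
    rnorm(sum(inside), sd = spec$noise_sigma)
  if (any(spec$bias_gradient != 1)) {
    ramp <- seq(spec$bias_gradient[1], spec$bias_gradient[2],
                length.out = dm[2])
    vol <- vol * rep(ramp, each = dm[1])[seq_len(dm[1] * dm[2])] # recycled
    vol <- array(vol, dim = dm)
  }
  vol[vol < 0] <- 0
  # 5-label medial block
  ext <- spec$subregion_extent_mm
  if (ext[1] > a || ext[2] > 2 * b || ext[3] > 2 * cc)
    stop("subregion extent exceeds the hemisphere bounds")
  inx <- x >= -gap - ext[1] & x <= -gap
  iny <- abs(y) <= ext[2] / 2
  inz <- abs(z) <= ext[3] / 2
  lab <- array(0L, dim = dm)
  yb <- y[iny]
  thirds <- quantile(range(yb), c(1 / 3, 2 / 3))
  ycut <- seq(min(yb), max(yb), length.out = 4)
  for (i in which(inx)) for (j in which(iny)) {
    yj <- y[j]
    part <- if (yj >= ycut[3]) "anterior" else if (yj >= ycut[2]) "tuberal"
            else "posterior"
    for (k in which(inz)) {
      id <- switch(part,
                   anterior = if (z[k] >= 0) 1L else 2L,
                   tuberal = if (z[k] >= 0) 3L else 4L,
                   posterior = 5L)
      lab[i, j, k] <- id
    }
  }
  volume <- as_volume(vol, affine)
  labels <- as_labelmap(lab, affine)
  if (spec$hemisphere_side == "right") {
    volume <- left_right_flip(volume)
    labels <- left_right_flip(labels)
  }
  list(volume = volume, labels = labels)
}

#' Generate a phantom cohort
#'
#' `n` phantoms with varied seeds, grid sizes and mirror gaps; by default a
#' 10-member cohort emulating a single-hemisphere ex vivo collection, with
#' 40% of members right-sided (flipped world-x anatomy) so left-right
#' flipping is exercised.
#'
#' @param n cohort size (default 10).
#' @param base_seed seed from which member seeds derive.
#' @param spec template [phantom_spec()]; per-member shape/gap/side vary
#'   around it deterministically.
#' @param right_fraction fraction of right-sided members (default 0.4).
#' @return list of `n` phantom lists (`volume`, `labels`, `side`).
#' @export
make_phantom_cohort <- function(n = 10, base_seed = 1,
                                spec = phantom_spec(),
                                right_fraction = 0.4) {
  stopifnot(n >= 1)
  n_right <- floor(n * right_fraction)
  lapply(seq_len(n), function(i) {
    side <- if (i > n - n_right) "right" else "left"
    shp <- pmax(32L, spec$shape - 8L * ((i - 1L) %% 3L))
    gap <- spec$medial_gap_mm * (0.5 + 0.25 * ((i - 1L) %% 4L))
    s <- spec
    s$shape <- shp
    s$medial_gap_mm <- gap
    s$hemisphere_side <- side
    s$seed <- spec$seed + base_seed * 1000L + i
    ph <- make_phantom_hemisphere(s)
    ph$side <- side
    ph
  })
}
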