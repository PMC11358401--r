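#' Synthesis configuration
#'
#' Hyperparameters of the synthetic-MRI generator: per-label Gaussian
#' intensity models (random mean/variance per label), geometric
#' augmentation (random affine plus smooth elastic displacement), and
#' resolution simulation (anisotropic blur + down/up-sampling emulating
#' thick-slice acquisitions). Ranges follow the public conventions of
#' generative contrast-randomisation training; all are tunable.
#'
#' @param mean_range interval for per-label Gaussian means (default
#'   `c(25, 225)`, arbitrary intensity units).
#' @param std_range interval for per-label standard deviations (default
#'   `c(5, 25)`; lower bound must be positive).
#' @param rotation_range max |rotation| per axis, degrees (default 15).
#' @param scale_range per-axis scale interval (default `c(0.85, 1.15)`).
#' @param shear_range max |shear| coefficient (default 0.012).
#' @param translation_range max |translation| per axis, mm (default 10).
#' @param elastic_scale_mm peak elastic displacement magnitude (default 3).
#' @param elastic_fwhm_mm smoothness of the elastic field (default 20).
#' @param thickness_range simulated slice thickness interval, mm (default
#'   `c(1, 9)`).
#' @param seed base seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(mean_range = c(25, 225), std_range = c(5, 25),
                         rotation_range = 15, scale_range = c(0.85, 1.15),
                         shear_range = 0.012, translation_range = 10,
                         elastic_scale_mm = 3, elastic_fwhm_mm = 20,
                         thickness_range = c(1, 9), seed = 1) {
  stopifnot(mean_range[1] <= mean_range[2],
            std_range[1] > 0, std_range[1] <= std_range[2],
            rotation_range >= 0, scale_range[1] <= scale_range[2],
            shear_range >= 0, translation_range >= 0,
            elastic_scale_mm >= 0, elastic_fwhm_mm > 0,
            thickness_range[1] <= thickness_range[2])
  structure(list(mean_range = mean_range, std_range = std_range,
                 rotation_range = rotation_range, scale_range = scale_range,
                 shear_range = shear_range,
                 translation_range = translation_range,
                 elastic_scale_mm = elastic_scale_mm,
                 elastic_fwhm_mm = elastic_fwhm_mm,
                 thickness_range = thickness_range, seed = as.integer(seed)),
            class = "synth_config")
}

runif1 <- function(lo, hi) runif(1, lo, hi)

# forward affine about the world center of the grid:
# p' = c + R S Sh (p - c) + t
draw_forward_affine <- function(cfg, affine, dm) {
  rot <- runif(3, -cfg$rotation_range, cfg$rotation_range)
  sc <- runif(3, cfg$scale_range[1], cfg$scale_range[2])
  sh <- runif(3, -cfg$shear_range, cfg$shear_range)
  tr <- runif(3, -cfg$translation_range, cfg$translation_range)
  Sh <- diag(3)
  Sh[1, 2] <- sh[1]; Sh[1, 3] <- sh[2]; Sh[2, 3] <- sh[3]
  A <- rotation_matrix(rot) %*% diag(sc) %*% Sh
  ctr <- drop(voxels_to_world(affine, matrix((dm - 1) / 2, 1)))
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- ctr - A %*% ctr + tr
  list(matrix = M, rotation = rot, scale = sc, shear = sh,
       translation = tr)
}

draw_elastic_field <- function(cfg, dm, sp) {
  if (cfg$elastic_scale_mm <= 0) return(NULL)
  sigma_vox <- fwhm_to_sigma(cfg$elastic_fwhm_mm) / sp
  lapply(1:3, function(a) {
    f <- gaussian_smooth3(array(rnorm(prod(dm)), dim = dm), sigma_vox)
    peak <- max(abs(f))
    if (peak > 0) f <- f / peak * cfg$elastic_scale_mm
    f
  })
}

#' Geometric augmentation of a label map
#'
#' Draws a random affine (rotation, anisotropic scale, shear, translation,
#' uniform within the config ranges, about the volume center) composed with
#' a smooth random elastic displacement field, and resamples the labels
#' with nearest-neighbour interpolation. The output id set is always a
#' subset of the input's, and a fixed seed reproduces the output exactly.
#'
#' @param lm `hemi_labelmap`.
#' @param cfg [synth_config()].
#' @param seed RNG seed.
#' @return deformed `hemi_labelmap`, with attribute `deformation` holding
#'   the forward affine and the per-axis backward displacement fields so
#'   the same warp can be re-applied or audited.
#' @export
augment_labels <- function(lm, cfg = synth_config(), seed = cfg$seed) {
  set.seed(seed)
  dm <- dim(lm$data)
  sp <- spacing(lm)
  fwd <- draw_forward_affine(cfg, lm$affine, dm)
  disp <- draw_elastic_field(cfg, dm, sp)
  Minv <- solve(fwd$matrix)
  W <- voxels_to_world(lm$affine, index_grid0(dm))
  src_w <- t(Minv[1:3, 1:3] %*% t(W) + Minv[1:3, 4])
  if (!is.null(disp))
    for (a in 1:3) src_w[, a] <- src_w[, a] + as.vector(disp[[a]])
  src <- world_to_voxels(lm$affine, src_w)
  lab <- interp_nearest(lm$data, src)
  out <- as_labelmap(array(lab, dim = dm), lm$affine,
                     label_table = lm$label_table)
  attr(out, "deformation") <- list(forward = fwd, displacement = disp)
  out
}

#' Sample a synthetic image from a label map
#'
#' For every label id l present (including background 0) draws a mean
#' `mu_l ~ U(mean_range)` and standard deviation `sd_l ~ U(std_range)`;
#' each voxel with label l receives an independent draw from
#' `N(mu_l, sd_l^2)`. The image is then min-max normalised to [0, 1].
#'
#' @param lm `hemi_labelmap`.
#' @param cfg [synth_config()].
#' @param seed RNG seed; fixed seed reproduces the image exactly.
#' @return `hemi_volume` in [0, 1], with attributes `gmm_params` (the drawn
#'   per-label data.frame of `label`, `mu`, `sd`) and `intensity_range`
#'   (the pre-normalisation min/max), exposed for statistical testing.
#' @export
sample_gmm_image <- function(lm, cfg = synth_config(), seed = cfg$seed) {
  set.seed(seed)
  ids <- sort(unique(as.vector(lm$data)))
  mu <- runif(length(ids), cfg$mean_range[1], cfg$mean_range[2])
  sd <- runif(length(ids), cfg$std_range[1], cfg$std_range[2])
  pos <- match(as.vector(lm$data), ids)
  n <- length(pos)
  img <- rnorm(n, mean = mu[pos], sd = sd[pos])
  rng <- range(img)
  norm <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  out <- as_volume(array(norm, dim = dim(lm$data)), lm$affine)
  attr(out, "gmm_params") <- data.frame(label = ids, mu = mu, sd = sd)
  attr(out, "intensity_range") <- rng
  out
}

#' Simulate acquisition at a coarser slice thickness
#'
#' Emulates a thick-slice acquisition: anisotropic Gaussian blur with
#' per-axis sigma `0.85 * thickness / (2 * spacing)` voxels, downsampling
#' to the simulated spacing, and linear resampling back to the native
#' grid. Axes whose requested thickness equals the native spacing are
#' passed through unchanged.
#'
#' @param v `hemi_volume`.
#' @param thickness simulated slice thickness in mm, length 1 or 3; must be
#'   at least the native spacing on each axis.
#' @param seed unused (the operation is deterministic); kept so all
#'   synthesis stages share one signature.
#' @return blurred and resampled `hemi_volume` on the native grid.
#' @export
simulate_resolution <- function(v, thickness, seed = NULL) {
  sp <- spacing(v)
  thickness <- rep_len(thickness, 3)
  if (any(thickness < sp - 1e-9))
    stop("thickness below the native spacing on axis ",
         which(thickness < sp - 1e-9)[1])
  act <- thickness > sp * (1 + 1e-6)
  if (!any(act)) return(v)
  sigma_vox <- ifelse(act, 0.85 * thickness / (2 * sp), 0)
  arr <- gaussian_smooth3(v$data, sigma_vox)
  dm <- dim(arr)
  low_dm <- pmax(2L, as.integer(ceiling(dm * sp / thickness)))
  low_dm[!act] <- dm[!act]
  fac <- dm / low_dm
  low_idx <- index_grid0(low_dm)
  low <- interp_trilinear(arr, sweep(low_idx, 2, fac, `*`))
  low <- array(low, dim = low_dm)
  hi_idx <- index_grid0(dm)
  hi <- interp_trilinear(low, sweep(hi_idx, 2, 1 / fac, `*`))
  out <- as_volume(array(hi, dim = dm), v$affine)
  attributes(out) <- c(attributes(out),
                       attributes(v)[c("gmm_params", "intensity_range")])
  out
}

#' Generate one synthetic training pair
#'
#' The full generative chain for segmenter training: geometric
#' augmentation of the whole-brain label map, per-label Gaussian intensity
#' sampling conditioned on the deformed labels, and resolution simulation
#' with a per-axis thickness drawn from `thickness_range`. The target map
#' shares the deformation with the image exactly (both are derived from the
#' same deformed label map) and keeps only the segmentation targets: ids
#' 0-10, with context ids collapsed to background.
#'
#' @param lm whole-brain `hemi_labelmap` (subregion ids 1-10 expected).
#' @param cfg [synth_config()].
#' @param seed RNG seed; sub-stages use `seed`, `seed + 1`, `seed + 2`.
#' @return list with elements `image` (`hemi_volume`), `target`
#'   (`hemi_labelmap`, ids 0-10) and `thickness` (the drawn mm per axis).
#' @export
generate_training_pair <- function(lm, cfg = synth_config(),
                                   seed = cfg$seed) {
  if (!all(1:10 %in% unique(as.vector(lm$data))))
    warning("label map is missing some subregion ids 1..10")
  deformed <- augment_labels(lm, cfg, seed = seed)
  img <- sample_gmm_image(deformed, cfg, seed = seed + 1L)
  set.seed(seed + 2L)
  sp <- spacing(lm)
  thickness <- pmax(runif(3, cfg$thickness_range[1], cfg$thickness_range[2]),
                    sp)
  img <- simulate_resolution(img, thickness)
  tgt <- deformed$data
  tgt[tgt > 10L] <- 0L
  target <- as_labelmap(tgt, deformed$affine,
                        label_table = default_label_table(tgt))
  attr(target, "deformation") <- attr(deformed, "deformation")
  list(image = img, target = target, thickness = thickness)
}
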