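#' Preprocessing configuration
#'
#' Parameters for background masking and bias-field correction. The mask is
#' an Otsu threshold followed by extraction of the largest 6-connected
#' component, which removes detached bright objects such as the packing bag
#' around an ex vivo specimen. The bias field is estimated as heavy Gaussian
#' smoothing of the log-intensities inside the mask (normalised convolution,
#' so the field extrapolates smoothly outside), applied multiplicatively and
#' normalised to mean 1 inside the mask so global brightness is preserved.
#'
#' @param mask_method `"otsu_largest_component"` or `"provided_mask"` (the
#'   caller supplies a mask to [run_preprocess()]).
#' @param bias_fwhm_mm smoothing scale (FWHM, mm) of the estimated bias
#'   field. The default 60 mm suits whole-hemisphere fields of view; use a
#'   scale around half the field of view for smaller images.
#' @param bias_epsilon positive intensity floor added before taking logs.
#' @param bias_classes number of provisional intensity classes used to
#'   separate tissue contrast from the bias field (default 4).
#' @param bias_iters classification/estimation iterations (default 10).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(mask_method = c("otsu_largest_component",
                                              "provided_mask"),
                              bias_fwhm_mm = 60, bias_epsilon = 1e-3,
                              bias_classes = 4, bias_iters = 10) {
  mask_method <- match.arg(mask_method)
  stopifnot(bias_fwhm_mm > 0, bias_epsilon > 0, bias_classes >= 2,
            bias_iters >= 1)
  structure(list(mask_method = mask_method, bias_fwhm_mm = bias_fwhm_mm,
                 bias_epsilon = bias_epsilon,
                 bias_classes = as.integer(bias_classes),
                 bias_iters = as.integer(bias_iters)),
            class = "preprocess_config")
}

# Fill interior cavities: background components that do not reach the
# image border are dark tissue below threshold, not true background
fill_holes <- function(bw) {
  comp <- label_components(!bw)
  n <- attr(comp, "n_components")
  if (n <= 1) return(bw)
  dm <- dim(bw)
  border <- unique(c(comp[c(1, dm[1]), , ], comp[, c(1, dm[2]), ],
                     comp[, , c(1, dm[3])]))
  holes <- setdiff(seq_len(n), border)
  if (length(holes) > 0) bw[comp %in% holes] <- TRUE
  bw
}

# Deterministic class centers: the k tallest density modes, falling back
# to quantiles when the distribution shows fewer than k modes
class_center_init <- function(x, k) {
  d <- stats::density(x, n = 512)
  loc <- which(diff(sign(diff(d$y))) == -2) + 1
  loc <- loc[order(d$y[loc], decreasing = TRUE)]
  ctr <- sort(d$x[head(loc, k)])
  if (length(ctr) < k)
    ctr <- unname(stats::quantile(x, (seq_len(k) - 0.5) / k))
  ctr[!duplicated(ctr)]
}

# Otsu's threshold on a 256-bin histogram; returns the intensity cut
otsu_threshold <- function(x, nbins = 256) {
  r <- range(x)
  if (diff(r) <= 0) stop("constant-intensity volume: cannot threshold")
  br <- seq(r[1], r[2], length.out = nbins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Segment the background of a hemisphere scan
#'
#' Thresholds the volume (Otsu) and keeps the largest 6-connected
#' above-threshold component, eliminating non-cerebral elements that are
#' detached from the specimen. Interior cavities (tissue darker than the
#' threshold, fully enclosed by the component) are filled, so the mask is
#' a single solid region.
#'
#' @param v `hemi_volume` with non-constant intensities.
#' @param cfg [preprocess_config()].
#' @return binary `hemi_labelmap` (1 = brain, 0 = background).
#' @export
mask_background <- function(v, cfg = preprocess_config()) {
  # threshold in the log domain: MR intensities are multiplicative and the
  # air/tissue separation dwarfs inter-tissue contrast there, so the cut
  # is insensitive to small tissue classes
  x <- as.vector(v$data)
  r <- range(x)
  if (diff(r) <= 0) stop("constant-intensity volume: cannot threshold")
  y <- log(x - r[1] + 1e-3 * diff(r))
  thr <- otsu_threshold(y)
  bw <- array(y > thr, dim = dim(v$data))
  if (!any(bw)) stop("empty mask after thresholding")
  comp <- label_components(bw)
  n <- attr(comp, "n_components")
  if (n > 1) {
    sizes <- tabulate(comp[comp > 0L], n)
    bw <- comp == which.max(sizes)
  }
  bw <- fill_holes(bw)
  m <- array(0L, dim = dim(v$data))
  m[bw] <- 1L
  as_labelmap(m, v$affine,
              label_table = data.frame(id = c(0L, 1L),
                                       role = c("background", "mask")))
}

#' Correct a multiplicative bias field
#'
#' Estimates a smooth multiplicative field in the log domain, adaptively to
#' contrast: in-mask log-intensities are provisionally classified into
#' `cfg$bias_classes` intensity classes (deterministic quantile-seeded
#' k-means), the residual of every voxel to its class mean is smoothed with
#' a Gaussian of FWHM `cfg$bias_fwhm_mm` (normalised convolution, so the
#' estimate extrapolates smoothly outside the mask), and classification and
#' estimation are alternated for `cfg$bias_iters` iterations. Removing the
#' class means before smoothing keeps tissue contrast out of the field
#' estimate. The field is normalised to mean 1 inside the mask — global
#' brightness is preserved — and divided out.
#'
#' @param v `hemi_volume` with non-negative intensities.
#' @param mask binary `hemi_labelmap` on the same grid.
#' @param cfg [preprocess_config()].
#' @return bias-corrected `hemi_volume`, with the estimated field attached
#'   as attribute `"bias_field"`.
#' @export
correct_bias_field <- function(v, mask, cfg = preprocess_config()) {
  m <- mask$data > 0
  if (!any(m)) stop("mask is empty")
  if (any(v$data < 0)) stop("negative intensities: bias model is multiplicative")
  sigma_vox <- fwhm_to_sigma(cfg$bias_fwhm_mm) / spacing(v)
  logi <- log(v$data + cfg$bias_epsilon)
  den <- pmax(gaussian_smooth3(m + 0, sigma_vox), 1e-10)
  field_log <- array(0, dim = dim(v$data))
  k <- min(cfg$bias_classes, length(unique(logi[m])))
  for (it in seq_len(cfg$bias_iters)) {
    xc <- logi[m] - field_log[m]
    if (k >= 2) {
      init <- class_center_init(xc, k)
      cl <- suppressWarnings(kmeans(xc, centers = matrix(init, ncol = 1),
                                    iter.max = 50))
      resid <- xc - cl$centers[cl$cluster, 1]
    } else resid <- xc - mean(xc)
    r <- array(0, dim = dim(v$data))
    r[m] <- resid
    field_log <- field_log + gaussian_smooth3(r, sigma_vox) / den
  }
  field <- exp(field_log)
  field <- field / mean(field[m])
  out <- as_volume(v$data / field, v$affine)
  attr(out, "bias_field") <- field
  out
}

#' Run the full preprocessing chain
#'
#' Applies, in order: reorientation to RAS+, background masking (voxels
#' outside the mask set to 0), isotropic resampling, and bias-field
#' correction. The chain is fully deterministic.
#'
#' @param v input `hemi_volume` in any orientation.
#' @param cfg [preprocess_config()].
#' @param target_spacing working voxel size in mm (default 0.3).
#' @param mask optional binary `hemi_labelmap` on the input grid, used when
#'   `cfg$mask_method == "provided_mask"`.
#' @return preprocessed `hemi_volume` on the isotropic RAS grid, with the
#'   resampled brain mask attached as attribute `"mask"`.
#' @export
run_preprocess <- function(v, cfg = preprocess_config(),
                           target_spacing = 0.3, mask = NULL) {
  v <- reorient_to_ras(v)
  m <- if (cfg$mask_method == "provided_mask") {
    if (is.null(mask)) stop("mask_method 'provided_mask' needs a mask")
    reorient_to_ras(mask)
  } else mask_background(v, cfg)
  v$data[m$data == 0L] <- 0
  v <- resample_isotropic(v, target_spacing)
  m <- resample_isotropic(m, target_spacing)
  out <- correct_bias_field(v, m, cfg)
  out$data[m$data == 0L] <- 0
  attr(out, "mask") <- m
  out
}
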