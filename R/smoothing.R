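# Separable Gaussian smoothing via per-axis dense kernel matrices. Rows are
# renormalised at the boundaries (zero-flux), which keeps a constant image
# exactly constant and supports kernels wider than the image — needed for
# bias fields whose smoothing scale rivals the field of view.

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

axis_kernel_matrix <- function(n, sigma_vox) {
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) dnorm(i - j, sd = sigma_vox))
  K / rowSums(K)
}

gaussian_smooth3 <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3)
  dm <- dim(arr)
  if (sigma_vox[1] > 1e-8) {
    K <- axis_kernel_matrix(dm[1], sigma_vox[1])
    arr <- array(K %*% matrix(arr, dm[1]), dim = dm)
  }
  if (sigma_vox[2] > 1e-8) {
    K <- axis_kernel_matrix(dm[2], sigma_vox[2])
    a2 <- aperm(arr, c(2, 1, 3))
    a2 <- array(K %*% matrix(a2, dm[2]), dim = dm[c(2, 1, 3)])
    arr <- aperm(a2, c(2, 1, 3))
  }
  if (sigma_vox[3] > 1e-8) {
    K <- axis_kernel_matrix(dm[3], sigma_vox[3])
    a3 <- aperm(arr, c(3, 1, 2))
    a3 <- array(K %*% matrix(a3, dm[3]), dim = dm[c(3, 1, 2)])
    arr <- aperm(a3, c(2, 3, 1))
  }
  arr
}

# squared Euclidean distance transform of a logical array; spacing in the
# units the distances should carry (mm or voxels)
edt_sq <- function(mask, spacing = c(1, 1, 1)) {
  dm <- dim(mask)
  d <- .edt_sq_cpp(as.logical(mask), as.integer(dm), as.numeric(spacing))
  array(d, dim = dm)
}

label_components <- function(mask) {
  dm <- dim(mask)
  lab <- .label_components_cpp(as.logical(mask), as.integer(dm))
  n <- attr(lab, "n_components")
  out <- array(as.integer(lab), dim = dm)
  attr(out, "n_components") <- n
  out
}
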