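# Shared fixtures and independent brute-force oracles. Oracles are written
# from the definitions (exhaustive enumeration, all-pairs distances, dense
# grid search) and never call the code paths they check.

small_phantom <- function(seed = 1, shape = 48, ...) {
  make_phantom_hemisphere(phantom_spec(shape = rep(shape, 3), seed = seed,
                                       ...))
}

# binary hemi_labelmap from a logical/integer array
as_mask <- function(arr, affine = diag(4)) {
  m <- array(as.integer(arr != 0), dim = dim(arr))
  as_labelmap(m, affine)
}

# axis-aligned affine with given spacing and world position of voxel 0
make_affine <- function(spacing, origin) {
  a <- diag(c(spacing, 1))
  a[1:3, 4] <- origin
  a
}

# --- 1-D k-means oracle: exhaustive search over contiguous partitions ----
# (the 1-D optimum is contiguous in sorted order)
bf_kmeans_1d <- function(x, k) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  cuts <- utils::combn(n - 1, k - 1)
  best <- NULL
  for (ci in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, ci], n)
    ssw <- 0
    assign_sorted <- integer(n)
    for (g in seq_len(k)) {
      seg <- xs[(b[g] + 1):b[g + 1]]
      ssw <- ssw + sum((seg - mean(seg))^2)
      assign_sorted[(b[g] + 1):b[g + 1]] <- g
    }
    if (is.null(best) || ssw < best$ssw) {
      assignment <- integer(n)
      assignment[ord] <- assign_sorted
      best <- list(ssw = ssw, assignment = assignment)
    }
  }
  best
}

# --- brute-force binary closing with a Euclidean ball (voxel units) ------
# out-of-grid positions are ignored for both dilation and erosion,
# matching the package's boundary convention
bf_ball_close <- function(mask, r_vox) {
  dm <- dim(mask)
  off <- as.matrix(expand.grid(-r_vox:r_vox, -r_vox:r_vox, -r_vox:r_vox))
  off <- off[rowSums(off^2) <= r_vox^2 + 1e-9, , drop = FALSE]
  shift_hits <- function(src) {
    hits <- array(FALSE, dim = dm)
    idx <- which(src, arr.ind = TRUE)
    for (r in seq_len(nrow(off))) {
      p <- sweep(idx, 2, off[r, ], `+`)
      ok <- p[, 1] >= 1 & p[, 1] <= dm[1] & p[, 2] >= 1 & p[, 2] <= dm[2] &
            p[, 3] >= 1 & p[, 3] <= dm[3]
      hits[p[ok, , drop = FALSE]] <- TRUE
    }
    hits
  }
  dil <- shift_hits(mask)
  # erosion: voxel survives unless some in-grid ball neighbour is outside dil
  ero <- dil & !shift_hits(!dil)
  ero
}

# --- all-pairs average Hausdorff distance oracle -------------------------
bf_ahd <- function(idxA, idxB, affine) {
  A <- t(affine[1:3, 1:3] %*% t(idxA - 1) + affine[1:3, 4])
  B <- t(affine[1:3, 1:3] %*% t(idxB - 1) + affine[1:3, 4])
  mind <- function(P, Q) vapply(seq_len(nrow(P)), function(i)
    sqrt(min((Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2 +
             (Q[, 3] - P[i, 3])^2)), numeric(1))
  (mean(mind(A, B)) + mean(mind(B, A))) / 2
}

# --- dense 1-D grid search over the mirror x-shift -----------------------
bf_mirror_shift <- function(mask, alpha, step = 0.01, pad = 2) {
  P <- hemilabel:::mask_world_coords(mask, 50000)
  x <- P[, 1]
  shifts <- seq(-max(x) - pad, -max(x) + pad, by = step)
  costs <- vapply(shifts, function(s) {
    xs <- x + s
    sum(xs[xs > 0]) - alpha * sum(xs)
  }, numeric(1))
  shifts[which.min(costs)]
}
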