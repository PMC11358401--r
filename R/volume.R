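#' Volume and label-map containers
#'
#' A `hemi_volume` is a 3-D scalar image: a numeric array plus a 4x4
#' voxel-to-world affine (mm, world axes RAS+, voxel indices 0-based in the
#' affine convention). A `hemi_labelmap` is the integer-valued counterpart
#' carrying a label table that records the role of every id: `0` is always
#' background, ids 1-5 are the manual hypothalamus subregions (anterior
#' superior/inferior, tuberal superior/inferior, posterior), 6-10 their
#' mirrored counterparts, and ids at or above the context offset (default
#' 100) are unsupervised context classes used only for image synthesis.
#'
#' @param data 3-D numeric (volume) or integer-valued (label map) array.
#' @param affine 4x4 voxel-to-world matrix; must be invertible.
#' @param label_table data.frame with columns `id` and `role`, or NULL to
#'   derive one from the ids present in `data`.
#' @return An object of class `hemi_volume` or `hemi_labelmap`.
#' @examples
#' v <- as_volume(array(rnorm(8^3), dim = c(8, 8, 8)), diag(4))
#' spacing(v)
#' @name volume-classes
NULL

SUBREGION_NAMES <- c("anterior_superior", "anterior_inferior",
                     "tuberal_superior", "tuberal_inferior", "posterior")

#' @rdname volume-classes
#' @export
as_volume <- function(data, affine = diag(4)) {
  check_geometry(data, affine)
  structure(list(data = data, affine = affine),
            class = c("hemi_volume", "hemi_image"))
}

#' @rdname volume-classes
#' @export
as_labelmap <- function(data, affine = diag(4), label_table = NULL) {
  check_geometry(data, affine)
  if (any(data < 0)) stop("label maps must be non-negative")
  if (max(abs(data - round(data))) > 0)
    stop("label maps must hold integer ids")
  storage.mode(data) <- "integer"
  if (is.null(label_table)) label_table <- default_label_table(data)
  miss <- setdiff(unique(as.vector(data)), label_table$id)
  if (length(miss) > 0)
    stop("ids present in data but absent from label_table: ",
         paste(miss, collapse = ", "))
  structure(list(data = data, affine = affine, label_table = label_table),
            class = c("hemi_labelmap", "hemi_image"))
}

check_geometry <- function(data, affine) {
  if (length(dim(data)) != 3L) stop("expected 3D image data")
  if (!is.matrix(affine) || !all(dim(affine) == c(4, 4)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  if (any(voxel_spacing(affine) <= 0))
    stop("voxel spacing must be strictly positive")
  invisible(TRUE)
}

default_label_table <- function(data, context_offset = 100L) {
  ids <- sort(unique(as.vector(data)))
  role <- vapply(ids, function(i) {
    if (i == 0) "background"
    else if (i >= 1 && i <= 5) SUBREGION_NAMES[i]
    else if (i >= 6 && i <= 10) paste0("mirrored_", SUBREGION_NAMES[i - 5])
    else if (i >= context_offset) paste0("context_", i - context_offset)
    else paste0("label_", i)
  }, character(1))
  data.frame(id = as.integer(ids), role = role, stringsAsFactors = FALSE)
}

merge_label_tables <- function(...) {
  tab <- do.call(rbind, list(...))
  tab <- tab[!duplicated(tab$id), , drop = FALSE]
  tab[order(tab$id), , drop = FALSE]
}

#' @export
is_labelmap <- function(x) inherits(x, "hemi_labelmap")

voxel_spacing <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

#' Voxel size of an image
#' @param v a `hemi_volume` or `hemi_labelmap`
#' @return numeric length-3 vector of per-axis voxel sizes in mm.
#' @export
spacing <- function(v) voxel_spacing(v$affine)

#' @export
print.hemi_image <- function(x, ...) {
  kind <- if (is_labelmap(x)) "label map" else "volume"
  cat(sprintf("<hemi %s> %s voxels, spacing %s mm\n", kind,
              paste(dim(x$data), collapse = " x "),
              paste(signif(spacing(x), 4), collapse = " x ")))
  cat("affine:\n"); print(signif(x$affine, 6))
  if (is_labelmap(x)) {
    ids <- x$label_table$id
    cat(sprintf("labels: %d ids (%s%s)\n", length(ids),
                paste(head(ids, 8), collapse = ", "),
                if (length(ids) > 8) ", ..." else ""))
  }
  invisible(x)
}

#' @export
plot.hemi_image <- function(x, axis = 3, slice = NULL, ...) {
  if (is.null(slice)) slice <- ceiling(dim(x$data)[axis] / 2)
  sl <- switch(axis, x$data[slice, , ], x$data[, slice, ], x$data[, , slice])
  graphics::image(sl, asp = 1, useRaster = TRUE,
                  col = grDevices::gray.colors(256), ...)
  invisible(x)
}

# world coordinates (mm) of 0-based voxel indices (m x 3 matrix)
voxels_to_world <- function(affine, ijk0) {
  ijk0 <- matrix(ijk0, ncol = 3)
  t(affine[1:3, 1:3] %*% t(ijk0) + affine[1:3, 4])
}

world_to_voxels <- function(affine, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(xyz) + inv[1:3, 4])
}

# 0-based index grid of an array, as an n x 3 matrix (x fastest)
index_grid0 <- function(dm) {
  cbind(rep.int(seq_len(dm[1]) - 1L, dm[2] * dm[3]),
        rep.int(rep(seq_len(dm[2]) - 1L, each = dm[1]), dm[3]),
        rep(seq_len(dm[3]) - 1L, each = dm[1] * dm[2]))
}

# TRUE when the affine is axis-aligned RAS+ (diagonal, positive scales)
is_ras_canonical <- function(affine, tol = 1e-6) {
  R <- affine[1:3, 1:3]
  off <- R; diag(off) <- 0
  all(diag(R) > 0) && max(abs(off)) <= tol * max(abs(diag(R)))
}

#' Read a NIfTI volume or label map
#'
#' Reads a 3-D NIfTI-1/NIfTI-2 file. The affine is taken from the sform when
#' set, otherwise the qform. Label maps are read without interpolation and
#' their integer ids are preserved exactly; non-integer data raise an error
#' rather than being rounded silently.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as_labels read as a `hemi_labelmap` (integer ids) instead of a
#'   `hemi_volume`.
#' @return `hemi_volume` or `hemi_labelmap`.
#' @export
read_volume <- function(path, as_labels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  dm <- dim(a)
  if (length(dm) == 4 && dm[4] == 1) { a <- a[, , , 1]; dm <- dim(a) }
  if (length(dm) != 3) stop("expected 3D image, got ", length(dm), "D: ", path)
  affine <- structure(RNifti::xform(img, useQuaternionFirst = FALSE),
                      imagedim = NULL, code = NULL)
  affine <- matrix(as.numeric(affine), 4, 4)
  if (as_labels) {
    if (max(abs(a - round(a))) > 0)
      stop("non-integer data cannot be read as labels: ", path)
    as_labelmap(a, affine)
  } else {
    as_volume(a, affine)
  }
}

#' Write a volume or label map to NIfTI
#'
#' Volumes are stored as float64, label maps as int32 (never floating
#' point). The affine is written as the sform (code 2); round-tripping
#' through [read_volume()] reproduces data and affine exactly.
#'
#' @param v `hemi_volume` or `hemi_labelmap`.
#' @param path output path (`.nii` or `.nii.gz`); parent must exist.
#' @export
write_volume <- function(v, path) {
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  if (file.exists(path)) message("overwriting ", path)
  img <- RNifti::asNifti(v$data)
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  dtype <- if (is_labelmap(v)) "int32" else "double"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Reorient an image to canonical RAS+
#'
#' Permutes and flips the voxel axes so axis 1 increases toward the
#' subject's Right, axis 2 toward Anterior and axis 3 toward Superior,
#' without moving any voxel in world space.
#'
#' @param v `hemi_volume` or `hemi_labelmap`.
#' @return same type, reoriented; the world coordinate of every voxel is
#'   unchanged.
#' @export
reorient_to_ras <- function(v) {
  R <- v$affine[1:3, 1:3]
  # dominant world axis of each voxel axis
  vox_for_world <- integer(3)
  flip <- logical(3)
  for (world in 1:3) {
    comp <- abs(R[world, ])
    j <- which.max(comp)
    if (sum(comp[-j] >= comp[j] - 1e-12) > 0)
      stop("oblique affine: world axis ", c("x", "y", "z")[world],
           " is not dominantly aligned with any voxel axis")
    vox_for_world[world] <- j
    flip[world] <- R[world, j] < 0
  }
  if (length(unique(vox_for_world)) != 3)
    stop("oblique affine: voxel axes do not map one-to-one onto world axes")
  dm <- dim(v$data)
  # index map: old_index = M %*% c(new_index, 1)
  M <- matrix(0, 4, 4); M[4, 4] <- 1
  for (world in 1:3) {
    j <- vox_for_world[world]
    if (flip[world]) {
      M[j, world] <- -1
      M[j, 4] <- dm[j] - 1
    } else M[j, world] <- 1
  }
  perm <- vox_for_world
  a <- aperm(v$data, perm)
  for (world in 1:3) if (flip[world]) {
    idx <- rev(seq_len(dim(a)[world]))
    a <- switch(world, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                a[, , idx, drop = FALSE])
  }
  affine <- v$affine %*% M
  rebuild(v, a, affine)
}

rebuild <- function(template, data, affine) {
  if (is_labelmap(template)) {
    storage.mode(data) <- "integer"
    as_labelmap(data, affine, label_table = template$label_table)
  } else as_volume(data, affine)
}

# world-space mirror x -> -x; exact on axis-aligned grids
mirror_x_grid <- function(v) {
  if (!is_ras_canonical(v$affine))
    stop("input must be in canonical RAS orientation; run reorient_to_ras() first")
  dm <- dim(v$data)
  dx <- v$affine[1, 1]
  a <- v$data[rev(seq_len(dm[1])), , , drop = FALSE]
  affine <- v$affine
  affine[1, 4] <- -(v$affine[1, 4] + (dm[1] - 1) * dx)
  rebuild(v, a, affine)
}

#' Left-right flip in world space
#'
#' Reverses the image along the left-right axis and updates the affine so
#' the anatomy occupies mirrored world-x positions (x -> -x). Used to turn
#' right hemispheres into left ones so a single model covers both.
#'
#' @param v `hemi_volume` or `hemi_labelmap` in canonical RAS orientation.
#' @return same type, mirrored about the world plane x = 0.
#' @export
left_right_flip <- function(v) mirror_x_grid(v)

#' Resample an image to an isotropic grid
#'
#' Intensities are resampled with trilinear interpolation, label maps with
#' nearest-neighbour so ids stay categorical. The output grid keeps the
#' input origin and covers the input field of view
#' (shape = ceiling(extent / target)).
#'
#' @param v `hemi_volume` or `hemi_labelmap` in canonical RAS orientation.
#' @param target_spacing isotropic voxel size in mm (default 0.3, the
#'   working resolution of the pipeline).
#' @return same type on the isotropic grid.
#' @export
resample_isotropic <- function(v, target_spacing = 0.3) {
  if (target_spacing <= 0) stop("target_spacing must be > 0")
  if (!is_ras_canonical(v$affine))
    stop("input must be in canonical RAS orientation; run reorient_to_ras() first")
  sp <- spacing(v)
  if (all(abs(sp - target_spacing) < 1e-9)) return(v)
  dm <- dim(v$data)
  new_dm <- as.integer(ceiling(dm * sp / target_spacing - 1e-9))
  affine <- diag(c(rep(target_spacing, 3), 1))
  affine[1:3, 4] <- v$affine[1:3, 4]
  ijk0 <- index_grid0(new_dm)
  # same origin, so old index = new index * target / spacing
  src <- sweep(ijk0, 2, target_spacing / sp, `*`)
  vals <- if (is_labelmap(v)) interp_nearest(v$data, src)
          else interp_trilinear(v$data, src)
  rebuild(v, array(vals, dim = new_dm), affine)
}
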