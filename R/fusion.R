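#' Fusion configuration
#'
#' @param closing_radius_mm radius of the spherical structuring element used
#'   to repair label-boundary inconsistencies (default 1.2 mm; at the 0.3 mm
#'   working resolution this is a 4-voxel ball).
#' @param structuring_element only `"sphere"` is supported.
#' @param precedence only `"manual_wins"` is supported: manual subregion
#'   labels always override context labels.
#' @return a `fusion_config` list.
#' @export
fusion_config <- function(closing_radius_mm = 1.2,
                          structuring_element = c("sphere"),
                          precedence = c("manual_wins")) {
  structuring_element <- match.arg(structuring_element)
  precedence <- match.arg(precedence)
  stopifnot(closing_radius_mm > 0)
  structure(list(closing_radius_mm = closing_radius_mm,
                 structuring_element = structuring_element,
                 precedence = precedence), class = "fusion_config")
}

same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) && max(abs(a$affine - b$affine)) <= tol
}

stop_unless_same_grid <- function(a, b) {
  if (!same_grid(a, b))
    stop("label maps are not on the same grid (shape/affine mismatch)")
}

#' Overlay manual subregion labels onto a context map
#'
#' Voxels carrying a manual subregion id (1-5) keep it; every other voxel
#' takes its context id; background stays 0.
#'
#' @param manual `hemi_labelmap` with ids in 0..5.
#' @param context `hemi_labelmap` with ids 0 or >= the context offset.
#' @param cfg [fusion_config()].
#' @return merged `hemi_labelmap`.
#' @export
merge_labels <- function(manual, context, cfg = fusion_config()) {
  stop_unless_same_grid(manual, context)
  mids <- setdiff(unique(as.vector(manual$data)), 0L)
  cids <- setdiff(unique(as.vector(context$data)), 0L)
  if (length(mids) > 0 && any(mids < 1 | mids > 5))
    stop("manual ids must lie in 1..5")
  if (length(cids) > 0 && any(cids <= 10))
    stop("context ids collide with the subregion id range 1..10")
  out <- context$data
  sel <- manual$data > 0L
  out[sel] <- manual$data[sel]
  as_labelmap(out, manual$affine,
              label_table = merge_label_tables(manual$label_table,
                                               context$label_table))
}

# binary closing with a discrete Euclidean ball of radius r_vox (voxels),
# via the exact distance transform: dilation keeps voxels within r of the
# set, erosion keeps voxels farther than r from the complement
ball_close <- function(mask, r_vox) {
  dil <- edt_sq(mask) <= r_vox^2 + 1e-9
  edt_sq(!dil) > r_vox^2 + 1e-9
}

#' Repair subregion boundaries with morphological closing
#'
#' Applies a closing (dilation then erosion) with a spherical structuring
#' element to the union hypothalamus mask (ids 1-5), filling small gaps and
#' inconsistent voxels at the interface with the context labels, e.g. along
#' the fornix and third-ventricle area. Voxels newly added by the closing
#' are assigned the subregion id of their nearest pre-existing hypothalamus
#' voxel (Euclidean distance; ties go to the lowest id). No voxel outside
#' the closed region changes.
#'
#' @param merged `hemi_labelmap` containing subregion ids 1-5.
#' @param cfg [fusion_config()]; the element radius in voxels is
#'   `round(closing_radius_mm / spacing)`.
#' @return refined `hemi_labelmap`.
#' @export
refine_with_closing <- function(merged, cfg = fusion_config()) {
  ids <- sort(intersect(unique(as.vector(merged$data)), 1:5))
  if (length(ids) == 0) stop("merged map contains no subregion ids 1..5")
  sp <- spacing(merged)
  r_vox <- round(cfg$closing_radius_mm / sp[1])
  if (r_vox < 1) {
    warning("closing radius below one voxel; using radius 1 voxel")
    r_vox <- 1
  }
  hypo <- merged$data %in% 1:5
  dim(hypo) <- dim(merged$data)
  closed <- ball_close(hypo, r_vox)
  newvox <- which(closed & !hypo)
  out <- merged$data
  if (length(newvox) > 0) {
    # nearest-subregion assignment, ascending id so ties take the lowest
    best_d <- rep(Inf, length(newvox))
    best_id <- integer(length(newvox))
    for (id in ids) {
      d2 <- edt_sq(merged$data == id)[newvox]
      take <- d2 < best_d - 1e-12
      best_d[take] <- d2[take]
      best_id[take] <- id
    }
    out[newvox] <- best_id
  }
  as_labelmap(out, merged$affine, label_table = merged$label_table)
}
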