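#' Dice coefficient between two segmentations
#'
#' `2 |A ∩ B| / (|A| + |B|)` where A and B are the voxel sets carrying any
#' id in `ids`. Two empty sets agree on absence and score 1; empty versus
#' non-empty scores 0.
#'
#' @param a,b `hemi_labelmap` on the same grid.
#' @param ids label ids defining the compared structure.
#' @return Dice overlap in [0, 1].
#' @export
dice_coefficient <- function(a, b, ids) {
  stop_unless_same_grid(a, b)
  A <- a$data %in% ids
  B <- b$data %in% ids
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0) return(1)
  2 * sum(A & B) / (na + nb)
}

#' Average Hausdorff distance between two segmentations
#'
#' The symmetric mean nearest-neighbour distance
#' `0.5 * (mean_{a in A} min_{b in B} d(a,b) + mean_{b in B} min_{a in A}
#' d(a,b))` between the voxel sets carrying any id in `ids`, with Euclidean
#' distances in world mm. All labeled voxels are used (not only surface
#' voxels); tools that use surface point sets will report different values.
#' Computed exactly via the Euclidean distance transform of each set.
#'
#' @param a,b `hemi_labelmap` on the same grid; both sets must be
#'   non-empty.
#' @param ids label ids defining the compared structure.
#' @return distance in mm; 0 iff the two voxel sets are identical.
#' @export
average_hausdorff_distance <- function(a, b, ids) {
  stop_unless_same_grid(a, b)
  A <- a$data %in% ids; dim(A) <- dim(a$data)
  B <- b$data %in% ids; dim(B) <- dim(b$data)
  if (!any(A) || !any(B))
    stop("average Hausdorff distance is undefined for empty voxel sets")
  sp <- spacing(a)
  dA <- sqrt(edt_sq(B, sp)[A])  # distance of each A voxel to B
  dB <- sqrt(edt_sq(A, sp)[B])
  (mean(dA) + mean(dB)) / 2
}

#' Agreement report over the standard subregion groups
#'
#' Dice and average Hausdorff distance between two subregion segmentations
#' for the groups used in intra-rater quality assessment: Whole (ids 1-5),
#' Anterior (anterior superior + inferior, ids 1-2), Tuberal (tuberal
#' superior + inferior, ids 3-4) and Posterior (id 5). Groups absent from
#' both maps are reported as missing (`NA`), not zero; a group present in
#' only one map has Dice 0 and an undefined (`NA`) distance.
#'
#' @param seg1,seg2 `hemi_labelmap` on the same grid.
#' @return data.frame with columns `group`, `dice`, `ahd_mm` (4 rows).
#' @export
intra_rater_report <- function(seg1, seg2) {
  stop_unless_same_grid(seg1, seg2)
  groups <- list(Whole = 1:5, Anterior = 1:2, Tuberal = 3:4, Posterior = 5)
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    in1 <- any(seg1$data %in% ids)
    in2 <- any(seg2$data %in% ids)
    if (!in1 && !in2) return(data.frame(group = g, dice = NA_real_,
                                        ahd_mm = NA_real_))
    dice <- dice_coefficient(seg1, seg2, ids)
    ahd <- if (in1 && in2) average_hausdorff_distance(seg1, seg2, ids)
           else NA_real_
    data.frame(group = g, dice = dice, ahd_mm = ahd)
  })
  do.call(rbind, rows)
}
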