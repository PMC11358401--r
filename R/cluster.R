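#' Context-set configuration
#'
#' Settings for the unsupervised context labeling of non-hypothalamic
#' tissue. One k-means label map is produced per k in `[k_min, k_max]`
#' (defaults 4..9, i.e. six maps per volume), purely to condition synthetic
#' image contrast — the clusters need not align with anatomy.
#'
#' @param k_min,k_max inclusive range of cluster counts (defaults 4 and 9).
#' @param seed base seed; the run for a given k uses `seed + k`.
#' @param context_id_offset ids are assigned as `offset + 1 .. offset + k`
#'   (default 100) so context ids never collide with subregion ids 1-10.
#' @return a `context_config` list.
#' @export
context_config <- function(k_min = 4, k_max = 9, seed = 1,
                           context_id_offset = 100) {
  stopifnot(k_min >= 2, k_min <= k_max, context_id_offset > 10)
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 seed = as.integer(seed),
                 context_id_offset = as.integer(context_id_offset)),
            class = "context_config")
}

# k-means++ seeding (Arthur & Vassilvitskii) on a 1-D feature
kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  d2 <- (x - centers[1])^2
  for (j in seq_len(k - 1) + 1) {
    p <- d2 / sum(d2)
    centers[j] <- x[sample.int(length(x), 1, prob = p)]
    d2 <- pmin(d2, (x - centers[j])^2)
  }
  centers
}

#' Cluster in-mask intensities into context labels
#'
#' Runs k-means on the (1-D) bias-corrected grayscale values inside the
#' brain mask. Initialisation is k-means++ with a fixed seed (best of three
#' restarts), so the output is reproducible. Cluster ids are assigned in
#' ascending order of cluster mean intensity: `offset + 1` is the darkest
#' tissue class.
#'
#' @param v `hemi_volume` (preprocessed intensities).
#' @param mask binary `hemi_labelmap` on the same grid.
#' @param k number of clusters (>= 2).
#' @param seed RNG seed for initialisation.
#' @param offset context id offset (default 100).
#' @return `hemi_labelmap` with in-mask ids `offset+1 .. offset+k`, 0
#'   outside the mask.
#' @export
cluster_intensities <- function(v, mask, k, seed = 1, offset = 100) {
  m <- mask$data > 0
  if (!any(m)) stop("mask is empty")
  if (k < 2) stop("k must be >= 2")
  x <- as.numeric(v$data[m])
  if (length(unique(x)) < k)
    stop("k = ", k, " exceeds the number of distinct in-mask intensities")
  best <- NULL
  for (r in 0:2) {
    set.seed(seed + 1000L * r)
    fit <- suppressWarnings(
      kmeans(x, centers = matrix(kmeanspp_centers(x, k), ncol = 1),
             iter.max = 100))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  ord <- order(best$centers[, 1])
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  lab <- array(0L, dim = dim(v$data))
  lab[m] <- as.integer(offset) + relabel[best$cluster]
  tab <- data.frame(id = c(0L, as.integer(offset) + seq_len(k)),
                    role = c("background", paste0("context_", seq_len(k))))
  out <- as_labelmap(lab, v$affine, label_table = tab)
  attr(out, "tot_withinss") <- best$tot.withinss
  out
}

#' Generate the full context label-map set
#'
#' One context map per k in `[k_min, k_max]`, in ascending k. With the
#' defaults this yields 6 maps per volume (so 60 for a 10-subject cohort).
#'
#' @param v `hemi_volume`.
#' @param mask binary `hemi_labelmap`.
#' @param cfg [context_config()].
#' @return list of `hemi_labelmap`, named `k4`, `k5`, ...
#' @export
generate_context_set <- function(v, mask, cfg = context_config()) {
  ks <- seq(cfg$k_min, cfg$k_max)
  out <- lapply(ks, function(k)
    cluster_intensities(v, mask, k, seed = cfg$seed + k,
                        offset = cfg$context_id_offset))
  names(out) <- paste0("k", ks)
  out
}
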