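#' Threshold a channel at a fraction below its global maximum
#'
#' Reproduces the particle caller's first stage: voxels are retained when
#' their intensity strictly exceeds a threshold set 0.1% (by default) below
#' the highest intensity of that channel's whole stack, i.e.
#' `I > (1 - fraction) * max(I)`. The threshold is relative, so the mask is
#' invariant to multiplying the channel by a positive constant.
#'
#' @param channel 3D (or 2D) non-negative intensity array.
#' @param fraction Relative offset below the maximum, in (0, 1).
#' @return A logical array of the same shape (class `binary_mask`), with the
#'   threshold recorded in attribute `"threshold"`.
#' @details A channel with no dynamic range (all voxels equal, including the
#'   all-zero case) has no peaks to call; an empty mask is returned with a
#'   warning.
#' @examples
#' ch <- array(0, c(4, 4, 2)); ch[2, 2, 1] <- 1000
#' sum(threshold_channel(ch))
#' @export
threshold_channel <- function(channel, fraction = 0.001) {
  if (!is.array(channel) || length(channel) == 0L)
    abort("`channel` must be a non-empty array.")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    abort("`fraction` must lie in (0, 1).")
  mx <- max(channel)
  if (mx <= 0 || mx == min(channel)) {
    warn("channel has no dynamic range; returning an empty mask.")
    mask <- array(FALSE, dim(channel))
    attr(mask, "threshold") <- NA_real_
    class(mask) <- c("binary_mask", class(mask))
    return(mask)
  }
  thr <- (1 - fraction) * mx
  mask <- channel > thr
  attr(mask, "threshold") <- thr
  class(mask) <- c("binary_mask", class(mask))
  mask
}

# neighbour offsets for a 3D connectivity scheme
connectivity_offsets <- function(connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6"  = rowSums(abs(off)) == 1L,
    "18" = rowSums(abs(off)) <= 2L,
    "26" = rep(TRUE, nrow(off)),
    abort("`connectivity` must be 6, 18 or 26.")
  )
  off[keep, , drop = FALSE]
}

#' Label 3D connected components of a logical mask
#'
#' Sparse union-find labelling over the set of TRUE voxels; suitable for the
#' few-bright-voxel masks produced by relative thresholding.
#'
#' @param mask Logical 3D array.
#' @param connectivity One of 6, 18, 26 (face / face+edge / full neighbour).
#' @return Integer array of the same shape: 0 for background, 1..k component
#'   labels in first-encounter order.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), is.array(mask), length(dim(mask)) == 3L)
  dims <- dim(mask)
  lin <- which(mask)
  lab <- array(0L, dims)
  k <- length(lin)
  if (k == 0L) {
    attr(lab, "n_components") <- 0L
    return(lab)
  }
  coord <- arrayInd(lin, dims)
  off <- connectivity_offsets(connectivity)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- function(m) (m[, 1] - 1) + (m[, 2] - 1) * dims[1] + (m[, 3] - 1) * dims[1] * dims[2]
  keys <- key(coord)
  for (o in seq_len(nrow(off))) {
    nb <- coord + matrix(off[o, ], k, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    j <- match(key(nb[ok, , drop = FALSE]), keys)
    src <- which(ok)[!is.na(j)]
    dst <- j[!is.na(j)]
    for (e in seq_along(src)) {
      a <- find(src[e]); b <- find(dst[e])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  lab[lin] <- match(roots, unique(roots))
  attr(lab, "n_components") <- length(unique(roots))
  lab
}

#' Coincidence particle detection across two thresholded channels
#'
#' Implements the caller's second stage: thresholded voxels of the two
#' channels are compared and only the overlapping ones (voxelwise AND) count
#' as BC particles. A particle is a 3D connected component of the coincident
#' mask (26-connectivity by default), which makes blobs present in only one
#' channel — autofluorescent confounders — impossible to count by
#' construction.
#'
#' @param mask_shg,mask_af Logical arrays of identical shape, typically from
#'   [threshold_channel()].
#' @param connectivity One of 6, 18, 26.
#' @return A list of class `particle_set`: `n_particles`, `voxels` (list of
#'   per-particle voxel index matrices), `centroids` (tibble with particle,
#'   x, y, z), and the coincident `mask`.
#' @examples
#' zs <- simulate_zstack_pair(4, 2, shape = c(32, 32, 16), seed = 7)
#' ps <- coincidence_particles(threshold_channel(zs$shg), threshold_channel(zs$af))
#' ps$n_particles
#' @export
coincidence_particles <- function(mask_shg, mask_af, connectivity = 26L) {
  if (!identical(dim(mask_shg), dim(mask_af)))
    abort("channel masks must have identical shapes.")
  both <- array(as.logical(mask_shg) & as.logical(mask_af), dim(mask_shg))
  lab <- label_components(both, connectivity)
  n <- attr(lab, "n_components")
  voxels <- vector("list", n)
  cent <- matrix(NA_real_, n, 3)
  if (n > 0L) {
    idx <- which(lab > 0L)
    co <- arrayInd(idx, dim(lab))
    l <- lab[idx]
    for (i in seq_len(n)) {
      m <- co[l == i, , drop = FALSE]
      colnames(m) <- c("x", "y", "z")
      voxels[[i]] <- m
      cent[i, ] <- colMeans(m)
    }
  }
  structure(list(n_particles = n,
                 voxels = voxels,
                 centroids = tibble(particle = seq_len(n),
                                    x = cent[, 1], y = cent[, 2], z = cent[, 3]),
                 mask = both),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat("<particle_set> ", x$n_particles, " particles (",
      sum(x$mask), " coincident voxels)\n", sep = "")
  invisible(x)
}

#' Count BC particles in a simulated or loaded z-stack pair
#'
#' Convenience wrapper chaining [threshold_channel()] on both channels and
#' [coincidence_particles()].
#'
#' @param zstack A `zstack_pair` (or list with `shg` and `af` arrays).
#' @inheritParams threshold_channel
#' @inheritParams coincidence_particles
#' @return A `particle_set`.
#' @export
detect_bc_particles <- function(zstack, fraction = 0.001, connectivity = 26L) {
  coincidence_particles(threshold_channel(zstack$shg, fraction),
                        threshold_channel(zstack$af, fraction),
                        connectivity)
}

#' Phylloplane BC load from per-stack particle counts
#'
#' Converts the average particle count over a sample's z-stacks into a
#' per-gram leaf load: the mean count is normalised to the imaging volume
#' (particles per um^3), scaled up to the full leaf-wash suspension volume
#' (1 mL = 1e12 um^3), and divided by the washed leaf mass. The suspension
#' volume is not part of the original description and must be supplied
#' explicitly; the simulator's default is 8 mL.
#'
#' @param counts Numeric vector of per-stack particle counts (one sample).
#' @param imaging_volume_um3 Imaging volume of one z-stack in um^3.
#' @param suspension_volume_ml Leaf-wash suspension volume in mL.
#' @param leaf_mass_g Washed leaf mass in grams.
#' @param sample_id Optional sample identifier.
#' @param reducer Summary over stacks; the field protocol averages
#'   (`"mean"`), `"median"` is available as an alternative.
#' @return One-row tibble: `sample_id`, `n_stacks`, `mean_count`,
#'   `imaging_volume_um3`, `suspension_volume_ml`, `leaf_mass_g`,
#'   `load_particles_per_g`.
#' @examples
#' bc_load(c(9, 10, 11, 10, 10), 425.1 * 425.1 * 35.1, 8, 2)
#' @export
bc_load <- function(counts, imaging_volume_um3, suspension_volume_ml,
                    leaf_mass_g, sample_id = NA_character_,
                    reducer = c("mean", "median")) {
  reducer <- match.arg(reducer)
  if (length(counts) == 0L || any(!is.finite(counts)) || any(counts < 0))
    abort("`counts` must be non-empty, finite and non-negative.")
  assert_scalar_number(imaging_volume_um3, "imaging_volume_um3", positive = TRUE)
  assert_scalar_number(suspension_volume_ml, "suspension_volume_ml", positive = TRUE)
  assert_scalar_number(leaf_mass_g, "leaf_mass_g", positive = TRUE)
  m <- if (reducer == "mean") mean(counts) else median(counts)
  load <- m / imaging_volume_um3 * (suspension_volume_ml * 1e12) / leaf_mass_g
  tibble(sample_id = sample_id,
         n_stacks = length(counts),
         mean_count = m,
         imaging_volume_um3 = imaging_volume_um3,
         suspension_volume_ml = suspension_volume_ml,
         leaf_mass_g = leaf_mass_g,
         load_particles_per_g = load)
}

#' Fold change of BC load between site categories
#'
#' Averages per-site mean loads within each BC-load category, then reports
#' the ratio of category means for every ordered category pair. With the
#' published site means this recovers the 2-7-fold contrast between
#' high- and low-load sites.
#'
#' @param site_loads Named numeric vector of per-site mean loads (any unit).
#' @param category_map Named character vector site -> category (defaults to
#'   the standard design's map).
#' @return Tibble with `category_num`, `category_den`, `mean_num`,
#'   `mean_den`, `fold_change`, one row per ordered pair of distinct
#'   categories.
#' @examples
#' loads <- c(HGa = 1.9, HGb = 1.7, HKa = 4.1, HKb = 4.4, DM = 0.6, DW = 0.7)
#' category_fold_change(loads)
#' @export
category_fold_change <- function(site_loads,
                                 category_map = study_design()$category_map) {
  if (is.null(names(site_loads)) || !all(names(site_loads) %in% names(category_map)))
    abort("`site_loads` must be named by sites present in `category_map`.")
  cats <- category_map[names(site_loads)]
  cat_means <- tapply(site_loads, cats, mean)
  if (any(cat_means <= 0))
    abort("category mean of zero: fold change undefined.")
  pairs <- expand.grid(category_num = names(cat_means),
                       category_den = names(cat_means),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$category_num != pairs$category_den, , drop = FALSE]
  tibble(category_num = pairs$category_num,
         category_den = pairs$category_den,
         mean_num = as.numeric(cat_means[pairs$category_num]),
         mean_den = as.numeric(cat_means[pairs$category_den]),
         fold_change = as.numeric(cat_means[pairs$category_num] /
                                    cat_means[pairs$category_den]))
}
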