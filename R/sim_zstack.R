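#' Simulate a two-channel z-stack with planted BC particles and confounders
#'
#' Generates a co-registered pair of 3D intensity arrays emulating the
#' two-channel acquisition used for BC particle detection: a narrow
#' second-harmonic generation (SHG) channel and a broad autofluorescence (AF)
#' channel. BC particles are small bright blobs present at the same voxels in
#' BOTH channels; autofluorescent confounders appear in the AF channel only.
#' Blobs have a 3D Gaussian intensity profile (default sigma = 1 voxel) and a
#' common, exact peak intensity of `snr` times the mean background level; the
#' blob profile is composited over the background with a voxelwise maximum
#' and background noise is clipped strictly below 0.999 x the blob peak, so
#' the stack-wide relative threshold of [threshold_channel()] isolates
#' exactly one voxel per planted blob. Blob centres are placed by rejection
#' sampling with a minimum Chebyshev separation.
#'
#' @param n_particles Number of coincident (two-channel) BC particles.
#' @param n_confounders Number of AF-only confounder blobs.
#' @param shape Integer vector `c(x, y, z)` of voxel dimensions.
#' @param snr Peak-to-background ratio of planted blobs (must exceed 1).
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @param sigma Gaussian blob sigma in voxels.
#' @param bg_mean,bg_sd Background noise mean and standard deviation
#'   (arbitrary intensity units; the detector is scale-invariant).
#' @param min_separation Minimum Chebyshev distance between blob centres, in
#'   voxels.
#' @param voxel_size Numeric `c(x, y, z)` voxel edge lengths in micrometres.
#'   The default mirrors a 425.1 x 425.1 x 35.1 um imaging volume at the
#'   default 64 x 64 x 35 voxel geometry (lateral extent much larger than
#'   axial, as in the instrument).
#' @param max_tries Rejection-sampling attempts per blob before erroring.
#' @return A list of class `zstack_pair` with elements `shg`, `af` (3D
#'   arrays), `voxel_size`, and `truth`, a list of class `planted_truth`
#'   holding `particle_centers`, `confounder_centers` (matrices with columns
#'   x, y, z) and `peak_intensity`.
#' @examples
#' zs <- simulate_zstack_pair(5, 3, shape = c(32, 32, 16), seed = 1)
#' dim(zs$shg)
#' nrow(zs$truth$particle_centers)
#' @export
simulate_zstack_pair <- function(n_particles,
                                 n_confounders = 0L,
                                 shape = c(64L, 64L, 35L),
                                 snr = 5,
                                 seed = NULL,
                                 sigma = 1,
                                 bg_mean = 10,
                                 bg_sd = 2,
                                 min_separation = 5L,
                                 voxel_size = c(425.1 / 64, 425.1 / 64, 35.1 / 35),
                                 max_tries = 200L) {
  if (n_particles < 0 || n_confounders < 0)
    abort("blob counts must be >= 0.")
  if (length(shape) != 3L || any(shape < 1))
    abort("`shape` must be three positive integers.")
  if (snr <= 1) abort("`snr` must exceed 1.")
  if (any(voxel_size <= 0)) abort("voxel sizes must be positive.")
  shape <- as.integer(shape)

  with_seed(seed, {
    peak <- snr * bg_mean
    # background: clipped Gaussian, bounded strictly below 0.999 * blob peak
    hi <- min(bg_mean + 4 * bg_sd, 0.995 * peak)
    bg1 <- pmin(pmax(array(rnorm(prod(shape), bg_mean, bg_sd), dim = shape), 0), hi)
    bg2 <- pmin(pmax(array(rnorm(prod(shape), bg_mean, bg_sd), dim = shape), 0), hi)

    centers <- place_blob_centers(n_particles + n_confounders, shape,
                                  min_separation, max_tries)
    p_idx <- seq_len(n_particles)
    part <- centers[p_idx, , drop = FALSE]
    conf <- centers[setdiff(seq_len(nrow(centers)), p_idx), , drop = FALSE]

    shg <- bg1
    af <- bg2
    for (i in seq_len(nrow(part))) {
      shg <- stamp_blob(shg, part[i, ], peak, sigma)
      af <- stamp_blob(af, part[i, ], peak, sigma)
    }
    for (i in seq_len(nrow(conf)))
      af <- stamp_blob(af, conf[i, ], peak, sigma)

    truth <- structure(list(particle_centers = part,
                            confounder_centers = conf,
                            peak_intensity = rep(peak, nrow(centers))),
                       class = "planted_truth")
    structure(list(shg = shg, af = af,
                   voxel_size = as.numeric(voxel_size),
                   truth = truth),
              class = "zstack_pair")
  })
}

# rejection-sample blob centres with a Chebyshev separation and a 2-voxel
# border margin; errors if the packing limit is hit
place_blob_centers <- function(n, shape, min_separation, max_tries) {
  centers <- matrix(integer(0), 0, 3, dimnames = list(NULL, c("x", "y", "z")))
  if (n == 0L) return(centers)
  margin <- 2L
  if (any(shape <= 2L * margin))
    abort("stack too small to place blobs with a border margin.")
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- vapply(1:3, function(d)
        sample.int(shape[d] - 2L * margin, 1L) + margin, integer(1))
      if (nrow(centers) == 0L ||
          min(apply(abs(sweep(centers, 2, cand)), 1, max)) >= min_separation) {
        centers <- rbind(centers, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      abort("could not place blobs without overlap: packing limit exceeded.",
            class = "phyllobc_packing_error")
  }
  rownames(centers) <- NULL
  colnames(centers) <- c("x", "y", "z")
  centers
}

# composite a Gaussian blob over an array with voxelwise max, so the centre
# voxel equals `peak` exactly
stamp_blob <- function(arr, center, peak, sigma) {
  r <- ceiling(3 * sigma)
  dims <- dim(arr)
  xs <- max(1L, center[1] - r):min(dims[1], center[1] + r)
  ys <- max(1L, center[2] - r):min(dims[2], center[2] + r)
  zs <- max(1L, center[3] - r):min(dims[3], center[3] + r)
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  dz2 <- (zs - center[3])^2
  prof <- peak * exp(-(outer(outer(dx2, dy2, "+"), dz2, "+")) / (2 * sigma^2))
  arr[xs, ys, zs] <- pmax(arr[xs, ys, zs], prof)
  arr
}

#' @export
print.zstack_pair <- function(x, ...) {
  cat("<zstack_pair> ", paste(dim(x$shg), collapse = " x "), " voxels, ",
      "voxel size ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " um\n", sep = "")
  cat("  planted: ", nrow(x$truth$particle_centers), " particles, ",
      nrow(x$truth$confounder_centers), " confounders\n", sep = "")
  invisible(x)
}

#' Imaging volume of a z-stack in cubic micrometres
#'
#' @param x A `zstack_pair` or a list with `shg` and `voxel_size`.
#' @return Volume in um^3.
#' @export
imaging_volume_um3 <- function(x) {
  prod(dim(x$shg) * x$voxel_size)
}
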