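# Independent oracles and tiny fixture builders, deliberately written with
# different algorithms than the package implementations.

# exhaustive voxel scan: returns logical array by looping every voxel
oracle_threshold <- function(channel, fraction = 0.001) {
  thr <- (1 - fraction) * max(channel)
  out <- array(FALSE, dim(channel))
  dims <- dim(channel)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3]))
      out[i, j, k] <- channel[i, j, k] > thr
  out
}

# brute-force component count via array flood fill with an explicit queue
oracle_flood_fill_count <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  if (connectivity == 18) off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  seen <- array(FALSE, dims)
  n <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (seen[v[1], v[2], v[3]]) next
    n <- n + 1L
    queue <- list(v)
    seen[v[1], v[2], v[3]] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(off))) {
        nb <- cur + off[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (mask[nb[1], nb[2], nb[3]] && !seen[nb[1], nb[2], nb[3]]) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  n
}

# all permutations of a vector, recursive (small n only)
oracle_permutations <- function(v) {
  if (length(v) <= 1L) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], oracle_permutations(v[-i])))
  out
}

# ANOSIM R computed independently (no shared code with the package)
oracle_anosim_r <- function(d, groups) {
  n <- nrow(d)
  pairs <- t(utils::combn(n, 2))
  dv <- d[pairs]
  r <- rank(dv)
  within <- groups[pairs[, 1]] == groups[pairs[, 2]]
  (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
}

# small ASV experiment built by hand
make_tiny_experiment <- function() {
  counts <- matrix(
    c(10, 5, 0, 2,
      0, 8, 3, 1,
      4, 4, 4, 4,
      100, 0, 0, 0,
      0, 0, 50, 50),
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("ASV_", 1:5), paste0("S", 1:4)))
  taxonomy <- tibble::tibble(
    taxon = paste0("ASV_", 1:5),
    kingdom = "Bacteria",
    phylum = c("P1", "P1", "P2", "Cyanobacteria", "P2"),
    class = c("C1", "C1", "C2", "Chloroplast", "C2"),
    order = c("O1", "O1", "O2", "Chloroplast", "O2"),
    family = c("F1", "F1", "F2", NA, "F2"),
    genus = c("G1", "G2", "G3", NA, "G3"))
  metadata <- tibble::tibble(
    sample_id = paste0("S", 1:4),
    site = c("HGa", "HGa", "DM", "DM"),
    round = c(1L, 2L, 1L, 2L),
    season = c("autumn", "winter", "autumn", "winter"),
    bc_category = c("bcM", "bcM", "bcL", "bcL"),
    leaf_mass_g = c(2, 2.2, 1.9, 2.1),
    suspension_volume_ml = 8)
  asv_experiment(counts, taxonomy, metadata)
}

# distance matrix from planted coordinates
euclid <- function(xy) as.matrix(dist(xy))
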