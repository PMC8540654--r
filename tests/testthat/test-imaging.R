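test_that("relative threshold keeps exactly the voxels above (1-f) x max", {
  ch <- array(0, c(4, 4, 2)); ch[2, 2, 1] <- 1000
  m <- threshold_channel(ch)
  expect_equal(sum(m), 1)
  expect_true(m[2, 2, 1])

  # constant image has no peaks: empty mask, with a warning
  const <- array(7, c(3, 3, 3))
  expect_warning(mc <- threshold_channel(const), "dynamic range")
  expect_equal(sum(mc), 0)

  # all-zero channel: empty mask with a warning
  expect_warning(m0 <- threshold_channel(array(0, c(3, 3, 2))))
  expect_equal(sum(m0), 0)

  # random integer stack vs exhaustive voxel-scan oracle
  set.seed(42)
  ch <- array(sample(0:255, 6 * 5 * 4, replace = TRUE), c(6, 5, 4))
  ch[3, 3, 2] <- 255 # ensure the max is 255
  m <- threshold_channel(ch)
  expect_identical(unclass(m)[seq_along(m)],
                   oracle_threshold(ch)[seq_along(m)])
  expect_identical(which(m), which(ch == 255))
})

test_that("growing the threshold fraction never shrinks the mask", {
  set.seed(7)
  ch <- array(runif(16^3), c(16, 16, 16))
  sizes <- vapply(c(0.0005, 0.001, 0.01, 0.1, 0.5),
                  function(f) sum(threshold_channel(ch, f)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("particle counts are invariant to positive intensity rescaling", {
  zs <- simulate_zstack_pair(6, 3, shape = c(40, 40, 16), seed = 5)
  n1 <- detect_bc_particles(zs)$n_particles
  zs$shg <- zs$shg * 37.5
  zs$af <- zs$af * 0.004
  expect_equal(detect_bc_particles(zs)$n_particles, n1)
})

test_that("coincidence AND rejects single-channel blobs by construction", {
  # empty second mask: zero particles
  m1 <- array(TRUE, c(4, 4, 2))
  m0 <- array(FALSE, c(4, 4, 2))
  expect_equal(coincidence_particles(m1, m0)$n_particles, 0)

  # identical single-voxel masks: one particle of one voxel
  a <- array(FALSE, c(5, 5, 3)); a[2, 3, 1] <- TRUE
  ps <- coincidence_particles(a, a)
  expect_equal(ps$n_particles, 1)
  expect_equal(nrow(ps$voxels[[1]]), 1)

  expect_error(coincidence_particles(a, array(FALSE, c(4, 4, 3))))

  # planted stacks: confounders never contribute
  for (seed in c(2, 12, 22)) {
    zs <- simulate_zstack_pair(10, 5, seed = seed)
    ps <- detect_bc_particles(zs)
    expect_equal(ps$n_particles, 10)
    conf <- zs$truth$confounder_centers
    for (i in seq_len(ps$n_particles)) {
      cen <- as.numeric(ps$centroids[i, c("x", "y", "z")])
      dd <- apply(abs(sweep(conf, 2, cen)), 1, max)
      expect_gt(min(dd), 1) # no detection at any confounder site
    }
  }
})

test_that("component labelling agrees with a brute-force flood fill", {
  set.seed(11)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:6) {
      mask <- array(runif(12^3) < 0.12, c(12, 12, 12))
      lab <- label_components(mask, conn)
      expect_equal(attr(lab, "n_components"),
                   oracle_flood_fill_count(mask, conn),
                   info = sprintf("conn=%d rep=%d", conn, rep))
      # labels partition exactly the TRUE voxels
      expect_identical(lab > 0, unclass(mask))
    }
  }
})

test_that("bc load arithmetic matches the hand-computed conversion", {
  vol <- 425.1 * 425.1 * 35.1
  rec <- bc_load(c(10, 10, 10, 10, 10), vol, 8, 2)
  expect_equal(rec$load_particles_per_g, 10 / vol * 8e12 / 2, tolerance = 1e-12)
  expect_equal(rec$load_particles_per_g, 6.306e6, tolerance = 1e-4)

  expect_equal(bc_load(c(0, 0, 0), vol, 8, 2)$load_particles_per_g, 0)

  # homogeneity: doubling mass halves the load
  r1 <- bc_load(c(3, 7), vol, 8, 1)$load_particles_per_g
  r2 <- bc_load(c(3, 7), vol, 8, 2)$load_particles_per_g
  expect_equal(r1, 2 * r2)

  expect_error(bc_load(c(1, 2), vol, 8, 0))
  expect_error(bc_load(numeric(0), vol, 8, 2))
})

test_that("category fold changes reproduce the published site-mean ratios", {
  loads <- setNames(reference_bc_loads()$mean_load, reference_bc_loads()$site)
  fc <- category_fold_change(loads)
  hl <- fc$fold_change[fc$category_num == "bcH" & fc$category_den == "bcL"]
  ml <- fc$fold_change[fc$category_num == "bcM" & fc$category_den == "bcL"]
  expect_equal(hl, 4.25 / 0.65, tolerance = 1e-12)
  expect_equal(ml, 1.8 / 0.65, tolerance = 1e-12)
  expect_gt(hl, 2); expect_lt(hl, 7)
  expect_gt(ml, 2); expect_lt(ml, 7)

  # equal category means give unit ratios
  eq <- category_fold_change(c(A = 2, B = 2),
                             category_map = c(A = "bcL", B = "bcH"))
  expect_true(all(eq$fold_change == 1))
  expect_error(category_fold_change(c(A = 0, B = 1),
                                    category_map = c(A = "bcL", B = "bcH")))
})
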