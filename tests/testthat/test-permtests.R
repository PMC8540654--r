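test_that("ANOSIM hits its closed-form extremes and matches vegan", {
  # perfect separation: every between distance above every within distance
  xy <- rbind(matrix(rnorm(10, 0, 0.01), 5), matrix(rnorm(10, 100, 0.01), 5))
  rownames(xy) <- paste0("s", 1:10)
  g <- rep(c("a", "b"), each = 5)
  fit <- anosim(euclid(xy), g, n_perm = 99, seed = 1)
  expect_equal(fit$statistic, 1, tolerance = 1e-12)
  expect_lte(fit$p_value, 0.05)

  # agreement with vegan's statistic on a generic instance
  set.seed(8)
  xy2 <- matrix(rnorm(36), 12, 3, dimnames = list(paste0("s", 1:12), NULL))
  g2 <- rep(c("a", "b", "c"), each = 4)
  ours <- anosim(euclid(xy2), g2, n_perm = 99, seed = 2)
  ref <- vegan::anosim(dist(xy2), g2, permutations = 0)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  # and with the independent rank-based oracle
  expect_equal(ours$statistic, oracle_anosim_r(euclid(xy2), g2),
               tolerance = 1e-12)
})

test_that("ANOSIM R averages to zero when labels carry no information", {
  set.seed(9)
  rs <- vapply(1:40, function(i) {
    xy <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
    anosim(euclid(xy), rep(c("a", "b"), each = 6), n_perm = 0)$statistic
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.08)
})

test_that("exact ANOSIM p equals full label-permutation enumeration", {
  set.seed(10)
  xy <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  d <- euclid(xy)
  g <- c("a", "a", "a", "b", "b", "b")
  fit <- anosim(d, g, exact = TRUE)
  perms <- oracle_permutations(g)
  stats <- apply(perms, 1, function(p) oracle_anosim_r(d, p))
  expect_equal(fit$p_value, mean(stats >= fit$statistic - 1e-12),
               tolerance = 1e-12)
  expect_error(anosim(d, c("a", "a", "a", "a", "a", "b")))
})

test_that("PERMANOVA pseudo-F equals classical one-way ANOVA F on Euclidean data", {
  set.seed(11)
  v <- c(rnorm(6), rnorm(7, 1.5), rnorm(5, -1))
  g <- rep(c("a", "b", "c"), c(6, 7, 5))
  d <- as.matrix(dist(v))
  dimnames(d) <- list(paste0("s", seq_along(v)), paste0("s", seq_along(v)))
  fit <- permanova(d, g, n_perm = 99, seed = 1)
  classical <- anova(aov(v ~ factor(g)))
  expect_equal(fit$statistic, classical$`F value`[1], tolerance = 1e-10)
  # effect size equals the classical R^2
  ss <- classical$`Sum Sq`
  expect_equal(fit$effect_size, ss[1] / sum(ss), tolerance = 1e-10)
  # agreement with vegan::adonis2 on the same distances
  ad <- vegan::adonis2(as.dist(d) ~ g, permutations = 2)
  expect_equal(fit$statistic, ad$F[1], tolerance = 1e-10)
  expect_equal(fit$effect_size, ad$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA R2 approaches 1 for tight, separated groups", {
  xy <- rbind(matrix(rnorm(10, 0, 1e-4), 5), matrix(rnorm(10, 10, 1e-4), 5))
  rownames(xy) <- paste0("s", 1:10)
  fit <- permanova(euclid(xy), rep(c("a", "b"), each = 5), n_perm = 99,
                   seed = 1)
  expect_gt(fit$effect_size, 0.999)
  expect_error(permanova(euclid(xy), rep("a", 10)))
})

test_that("permutation p-values include the observed statistic", {
  set.seed(12)
  xy <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("s", 1:8), NULL))
  g <- rep(c("a", "b"), each = 4)
  for (f in list(anosim, permanova)) {
    fit <- f(euclid(xy), g, n_perm = 19, seed = 5)
    expect_gte(fit$p_value, 1 / 20)
    expect_lte(fit$p_value, 1)
  }
  # tidy/glance carry the core fields
  fit <- anosim(euclid(xy), g, n_perm = 19, seed = 5)
  td <- tidy(fit)
  expect_named(td, c("method", "statistic", "statistic_name", "effect_size",
                     "p_value", "permutations"))
  expect_equal(td$permutations, 19)
})
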