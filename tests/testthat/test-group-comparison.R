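test_that("one-way F reduces to t-squared with two groups", {
  set.seed(19)
  df <- data.frame(v = c(rnorm(8), rnorm(8, 1)),
                   g = rep(c("a", "b"), each = 8))
  fit <- one_way_anova(df, "v", "g")
  tt <- t.test(v ~ g, data = df, var.equal = TRUE)
  expect_equal(fit$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$p_value, tt$p.value, tolerance = 1e-10)

  expect_error(one_way_anova(data.frame(v = rep(1, 6),
                                        g = rep(c("a", "b"), 3)), "v", "g"))
  expect_error(one_way_anova(data.frame(v = rnorm(3), g = c("a", "a", "b")),
                             "v", "g"))
})

test_that("one-way ANOVA is calibrated under the null and powered at 2 SD", {
  set.seed(20)
  ps <- vapply(1:200, function(i) {
    df <- data.frame(v = rnorm(30), g = rep(c("a", "b", "c"), each = 10))
    one_way_anova(df, "v", "g")$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  hits <- vapply(1:50, function(i) {
    df <- data.frame(v = c(rnorm(20), rnorm(20, 2)),
                     g = rep(c("a", "b"), each = 20))
    one_way_anova(df, "v", "g")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("pairwise corrections match hand-computed adjustments", {
  # BH step-up on p = (0.01, 0.02, 0.03, 0.04) over 4 pairs -> all 0.04
  raw <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(raw, "BH"), rep(0.04, 4))

  set.seed(21)
  df <- data.frame(v = rnorm(40), g = rep(letters[1:4], each = 10))
  bh <- pairwise_t_tests(df, "v", "g", correction = "bh")
  expect_equal(nrow(bh), 6)
  expect_equal(bh$p_adjusted,
               p.adjust(bh$p_value, "BH"), tolerance = 1e-12)
  bon <- pairwise_t_tests(df, "v", "g", correction = "bonferroni")
  expect_equal(bon$p_adjusted, pmin(1, bon$p_value * 6), tolerance = 1e-12)
  expect_true(all(bon$p_adjusted >= bon$p_value))

  # m = 1: correction is the identity
  df2 <- data.frame(v = rnorm(10), g = rep(c("a", "b"), each = 5))
  one <- pairwise_t_tests(df2, "v", "g", correction = "bonferroni")
  expect_equal(one$p_adjusted, one$p_value)

  expect_error(pairwise_t_tests(data.frame(v = rnorm(5), g = "a"), "v", "g"))
})

test_that("results are invariant to group label order", {
  set.seed(22)
  df <- data.frame(v = rnorm(30), g = rep(c("a", "b", "c"), each = 10))
  r1 <- pairwise_t_tests(df, "v", "g", correction = "bh")
  df2 <- df[rev(seq_len(nrow(df))), ]
  r2 <- pairwise_t_tests(df2, "v", "g", correction = "bh")
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("significance letters follow the fixed site-order convention", {
  sites <- c("HGa", "HGb", "HKa", "HKb", "DM", "DW")
  # no significant pairs: empty sets
  res <- tibble::tibble(group_a = "HGa", group_b = "HGb",
                        t_statistic = 0.1, df = 10, p_value = 0.9,
                        p_adjusted = 0.9, correction = "bh")
  sl <- significance_letters(res)
  expect_true(all(sl$differs_from == ""))

  # all pairs significant: each site lists the other five letters
  pr <- t(utils::combn(sites, 2))
  res2 <- tibble::tibble(group_a = pr[, 1], group_b = pr[, 2],
                         t_statistic = 5, df = 10, p_value = 1e-5,
                         p_adjusted = 1e-4, correction = "bh")
  sl2 <- significance_letters(res2)
  expect_true(all(sl2$n_significant == 5))
  expect_equal(sl2$letter, c("u", "v", "w", "x", "y", "z"))
  expect_equal(sl2$differs_from[sl2$site == "HGa"], "vwxyz")
})

test_that("category contrasts are detected on loads drawn at the field scale", {
  # per-site draws at the published means/SDs, n = 80 per site
  ref <- reference_bc_loads()
  set.seed(23)
  flagged <- vapply(1:20, function(i) {
    df <- purrr::map_dfr(seq_len(nrow(ref)), function(r)
      tibble::tibble(site = ref$site[r],
                     v = pmax(0, rnorm(80, ref$mean_load[r], ref$sd_load[r]))))
    res <- pairwise_t_tests(df, "v", "site", correction = "bh")
    hi_lo <- res$p_adjusted[(res$group_a %in% c("HKa", "HKb") &
                               res$group_b %in% c("DM", "DW")) |
                              (res$group_b %in% c("HKa", "HKb") &
                                 res$group_a %in% c("DM", "DW"))]
    all(hi_lo < 0.05)
  }, logical(1))
  expect_gte(mean(flagged), 0.95)
})
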