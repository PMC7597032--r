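test_that("pearson_r2 reproduces hand-computed and degenerate cases", {
  ex <- pearson_r2(1:5, 2 * (1:5) + 1)
  expect_equal(ex$r, 1)
  expect_equal(ex$r2, 1)
  # covariance/SD computed by hand: r = 3 / sqrt(5 * 5)
  hc <- pearson_r2(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(hc$r, 0.6, tolerance = 1e-12)
  expect_equal(hc$r2, 0.36, tolerance = 1e-12)
  expect_identical(pearson_r2(1:5, rep(2, 5))$flag, "degenerate")
  expect_identical(pearson_r2(1:2, 2:1)$flag, "insufficient")
  # pairwise deletion
  pd <- pearson_r2(c(1, 2, NA, 4, 5), c(2, 4, 9, NA, 10))
  expect_equal(pd$n, 3L)
})

test_that("pearson_r2 matches the definitional brute-force formulas", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- 0.4 * x + rnorm(n)
    got <- pearson_r2(x, y)
    ref <- brute_pearson(x, y)
    expect_equal(got$r, ref$r, tolerance = 1e-12)
    expect_equal(got$p, ref$p, tolerance = 1e-12)
  }
})

test_that("strength classes follow the 0.30 / 0.70 boundaries exactly", {
  expect_identical(classify_strength(c(0, 0.29, 0.30)),
                   c("weak", "weak", "weak"))
  expect_identical(classify_strength(c(0.300001, 0.5, 0.70)),
                   c("moderate", "moderate", "moderate"))
  expect_identical(classify_strength(c(0.700001, 0.77, 1)),
                   c("strong", "strong", "strong"))
  expect_true(is.na(classify_strength(NA_real_)))
  expect_error(classify_strength(1.2), "\\[0, 1\\]")
})

test_that("the pair design enumerates 1512 + 3486 + 66 correlations", {
  co <- make_cohort(seed = 3)
  for (g in c("ALL", "N", "D")) {
    res <- correlate_all(co$table, g)
    expect_equal(sum(res$category == "inter"), 1512L)     # 84 x 18
    expect_equal(sum(res$category == "intra3D"), 3486L)   # C(84, 2)
    expect_equal(sum(res$category == "intraLOAD"), 66L)   # C(12, 2)
    expect_equal(sum(res$category != "inter"), 3552L)
    expect_true(all(res$significant == (!is.na(res$p) & res$p < 0.05)))
    expect_true(all(abs(res$r2 - res$r^2) < 1e-12, na.rm = TRUE))
  }
  expect_error(correlate_all(co$table, "XX"), "no patients")
})

test_that("groups that are too small flag every pair as insufficient", {
  co <- make_cohort(default_cohort_spec(n = c(N = 2, D = 5), links = list()),
                    seed = 4)
  res <- correlate_all(co$table, "N")
  expect_true(all(res$flag == "insufficient"))
  expect_true(all(is.na(res$r)))
})

test_that("correlation results are invariant to variable-pair order", {
  set.seed(13)
  x <- rnorm(20); y <- rnorm(20)
  a <- pearson_r2(x, y)
  b <- pearson_r2(y, x)
  expect_equal(a$r, b$r)
  expect_equal(a$p, b$p)
})

test_that("group t-test matches the pooled-variance textbook formula", {
  # hand-calculated example: t = -12.247, df = 4
  small <- data.frame(group = c("N", "N", "N", "D", "D", "D"),
                      v = c(10, 11, 12, 20, 21, 22))
  gt <- group_ttest(small, "v")
  expect_equal(gt$t, -10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(gt$t, -12.2474, tolerance = 1e-4)
  expect_equal(gt$df, 4)
  same <- data.frame(group = rep(c("N", "D"), each = 3), v = rep(c(1, 2, 3), 2))
  st <- group_ttest(same, "v")
  expect_equal(st$t, 0)
  expect_equal(st$p, 1)
  # oracle equivalence on random draws, and the Welch option differs
  set.seed(19)
  for (i in 1:25) {
    d <- data.frame(group = rep(c("N", "D"), c(8, 11)),
                    v = c(rnorm(8, 1), rnorm(11, 0, 2)))
    got <- group_ttest(d, "v")
    ref <- brute_ttest(d$v[d$group == "N"], d$v[d$group == "D"])
    expect_equal(got$t, ref$t, tolerance = 1e-12)
    expect_equal(got$p, ref$p, tolerance = 1e-12)
    expect_equal(got$df, ref$df)
  }
  w <- group_ttest(d, "v", welch = TRUE)
  expect_false(isTRUE(all.equal(w$df, 17)))
  ins <- group_ttest(data.frame(group = c("N", "D"), v = c(1, 2)), "v")
  expect_identical(ins$flag, "insufficient")
})

test_that("family summaries count 180/180/180/180/240/48 LOAD pairs", {
  co <- make_cohort(seed = 6)
  res <- correlate_all(co$table, "ALL")
  s <- summarize_correlations(res)
  fam <- s$families
  expect_equal(fam$n_pairs[match(c("lateral_angles", "transverse_angles",
                                   "frontal_angles", "threeD_angles",
                                   "forefoot_heights", "midfoot_heights"),
                                 fam$family)],
               c(180L, 180L, 180L, 180L, 240L, 48L))
  expect_true(all(fam$n_sig <= fam$n_pairs))
  expect_equal(nrow(s$r2_significant), 1L)
  # with an impossibly small alpha nothing is significant
  res0 <- correlate_all(co$table, "ALL", alpha = 1e-12)
  s0 <- summarize_correlations(res0)
  expect_true(all(s0$families$n_sig == 0))
})

test_that("Benjamini-Hochberg shrinks the significant set monotonically", {
  co <- make_cohort(seed = 7)
  raw <- correlate_all(co$table, "ALL")
  bh <- correlate_all(co$table, "ALL", p_adjust = "BH")
  expect_lte(sum(bh$significant), sum(raw$significant))
  expect_true(all(which(bh$significant) %in% which(raw$significant)))
})
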