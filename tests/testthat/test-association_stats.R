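test_that("chi-square reproduces the printed subtype-association p-values", {
  # microsatellite status by miR subtype (2x3): printed p = 0.036
  msi <- rbind(MSS = c(24, 24, 31), MSI = c(3, 6, 0))
  res <- chi_square(msi)
  expect_equal(res$df, 2)
  expect_equal(round(res$p, 3), 0.036)
  # CMS single-sample-predictor labels incl. the NA row (5x3): printed 0.001
  ssp <- rbind(CMS1 = c(2, 8, 3), CMS2 = c(21, 16, 11), CMS3 = c(1, 0, 0),
               CMS4 = c(0, 3, 12), NAv = c(3, 3, 5))
  expect_equal(round(chi_square(ssp)$p, 3), 0.001)
  # mRNA-subtype table (5x3): printed "0.000", asserted as a bound
  vil <- rbind(c(22, 7, 6), c(2, 6, 4), c(1, 4, 17), c(2, 9, 3), c(0, 4, 1))
  expect_lt(chi_square(vil)$p, 0.001)
})

test_that("chi-square basic properties hold", {
  # table equal to its own expecteds -> statistic 0, p 1
  tab <- outer(c(10, 20), c(6, 9, 15)) / 30
  expect_true(all(tab == round(tab)))
  res <- chi_square(tab)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  # invariant to row/column permutation
  set.seed(111)
  t2 <- matrix(rpois(12, 10), 3, 4)
  r1 <- chi_square(t2)
  r2 <- chi_square(t2[sample(3), sample(4)])
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  # zero margin errors
  expect_error(chi_square(rbind(c(0, 0), c(3, 4))), "margin")
  # df = 2 closed form: upper tail p = exp(-x/2), to 1e-12
  msi <- rbind(c(24, 24, 31), c(3, 6, 0))
  res3 <- chi_square(msi)
  expect_equal(res3$p, exp(-res3$statistic / 2), tolerance = 1e-12)
})

test_that("fisher_exact matches full hypergeometric enumeration", {
  tab <- rbind(c(1, 9), c(11, 3))
  p <- fisher_exact(tab)
  expect_equal(p, 0.00276, tolerance = 1e-3)
  expect_equal(p, fisher_2x2_enumeration(tab), tolerance = 1e-9)
  set.seed(112)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 6), 2, 2) + 1
    expect_equal(fisher_exact(t2), fisher_2x2_enumeration(t2),
                 tolerance = 1e-9)
    # p >= the point probability of the observed table
    pt <- dhyper(t2[1, 1], sum(t2[, 1]), sum(t2[, 2]), sum(t2[1, ]))
    expect_gte(fisher_exact(t2) + 1e-12, pt)
  }
  # independence-structured table -> p = 1
  expect_equal(fisher_exact(rbind(c(4, 4), c(4, 4))), 1)
  expect_error(fisher_exact(matrix(50, 11, 11)), "too large|2x2")
})

test_that("fisher and chi-square agree on large association-bearing 2x2 tables", {
  # within the exact test's n <= 200 budget the two p-values only converge
  # where the tables carry signal; near the null the exact test stays up to
  # ~0.1 more conservative at these counts
  set.seed(113)
  kept <- 0
  while (kept < 10) {
    t2 <- rbind(rpois(2, c(55, 30)), rpois(2, c(30, 55))) + 5
    if (sum(t2) > 200) next
    kept <- kept + 1
    expect_lt(abs(fisher_exact(t2) - chi_square(t2)$p), 0.02)
  }
})

test_that("kruskal_wallis reproduces the hand example and matches kruskal.test", {
  res <- kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(res$statistic, 7.2, tolerance = 1e-12)
  expect_equal(res$p, 0.0273, tolerance = 1e-3)
  # tie correction equals the reference implementation
  set.seed(114)
  for (i in 1:10) {
    v <- sample(1:6, 30, replace = TRUE)   # heavy ties
    g <- rep(c("x", "y", "z"), each = 10)
    ref <- stats::kruskal.test(v, factor(g))
    got <- kruskal_wallis(v, g)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  # duplicating every observation preserves the ordering of H across datasets
  v1 <- c(1, 2, 3, 7, 8, 9); g1 <- rep(c("a", "b"), each = 3)
  v2 <- c(1, 5, 3, 4, 2, 6)
  h1 <- kruskal_wallis(v1, g1)$statistic
  h2 <- kruskal_wallis(v2, g1)$statistic
  h1d <- kruskal_wallis(rep(v1, 2), rep(g1, 2))$statistic
  h2d <- kruskal_wallis(rep(v2, 2), rep(g1, 2))$statistic
  expect_identical(h1 > h2, h1d > h2d)
  # identical values -> p = 1
  expect_equal(kruskal_wallis(rep(5, 9), rep(c("a", "b", "c"), 3))$p, 1)
})

test_that("kruskal_wallis p is uniform under label permutation", {
  set.seed(115)
  v <- rnorm(45)
  ps <- replicate(1000, {
    kruskal_wallis(v, sample(rep(c("a", "b", "c"), each = 15)))$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Mantel-Haenszel trend test detects monotone association only", {
  mono <- diag(10, 3)
  res <- mantel_haenszel_trend(mono)
  expect_lt(res$p, 0.001)
  # independence-structured table -> statistic ~ 0
  flat <- matrix(8, 3, 3)
  expect_equal(mantel_haenszel_trend(flat)$statistic, 0, tolerance = 1e-12)
  # affine rescaling of scores changes nothing
  set.seed(116)
  tab <- matrix(rpois(9, 10), 3, 3)
  a <- mantel_haenszel_trend(tab, row_scores = 1:3, col_scores = 1:3)
  b <- mantel_haenszel_trend(tab, row_scores = 2 * (1:3) + 7,
                             col_scores = -3 * (1:3) + 1)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  # row order matters (unlike plain chi-square)
  skewed <- rbind(c(12, 2, 1), c(5, 8, 5), c(1, 2, 12))
  s_ord <- mantel_haenszel_trend(skewed)$statistic
  s_perm <- mantel_haenszel_trend(skewed[c(2, 1, 3), ])$statistic
  expect_false(isTRUE(all.equal(s_ord, s_perm)))
  expect_error(mantel_haenszel_trend(matrix(1:3, 1)), "2")
})

test_that("association_report ties subtypes to annotation columns", {
  set.seed(117)
  labels <- setNames(rep(c("S1", "S2", "S3"), each = 20), sprintf("s%02d", 1:60))
  ann <- data.frame(sample_id = names(labels),
                    msi = ifelse(labels == "S2" & runif(60) < 0.6, "MSI", "MSS"),
                    stroma = rnorm(60, mean = c(S1 = 10, S2 = 15, S3 = 25)[labels]))
  rep <- association_report(labels, ann)
  expect_setequal(rep$variable, c("msi", "stroma"))
  expect_identical(rep$test[rep$variable == "msi"], "chi_square")
  expect_identical(rep$test[rep$variable == "stroma"], "kruskal_wallis")
  expect_lt(rep$p[rep$variable == "stroma"], 0.01)
})
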