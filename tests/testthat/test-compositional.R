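# CLR pipeline, diversity indices, ANOSIM and two-group comparison.

test_that("CLR matches the closed form and its rows sum to zero", {
  m <- matrix(c(0.5, 0.25, 0.25), 1, dimnames = list("s1", letters[1:3]))
  out <- clr_transform(m, gamma = 0)
  expect_equal(round(unclass(out)[1, ], 3),
               c(a = 0.462, b = -0.231, c = -0.231))
  set.seed(3)
  r <- matrix(rexp(60), 6, 10, dimnames = list(paste0("s", 1:6), paste0("f", 1:10)))
  expect_true(all(abs(rowSums(clr_transform(r, 0))) < 1e-9))
  # scale invariance: multiplying one raw sample by 10 changes nothing
  r2 <- r; r2[3, ] <- r2[3, ] * 10
  expect_equal(unclass(clr_transform(r, 0)), unclass(clr_transform(r2, 0)))
  # uniform composition maps to the zero vector
  u <- matrix(1 / 7, 1, 7, dimnames = list("s", paste0("f", 1:7)))
  expect_equal(max(abs(clr_transform(u, 0))), 0)
  expect_error(clr_transform(matrix(c(1, 0), 1, dimnames = list("s", c("a", "b"))), 0),
               "strictly positive")
})

test_that("gamma perturbation is a seeded per-row constant shift", {
  set.seed(8)
  r <- matrix(rexp(40), 4, 10, dimnames = list(paste0("s", 1:4), paste0("f", 1:10)))
  a <- clr_transform(r, gamma = 0.1, seed = 11)
  b <- clr_transform(r, gamma = 0.1, seed = 11)
  expect_identical(unclass(a), unclass(b))
  cc <- clr_transform(r, gamma = 0.1, seed = 12)
  base <- clr_transform(r, gamma = 0)
  dev <- unclass(cc) - unclass(base)
  expect_true(all(abs(dev - rowMeans(dev)) < 1e-12))  # constant within each row
  expect_false(identical(unclass(a), unclass(cc)))
})

test_that("winsorization clips tails without reordering; imputation stays in range", {
  set.seed(21)
  m <- matrix(rexp(200, 0.5), 20, 10, dimnames = list(paste0("s", 1:20), paste0("f", 1:10)))
  w <- winsorize(m, 0.1)
  for (j in 1:10) {
    o1 <- order(m[, j])
    expect_true(all(diff(w[o1, j]) >= 0))  # no rank inversions
    expect_lte(max(w[, j]), max(m[, j]))
    expect_gte(min(w[, j]), min(m[, j]))
  }
  m2 <- m; m2[sample(length(m2), 30)] <- 0; m2[sample(length(m2), 10)] <- NA
  imp <- impute_missing(m2, "half_min")
  expect_true(all(imp > 0))
  for (j in 1:10) expect_lte(max(imp[, j]), max(m2[, j], na.rm = TRUE))
  # forest mode is seeded and in range
  impf1 <- impute_missing(m2, "forest", seed = 5)
  impf2 <- impute_missing(m2, "forest", seed = 5)
  expect_identical(impf1, impf2)
  expect_true(all(impf1 > 0))
  expect_error(impute_missing(matrix(c(0, 0, 1, 2), 2,
                                     dimnames = list(NULL, c("x", "y"))), "half_min"),
               "missing in all samples")
})

test_that("preprocessing with no missing data, no winsorization, gamma 0 is plain CLR", {
  m <- matrix(c(50, 25, 25, 20, 30, 50), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  tab <- abundance_table(m, c("A", "B"), c(2, 7))
  out <- preprocess_abundance(tab, winsor_fraction = 0, gamma = 0)
  expect_equal(unclass(out), unclass(clr_transform(m / rowSums(m), 0)),
               ignore_attr = TRUE)
})

test_that("alpha diversity has its closed-form values and uniform maximizes Shannon", {
  u <- matrix(1, 1, 6, dimnames = list("s", paste0("f", 1:6)))
  expect_equal(unname(alpha_diversity(u, "shannon")), log(6))
  single <- matrix(c(1, 0, 0), 1, dimnames = list("s", c("a", "b", "c")))
  expect_equal(unname(alpha_diversity(single, "shannon")), 0)
  expect_equal(unname(alpha_diversity(single, "simpson")), 0)
  expect_equal(unname(alpha_diversity(single, "richness")), 1)
  h <- matrix(c(0.5, 0.5, 0), 1, dimnames = list("s", c("a", "b", "c")))
  expect_equal(unname(alpha_diversity(h, "shannon")), log(2))
  expect_equal(unname(alpha_diversity(h, "richness")), 2)
  set.seed(10)
  for (k in c(3, 8, 20)) {
    comps <- matrix(rexp(50 * k), 50, k,
                    dimnames = list(paste0("s", 1:50), paste0("f", 1:k)))
    expect_true(all(alpha_diversity(comps, "shannon") <= log(k) + 1e-12))
  }
  expect_error(alpha_diversity(matrix(0, 1, 3, dimnames = list("s", letters[1:3]))),
               "all-zero")
})

test_that("ANOSIM statistic matches the rank-formula oracle and R = 1 at full separation", {
  set.seed(14)
  x <- rbind(matrix(rnorm(12, 0), 4, 3), matrix(rnorm(12, 50), 4, 3))
  rownames(x) <- paste0("s", 1:8)
  grp <- rep(c("a", "b"), each = 4)
  d <- dist(x)
  res <- anosim_test(d, grp, n_permutations = 99, seed = 1)
  expect_equal(res$statistic, 1)
  expect_equal(res$statistic, anosim_R_oracle(d, grp))
  # rank-based: monotone transform of distances leaves R unchanged
  expect_equal(anosim_test(d^2, grp, n_permutations = 49, seed = 1)$statistic, 1)
  expect_error(anosim_test(d, c("a", rep("b", 7)), 49), "singleton")
})

test_that("Monte-Carlo ANOSIM p agrees with full enumeration for small n", {
  set.seed(33)
  x <- matrix(rnorm(7 * 3, mean = rep(c(0, 1.2), c(3, 4))), 7, 3)
  rownames(x) <- paste0("s", 1:7)
  grp <- rep(c("a", "b"), c(3, 4))
  d <- dist(x)
  exact <- anosim_exact_tail(d, grp)
  mc <- anosim_test(d, grp, n_permutations = 999, seed = 21)$p_value
  # Monte-Carlo estimate within 3 binomial standard errors of the exact tail
  se <- sqrt(exact * (1 - exact) / 999)
  expect_lt(abs(mc - exact), 3 * se + 2 / 999)
})

test_that("two fully separated groups of five give the exact two-tailed MWU p-value", {
  m <- matrix(c(1:5, 11:15), ncol = 1, dimnames = list(paste0("s", 1:10), "f"))
  res <- group_compare(m, rep(c("lo", "hi"), each = 5))
  expect_equal(res$p, 2 / choose(10, 5))
  expect_error(group_compare(m, rep(c("lo", "hi"), c(2, 8))), "at least 3")
})

test_that("two-stage BH q-values match an independent reference implementation", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216,
         0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569, 0.594, 0.696,
         0.762, 0.94, 0.942, 0.975, 0.986)
  # frozen expected values from an independent adaptive two-stage step-up
  expected <- c(0.024, 0.096, 0.2016, 0.2016, 0.2016, 0.24, 0.2537142857,
                0.4714285714, 0.4714285714, 0.4714285714, 0.4714285714,
                0.4714285714, 0.4714285714, 0.4714285714, 0.5115, 0.5115,
                0.5421176471, 0.7503157895, 0.7503157895, 0.8352,
                0.8708571429, 0.94656, 0.94656, 0.94656, 0.94656)
  expect_equal(two_stage_bh(p, alpha = 0.05), expected, tolerance = 1e-9)
})

test_that("two-stage BH reduces to plain BH without stage-one rejections and controls FDR", {
  p <- c(0.2, 0.5, 0.8, 0.9)
  expect_equal(two_stage_bh(p), p.adjust(p, "BH"))
  # q monotone in p
  set.seed(2)
  p2 <- runif(40)^2
  q2 <- two_stage_bh(p2)
  expect_true(all(diff(q2[order(p2)]) >= -1e-12))
  # empirical FDR <= 0.05 (within binomial CI) with 10% strong true effects
  set.seed(77)
  nsim <- 300
  fdp <- replicate(nsim, {
    m <- 50
    true <- seq_len(5)
    z <- rnorm(m); z[true] <- z[true] + 4.5
    p <- 2 * pnorm(abs(z), lower.tail = FALSE)
    rej <- which(two_stage_bh(p) < 0.05)
    if (!length(rej)) 0 else mean(!(rej %in% true))
  })
  fdr <- mean(fdp)
  expect_lte(fdr, 0.05 + 1.96 * sd(fdp) / sqrt(nsim))
})
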